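taxa4 <- c("Acidovorax", "Ralstonia", "Polaromonas", "Pseudomonas")
panel16 <- generate_16s_panel(taxa4, seed = 151)

test_that("reads matching a reference substring get its taxon", {
  reads <- c(r1 = substr(panel16[[1]], 201, 500),
             r2 = substr(panel16[[3]], 101, 400))
  cl <- classify_16s(reads, panel16)
  expect_identical(cl$taxon, c("Acidovorax", "Polaromonas"))
  expect_identical(cl$identity, c(1, 1))
  expect_error(classify_16s(reads, character()), "empty")
})

test_that("reads below the identity floor are unclassified", {
  set.seed(161)
  # degrade a fragment to ~90% identity
  frag <- strsplit(substr(panel16[[2]], 101, 400), "")[[1]]
  idx <- sample(300, 30)
  for (p in idx) frag[p] <- setdiff(c("A", "C", "G", "T"), frag[p])[1]
  cl <- classify_16s(c(bad = paste(frag, collapse = "")), panel16,
                     min_identity = 0.97)
  expect_identical(cl$taxon, "UNCLASSIFIED")
})

test_that("a best-identity tie between taxa is unclassified", {
  # two references identical except in a region the read avoids
  refs <- c("TaxA|x" = paste0(strrep("ACGT", 50), strrep("AAAA", 10)),
            "TaxB|y" = paste0(strrep("ACGT", 50), strrep("TTTT", 10)))
  cl <- classify_16s(c(r = strrep("ACGT", 20)), refs, min_identity = 0.9)
  expect_identical(cl$taxon, "UNCLASSIFIED")
})

test_that("with exact matching required the classifier is a lookup", {
  reads <- c(hit = substr(panel16[[4]], 301, 600))
  cl <- classify_16s(reads, panel16, min_identity = 1)
  expect_identical(cl$taxon, "Pseudomonas")
})

test_that("relative abundance sums to 100% of classified reads", {
  cl <- data.frame(read_id = paste0("r", 1:10),
                   taxon = c(rep("T1", 5), rep("T2", 4), "UNCLASSIFIED"),
                   stringsAsFactors = FALSE)
  ab <- relative_abundance(cl, "heavy_13C")
  expect_equal(sum(ab$abundance), 100, tolerance = 0.01)
  expect_equal(ab$abundance[ab$taxon == "T1"], 100 * 5 / 9)
  expect_identical(attr(ab, "unclassified"), 1L)
  # permutation invariance
  ab2 <- relative_abundance(cl[sample(10), ], "heavy_13C")
  expect_equal(ab2$abundance, ab$abundance)

  # all unclassified: counts zero, NA abundance, unclassified tallied
  cl0 <- data.frame(read_id = "r", taxon = "UNCLASSIFIED")
  ab0 <- relative_abundance(cl0, "light_12C", taxa = "T1")
  expect_true(all(is.na(ab0$abundance)))
  expect_identical(attr(ab0, "unclassified"), 1L)
})

test_that("abundance recovery matches truth within 3 binomial SE", {
  weights <- c(Acidovorax = 0.55, Ralstonia = 0.01, Polaromonas = 0.001,
               Pseudomonas = 0.439)
  refs <- setNames(as.character(panel16), names(weights))
  sim <- simulate_reads(refs, as.numeric(weights), 1500, seed = 171,
                        sub_rate = 0.01, indel_rate = 0.001)
  cl <- classify_16s(sim$reads, panel16)
  ab <- relative_abundance(cl, "heavy_13C", taxa = names(weights))
  n <- attr(ab, "n_classified")
  expect_gt(n, 1400) # nearly everything classifies at 1% error
  for (tx in names(weights)) {
    p <- weights[[tx]]
    se <- sqrt(p * (1 - p) / n) * 100
    expect_lt(abs(ab$abundance[ab$taxon == tx] - 100 * p), 3 * se + 1e-9)
  }
})

test_that("enrichment calls follow the ratio and abundance thresholds", {
  heavy <- data.frame(taxon = c("T1", "T2"), abundance = c(55, 10))
  light <- data.frame(taxon = c("T1", "T2"), abundance = c(0, 10))
  e <- call_enrichment(heavy, light)
  expect_true(e$enriched[e$taxon == "T1"]) # ratio bounded by pseudocount
  expect_false(e$enriched[e$taxon == "T2"]) # equal in both fractions
  expect_true(all(e$ratio > 0))
})

test_that("enrichment is monotone in heavy and antitone in light abundance", {
  ratio_of <- function(h, l) {
    call_enrichment(data.frame(taxon = "T", abundance = h),
                    data.frame(taxon = "T", abundance = l))$ratio
  }
  hs <- seq(0, 60, by = 10)
  expect_true(all(diff(vapply(hs, ratio_of, numeric(1), l = 5)) > 0))
  ls <- seq(0, 60, by = 10)
  expect_true(all(diff(vapply(ls, function(l) ratio_of(20, l),
                              numeric(1))) < 0))
})

test_that("one labelled taxon with zero leakage owns the heavy pool", {
  comm <- data.frame(taxon = taxa4,
                     abundance = c(0.2, 0.3, 0.25, 0.25),
                     labelled = c(TRUE, FALSE, FALSE, FALSE))
  pools <- simulate_sip_pools(comm, panel16, n_reads = 60, leakage = 0,
                              seed = 181)
  expect_true(all(pools$heavy$truth$template == "Acidovorax"))
  cl <- classify_16s(pools$heavy$reads, panel16)
  expect_true(all(cl$taxon %in% c("Acidovorax", "UNCLASSIFIED")))
})
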