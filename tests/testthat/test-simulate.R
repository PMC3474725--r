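test_that("generators are pure functions of their seed", {
  p1 <- generate_parent_pair(seed = 301)
  p2 <- generate_parent_pair(seed = 301)
  expect_identical(p1$parentA$seq, p2$parentA$seq)
  expect_identical(p1$parentB$seq, p2$parentB$seq)
  p3 <- generate_parent_pair(seed = 302)
  expect_false(identical(p1$parentA$seq, p3$parentA$seq))

  s1 <- simulate_reads(c(t = p1$parentA$seq), 1, 25, seed = 303)
  s2 <- simulate_reads(c(t = p1$parentA$seq), 1, 25, seed = 303)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero divergence gives identical parents; 10% is binomial", {
  layout <- data.frame(gene = "g", length = 10000L)
  p0 <- generate_parent_pair(layout, divergence = 0, seed = 311)
  expect_identical(p0$parentA$seq, p0$parentB$seq)

  p <- generate_parent_pair(layout, divergence = 0.1, seed = 312)
  d <- sum(strsplit(p$parentA$seq, "")[[1]] !=
             strsplit(p$parentB$seq, "")[[1]])
  expect_lt(abs(d - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_error(generate_parent_pair(layout, divergence = 0.5), "0.3")
})

test_that("a single-donor plan without novel sites copies parent A", {
  p <- generate_parent_pair(seed = 321)
  L <- nchar(p$parentA$seq)
  mos <- generate_mosaic(p, mosaic_plan("A", L, novel_rate = 0),
                         seed = 322)
  expect_identical(mos$operon$seq, p$parentA$seq)
  expect_identical(length(mos$truth$novel_sites), 0L)
  expect_error(generate_mosaic(p, mosaic_plan("A", L - 1, 0), 1), "sum")
  expect_error(mosaic_plan("A", 10, novel_rate = 0.3), "novel_rate")
})

test_that("attribution of a generated mosaic recovers the planted truth", {
  p <- generate_parent_pair(seed = 331)
  L <- nchar(p$parentA$seq)
  plan <- mosaic_plan(c("A", "B", "A"), c(3400L, 3400L, L - 6800L),
                      novel_rate = 0.005)
  mos <- generate_mosaic(p, plan, seed = 332)
  tr <- attribute_sites(mos$operon, p$parentA, p$parentB)

  # novel count is binomial around L * novel_rate
  nn <- length(mos$truth$novel_sites)
  expect_lt(abs(nn - L * 0.005), 3 * sqrt(L * 0.005 * 0.995))
  # planted novel sites are labelled NOVEL (a handful may fall inside
  # rare local alignment shifts, where a gap pair beats a mismatch run)
  expect_gte(mean(tr$labels[mos$truth$novel_sites] == "NOVEL"), 0.95)
  # informative non-novel sites carry their true donor: never the wrong
  # one; shift pockets may only dilute them to SHARED, and rarely
  pa <- strsplit(p$parentA$seq, "")[[1]]
  pb <- strsplit(p$parentB$seq, "")[[1]]
  informative <- which(pa != pb)
  informative <- setdiff(informative, mos$truth$novel_sites)
  want <- paste0(mos$truth$donor[informative], "_SPECIFIC")
  got <- tr$labels[informative]
  wrong <- paste0(ifelse(mos$truth$donor[informative] == "A", "B", "A"),
                  "_SPECIFIC")
  expect_false(any(got == wrong))
  expect_gte(mean(got == want), 0.97)
})

test_that("read lengths respect the model and clean reads are substrings", {
  tmpl <- c(t1 = rand_seq(2000))
  sim <- simulate_reads(tmpl, 1, 200, read_length_model(30, 530),
                        sub_rate = 0, indel_rate = 0, seed = 341)
  lens <- nchar(sim$reads)
  expect_true(all(lens >= 30 & lens <= 530))
  for (i in seq_len(50)) {
    rd <- sim$reads[[i]]
    tru <- sim$truth[i, ]
    frag <- substr(tmpl[[1]], tru$start, tru$end)
    expect_identical(if (tru$strand == "-") revcomp_r(rd) else rd, frag)
  }
  expect_error(read_length_model(10, 500), "min_len")
  expect_identical(length(simulate_reads(tmpl, 1, 0, seed = 1)$reads), 0L)
})

test_that("per-template read counts are multinomial around the weights", {
  tmpl <- c(a = rand_seq(1500), b = rand_seq(1500), c = rand_seq(1500))
  w <- c(0.6, 0.3, 0.1)
  sim <- simulate_reads(tmpl, w, 2000, seed = 351)
  cnt <- table(factor(sim$truth$template, levels = names(tmpl)))
  for (k in 1:3) {
    expect_lt(abs(cnt[[k]] - 2000 * w[k]),
              3 * sqrt(2000 * w[k] * (1 - w[k])))
  }
  expect_error(simulate_reads(tmpl, c(0.5, 0.5, 0.5), 10, seed = 1),
               "sum to 1")
})

test_that("SIP pools respect labelling, leakage bounds and truth files", {
  taxa <- c("X", "Y", "Z")
  refs <- generate_16s_panel(taxa, seed = 361)
  comm <- data.frame(taxon = taxa, abundance = c(0.2, 0.3, 0.5),
                     labelled = c(TRUE, FALSE, FALSE))
  pools <- simulate_sip_pools(comm, refs, n_reads = 50, leakage = 0,
                              seed = 362)
  expect_true(all(pools$heavy$truth$template == "X"))
  expect_identical(nrow(pools$light$truth), 50L)

  expect_error(simulate_sip_pools(comm, refs, leakage = 0.5, seed = 1),
               "leakage")
  comm$labelled <- FALSE
  expect_error(simulate_sip_pools(comm, refs, seed = 1), "labelled")
})

test_that("operon panel variants are pairwise diverged as configured", {
  panel <- generate_operon_panel(divergences = c(u = 0, v = 0.05,
                                                 w = 0.10),
                                 seed = 371)
  ham <- function(x, y) {
    mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  expect_lt(abs(ham(panel$u$seq, panel$v$seq) - 0.05), 0.01)
  # divergence from a shared ancestor compounds, minus coincidences
  expect_gt(ham(panel$v$seq, panel$w$seq), 0.10)
  expect_identical(panel$u$genes, panel$w$genes)
})
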