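# three mutually diverged variants shared by the recruitment tests
panel <- generate_operon_panel(data.frame(gene = c("g1", "g2"),
                                          length = c(600L, 600L)),
                               divergences = c(v1 = 0, v2 = 0.06,
                                               v3 = 0.12),
                               seed = 91)
vseqs <- vapply(panel, function(v) v$seq, character(1))

test_that("an exact substring of one variant is assigned to it", {
  read <- c(r1 = substr(vseqs[["v1"]], 301, 500))
  asg <- recruit_and_assign(read, vseqs)
  expect_identical(asg$status, "assigned")
  expect_identical(asg$variant, "v1")
  expect_identical(asg$best_identity, 1)
  expect_identical(asg$strand, "+")
  expect_identical(asg$t_start, 301L)
  expect_identical(asg$t_end, 500L)
  expect_error(recruit_and_assign(read, list()), "variant")
})

test_that("a read from a region identical across variants is ambiguous", {
  # two variants that share their first 300 bases exactly
  set.seed(101)
  common <- rand_seq(300)
  va <- paste0(common, rand_seq(300))
  vb <- paste0(common, rand_seq(300))
  asg <- recruit_and_assign(c(r = substr(va, 50, 249)),
                            c(va = va, vb = vb))
  expect_identical(asg$status, "ambiguous")
  expect_identical(asg$variant, "AMBIGUOUS")
  expect_identical(asg$best_identity, asg$second_identity)
})

test_that("junk reads are unrecruited and counts are conserved", {
  set.seed(111)
  reads <- c(good = substr(vseqs[["v2"]], 101, 350),
             junk1 = rand_seq(250), junk2 = rand_seq(250))
  asg <- recruit_and_assign(reads, vseqs)
  expect_identical(asg$status[1], "assigned")
  expect_true(all(asg$status[2:3] == "unrecruited"))
  ab <- operon_fractions(asg)
  expect_identical(ab$n_assigned + ab$ambiguous + ab$unrecruited,
                   nrow(asg))
})

test_that("raising the recruit threshold never recruits more reads", {
  sim <- simulate_reads(vseqs, c(0.4, 0.3, 0.3), 60, seed = 121,
                        sub_rate = 0.02, indel_rate = 0.002)
  recruited <- vapply(c(0.5, 0.8, 0.95, 0.999), function(thr) {
    asg <- recruit_and_assign(sim$reads, vseqs, recruit_min_identity = thr)
    sum(asg$status != "unrecruited")
  }, numeric(1))
  expect_true(all(diff(recruited) <= 0))
})

test_that("reverse-complementing every read leaves assignments unchanged", {
  sim <- simulate_reads(vseqs, c(0.4, 0.3, 0.3), 40, seed = 131)
  asg1 <- recruit_and_assign(sim$reads, vseqs)
  rc <- setNames(vapply(sim$reads, revcomp_r, character(1)),
                 names(sim$reads))
  asg2 <- recruit_and_assign(rc, vseqs)
  expect_identical(asg1$variant, asg2$variant)
  expect_identical(asg1$best_identity, asg2$best_identity)
  expect_identical(asg1$t_start, asg2$t_start)
  # strands flip
  expect_true(all(asg1$strand != asg2$strand))
})

test_that("assignment accuracy on clean mixtures is essentially perfect", {
  sim <- simulate_reads(vseqs, c(0.5, 0.25, 0.25), 400, seed = 141)
  asg <- recruit_and_assign(sim$reads, vseqs)
  m <- merge(asg[asg$status == "assigned", ], sim$truth, by = "read_id")
  expect_gte(mean(m$variant == m$template), 0.99)
})

test_that("operon fractions use assigned reads as denominator", {
  asg <- data.frame(
    read_id = paste0("r", 1:5),
    status = c("assigned", "assigned", "assigned", "assigned", "ambiguous"),
    variant = c("X", "X", "X", "Y", "AMBIGUOUS"),
    stringsAsFactors = FALSE)
  ab <- operon_fractions(asg)
  expect_equal(ab$abundance$fraction[ab$abundance$variant == "X"], 0.75)
  expect_equal(ab$abundance$fraction[ab$abundance$variant == "Y"], 0.25)
  expect_identical(ab$ambiguous, 1L)
  expect_equal(sum(ab$abundance$fraction), 1, tolerance = 1e-9)

  # single variant: fraction 1; permutation invariance
  one <- asg[asg$variant == "X", ]
  expect_equal(operon_fractions(one)$abundance$fraction, 1)
  perm <- asg[sample(nrow(asg)), ]
  expect_equal(operon_fractions(perm)$abundance,
               ab$abundance)

  # all ambiguous: zero denominator flagged as NA fractions
  amb <- asg[5, ]
  ab0 <- operon_fractions(amb, variant_labels = "X")
  expect_true(is.na(ab0$abundance$fraction))
  expect_identical(ab0$n_assigned, 0L)
})

test_that("linking reads must cover both genes by the minimum overlap", {
  v <- panel$v1
  junction <- v$genes$end[1] # g1|g2 boundary at 600
  spanning <- c(sp = substr(v$seq, junction - 49, junction + 50))
  inside <- c(ins = substr(v$seq, 101, 300))
  asg <- recruit_and_assign(c(spanning, inside), vseqs)
  expect_identical(find_linking_reads(asg, v, "g1", "g2", min_overlap = 20),
                   "sp")
  # 50 bases in each gene, so an overlap demand of 60 excludes it
  expect_identical(find_linking_reads(asg, v, "g1", "g2", min_overlap = 60),
                   character(0))
  expect_error(find_linking_reads(asg, v, "g1", "gX"), "not annotated")
})
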