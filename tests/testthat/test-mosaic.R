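test_that("attribution follows the per-site matching rule", {
  tr <- attribute_sites("ACGT", "ACGA", "TCGT")
  expect_identical(tr$labels,
                   c("A_SPECIFIC", "SHARED", "SHARED", "B_SPECIFIC"))

  # query identical to A, and B identical to A: everything shared
  tr2 <- attribute_sites("ACGTAC", "ACGTAC", "ACGTAC")
  expect_true(all(tr2$labels == "SHARED"))
  expect_identical(nrow(detect_segments(tr2)$segments), 0L)

  # a base differing from both parents is novel
  tr3 <- attribute_sites("AAGT", "ACGT", "ACGT")
  expect_identical(tr3$labels[2], "NOVEL")
  expect_error(attribute_sites("", "A", "A"), "empty")
})

test_that("parent swap exchanges A/B labels and preserves SHARED/NOVEL", {
  set.seed(71)
  for (i in 1:10) {
    q <- rand_seq(60); a <- rand_seq(60); b <- rand_seq(55)
    t1 <- attribute_sites(q, a, b)$labels
    t2 <- attribute_sites(q, b, a)$labels
    swapped <- ifelse(t2 == "A_SPECIFIC", "B_SPECIFIC",
               ifelse(t2 == "B_SPECIFIC", "A_SPECIFIC", t2))
    expect_identical(t1, swapped)
  }
})

test_that("label counts over any interval sum to the interval length", {
  trio <- tiny_operon_trio()
  tr <- attribute_sites(trio$mosaic$operon, trio$parents$parentA,
                        trio$parents$parentB)
  expect_identical(length(tr$labels), nchar(trio$mosaic$operon$seq))
  for (g in seq_len(nrow(trio$mosaic$operon$genes))) {
    gene <- trio$mosaic$operon$genes[g, ]
    rep <- summarize_gene(tr, gene)
    expect_equal(rep$pct_A_specific + rep$pct_B_specific + rep$pct_shared +
                   rep$pct_novel, 100, tolerance = 0.01)
  }
})

test_that("gene summaries match a direct count oracle on a built track", {
  # synthetic track: 80 A-specific, 10 shared, 5 B-specific, 5 novel
  labels <- c(rep("A_SPECIFIC", 80), rep("SHARED", 10),
              rep("B_SPECIFIC", 5), rep("NOVEL", 5))
  track <- structure(list(labels = labels, query = strrep("A", 100),
                          query_label = "q",
                          parent_labels = c(A = "a", B = "b")),
                     class = "site_attribution")
  rep <- summarize_gene(track, data.frame(gene = "g", start = 1, end = 100))
  expect_equal(rep$pct_A_specific, 80)
  expect_equal(rep$pct_B_specific, 5)
  expect_equal(rep$pct_shared, 10)
  expect_equal(rep$pct_novel, 5)
  expect_equal(rep$identity_to_A, 90)
  expect_equal(rep$identity_to_B, 15)
  expect_identical(rep$gene_call, "A_LIKE")

  # all shared: both identities 100, uninformative
  tr_sh <- structure(list(labels = rep("SHARED", 50)),
                     class = "site_attribution")
  rep2 <- summarize_gene(tr_sh, data.frame(gene = "g", start = 1, end = 50))
  expect_equal(rep2$identity_to_A, 100)
  expect_equal(rep2$identity_to_B, 100)
  expect_identical(rep2$gene_call, "UNINFORMATIVE")

  # balanced donors with long runs: mosaic
  tr_mo <- structure(list(labels = c(rep("A_SPECIFIC", 10),
                                     rep("B_SPECIFIC", 10))),
                     class = "site_attribution")
  rep3 <- summarize_gene(tr_mo, data.frame(gene = "g", start = 1, end = 20))
  expect_identical(rep3$gene_call, "MOSAIC")
  expect_error(summarize_gene(tr_mo,
                              data.frame(gene = "g", start = 1, end = 21)),
               "range")
})

test_that("segment detection finds runs, absorbs short runs, reports gaps", {
  mk <- function(labels) structure(list(labels = labels),
                                   class = "site_attribution")
  # all informative sites from one donor: one segment, no breakpoints
  s1 <- detect_segments(mk(rep("A_SPECIFIC", 8)), min_run = 3)
  expect_identical(nrow(s1$segments), 1L)
  expect_identical(s1$segments$donor, "A")
  expect_identical(nrow(s1$breakpoints), 0L)

  # AAAA BBBB: two segments, one breakpoint between sites 4 and 5
  s2 <- detect_segments(mk(c(rep("A_SPECIFIC", 4), rep("B_SPECIFIC", 4))),
                        min_run = 3)
  expect_identical(s2$segments$donor, c("A", "B"))
  expect_identical(s2$breakpoints$start, 5L)
  expect_identical(s2$breakpoints$end, 5L)

  # a short opposing run inside a long one is absorbed
  s3 <- detect_segments(mk(c(rep("A_SPECIFIC", 5), rep("B_SPECIFIC", 2),
                             rep("A_SPECIFIC", 5))), min_run = 3)
  expect_identical(nrow(s3$segments), 1L)
  expect_identical(s3$segments$donor, "A")
  expect_identical(s3$segments$n_informative_sites, 12L)

  # shared/novel positions interleaved do not break runs
  s4 <- detect_segments(mk(c("A_SPECIFIC", "SHARED", "A_SPECIFIC", "NOVEL",
                             "A_SPECIFIC", "B_SPECIFIC", "SHARED",
                             "B_SPECIFIC", "B_SPECIFIC")), min_run = 3)
  expect_identical(s4$segments$donor, c("A", "B"))
  # breakpoint interval spans the uninformative gap between the runs
  expect_identical(s4$breakpoints$start, 6L)
  expect_identical(s4$breakpoints$end, 6L)
})

test_that("query equal to parent A yields no B/novel labels, one segment", {
  set.seed(81)
  a <- rand_seq(400)
  b <- paste(substitute_chars <- {
    bc <- strsplit(a, "")[[1]]
    idx <- sample(400, 40)
    for (p in idx) bc[p] <- setdiff(c("A", "C", "G", "T"), bc[p])[1]
    bc
  }, collapse = "")
  tr <- attribute_sites(a, a, b)
  expect_false(any(tr$labels %in% c("B_SPECIFIC", "NOVEL")))
  seg <- detect_segments(tr)
  expect_lte(nrow(seg$segments), 1L)
  if (nrow(seg$segments) == 1L) expect_identical(seg$segments$donor, "A")
})

test_that("BED export is 0-based half-open with one record per label run", {
  tr <- structure(list(labels = c("SHARED", "SHARED", "A_SPECIFIC",
                                  "NOVEL"),
                       query_label = "q1"), class = "site_attribution")
  f <- withr::local_tempfile(fileext = ".bed")
  write_attribution_bed(tr, f)
  bed <- read.delim(f, header = FALSE)
  expect_identical(bed$V2, c(0L, 2L, 3L))
  expect_identical(bed$V3, c(2L, 3L, 4L))
  expect_identical(bed$V4, c("SHARED", "A_SPECIFIC", "NOVEL"))
  # 1-based inclusive <-> 0-based half-open conversion is bijective
  expect_identical(bed$V3 - bed$V2, c(2L, 1L, 1L))
})
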