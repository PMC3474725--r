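# Independent oracles used across the test suite.  Each one re-derives the
# quantity from first principles, by a different route than the package
# implementation (pure R, exhaustive where feasible).

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Score of one complete alignment path.  A path is a vector over
# {"M","X","Y"}: M consumes one base of each sequence, X one query base
# against a gap, Y one target base against a gap.  Gap runs are scored as
# gap_open + (len - 1) * gap_extend by scanning the path.
score_path <- function(path, a, b, sc) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  i <- 0; j <- 0; score <- 0; prev <- "S"
  for (mv in path) {
    if (mv == "M") {
      i <- i + 1; j <- j + 1
      score <- score + if (ac[i] == bc[j]) sc$match else sc$mismatch
    } else {
      if (mv == "X") i <- i + 1 else j <- j + 1
      score <- score + if (prev == mv) sc$gap_extend else sc$gap_open
    }
    prev <- mv
  }
  score
}

# Exhaustive enumeration of every alignment path (exponential; tiny inputs
# only).  Returns the best path score.
oracle_enumerate_score <- function(a, b, sc) {
  n <- nchar(a); m <- nchar(b)
  best <- -Inf
  recurse <- function(i, j, path) {
    if (i == n && j == m) {
      s <- score_path(path, a, b, sc)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, c(path, "M"))
    if (i < n) recurse(i + 1, j, c(path, "X"))
    if (j < m) recurse(i, j + 1, c(path, "Y"))
  }
  recurse(0, 0, character())
  best
}

# Memoized recursion on (query suffix, target suffix, preceding move),
# scoring gap runs from the definition.  Handles lengths up to ~hundreds.
oracle_memo_score <- function(a, b, sc) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  states <- c(S = 1, X = 2, Y = 3) # preceding move class for gap charging
  f <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    si <- states[[prev]]
    v <- memo[min(i, n + 1), min(j, m + 1), si]
    if (!is.na(v)) return(v)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ac[i] == bc[j]) sc$match else sc$mismatch
      best <- max(best, s + f(i + 1, j + 1, "S"))
    }
    if (i <= n) {
      g <- if (prev == "X") sc$gap_extend else sc$gap_open
      best <- max(best, g + f(i + 1, j, "X"))
    }
    if (j <= m) {
      g <- if (prev == "Y") sc$gap_extend else sc$gap_open
      best <- max(best, g + f(i, j + 1, "Y"))
    }
    memo[min(i, n + 1), min(j, m + 1), si] <<- best
    best
  }
  f(1, 1, "S")
}

# Biostrings global alignment score under the same gap-cost convention:
# ours charges gap_open + (L-1)*gap_extend for a gap of length L,
# pairwiseAlignment charges gapOpening + L*gapExtension.
biostrings_global_score <- function(a, b, sc) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = sc$match,
                                                  mismatch = sc$mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = -(sc$gap_open - sc$gap_extend),
    gapExtension = -sc$gap_extend, scoreOnly = TRUE)
}

# Per-position attribution rule, evaluated position by position with
# explicit branching (independent of the vectorized implementation).
oracle_attribution <- function(qseq, proj_a, proj_b) {
  qc <- strsplit(qseq, "")[[1]]
  out <- character(length(qc))
  for (p in seq_along(qc)) {
    ma <- !is.na(proj_a[p]) && proj_a[p] == qc[p] &&
      proj_a[p] != "-" && qc[p] != "N"
    mb <- !is.na(proj_b[p]) && proj_b[p] == qc[p] &&
      proj_b[p] != "-" && qc[p] != "N"
    out[p] <- if (ma && mb) "SHARED" else if (ma) "A_SPECIFIC"
      else if (mb) "B_SPECIFIC" else "NOVEL"
  }
  out
}

# IUPAC set per code, for the naive primer-site scan
iupac_set <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

# All primer sites on a template (forward orientation of the primer) by
# naive position-by-position scanning with IUPAC sets.
naive_primer_sites <- function(primer, template, max_mm) {
  pc <- strsplit(primer, "")[[1]]
  tc <- strsplit(template, "")[[1]]
  k <- length(pc)
  hits <- integer()
  mms <- integer()
  for (s in seq_len(length(tc) - k + 1)) {
    mm <- 0
    for (q in seq_len(k)) {
      if (!(tc[s + q - 1] %in% iupac_set[[pc[q]]])) mm <- mm + 1
      if (mm > max_mm) break
    }
    if (mm <= max_mm) { hits <- c(hits, s); mms <- c(mms, mm) }
  }
  data.frame(start = hits, mismatches = mms)
}

revcomp_r <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Naive amplicon scan (one template orientation)
naive_amplicons <- function(template, fwd, rev, max_mm, max_len) {
  fs <- naive_primer_sites(fwd, template, max_mm)
  rs <- naive_primer_sites(revcomp_r(rev), template, max_mm)
  lf <- nchar(fwd); lr <- nchar(rev)
  out <- list()
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    if (rs$start[j] < fs$start[i] + lf) next
    len <- rs$start[j] + lr - fs$start[i]
    if (len > max_len) next
    out[[length(out) + 1]] <- data.frame(start = fs$start[i],
                                         end = rs$start[j] + lr - 1,
                                         length = len)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  do.call(rbind, out)
}

# brute-force best ungapped offset of a read on a reference
brute_best_offset <- function(read, ref) {
  rc <- strsplit(read, "")[[1]]
  tc <- strsplit(ref, "")[[1]]
  L <- length(rc)
  scores <- vapply(seq_len(length(tc) - L + 1), function(s) {
    sum(rc == tc[s:(s + L - 1)])
  }, numeric(1))
  list(offset = which.max(scores), matches = max(scores),
       n_best = sum(scores == max(scores)))
}

# small annotated operon trio used by several tests
tiny_operon_trio <- function(seed = 7) {
  layout <- data.frame(gene = c("gA", "gB", "gC"),
                       length = c(120L, 150L, 130L))
  parents <- generate_parent_pair(layout, divergence = 0.12, seed = seed)
  plan <- mosaic_plan(c("A", "B"), c(200L, 200L), novel_rate = 0)
  mos <- generate_mosaic(parents, plan, seed = seed + 1)
  list(parents = parents, mosaic = mos, layout = layout)
}
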