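# Read recruitment and per-variant abundance.
#
# Every read is compared against every operon variant on both strands.
# Exact k-mer seeding locates the candidate reference window first
# (full-length dynamic programming of every read against every ~10 kb operon
# would be prohibitively slow and is unnecessary for collinear variants);
# the read is then semi-globally aligned inside the window and identity is
# measured over its aligned span.  Short references (<= `max_full_len`,
# e.g. 16S genes) fall back to full-length alignment when seeding finds no
# candidate, so divergent-but-related reads are never silently dropped.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Semi-global stats for a subset of reads, given per-read windows and
# diagonal bands (band 0 = full-window DP).
.window_align <- function(reads, idx, ref, ws, we, off, band, scoring, out) {
  if (length(idx) == 0L) return(out)
  m <- .cpp_semiglobal_batch(reads[idx], ref, ws[idx], we[idx],
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend,
                             off[idx], band[idx])
  out$identity[idx] <- ifelse(m[, "columns"] > 0,
                              m[, "matches"] / m[, "columns"], 0)
  out$score[idx] <- m[, "score"]
  out$t_start[idx] <- as.integer(m[, "t_start"])
  out$t_end[idx] <- as.integer(m[, "t_end"])
  out
}

# Best hit per read on one reference over both strands (tie -> forward).
# Seeding runs on both strands first and only the voted strand is aligned
# (both when votes tie); reads with no seed on either strand fall back to a
# full-length alignment when the reference is short, and score identity 0
# otherwise.
.read_ref_best <- function(reads, ref, scoring, k, stride, pad,
                           max_full_len) {
  n <- length(reads)
  empty <- data.frame(identity = numeric(n), score = rep(-Inf, n),
                      t_start = NA_integer_, t_end = NA_integer_)
  L <- nchar(ref)
  rc <- revcomp(reads)
  sf <- .cpp_seed_diagonals(reads, ref, k, stride)
  sr <- .cpp_seed_diagonals(rc, ref, k, stride)
  vf <- sf[, "votes"]; vr <- sr[, "votes"]
  rl <- nchar(reads)

  window <- function(seeds, full) {
    ws <- pmax(1L, seeds[, "diag"] + 1L - pad)
    we <- pmin(L, seeds[, "diag"] + rl + pad)
    off <- seeds[, "diag"] + 1L - ws # expected read-start column in window
    band <- rep.int(as.integer(pad), length(ws))
    ws[full] <- 1L; we[full] <- L; off[full] <- 0L; band[full] <- 0L
    list(ws = ws, we = we, off = off, band = band)
  }
  full_ok <- L <= max_full_len
  none <- vf == 0L & vr == 0L
  do_f <- (vf > 0L & vf >= vr) | (none & full_ok)
  do_r <- (vr > 0L & vr >= vf) | (none & full_ok)

  wf <- window(sf, none)
  fwd <- .window_align(reads, which(do_f), ref, wf$ws, wf$we, wf$off,
                       wf$band, scoring, empty)
  wr <- window(sr, none)
  rev <- .window_align(rc, which(do_r), ref, wr$ws, wr$we, wr$off,
                       wr$band, scoring, empty)

  take_rev <- rev$identity > fwd$identity
  out <- fwd
  out[take_rev, ] <- rev[take_rev, ]
  out$strand <- ifelse(take_rev, "-", "+")
  out
}

variant_seqs <- function(variants) {
  if (inherits(variants, "annotated_operon")) variants <- list(variants)
  if (is.character(variants)) {
    if (is.null(names(variants))) stop("variants must be named",
                                       call. = FALSE)
    return(as.list(variants))
  }
  seqs <- lapply(variants, as_seq, what = "variant")
  names(seqs) <- vapply(variants, seq_label, character(1L))
  seqs
}

#' Recruit reads and assign them to operon variants
#'
#' Each read is semi-globally aligned to every variant on both strands
#' (best strand kept, ties to forward). A read is `unrecruited` when its
#' best identity falls below `recruit_min_identity`; otherwise it is
#' `assigned` to the top variant when the identity lead over the runner-up
#' is at least `assign_margin`, else `ambiguous`.
#'
#' @param reads Named character vector of reads.
#' @param variants List of [annotated_operon()] objects (or named character
#'   vector), co-oriented.
#' @param recruit_min_identity Identity floor defining a recruited
#'   ("operon-related") read.
#' @param assign_margin Minimum identity lead (fraction) for a confident
#'   assignment.
#' @param scoring A [scoring_scheme()].
#' @param k,stride Seeding k-mer size and sampling stride along the read.
#' @param pad Window padding around the seeded diagonal, bases.
#' @param max_full_len References at most this long are aligned in full when
#'   seeding finds no window.
#' @return Data frame with one row per read: `read_id`, `status`
#'   (`assigned`/`ambiguous`/`unrecruited`), `variant` (assignment or the
#'   status marker), `best_variant`, `best_identity`, `second_identity`,
#'   `strand`, `t_start`, `t_end` (1-based inclusive span on the best
#'   variant).
#' @export
recruit_and_assign <- function(reads, variants, recruit_min_identity = 0.80,
                               assign_margin = 0.005,
                               scoring = scoring_scheme(), k = 13L,
                               stride = 7L, pad = 40L, max_full_len = 3000L) {
  seqs <- variant_seqs(variants)
  if (length(seqs) == 0L) stop("need at least one variant", call. = FALSE)
  if (length(reads) == 0L) {
    return(data.frame(read_id = character(), status = character(),
                      variant = character(), best_variant = character(),
                      best_identity = numeric(), second_identity = numeric(),
                      strand = character(), t_start = integer(),
                      t_end = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))

  hits <- lapply(seqs, function(ref) {
    .read_ref_best(reads, ref, scoring, k, stride, pad, max_full_len)
  })
  idm <- vapply(hits, function(h) h$identity, numeric(length(reads)))
  idm <- matrix(idm, nrow = length(reads),
                dimnames = list(NULL, names(seqs)))
  best_j <- max.col(idm, ties.method = "first")
  best_id <- idm[cbind(seq_along(reads), best_j)]
  second_id <- vapply(seq_along(reads), function(i) {
    if (ncol(idm) == 1L) 0 else max(idm[i, -best_j[i]])
  }, numeric(1L))

  status <- ifelse(best_id < recruit_min_identity, "unrecruited",
            ifelse(best_id - second_id >= assign_margin, "assigned",
                   "ambiguous"))
  best_variant <- colnames(idm)[best_j]
  bh <- do.call(rbind, lapply(seq_along(reads), function(i) {
    hits[[best_j[i]]][i, c("strand", "t_start", "t_end")]
  }))
  data.frame(read_id = names(reads), status = status,
             variant = ifelse(status == "assigned", best_variant,
                              toupper(status)),
             best_variant = best_variant,
             best_identity = best_id, second_identity = second_id,
             strand = bh$strand, t_start = bh$t_start, t_end = bh$t_end,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-variant read fractions
#'
#' Fractions are computed over confidently assigned reads only — the
#' denominator excludes ambiguous and unrecruited reads, which are tallied
#' separately (and reported, since published read fractions rarely state
#' their denominator).
#'
#' @param assignments Data frame from [recruit_and_assign()].
#' @param variant_labels Optional variant universe (so zero-count variants
#'   appear).
#' @return An `operon_abundance`: list with `abundance` (variant, count,
#'   fraction), `ambiguous`, `unrecruited`, `n_assigned`, `n_reads`.
#' @export
operon_fractions <- function(assignments, variant_labels = NULL) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  labs <- variant_labels %||% sort(unique(asg$variant))
  counts <- table(factor(asg$variant, levels = labs))
  n_assigned <- sum(counts)
  ab <- data.frame(variant = labs, count = as.integer(counts),
                   fraction = if (n_assigned > 0L) {
                     as.numeric(counts) / n_assigned
                   } else {
                     rep(NA_real_, length(labs)) # zero denominator, flagged
                   },
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(abundance = ab,
                 ambiguous = sum(assignments$status == "ambiguous"),
                 unrecruited = sum(assignments$status == "unrecruited"),
                 n_assigned = n_assigned,
                 n_reads = nrow(assignments)),
            class = "operon_abundance")
}

#' @export
print.operon_abundance <- function(x, ...) {
  cat(sprintf(paste0("<operon_abundance> %d reads: %d assigned, ",
                     "%d ambiguous, %d unrecruited\n"),
              x$n_reads, x$n_assigned, x$ambiguous, x$unrecruited))
  cat("fractions are of confidently assigned reads only\n")
  print(x$abundance, row.names = FALSE)
  invisible(x)
}

#' Find reads linking two genes of a variant
#'
#' Returns reads assigned to `variant` whose aligned span covers at least
#' `min_overlap` bases inside each of two gene intervals — evidence that the
#' genes are physically linked on one molecule.
#'
#' @param assignments Data frame from [recruit_and_assign()].
#' @param variant An [annotated_operon()].
#' @param gene1,gene2 Gene names on `variant`.
#' @param min_overlap Minimum bases covered inside each gene.
#' @return Character vector of read ids.
#' @export
find_linking_reads <- function(assignments, variant, gene1, gene2,
                               min_overlap = 20L) {
  g <- variant$genes
  for (gn in c(gene1, gene2)) {
    if (!gn %in% g$gene) stop("gene '", gn, "' is not annotated on variant '",
                              variant$label, "'", call. = FALSE)
  }
  g1 <- g[g$gene == gene1, ]; g2 <- g[g$gene == gene2, ]
  asg <- assignments[assignments$status == "assigned" &
                       assignments$variant == variant$label, , drop = FALSE]
  if (nrow(asg) == 0L) return(character())
  ov <- function(s, e, gs, ge) pmax(0L, pmin(e, ge) - pmax(s, gs) + 1L)
  keep <- ov(asg$t_start, asg$t_end, g1$start, g1$end) >= min_overlap &
    ov(asg$t_start, asg$t_end, g2$start, g2$end) >= min_overlap
  asg$read_id[keep]
}

#' Write read assignments as TSV
#'
#' @param assignments Data frame from [recruit_and_assign()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @export
write_assignments <- function(assignments, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(assignments, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
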