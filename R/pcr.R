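# In-silico PCR: IUPAC-aware primer matching and virtual amplification.
#
# The forward primer is matched on the forward strand and the reverse primer
# as its reverse complement downstream; both template orientations are
# scanned, so products defined on either strand are found.  IUPAC
# degeneracy codes in primers match any base of their set (Biostrings does
# the site matching; the amplification logic — pairing, orientation,
# product-length bound, read-set screening — is this module's).

primer_site_starts <- function(primer, template, max_mismatch) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(primer), template,
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE, fixed = "subject")
  st <- Biostrings::start(hits)
  if (length(st) == 0L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(primer), template,
                                    starting.at = st, fixed = "subject")
  data.frame(start = st, mismatches = as.integer(mm))
}

find_amplicons_one_strand <- function(template, primers, max_mismatch,
                                      max_product_len) {
  fwd_sites <- primer_site_starts(primers$fwd, template, max_mismatch)
  rc_rev <- revcomp(primers$rev)
  rev_sites <- primer_site_starts(rc_rev, template, max_mismatch)
  lf <- nchar(primers$fwd); lr <- nchar(rc_rev)
  out <- list()
  for (i in seq_len(nrow(fwd_sites))) {
    fs <- fwd_sites$start[i]
    for (j in seq_len(nrow(rev_sites))) {
      rs <- rev_sites$start[j]
      if (rs < fs + lf) next # primer footprints must not overlap
      len <- rs + lr - fs
      if (len > max_product_len) next
      out[[length(out) + 1L]] <- data.frame(
        start = fs, end = rs + lr - 1L, length = len,
        fwd_mismatches = fwd_sites$mismatches[i],
        rev_mismatches = rev_sites$mismatches[j])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer()))
  }
  do.call(rbind, out)
}

#' Find virtual PCR products of a primer pair on a template
#'
#' All (forward site, reverse site) pairings with product length at most
#' `max_product_len` and at most `max_mismatch` mismatches per primer are
#' returned, on both template orientations. Coordinates are 1-based
#' inclusive on the forward strand of the template and span both primer
#' footprints.
#'
#' @param template Template sequence (string, named string, or
#'   [annotated_operon()]).
#' @param primers A [primer_pair()].
#' @param max_mismatch Mismatches tolerated per primer (indels are not).
#' @param max_product_len Longest product considered, bases.
#' @return Data frame sorted by `start`: `template_id`, `start`, `end`,
#'   `length`, `strand`, `fwd_mismatches`, `rev_mismatches`.
#' @export
find_amplicons <- function(template, primers, max_mismatch = 0L,
                           max_product_len = 10000L) {
  stopifnot(inherits(primers, "primer_pair"))
  seq <- as_seq(template, "template")
  id <- seq_label(template, "template")
  tmpl <- Biostrings::DNAString(seq)
  L <- nchar(seq)

  plus <- find_amplicons_one_strand(tmpl, primers, max_mismatch,
                                    max_product_len)
  if (nrow(plus) > 0L) plus$strand <- "+"
  rc <- Biostrings::reverseComplement(tmpl)
  minus <- find_amplicons_one_strand(rc, primers, max_mismatch,
                                     max_product_len)
  if (nrow(minus) > 0L) {
    # map coordinates back to the forward strand
    s <- L - minus$end + 1L
    minus$end <- L - minus$start + 1L
    minus$start <- s
    minus$strand <- "-"
  }
  amps <- rbind(plus, minus)
  if (nrow(amps) == 0L) {
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      strand = character(), fwd_mismatches = integer(),
                      rev_mismatches = integer(), stringsAsFactors = FALSE))
  }
  amps$template_id <- id
  amps <- amps[order(amps$start, amps$end), c("template_id", "start", "end",
                                              "length", "strand",
                                              "fwd_mismatches",
                                              "rev_mismatches")]
  rownames(amps) <- NULL
  amps
}

#' Screen a read set with primer pairs
#'
#' A pair is `POSITIVE` when at least `min_hit_reads` reads contain a site
#' for either of its primers (single-primer evidence suffices: short
#' fragmented reads rarely span a whole product). A read-count proxy for a
#' gel's "strong product" band.
#'
#' @param reads Named character vector of reads.
#' @param primer_pairs List of [primer_pair()] objects.
#' @param max_mismatch Mismatches tolerated per primer site.
#' @param min_hit_reads Reads-with-site threshold for a positive call
#'   (`0` makes every pair trivially positive — a degenerate configuration).
#' @return Data frame per pair: `pair`, `fwd_hit_reads`, `rev_hit_reads`,
#'   `reads_with_hit`, `call`.
#' @export
screen_readset <- function(reads, primer_pairs, max_mismatch = 0L,
                           min_hit_reads = 5L) {
  if (inherits(primer_pairs, "primer_pair")) primer_pairs <- list(primer_pairs)
  if (length(reads) > 0L) {
    set <- Biostrings::DNAStringSet(reads)
    rcset <- Biostrings::reverseComplement(set)
  }
  count_hit_reads <- function(primer) {
    if (length(reads) == 0L) return(logical(0L))
    p <- Biostrings::DNAString(primer)
    n1 <- Biostrings::vcountPattern(p, set, max.mismatch = max_mismatch,
                                    fixed = "subject")
    n2 <- Biostrings::vcountPattern(p, rcset, max.mismatch = max_mismatch,
                                    fixed = "subject")
    n1 + n2 > 0L
  }
  rows <- lapply(primer_pairs, function(pp) {
    fh <- count_hit_reads(pp$fwd)
    rh <- count_hit_reads(pp$rev)
    n_any <- sum(fh | rh)
    data.frame(pair = pp$name, fwd_hit_reads = sum(fh),
               rev_hit_reads = sum(rh), reads_with_hit = n_any,
               call = if (n_any >= min_hit_reads) "POSITIVE" else "NEGATIVE",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
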