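# Parent-of-origin attribution of a mosaic operon.
#
# The query operon is globally aligned to each of two reference (parent)
# operons independently; both alignments are projected onto query
# coordinates, and every query position is labelled by which parent(s) it
# matches.  Positions where the parents disagree ("informative sites")
# identify the donor; maximal same-donor runs of informative sites become
# segments, and the intervals between consecutive segments are reported as
# recombination breakpoints.  This is the machine form of a three-colour
# alignment highlight: parent-A-specific, parent-B-specific, shared, novel.

ATTRIBUTION_LABELS <- c("A_SPECIFIC", "B_SPECIFIC", "SHARED", "NOVEL")

#' Attribute each query position to a parent of origin
#'
#' For each query position `p` with base `q`: the position matches a parent
#' iff the parent symbol aligned to `p` equals `q` (a gap or `N` never
#' matches). Labels: `A_SPECIFIC` (matches A only), `B_SPECIFIC` (matches B
#' only), `SHARED` (both), `NOVEL` (neither). A query position absent from a
#' parent (aligned to a gap) therefore counts against that parent.
#'
#' @param query The operon under study (string or [annotated_operon()]).
#' @param parentA,parentB Gap-free reference operons.
#' @param scoring A [scoring_scheme()] used for both global alignments.
#' @return A `site_attribution`: list with `labels` (character vector, one
#'   per query position), the two projections `proj_a`/`proj_b`, the two
#'   pairwise identities, and the input labels.
#' @export
attribute_sites <- function(query, parentA, parentB,
                            scoring = scoring_scheme()) {
  qseq <- as_seq(query, "query")
  aln_a <- align_global(query, parentA, scoring)
  aln_b <- align_global(query, parentB, scoring)
  proj_a <- project_alignment(aln_a)
  proj_b <- project_alignment(aln_b)
  qc <- strsplit(qseq, "", fixed = TRUE)[[1L]]
  ma <- proj_a$symbols == qc & qc != "N" & proj_a$symbols != "-"
  mb <- proj_b$symbols == qc & qc != "N" & proj_b$symbols != "-"
  labels <- ifelse(ma & mb, "SHARED",
            ifelse(ma, "A_SPECIFIC",
            ifelse(mb, "B_SPECIFIC", "NOVEL")))
  structure(list(
    labels = labels, query = qseq,
    proj_a = proj_a, proj_b = proj_b,
    identity_to_A = aln_a$identity, identity_to_B = aln_b$identity,
    query_label = seq_label(query, "query"),
    parent_labels = c(A = seq_label(parentA, "parentA"),
                      B = seq_label(parentB, "parentB"))),
    class = "site_attribution")
}

#' @export
print.site_attribution <- function(x, ...) {
  tab <- table(factor(x$labels, levels = ATTRIBUTION_LABELS))
  cat(sprintf("<site_attribution> %s vs A=%s, B=%s (%d positions)\n",
              x$query_label, x$parent_labels[["A"]], x$parent_labels[["B"]],
              length(x$labels)))
  print(tab)
  invisible(x)
}

# informative sites: positions where exactly one parent matches
informative_sites <- function(track) {
  keep <- track$labels %in% c("A_SPECIFIC", "B_SPECIFIC")
  data.frame(pos = which(keep),
             donor = ifelse(track$labels[keep] == "A_SPECIFIC", "A", "B"),
             stringsAsFactors = FALSE)
}

#' Summarize attribution over one gene interval
#'
#' Percentages of the gene length carrying each label, the two per-gene
#' identities (`identity_to_X` = % positions matching parent X =
#' `pct_X_specific + pct_shared`), and a categorical call:
#' `A_LIKE`/`B_LIKE` when one identity exceeds the other by `call_margin`
#' percentage points, otherwise `MOSAIC` when both donors contribute
#' informative runs of at least `min_run` sites, otherwise `NOVEL` when
#' `pct_novel` exceeds `novel_threshold`, else `UNINFORMATIVE`.
#'
#' @param track A `site_attribution` from [attribute_sites()].
#' @param gene A one-row gene interval (columns `gene`, `start`, `end`).
#' @param call_margin Identity margin, percentage points.
#' @param min_run Minimum informative-site run for a MOSAIC call.
#' @param novel_threshold Percent of gene length above which the gene is
#'   called NOVEL.
#' @return One-row data frame (gene, the four percentages, two identities,
#'   `gene_call`).
#' @export
summarize_gene <- function(track, gene, call_margin = 2, min_run = 3L,
                           novel_threshold = 5) {
  start <- as.integer(gene$start); end <- as.integer(gene$end)
  if (is.na(start) || start < 1L || end > length(track$labels) || start > end) {
    stop("gene interval out of range of the attribution track", call. = FALSE)
  }
  lab <- track$labels[start:end]
  len <- length(lab)
  cnt <- table(factor(lab, levels = ATTRIBUTION_LABELS))
  pct <- 100 * as.numeric(cnt) / len
  names(pct) <- ATTRIBUTION_LABELS
  id_a <- pct[["A_SPECIFIC"]] + pct[["SHARED"]]
  id_b <- pct[["B_SPECIFIC"]] + pct[["SHARED"]]

  inf <- lab[lab %in% c("A_SPECIFIC", "B_SPECIFIC")]
  runs <- if (length(inf) > 0L) rle(inf) else list(lengths = integer(),
                                                   values = character())
  has_a_run <- any(runs$lengths >= min_run & runs$values == "A_SPECIFIC")
  has_b_run <- any(runs$lengths >= min_run & runs$values == "B_SPECIFIC")

  call <- if (id_a - id_b >= call_margin) "A_LIKE"
    else if (id_b - id_a >= call_margin) "B_LIKE"
    else if (has_a_run && has_b_run) "MOSAIC"
    else if (pct[["NOVEL"]] > novel_threshold) "NOVEL"
    else "UNINFORMATIVE"

  data.frame(gene = as.character(gene$gene),
             pct_A_specific = pct[["A_SPECIFIC"]],
             pct_B_specific = pct[["B_SPECIFIC"]],
             pct_shared = pct[["SHARED"]],
             pct_novel = pct[["NOVEL"]],
             identity_to_A = id_a, identity_to_B = id_b,
             gene_call = call, stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize attribution for every gene of an operon
#'
#' @param track A `site_attribution`.
#' @param genes Gene-interval data frame (as in [annotated_operon()]).
#' @inheritParams summarize_gene
#' @return Data frame with one row per gene.
#' @export
summarize_genes <- function(track, genes, call_margin = 2, min_run = 3L,
                            novel_threshold = 5) {
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    summarize_gene(track, genes[i, , drop = FALSE], call_margin, min_run,
                   novel_threshold)
  }))
}

#' Call donor segments and recombination breakpoints
#'
#' Informative sites (A-/B-specific positions) are taken in order; maximal
#' same-donor runs of at least `min_run` sites become segments. Shorter runs
#' are absorbed into the flanking segment with more informative sites (ties
#' go to the preceding segment). Each breakpoint is the interval between the
#' last informative site of one segment and the first of the next — the true
#' switch position inside that interval is unidentifiable, so an interval,
#' not a point, is reported.
#'
#' @param track A `site_attribution`.
#' @param min_run Minimum informative-site run to found a segment.
#' @return List with `segments` (donor, start, end, n_informative_sites; the
#'   span runs from the first to the last informative site of the run) and
#'   `breakpoints` (start, end, 1-based inclusive intervals). Zero
#'   informative sites give empty tables.
#' @export
detect_segments <- function(track, min_run = 3L) {
  inf <- informative_sites(track)
  empty_seg <- data.frame(donor = character(), start = integer(),
                          end = integer(), n_informative_sites = integer(),
                          stringsAsFactors = FALSE)
  empty_bp <- data.frame(start = integer(), end = integer())
  if (nrow(inf) == 0L) return(list(segments = empty_seg,
                                   breakpoints = empty_bp))

  donors <- inf$donor
  repeat {
    runs <- rle(donors)
    if (length(runs$lengths) <= 1L) break
    small <- which(runs$lengths < min_run)
    if (length(small) == 0L) break
    k <- small[[1L]]
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    left_n <- if (k > 1L) runs$lengths[k - 1L] else -1L
    right_n <- if (k < length(runs$lengths)) runs$lengths[k + 1L] else -1L
    absorb_left <- left_n >= right_n # ties -> preceding segment
    new_donor <- if (absorb_left && k > 1L) runs$values[k - 1L]
      else runs$values[k + 1L]
    donors[starts[k]:ends[k]] <- new_donor
  }

  runs <- rle(donors)
  if (length(runs$lengths) == 1L && runs$lengths[[1L]] < min_run) {
    return(list(segments = empty_seg, breakpoints = empty_bp))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segments <- data.frame(
    donor = runs$values,
    start = inf$pos[starts], end = inf$pos[ends],
    n_informative_sites = runs$lengths, stringsAsFactors = FALSE)

  breakpoints <- if (nrow(segments) > 1L) {
    data.frame(start = segments$end[-nrow(segments)] + 1L,
               end = segments$start[-1L])
  } else {
    empty_bp
  }
  list(segments = segments, breakpoints = breakpoints)
}

#' Export an attribution track as BED
#'
#' One record per maximal same-label run; BED uses 0-based half-open
#' coordinates (the conversion happens here, at the format boundary).
#'
#' @param track A `site_attribution`.
#' @param path Output path.
#' @export
write_attribution_bed <- function(track, path) {
  runs <- rle(track$labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bed <- data.frame(chrom = track$query_label,
                    start = starts - 1L, # 0-based half-open
                    end = ends,
                    name = runs$values, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export a per-gene attribution report as TSV
#'
#' @param report Data frame from [summarize_genes()].
#' @param path Output path.
#' @param header Optional provenance comment lines (written prefixed
#'   with `#`).
#' @export
write_gene_report <- function(report, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
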