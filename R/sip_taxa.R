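# Nearest-reference 16S classification and heavy/light enrichment calling.
#
# In a SIP experiment the heavy (13C) DNA pool is drawn from organisms that
# incorporated the labelled substrate, plus some carry-over of unlabelled
# background DNA.  Classifying 16S reads from both pools against a small
# reference panel and comparing per-taxon relative abundance between pools
# operationalizes the "who ate the label" inference.  The classifier is a
# deliberate nearest-reference stand-in for a full taxonomic pipeline
# against a curated database: it assigns each read the taxon of its best
# reference, requiring a minimum identity.

# split "taxon|id" headers; a header without "|" is its own taxon
ref_taxa <- function(references) {
  sub("\\|.*$", "", names(references))
}

#' Classify 16S reads against a reference panel
#'
#' Each read is semi-globally aligned to every reference on both strands and
#' assigned the taxon of the best reference when identity reaches
#' `min_identity`. A read whose best identity is tied between references of
#' different taxa is `UNCLASSIFIED` (no evidence to choose).
#'
#' @param reads Named character vector of reads.
#' @param references Named character vector of 16S sequences; names are
#'   `"taxon|id"` (or bare taxon) labels.
#' @param min_identity Species-level identity floor (default 0.97, the
#'   conventional 16S species threshold).
#' @param scoring A [scoring_scheme()].
#' @param ... Seeding controls passed through ([recruit_and_assign()]
#'   parameters `k`, `stride`, `pad`, `max_full_len`).
#' @return Data frame: `read_id`, `taxon` (or `"UNCLASSIFIED"`), `identity`.
#' @export
classify_16s <- function(reads, references, min_identity = 0.97,
                         scoring = scoring_scheme(), ...) {
  if (length(references) == 0L) stop("empty reference panel", call. = FALSE)
  if (length(reads) == 0L) {
    return(data.frame(read_id = character(), taxon = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  dots <- list(...)
  k <- dots$k %||% 13L; stride <- dots$stride %||% 7L
  pad <- dots$pad %||% 40L; max_full_len <- dots$max_full_len %||% 1600L

  idm <- vapply(references, function(ref) {
    .read_ref_best(reads, normalize_seq(ref), scoring, k, stride, pad,
                   max_full_len)$identity
  }, numeric(length(reads)))
  idm <- matrix(idm, nrow = length(reads),
                dimnames = list(NULL, names(references)))
  taxa <- ref_taxa(references)

  best <- apply(idm, 1L, max)
  taxon <- vapply(seq_along(reads), function(i) {
    hit_taxa <- unique(taxa[idm[i, ] == best[i]])
    if (best[i] < min_identity || length(hit_taxa) > 1L) "UNCLASSIFIED"
    else hit_taxa
  }, character(1L))
  data.frame(read_id = names(reads), taxon = taxon, identity = best,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-taxon relative abundance in one fraction
#'
#' Abundance is `100 * taxon count / classified count` for the fraction; the
#' denominator is classified reads (not total reads), and the unclassified
#' count is carried in the result so the difference is visible.
#'
#' @param classifications Data frame from [classify_16s()].
#' @param fraction_label Fraction name, e.g. `"heavy_13C"` or `"light_12C"`.
#' @param taxa Optional taxon universe (zero-count taxa then appear).
#' @return A `taxon_abundance` data frame: `fraction`, `taxon`, `count`,
#'   `abundance` (percent), with attributes `unclassified` and
#'   `n_classified`.
#' @export
relative_abundance <- function(classifications, fraction_label,
                               taxa = NULL) {
  cl <- classifications[classifications$taxon != "UNCLASSIFIED", ,
                        drop = FALSE]
  labs <- taxa %||% sort(unique(cl$taxon))
  counts <- table(factor(cl$taxon, levels = labs))
  n <- sum(counts)
  out <- data.frame(fraction = fraction_label, taxon = labs,
                    count = as.integer(counts),
                    abundance = if (n > 0L) 100 * as.numeric(counts) / n
                                else rep(NA_real_, length(labs)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "unclassified") <- sum(classifications$taxon == "UNCLASSIFIED")
  attr(out, "n_classified") <- n
  class(out) <- c("taxon_abundance", "data.frame")
  out
}

#' Call heavy-fraction enrichment per taxon
#'
#' A taxon is enriched when its pseudocount-stabilized heavy/light abundance
#' ratio reaches `min_ratio` and its heavy abundance reaches
#' `min_heavy_abundance`. The thresholds are declared heuristics: published
#' SIP studies typically read enrichment off gels qualitatively.
#'
#' @param heavy,light `taxon_abundance` tables from the heavy (13C) and
#'   light (12C) pools, same taxon universe.
#' @param pseudocount Percentage points added to both abundances.
#' @param min_ratio Minimum heavy/light abundance ratio.
#' @param min_heavy_abundance Minimum heavy abundance, percent.
#' @return Data frame: `taxon`, `heavy_abundance`, `light_abundance`,
#'   `ratio`, `enriched`.
#' @export
call_enrichment <- function(heavy, light, pseudocount = 0.5, min_ratio = 5,
                            min_heavy_abundance = 1) {
  taxa <- union(heavy$taxon, light$taxon)
  h <- setNames(rep(0, length(taxa)), taxa)
  h[heavy$taxon] <- ifelse(is.na(heavy$abundance), 0, heavy$abundance)
  l <- setNames(rep(0, length(taxa)), taxa)
  l[light$taxon] <- ifelse(is.na(light$abundance), 0, light$abundance)
  ratio <- (h + pseudocount) / (l + pseudocount)
  data.frame(taxon = taxa, heavy_abundance = as.numeric(h),
             light_abundance = as.numeric(l), ratio = as.numeric(ratio),
             enriched = as.numeric(ratio) >= min_ratio &
               as.numeric(h) >= min_heavy_abundance,
             stringsAsFactors = FALSE, row.names = NULL)
}
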