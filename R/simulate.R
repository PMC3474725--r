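# Synthetic community generator.
#
# Produces every input the pipeline consumes — two diverged parent operons,
# a recombinant mosaic with known per-position donor truth, mixed
# pyrosequencing-style read sets (30-530 bp, substitution + single-base
# indel errors), and heavy/light 16S read pools with a labelled-taxon
# structure — so every stage is testable against ground truth without any
# external download.  Every generator is a pure function of its seed.

DNA_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute positions `pos` of a character-vector sequence with a uniformly
# chosen different base
substitute_bases <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

#' Default gene layout of a nag-type naphthalene catabolic operon
#'
#' Gene order follows the nag operon literature
#' (nagAa-G-H-Ab-Ac-Ad-B-F-C-Q-E-D); lengths are round stand-ins of
#' realistic magnitude, not the real gene lengths.
#'
#' @return Data frame `gene`, `length` (bp).
#' @export
default_gene_layout <- function() {
  data.frame(
    gene = c("nagAa", "nagG", "nagH", "nagAb", "nagAc", "nagAd",
             "nagB", "nagF", "nagC", "nagQ", "nagE", "nagD"),
    length = c(1500L, 1300L, 500L, 350L, 1350L, 600L,
               800L, 800L, 800L, 350L, 950L, 900L),
    stringsAsFactors = FALSE)
}

layout_to_genes <- function(gene_layout) {
  ends <- cumsum(gene_layout$length)
  data.frame(gene = gene_layout$gene, start = ends - gene_layout$length + 1L,
             end = ends, strand = "+", stringsAsFactors = FALSE)
}

#' Generate a pair of diverged parent operons
#'
#' Parent A is drawn uniformly over `{A,C,G,T}`; parent B substitutes each
#' base independently with its gene's divergence probability (to a uniformly
#' chosen different base). The parents share length and annotation, so
#' donor truth maps one-to-one onto mosaic coordinates.
#'
#' @param gene_layout Data frame `gene`, `length` (default
#'   [default_gene_layout()]).
#' @param divergence Per-gene substitution probability in `[0, 0.3]`; scalar
#'   or one value per gene.
#' @param seed Integer seed.
#' @param labels Operon labels for the two parents.
#' @return List with `parentA` and `parentB` ([annotated_operon()] objects).
#' @export
generate_parent_pair <- function(gene_layout = default_gene_layout(),
                                 divergence = 0.10, seed = 1L,
                                 labels = c("parentA", "parentB")) {
  div <- rep_len(divergence, nrow(gene_layout))
  if (any(div < 0 | div > 0.3)) {
    stop("divergence must lie in [0, 0.3]", call. = FALSE)
  }
  with_seed(seed, {
    total <- sum(gene_layout$length)
    a <- strsplit(rand_dna(total), "", fixed = TRUE)[[1L]]
    b <- a
    ends <- cumsum(gene_layout$length)
    starts <- ends - gene_layout$length + 1L
    for (g in seq_len(nrow(gene_layout))) {
      span <- starts[g]:ends[g]
      hit <- span[runif(length(span)) < div[g]]
      b <- substitute_bases(b, hit)
    }
    genes <- layout_to_genes(gene_layout)
    list(parentA = annotated_operon(labels[[1L]],
                                    paste(a, collapse = ""), genes),
         parentB = annotated_operon(labels[[2L]],
                                    paste(b, collapse = ""), genes))
  })
}

#' Generate a panel of mutually diverged operon variants
#'
#' One ancestral operon is drawn at random; each variant substitutes bases
#' independently at its own divergence. Pairwise divergence between two
#' variants is then approximately the sum of their divergences, so a panel
#' like `c(0, 0.05, 0.10)` yields variants that differ pairwise by at least
#' ~5% — every read position is variant-specific, which is what a read
#' mixture experiment needs for unambiguous assignment.
#'
#' @param gene_layout Data frame `gene`, `length`.
#' @param divergences Named numeric vector, one per variant; names become
#'   operon labels.
#' @param seed Integer seed.
#' @return Named list of [annotated_operon()] objects.
#' @export
generate_operon_panel <- function(gene_layout = default_gene_layout(),
                                  divergences = c(nag2 = 0, nagU2 = 0.05,
                                                  nagCJ2 = 0.10),
                                  seed = 1L) {
  if (is.null(names(divergences)) || any(!nzchar(names(divergences)))) {
    stop("divergences must be named by variant label", call. = FALSE)
  }
  if (any(divergences < 0 | divergences > 0.3)) {
    stop("divergences must lie in [0, 0.3]", call. = FALSE)
  }
  with_seed(seed, {
    total <- sum(gene_layout$length)
    genes <- layout_to_genes(gene_layout)
    anc <- strsplit(rand_dna(total), "", fixed = TRUE)[[1L]]
    out <- lapply(names(divergences), function(lbl) {
      hit <- which(runif(total) < divergences[[lbl]])
      annotated_operon(lbl, paste(substitute_bases(anc, hit),
                                  collapse = ""), genes)
    })
    names(out) <- names(divergences)
    out
  })
}

#' Plan a recombinant mosaic
#'
#' @param donors Character vector over `{"A","B"}`, one per segment.
#' @param lengths Segment lengths in bases (must sum to the parent length
#'   when the plan is executed).
#' @param novel_rate Per-base probability of a point mutation matching
#'   neither parent, `[0, 0.2)`.
#' @return A `mosaic_plan`.
#' @export
mosaic_plan <- function(donors, lengths, novel_rate = 0.005) {
  if (length(donors) != length(lengths) || !all(donors %in% c("A", "B"))) {
    stop("donors must be 'A'/'B', one per segment length", call. = FALSE)
  }
  if (novel_rate < 0 || novel_rate >= 0.2) {
    stop("novel_rate must lie in [0, 0.2)", call. = FALSE)
  }
  structure(list(donors = as.character(donors),
                 lengths = as.integer(lengths),
                 novel_rate = novel_rate), class = "mosaic_plan")
}

#' Generate a mosaic operon from two parents
#'
#' Each planned segment is copied from its donor parent; each position is
#' then independently mutated to a base differing from BOTH parents with
#' probability `novel_rate`. The returned truth records the donor of every
#' position and the novel-site list — sufficient to recompute every
#' downstream expected value.
#'
#' @param parents List with `parentA`/`parentB` from
#'   [generate_parent_pair()]; equal lengths required.
#' @param plan A [mosaic_plan()].
#' @param seed Integer seed.
#' @param label Label of the mosaic operon.
#' @return List: `operon` ([annotated_operon()]) and `truth` (list with
#'   `donor` per position, `novel_sites`, `breakpoints` — the first position
#'   of each new segment).
#' @export
generate_mosaic <- function(parents, plan, seed = 1L, label = "mosaic") {
  a <- strsplit(parents$parentA$seq, "", fixed = TRUE)[[1L]]
  b <- strsplit(parents$parentB$seq, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("parents must have equal length (substitution-only divergence)",
         call. = FALSE)
  }
  if (sum(plan$lengths) != length(a)) {
    stop("plan segment lengths must sum to the parent length (",
         length(a), ")", call. = FALSE)
  }
  with_seed(seed, {
    donor <- rep(plan$donors, plan$lengths)
    mosaic <- ifelse(donor == "A", a, b)
    hit <- which(runif(length(mosaic)) < plan$novel_rate)
    for (p in hit) {
      choices <- setdiff(DNA_BASES, c(a[p], b[p]))
      mosaic[p] <- sample(choices, 1L)
    }
    seg_starts <- cumsum(c(1L, utils::head(plan$lengths, -1L)))
    truth <- list(donor = donor, novel_sites = hit,
                  breakpoints = seg_starts[-1L], plan = plan)
    list(operon = annotated_operon(label, paste(mosaic, collapse = ""),
                                   parents$parentA$genes),
         truth = truth)
  })
}

#' Read length model
#'
#' @param min_len,max_len Length bounds in bases (pyrosequencing-style
#'   defaults 30 and 530).
#' @param distribution `"uniform"` or `"truncated_lognormal"`.
#' @param meanlog,sdlog Log-normal parameters (used by
#'   `truncated_lognormal`).
#' @return A `read_length_model`.
#' @export
read_length_model <- function(min_len = 30L, max_len = 530L,
                              distribution = c("uniform",
                                               "truncated_lognormal"),
                              meanlog = 5.2, sdlog = 0.6) {
  distribution <- match.arg(distribution)
  if (min_len < 30L || min_len > max_len) {
    stop("need 30 <= min_len <= max_len", call. = FALSE)
  }
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 distribution = distribution,
                 meanlog = meanlog, sdlog = sdlog),
            class = "read_length_model")
}

draw_lengths <- function(model, n) {
  if (model$distribution == "uniform") {
    sample(model$min_len:model$max_len, n, replace = TRUE)
  } else {
    x <- round(rlnorm(n, model$meanlog, model$sdlog))
    pmin(pmax(x, model$min_len), model$max_len)
  }
}

# apply substitution and single-base indel errors to one read
apply_read_errors <- function(chars, sub_rate, indel_rate) {
  n <- length(chars)
  subs <- which(runif(n) < sub_rate)
  if (length(subs) > 0L) chars <- substitute_bases(chars, subs)
  ind <- which(runif(length(chars)) < indel_rate)
  if (length(ind) > 0L) {
    for (p in rev(ind)) { # right-to-left keeps earlier positions valid
      if (runif(1L) < 0.5 && length(chars) > 1L) {
        chars <- chars[-p] # deletion
      } else {
        chars <- append(chars, sample(DNA_BASES, 1L), after = p - 1L)
      }
    }
  }
  chars
}

#' Simulate reads from a mixture of templates
#'
#' Per read: template drawn from the mixture, start uniform over valid
#' positions, length from the model (clamped to the template), strand
#' uniform; substitution and single-base indel errors applied at the stated
#' per-base rates.
#'
#' @param templates Named character vector of template sequences, or a list
#'   of [annotated_operon()] objects.
#' @param weights Mixture weights (sum to 1), one per template.
#' @param n_reads Number of reads.
#' @param length_model A [read_length_model()].
#' @param sub_rate Substitution rate per base (default 0.5%,
#'   pyrosequencing-like).
#' @param indel_rate Single-base indel rate per base (default 0.1%).
#' @param seed Integer seed.
#' @param read_prefix Read id prefix.
#' @return List: `reads` (named character vector) and `truth` (data frame
#'   `read_id`, `template`, `start`, `end`, `strand` — the true origin of
#'   every read, 1-based inclusive on the template).
#' @export
simulate_reads <- function(templates, weights = NULL, n_reads,
                           length_model = read_length_model(),
                           sub_rate = 0.005, indel_rate = 0.001, seed = 1L,
                           read_prefix = "read") {
  seqs <- variant_seqs(templates)
  nt <- length(seqs)
  weights <- weights %||% rep(1 / nt, nt)
  if (length(weights) != nt || abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to 1, one per template", call. = FALSE)
  }
  if (sub_rate >= 0.1 || indel_rate >= 0.1) {
    stop("error rates must be < 0.1", call. = FALSE)
  }
  empty <- list(reads = setNames(character(), character()),
                truth = data.frame(read_id = character(),
                                   template = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   stringsAsFactors = FALSE))
  if (n_reads == 0L) return(empty)
  with_seed(seed, {
    origin <- sample(names(seqs), n_reads, replace = TRUE, prob = weights)
    lens <- draw_lengths(length_model, n_reads)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- character(n_reads)
    starts <- integer(n_reads)
    ends <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      tmpl <- seqs[[origin[i]]]
      L <- nchar(tmpl)
      len <- min(lens[i], L)
      starts[i] <- sample.int(L - len + 1L, 1L)
      ends[i] <- starts[i] + len - 1L
      frag <- substr(tmpl, starts[i], ends[i])
      chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
      chars <- apply_read_errors(chars, sub_rate, indel_rate)
      rd <- paste(chars, collapse = "")
      reads[i] <- if (strands[i] == "-") revcomp(rd) else rd
    }
    ids <- sprintf("%s_%05d", read_prefix, seq_len(n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, template = origin,
                            start = starts, end = ends, strand = strands,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic 16S reference panel
#'
#' One random ancestral sequence is mutated independently per taxon, giving
#' a panel of diverged full-length 16S stand-ins (synthetic sequences, not
#' real 16S genes) whose pairwise divergence comfortably exceeds the
#' species-level classification threshold.
#'
#' @param taxa Character vector of taxon names.
#' @param seed Integer seed.
#' @param length Reference length, bp.
#' @param divergence Per-taxon substitution probability from the ancestor.
#' @return Named character vector with `"taxon|synthetic16S"` names.
#' @export
generate_16s_panel <- function(taxa, seed = 1L, length = 1500L,
                               divergence = 0.10) {
  with_seed(seed, {
    base <- strsplit(rand_dna(length), "", fixed = TRUE)[[1L]]
    seqs <- vapply(taxa, function(tx) {
      hit <- which(runif(length) < divergence)
      paste(substitute_bases(base, hit), collapse = "")
    }, character(1L))
    names(seqs) <- paste0(taxa, "|synthetic16S")
    seqs
  })
}

#' Simulate heavy and light SIP read pools
#'
#' The light (12C) pool is drawn from the full community at its stated
#' abundances. The heavy (13C) pool is drawn from the labelled taxa
#' re-normalized, except each heavy read comes from the unlabelled
#' background with probability `leakage` — modelling carry-over of
#' unlabelled DNA into heavy gradient fractions.
#'
#' @param community Data frame `taxon`, `abundance` (sums to 1), `labelled`
#'   (logical).
#' @param references Named character vector of 16S references; names must
#'   start with the taxon (`"taxon|id"` or bare taxon).
#' @param n_reads Reads per pool.
#' @param leakage Unlabelled carry-over probability, `[0, 0.5)`.
#' @param length_model,sub_rate,indel_rate Read simulation controls (see
#'   [simulate_reads()]).
#' @param seed Integer seed.
#' @return List: `heavy` and `light` (each with `reads` and `truth`),
#'   `community`, and the effective pool weights.
#' @export
simulate_sip_pools <- function(community, references, n_reads = 400L,
                               leakage = 0.05,
                               length_model = read_length_model(),
                               sub_rate = 0.005, indel_rate = 0.001,
                               seed = 1L) {
  if (abs(sum(community$abundance) - 1) > 1e-6) {
    stop("community abundances must sum to 1", call. = FALSE)
  }
  if (leakage < 0 || leakage >= 0.5) {
    stop("leakage must lie in [0, 0.5)", call. = FALSE)
  }
  if (!any(community$labelled)) {
    stop("heavy pool requested but no taxon is labelled", call. = FALSE)
  }
  taxa <- community$taxon
  panel_taxa <- ref_taxa(references)
  if (!all(taxa %in% panel_taxa)) {
    stop("missing 16S reference for: ",
         paste(setdiff(taxa, panel_taxa), collapse = ", "), call. = FALSE)
  }
  refs <- setNames(as.character(references)[match(taxa, panel_taxa)], taxa)

  light_w <- community$abundance
  lab <- community$labelled
  heavy_w <- ifelse(lab, community$abundance, 0)
  heavy_w <- heavy_w / sum(heavy_w)
  if (any(!lab)) {
    bg <- ifelse(lab, 0, community$abundance)
    bg <- bg / sum(bg)
    heavy_w <- (1 - leakage) * heavy_w + leakage * bg
  }

  light <- simulate_reads(refs, light_w, n_reads, length_model, sub_rate,
                          indel_rate, seed = child_seed(seed, 1L),
                          read_prefix = "light")
  heavy <- simulate_reads(refs, heavy_w, n_reads, length_model, sub_rate,
                          indel_rate, seed = child_seed(seed, 2L),
                          read_prefix = "heavy")
  list(heavy = heavy, light = light, community = community,
       heavy_weights = setNames(heavy_w, taxa),
       light_weights = setNames(light_w, taxa))
}

#' Simulate a biosensor induction experiment
#'
#' Builds an induced and a vehicle-control kinetic series on a shared time
#' grid with the induction onset planted at a known sample index: the
#' normalized induced signal sits at the control level before onset and at
#' `fold` times it afterwards, with multiplicative noise well below the
#' calling threshold.
#'
#' @param onset_index Sample index (1-based) of the true onset.
#' @param n_times Number of time points.
#' @param dt Sampling interval, minutes.
#' @param fold Induced/control fold change after onset.
#' @param noise_sd Multiplicative noise SD.
#' @param seed Integer seed.
#' @return List: `induced`, `control` ([kinetic_series()] objects) and
#'   `onset_time` (minutes).
#' @export
simulate_kinetic_series <- function(onset_index, n_times = 21L, dt = 10,
                                    fold = 10, noise_sd = 0.02, seed = 1L) {
  stopifnot(onset_index >= 1L, onset_index < n_times)
  with_seed(seed, {
    times <- (seq_len(n_times) - 1L) * dt
    od <- 0.3 * exp(0.004 * times) # slow growth
    base_rel <- 500
    ctrl_rel <- base_rel * exp(rnorm(n_times, 0, noise_sd))
    ind_rel <- base_rel * exp(rnorm(n_times, 0, noise_sd))
    ind_rel[onset_index:n_times] <- ind_rel[onset_index:n_times] * fold
    list(induced = kinetic_series("ind1", times, ind_rel * od, od,
                                  "induced"),
         control = kinetic_series("ctl1", times, ctrl_rel * od, od,
                                  "vehicle_control"),
         onset_time = times[[onset_index]])
  })
}

#' Synthetic stand-in for the cloned nagFCQED operon region
#'
#' A code-generated template (synthetic sequence, not the deposited
#' accession) that embeds the study's real primer sequences with the
#' documented geometry: the cluster-amplification pair (NagF1_For/NagD_Rev)
#' brackets a 4973 bp product, and a Comamonas-type NDO primer-pair site
#' (COM1) lies inside it; no Pseudomonas-type (PSE1) site is present.
#' Suitable for exercising amplicon sizing and read-set screening.
#'
#' @param seed Integer seed for the random filler sequence.
#' @return An [annotated_operon()] labelled `"synthetic_nag2_region"`.
#' @export
synthetic_nag_region <- function(seed = 424242L) {
  pairs <- study_primer_pairs()
  nagp <- pairs[["nagFCQED"]]
  com <- pairs[["COM1"]]
  amplicon_len <- 4973L
  with_seed(seed, {
    lf <- nchar(nagp$fwd); lr <- nchar(nagp$rev)
    com_block <- paste0(com$fwd, rand_dna(377L - nchar(com$fwd) -
                                            nchar(com$rev)),
                        revcomp(com$rev))
    inner_total <- amplicon_len - lf - lr
    inner_a <- 2000L
    inner_b <- inner_total - inner_a - nchar(com_block)
    seq <- paste0(rand_dna(150L), nagp$fwd, rand_dna(inner_a), com_block,
                  rand_dna(inner_b), revcomp(nagp$rev), rand_dna(150L))
    # rough gene placement inside the amplicon (round stand-in lengths)
    lens <- c(nagF = 800L, nagC = 800L, nagQ = 350L, nagE = 950L,
              nagD = 900L)
    ends <- 150L + lf + cumsum(lens)
    genes <- data.frame(gene = names(lens), start = ends - lens + 1L,
                        end = ends, strand = "+", stringsAsFactors = FALSE)
    annotated_operon("synthetic_nag2_region", seq, genes)
  })
}
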