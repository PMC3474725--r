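# Pipeline orchestration: one config drives every stage; each stage writes
# machine-readable reports plus a manifest, and stamps outputs with a
# provenance header (package version, config hash, seed) so any report can
# be traced to the exact run that produced it.  All stages are idempotent:
# identical inputs and seed reproduce byte-identical outputs.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "sipmosaic_out",
    # input paths (stage-dependent; NULL = not supplied)
    query_fasta = NULL, parents_fasta = NULL, annotations_tsv = NULL,
    reads_fasta = NULL, variants_fasta = NULL, refs_16s_fasta = NULL,
    heavy_fasta = NULL, light_fasta = NULL, primers_tsv = NULL,
    template_fasta = NULL, plate_csv = NULL,
    # attribution
    call_margin = 2, min_run = 3L, novel_threshold = 5,
    # recruitment / assignment
    recruit_min_identity = 0.80, assign_margin = 0.005, min_overlap = 20L,
    # 16S classification / enrichment
    min_identity_16s = 0.97, pseudocount = 0.5, min_ratio = 5,
    min_heavy_abundance = 1,
    # in-silico PCR
    max_mismatch = 0L, max_product_len = 10000L, min_hit_reads = 5L,
    # kinetics
    fold_threshold = 2,
    # simulation: study-like conditions
    divergence = 0.10, novel_rate = 0.005,
    mosaic_donors = c("A", "B", "A"),
    n_reads = 2000L,
    variant_divergences = c(nag2 = 0, nagU2 = 0.05, nagCJ2 = 0.10),
    variant_weights = c(nag2 = 0.643, nagU2 = 0.177, nagCJ2 = 0.180),
    sub_rate = 0.005, indel_rate = 0.001,
    community = data.frame(
      taxon = c("Acidovorax", "Ralstonia", "Polaromonas", "Pseudomonas"),
      abundance = c(0.014, 0.004, 0.002, 0.98),
      labelled = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE),
    n_reads_16s = 500L, leakage = 0.05)
}

#' Build a validated pipeline configuration
#'
#' Starts from documented defaults; `...` overrides them. Unknown keys are
#' rejected, and thresholds are checked against their documented ranges.
#'
#' @param ... Named overrides of the defaults (see `pipeline_defaults`
#'   source for the full key list).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(!nzchar(names(over))))) {
    stop("config overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  stopifnot(cfg$recruit_min_identity > 0, cfg$recruit_min_identity <= 1,
            cfg$assign_margin >= 0, cfg$min_identity_16s > 0,
            cfg$min_identity_16s <= 1, cfg$min_run >= 1,
            cfg$max_mismatch >= 0, cfg$leakage >= 0, cfg$leakage < 0.5)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$community)) {
    vals$community <- as.data.frame(vals$community,
                                    stringsAsFactors = FALSE)
  }
  do.call(pipeline_config, vals)
}

prepare_out <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$out_dir)) stop("cannot create output directory: ",
                                     cfg$out_dir, call. = FALSE)
  # dump the effective config and derive its hash for provenance stamps
  cfg_path <- file.path(cfg$out_dir, "effective_config.yaml")
  dump <- unclass(cfg)
  dump$community <- as.list(dump$community)
  yaml::write_yaml(dump, cfg_path)
  # the provenance hash covers the analysis parameters, not where the
  # outputs land, so identical runs into different directories stay
  # byte-identical
  dump$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(dump, tmp)
  hash <- substr(unname(tools::md5sum(tmp)), 1L, 8L)
  sprintf("sipmosaic %s | config %s | seed %d",
          as.character(packageVersion("sipmosaic")), hash,
          as.integer(cfg$seed))
}

write_manifest <- function(files, out_dir, provenance) {
  files <- files[file.exists(files)]
  manifest <- list(provenance = provenance,
                   files = lapply(files, function(f) {
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))
                   }))
  names(manifest$files) <- basename(files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate the full synthetic input set
#'
#' Runs the synthetic-community generator end to end: parent operons,
#' mosaic with truth, mixed operon reads, 16S panel and heavy/light pools.
#' Every emitted file is listed, with checksums, in `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the named vector of emitted file paths.
#' @export
run_simulate <- function(config = pipeline_config()) {
  prov <- prepare_out(config)
  od <- config$out_dir
  seed <- as.integer(config$seed)

  parents <- generate_parent_pair(divergence = config$divergence,
                                  seed = child_seed(seed, 1L))
  L <- nchar(parents$parentA$seq)
  nseg <- length(config$mosaic_donors)
  lens <- diff(round(seq(0L, L, length.out = nseg + 1L)))
  plan <- mosaic_plan(config$mosaic_donors, lens, config$novel_rate)
  mos <- generate_mosaic(parents, plan, seed = child_seed(seed, 2L))

  f <- c(parents = file.path(od, "parents.fasta"),
         mosaic = file.path(od, "mosaic.fasta"),
         annotations = file.path(od, "annotations.tsv"),
         mosaic_truth = file.path(od, "mosaic_truth.json"),
         variants = file.path(od, "variants.fasta"),
         reads = file.path(od, "reads.fasta"),
         reads_truth = file.path(od, "reads_truth.tsv"),
         refs_16s = file.path(od, "refs_16s.fasta"),
         heavy = file.path(od, "heavy_16s.fasta"),
         light = file.path(od, "light_16s.fasta"),
         pools_truth = file.path(od, "pools_truth.tsv"),
         community = file.path(od, "community.tsv"))

  write_fasta(c(setNames(parents$parentA$seq, parents$parentA$label),
                setNames(parents$parentB$seq, parents$parentB$label)),
              f[["parents"]])
  write_fasta(setNames(mos$operon$seq, mos$operon$label), f[["mosaic"]])
  write_annotations(list(parentA = parents$parentA$genes,
                         parentB = parents$parentB$genes,
                         mosaic = mos$operon$genes), f[["annotations"]])
  jsonlite::write_json(list(provenance = prov, donor = mos$truth$donor,
                            novel_sites = mos$truth$novel_sites,
                            breakpoints = mos$truth$breakpoints),
                       f[["mosaic_truth"]])

  panel <- generate_operon_panel(divergences = config$variant_divergences,
                                 seed = child_seed(seed, 6L))
  vseqs <- vapply(panel, function(v) v$seq, character(1L))
  write_fasta(vseqs, f[["variants"]])
  w <- config$variant_weights[names(panel)]
  sim <- simulate_reads(vseqs, weights = as.numeric(w),
                        n_reads = config$n_reads,
                        sub_rate = config$sub_rate,
                        indel_rate = config$indel_rate,
                        seed = child_seed(seed, 3L))
  write_fasta(sim$reads, f[["reads"]])
  write.table(sim$truth, f[["reads_truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  comm <- config$community
  panel <- generate_16s_panel(comm$taxon, seed = child_seed(seed, 4L))
  write_fasta(panel, f[["refs_16s"]])
  pools <- simulate_sip_pools(comm, panel, n_reads = config$n_reads_16s,
                              leakage = config$leakage,
                              sub_rate = config$sub_rate,
                              indel_rate = config$indel_rate,
                              seed = child_seed(seed, 5L))
  write_fasta(pools$heavy$reads, f[["heavy"]])
  write_fasta(pools$light$reads, f[["light"]])
  both <- rbind(cbind(pool = "heavy_13C", pools$heavy$truth),
                cbind(pool = "light_12C", pools$light$truth))
  write.table(both, f[["pools_truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(comm, f[["community"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  write_manifest(f, od, prov)
  invisible(f)
}

#' Attribute a query operon against two parents and report
#'
#' Reads `query_fasta` (one record), `parents_fasta` (two records, order =
#' parent A then parent B) and `annotations_tsv` (intervals on the query);
#' writes the attribution BED, the per-gene report and the
#' segment/breakpoint tables.
#'
#' @param config A [pipeline_config()] with the input paths set.
#' @return Invisibly, the attribution track.
#' @export
run_mosaic <- function(config) {
  prov <- prepare_out(config)
  od <- config$out_dir
  qs <- read_fasta(config$query_fasta)
  ps <- read_fasta(config$parents_fasta, allow_n = FALSE)
  if (length(ps) < 2L) stop("parents_fasta must hold two records",
                            call. = FALSE)
  ann <- read_annotations(config$annotations_tsv, "tsv", sequences = qs)
  qlab <- names(qs)[[1L]]
  genes <- ann[[qlab]] %||% ann[[1L]]
  query <- annotated_operon(qlab, qs[[1L]], genes, is_reference = FALSE)
  a <- annotated_operon(names(ps)[[1L]], ps[[1L]])
  b <- annotated_operon(names(ps)[[2L]], ps[[2L]])

  track <- attribute_sites(query, a, b)
  report <- summarize_genes(track, genes, call_margin = config$call_margin,
                            min_run = config$min_run,
                            novel_threshold = config$novel_threshold)
  seg <- detect_segments(track, min_run = config$min_run)

  write_attribution_bed(track, file.path(od, "attribution.bed"))
  write_gene_report(report, file.path(od, "gene_report.tsv"), header = prov)
  write_gene_report(seg$segments, file.path(od, "segments.tsv"),
                    header = prov)
  write_gene_report(seg$breakpoints, file.path(od, "breakpoints.tsv"),
                    header = prov)
  write_manifest(file.path(od, c("attribution.bed", "gene_report.tsv",
                                 "segments.tsv", "breakpoints.tsv")),
                 od, prov)
  invisible(track)
}

#' Recruit reads to operon variants and report abundance
#'
#' @param config A [pipeline_config()] with `reads_fasta` and
#'   `variants_fasta` set.
#' @return Invisibly, the `operon_abundance`.
#' @export
run_quantify <- function(config) {
  prov <- prepare_out(config)
  od <- config$out_dir
  reads <- if (file.size(config$reads_fasta) > 0L) {
    read_fasta(config$reads_fasta)
  } else {
    setNames(character(), character()) # empty read file: zero-count report
  }
  variants <- read_fasta(config$variants_fasta, allow_n = FALSE)
  asg <- recruit_and_assign(reads, variants,
                            recruit_min_identity = config$recruit_min_identity,
                            assign_margin = config$assign_margin)
  ab <- operon_fractions(asg, variant_labels = names(variants))
  write_assignments(asg, file.path(od, "assignments.tsv"), header = prov)
  write_gene_report(ab$abundance, file.path(od, "abundance.tsv"),
                    header = c(prov,
                               "fractions are of confidently assigned reads"))
  jsonlite::write_json(list(provenance = prov, abundance = ab$abundance,
                            ambiguous = ab$ambiguous,
                            unrecruited = ab$unrecruited,
                            n_assigned = ab$n_assigned,
                            n_reads = ab$n_reads,
                            denominator = "confidently assigned reads"),
                       file.path(od, "abundance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  write_manifest(file.path(od, c("assignments.tsv", "abundance.tsv",
                                 "abundance.json")), od, prov)
  invisible(ab)
}

#' Classify 16S pools and call heavy-fraction enrichment
#'
#' @param config A [pipeline_config()] with `heavy_fasta`, `light_fasta`
#'   and `refs_16s_fasta` set.
#' @return Invisibly, the enrichment table.
#' @export
run_taxa <- function(config) {
  prov <- prepare_out(config)
  od <- config$out_dir
  refs <- read_fasta(config$refs_16s_fasta, allow_n = FALSE)
  taxa <- sort(unique(ref_taxa(refs)))
  heavy_cl <- classify_16s(read_fasta(config$heavy_fasta), refs,
                           min_identity = config$min_identity_16s)
  light_cl <- classify_16s(read_fasta(config$light_fasta), refs,
                           min_identity = config$min_identity_16s)
  heavy_ab <- relative_abundance(heavy_cl, "heavy_13C", taxa = taxa)
  light_ab <- relative_abundance(light_cl, "light_12C", taxa = taxa)
  enr <- call_enrichment(heavy_ab, light_ab,
                         pseudocount = config$pseudocount,
                         min_ratio = config$min_ratio,
                         min_heavy_abundance = config$min_heavy_abundance)
  ab <- rbind(as.data.frame(heavy_ab), as.data.frame(light_ab))
  write_gene_report(ab, file.path(od, "taxon_abundance.tsv"),
                    header = c(prov,
                               "abundance % of classified reads per fraction"))
  write_gene_report(enr, file.path(od, "enrichment.tsv"), header = prov)
  write_manifest(file.path(od, c("taxon_abundance.tsv", "enrichment.tsv")),
                 od, prov)
  invisible(enr)
}

#' In-silico PCR: amplicons on a template and a read-set screen
#'
#' @param config A [pipeline_config()] with `primers_tsv` plus
#'   `template_fasta` and/or `reads_fasta` set.
#' @return Invisibly, a list with `amplicons` and `screen`.
#' @export
run_pcr <- function(config) {
  prov <- prepare_out(config)
  od <- config$out_dir
  pairs <- read_primer_pairs(config$primers_tsv)
  out <- list(amplicons = NULL, screen = NULL)
  if (!is.null(config$template_fasta)) {
    tmpl <- read_fasta(config$template_fasta)
    amps <- do.call(rbind, lapply(names(tmpl), function(id) {
      do.call(rbind, lapply(pairs, function(pp) {
        a <- find_amplicons(setNames(tmpl[id], id), pp,
                            max_mismatch = config$max_mismatch,
                            max_product_len = config$max_product_len)
        if (nrow(a) > 0L) cbind(pair = pp$name, a) else NULL
      }))
    }))
    if (is.null(amps)) {
      amps <- data.frame(pair = character(), template_id = character(),
                         start = integer(), end = integer(),
                         length = integer(), strand = character(),
                         fwd_mismatches = integer(),
                         rev_mismatches = integer())
    }
    write_gene_report(amps, file.path(od, "amplicons.tsv"), header = prov)
    out$amplicons <- amps
  }
  if (!is.null(config$reads_fasta)) {
    reads <- read_fasta(config$reads_fasta)
    scr <- screen_readset(reads, pairs, max_mismatch = config$max_mismatch,
                          min_hit_reads = config$min_hit_reads)
    write_gene_report(scr, file.path(od, "primer_screen.tsv"), header = prov)
    out$screen <- scr
  }
  write_manifest(file.path(od, c("amplicons.tsv", "primer_screen.tsv")),
                 od, prov)
  invisible(out)
}

#' Normalize plate-reader kinetics and call induction
#'
#' Replicate wells are averaged per condition and time point before
#' calling; per-well normalized series and the onset call are written.
#'
#' @param config A [pipeline_config()] with `plate_csv` set.
#' @return Invisibly, the onset call.
#' @export
run_kinetics <- function(config) {
  prov <- prepare_out(config)
  od <- config$out_dir
  wells <- read_plate_csv(config$plate_csv)
  norm <- lapply(wells, relative_bioluminescence)
  long <- do.call(rbind, lapply(norm, as.data.frame))
  write_gene_report(long, file.path(od, "normalized_kinetics.tsv"),
                    header = prov)
  cond <- vapply(wells, function(w) w$condition[[1L]], character(1L))
  ind <- average_replicates(wells[cond == "induced"])
  ctl <- average_replicates(wells[cond == "vehicle_control"])
  call <- call_induction(ind, ctl, fold_threshold = config$fold_threshold)
  onset <- data.frame(induced = call$induced,
                      onset_time_min = ifelse(call$induced,
                                              call$onset_time, NA_real_),
                      fold_threshold = config$fold_threshold)
  write_gene_report(onset, file.path(od, "induction_call.tsv"),
                    header = prov)
  write_manifest(file.path(od, c("normalized_kinetics.tsv",
                                 "induction_call.tsv")), od, prov)
  invisible(call)
}
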