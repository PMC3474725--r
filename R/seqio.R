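# Sequence and annotation I/O plus the core shared types.
#
# Coordinates: 1-based inclusive everywhere inside the package (GenBank
# convention, the native R/Biostrings style); the only 0-based half-open
# surface is BED export, converted at the boundary.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# Normalize a nucleotide string: upcase, U -> T.
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

validate_seq <- function(seq, id = "<sequence>", allow_n = TRUE) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("sequence '", id, "' is empty", call. = FALSE)
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad)) {
    stop("sequence '", id, "' contains illegal character(s) after ",
         "normalization: ", paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  invisible(seq)
}

#' Read a multi-record FASTA file
#'
#' Sequences are normalized to uppercase with `U` mapped to `T` and validated
#' against the `{A,C,G,T,N}` alphabet; a record failing validation raises an
#' error naming it.
#'
#' @param path Path to a FASTA file.
#' @param allow_n Whether `N` is permitted. Reads may contain `N`; curated
#'   reference operons must not (an ambiguous reference base would poison
#'   parent attribution), so pass `allow_n = FALSE` when reading references.
#' @return A named character vector of uppercase sequences, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path, allow_n = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' has no records",
                              call. = FALSE)
  seqs <- normalize_seq(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file '", path, "' has an empty header",
                              call. = FALSE)
  names(seqs) <- ids
  for (i in seq_along(seqs)) validate_seq(seqs[[i]], ids[[i]], allow_n = allow_n)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Gene intervals on an operon
#'
#' Builds and validates the ordered gene-interval table of an operon:
#' non-overlapping, in-range, uniquely named intervals with 1-based inclusive
#' coordinates.
#'
#' @param gene Character vector of gene names (e.g. `"nagF"`).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`; recycled.
#' @param seq_length Optional operon length to validate `end` against.
#' @return A `data.frame` with columns `gene`, `start`, `end`, `strand`,
#'   sorted by `start`.
#' @export
gene_intervals <- function(gene, start, end, strand = "+", seq_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(as.character(strand), length(gene))
  if (any(duplicated(gene))) {
    stop("duplicate gene name(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "), call. = FALSE)
  }
  if (any(start < 1L) || any(end < start)) {
    stop("gene intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'",
                                          call. = FALSE)
  if (!is.null(seq_length) && any(end > seq_length)) {
    bad <- gene[end > seq_length]
    stop("gene interval(s) out of range: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  o <- order(start)
  df <- data.frame(gene = as.character(gene)[o], start = start[o],
                   end = end[o], strand = strand[o],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop("gene intervals overlap", call. = FALSE)
  }
  df
}

#' Construct an annotated operon
#'
#' The unit of mosaic analysis: one nucleotide sequence plus its ordered gene
#' intervals.
#'
#' @param label Operon label (e.g. `"nag2"`).
#' @param seq Nucleotide sequence (normalized on input).
#' @param genes A gene-interval table as from [gene_intervals()], or `NULL`.
#' @param is_reference Reference operons forbid `N`.
#' @return An object of class `annotated_operon`.
#' @export
annotated_operon <- function(label, seq, genes = NULL, is_reference = TRUE) {
  seq <- normalize_seq(seq)
  validate_seq(seq, label, allow_n = !is_reference)
  if (is.null(genes)) {
    genes <- data.frame(gene = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  } else {
    genes <- gene_intervals(genes$gene, genes$start, genes$end,
                            genes$strand %||% "+", seq_length = nchar(seq))
  }
  structure(list(label = label, seq = seq, genes = genes),
            class = "annotated_operon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotated_operon <- function(x, ...) {
  cat(sprintf("<annotated_operon> %s: %d bp, %d gene(s)\n",
              x$label, nchar(x$seq), nrow(x$genes)))
  if (nrow(x$genes) > 0L) {
    cat(paste(sprintf("  %-8s %7d..%-7d %s", x$genes$gene, x$genes$start,
                      x$genes$end, x$genes$strand), collapse = "\n"), "\n")
  }
  invisible(x)
}

# pull the plain character sequence out of whatever the caller handed us
as_seq <- function(x, what = "sequence") {
  if (inherits(x, "annotated_operon")) return(x$seq)
  if (is.character(x) && length(x) == 1L) return(normalize_seq(x))
  stop(what, " must be a single character string or an annotated_operon",
       call. = FALSE)
}

seq_label <- function(x, default = "seq") {
  if (inherits(x, "annotated_operon")) return(x$label)
  if (!is.null(names(x)) && nzchar(names(x)[1L])) return(names(x)[1L])
  default
}

#' Read gene annotations
#'
#' Two dialects: a 4-column TSV (`seqid`, `gene_name`, `start_1based`,
#' `end_1based`, optional 5th column `strand`) or GFF3 restricted to `gene`
#' features (via \pkg{rtracklayer}). Coordinates are 1-based inclusive in
#' both dialects and are kept that way internally.
#'
#' @param path Annotation file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param sequences Optional named character vector used to validate interval
#'   ranges against sequence lengths.
#' @return Named list (by operon label) of gene-interval data frames.
#' @export
read_annotations <- function(path, dialect = c("tsv", "gff3"),
                             sequences = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("annotation TSV needs >= 4 columns ",
                            "(seqid, gene, start, end)", call. = FALSE)
    names(df)[1:4] <- c("seqid", "gene", "start", "end")
    df$strand <- if (ncol(df) >= 5L) as.character(df[[5L]]) else "+"
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gd <- as.data.frame(gr, stringsAsFactors = FALSE)
    gd <- gd[gd$type == "gene", , drop = FALSE]
    nm <- if (!is.null(gd$Name)) gd$Name else gd$ID
    df <- data.frame(seqid = as.character(gd$seqnames), gene = as.character(nm),
                     start = gd$start, end = gd$end,
                     strand = as.character(gd$strand), stringsAsFactors = FALSE)
    df$strand[!df$strand %in% c("+", "-")] <- "+"
  }
  out <- lapply(split(df, df$seqid), function(d) {
    len <- if (!is.null(sequences) && d$seqid[1L] %in% names(sequences)) {
      nchar(sequences[[d$seqid[1L]]])
    } else {
      NULL
    }
    gene_intervals(d$gene, d$start, d$end, d$strand, seq_length = len)
  })
  out[unique(df$seqid)]
}

#' Write gene annotations as 4-column TSV
#'
#' @param annotations Named list of gene-interval data frames.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(names(annotations), function(lbl) {
    g <- annotations[[lbl]]
    data.frame(seqid = lbl, gene = g$gene, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct a primer pair
#'
#' @param name Pair name.
#' @param fwd,rev Primer sequences over IUPAC nucleotide codes, length >= 10.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev) {
  fwd <- normalize_seq(fwd); rev <- normalize_seq(rev)
  for (p in c(fwd = fwd, rev = rev)) {
    if (nchar(p) < 10L) stop("primer shorter than 10 nt in pair '", name, "'",
                             call. = FALSE)
    bad <- gsub(sprintf("[%s]", paste(names(IUPAC_CODES), collapse = "")),
                "", p)
    if (nzchar(bad)) stop("invalid IUPAC character(s) in primer pair '", name,
                          "': ", bad, call. = FALSE)
  }
  structure(list(name = name, fwd = fwd, rev = rev), class = "primer_pair")
}

#' Read primer pairs from a 3-column TSV (name, fwd, rev)
#'
#' @param path TSV path; lines starting with `#` are ignored.
#' @return A list of [primer_pair()] objects, named by pair.
#' @export
read_primer_pairs <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("primer TSV needs 3 columns (name, fwd, rev)",
                          call. = FALSE)
  pairs <- lapply(seq_len(nrow(df)),
                  function(i) primer_pair(df[[1L]][i], df[[2L]][i], df[[3L]][i]))
  names(pairs) <- df[[1L]]
  pairs
}

#' Naphthalene catabolic operon primer panel
#'
#' The nag-cluster amplification pair (`nagFCQED`: NagF1_For/NagD_Rev) and
#' the two degenerate naphthalene dioxygenase screening pairs (`COM1`:
#' Comamonas-type, `PSE1`: Pseudomonas-type), shipped with the package.
#'
#' @return Named list of [primer_pair()] objects.
#' @export
study_primer_pairs <- function() {
  read_primer_pairs(system.file("extdata", "primers.tsv",
                                package = "sipmosaic", mustWork = TRUE))
}
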