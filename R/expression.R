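#' Expression matrix with feature class and scale
#'
#' A light container for a features x samples numeric matrix carrying two
#' pieces of metadata the pipeline needs at every step: the feature class
#' (`"miRNA"`, `"lncRNA"` or `"mRNA"`) and the measurement scale (`"raw"`
#' counts or `"log2"`-transformed values).
#'
#' @param values Numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required).
#' @param feature_class One of `"miRNA"`, `"lncRNA"`, `"mRNA"`.
#' @param scale `"raw"` (non-negative counts) or `"log2"`.
#' @return An `ExpressionMatrix`: a numeric matrix with attributes
#'   `feature_class` and `scale`.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, "mRNA", "raw")
#' feature_class(em)
#' @export
expression_matrix <- function(values,
                              feature_class = c("mRNA", "miRNA", "lncRNA"),
                              scale = c("raw", "log2")) {
  feature_class <- match.arg(feature_class)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids in expression matrix")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw expression values must be non-negative")
  structure(values,
            feature_class = feature_class,
            scale = scale,
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
feature_class <- function(x) attr(x, "feature_class")

#' @rdname expression_matrix
#' @export
expr_scale <- function(x) attr(x, "scale")

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "feature_class") <- attr(x, "feature_class")
    attr(out, "scale") <- attr(x, "scale")
    class(out) <- class(x)
  }
  out
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s features x %d samples [%s scale]\n",
              nrow(x), feature_class(x), ncol(x), expr_scale(x)))
  y <- unclass(x)
  attr(y, "feature_class") <- NULL
  attr(y, "scale") <- NULL
  print(utils::head(y, 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Aggregate transcript-level counts to gene level
#'
#' Multiple transcripts mapping to one gene are summarised by the arithmetic
#' mean of their rows, computed on the raw scale. Transcripts absent from the
#' id map are dropped (with a message giving the count). The result is split
#' by gene class, since downstream steps treat miRNA, lncRNA and mRNA
#' profiles as separate matrices.
#'
#' @param transcript_matrix `ExpressionMatrix` on the raw scale, rows are
#'   transcript ids.
#' @param map Data frame with columns `transcript_id`, `gene_id`,
#'   `gene_class`; every transcript maps to exactly one gene.
#' @return Named list of `ExpressionMatrix` objects, one per gene class
#'   present in the mapped data.
#' @export
aggregate_transcripts <- function(transcript_matrix, map) {
  stopifnot(inherits(transcript_matrix, "ExpressionMatrix"))
  if (expr_scale(transcript_matrix) != "raw")
    stop("aggregation operates on the raw scale")
  req <- c("transcript_id", "gene_id", "gene_class")
  if (!all(req %in% names(map)))
    stop("id map must have columns transcript_id, gene_id, gene_class")
  if (anyDuplicated(map$transcript_id))
    stop("id map assigns some transcript to more than one gene")
  keep <- rownames(transcript_matrix) %in% map$transcript_id
  if (!any(keep))
    stop("no transcripts in the matrix are present in the id map")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("dropping %d unmapped transcript(s)", n_drop))
  m <- transcript_matrix[keep, , drop = FALSE]
  idx <- match(rownames(m), map$transcript_id)
  gene <- map$gene_id[idx]
  gclass <- map$gene_class[idx]
  out <- list()
  for (cl in unique(gclass)) {
    sel <- gclass == cl
    sums <- rowsum(unclass(m)[sel, , drop = FALSE], group = gene[sel])
    counts <- as.vector(table(gene[sel])[rownames(sums)])
    means <- sums / counts
    out[[cl]] <- expression_matrix(means, feature_class = cl, scale = "raw")
  }
  out
}

#' Log2-transform a raw expression matrix
#'
#' Applies `log2(x + 1)`; the unit pseudocount guards zero counts.
#'
#' @param m `ExpressionMatrix` on the raw scale.
#' @return `ExpressionMatrix` on the log2 scale.
#' @export
log2_standardize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (expr_scale(m) != "raw") stop("input is already log2-scaled")
  if (any(m < 0)) stop("negative values cannot be log2-transformed")
  expression_matrix(log2(unclass(m) + 1),
                    feature_class = feature_class(m), scale = "log2")
}

#' Read / write expression matrices as TSV
#'
#' The expected layout is the usual one: first column feature id, remaining
#' columns one per sample, header row required.
#'
#' @param path File path.
#' @param feature_class,scale Metadata for the returned `ExpressionMatrix`.
#' @return `read_expression_tsv()` returns an `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, feature_class = "mRNA", scale = "raw") {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, feature_class = feature_class, scale = scale)
}

#' @rdname read_expression_tsv
#' @param m An `ExpressionMatrix` to write.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), unclass(m),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical follow-up table
#'
#' Expects columns `sample_id`, `time` (follow-up, days, > 0) and `event`
#' (1 = death/event, 0 = censored).
#'
#' @param path File path to a TSV.
#' @return Data frame with validated columns.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(df)))
    stop("clinical table must have columns sample_id, time, event")
  if (any(df$time <= 0)) stop("follow-up times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a regulator-target edge list
#'
#' Expects columns `regulator_id` and `target_id` (a `source` column is kept
#' if present). Duplicate (regulator, target) pairs are collapsed.
#'
#' @param path File path to a TSV.
#' @return Data frame of unique edges.
#' @export
read_interactions_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("regulator_id", "target_id") %in% names(df)))
    stop("interaction table must have columns regulator_id, target_id")
  df[!duplicated(df[c("regulator_id", "target_id")]), , drop = FALSE]
}

#' Read / write sequences in FASTA
#'
#' Thin wrappers around [Biostrings::readBStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors,
#' which is the form the seed scanner and PWM scanner consume (miRNA
#' sequences use the RNA alphabet, transcripts and promoters DNA).
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' Imported through [rtracklayer::import.bed()] and returned in BED's own
#' 0-based half-open convention, which the promoter/enhancer operations use.
#'
#' @param path File path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name` and `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}
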