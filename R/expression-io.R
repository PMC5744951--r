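#' Read an expression matrix from a tab-separated file
#'
#' Expected layout: UTF-8 TSV, header row `transcript_id<TAB>sample1<TAB>...`,
#' one row per transcript, numeric body. Row and column order are preserved.
#' IDs are whitespace-trimmed and case-sensitive.
#'
#' @param path path to the TSV file.
#' @param metric expression unit recorded on the result
#'   (`"counts"`, `"TPM"`, `"FPKM"`).
#' @return an [expr_matrix].
#' @export
read_expression_matrix <- function(path, metric = c("counts", "TPM", "FPKM")) {
  metric <- match.arg(metric)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("expression matrix file needs a transcript_id column plus >= 1 sample column",
         call. = FALSE)
  ids <- trimws(df[[1L]])
  samples <- trimws(colnames(df)[-1L])
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], samples[j], body[[j]][bad[1L]]), call. = FALSE)
    vals[, j] <- v
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at row '%s', column '%s'",
                 ids[neg[1L, 1L]], samples[neg[1L, 2L]]), call. = FALSE)
  dimnames(vals) <- list(ids, samples)
  expr_matrix(vals, metric = metric)
}

#' Write an expression matrix to a tab-separated file
#'
#' Values are written with 6 significant digits; the metric tag is not stored
#' in the file and must be supplied again on reading.
#'
#' @param x an [expr_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is_expr_matrix(x))
  df <- data.frame(transcript_id = rownames(x),
                   signif(expr_values(x), 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample design: sample-to-group assignment
#'
#' @param sample_ids character vector of unique sample IDs.
#' @param groups character vector of group labels, same length.
#' @return a `sample_design` object (data frame with columns `sample_id`,
#'   `group`).
#' @export
sample_design <- function(sample_ids, groups) {
  sample_ids <- trimws(as.character(sample_ids))
  groups <- trimws(as.character(groups))
  if (length(sample_ids) != length(groups))
    stop("'sample_ids' and 'groups' must have the same length", call. = FALSE)
  validate_ids(sample_ids, "sample")
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("group labels must be non-empty", call. = FALSE)
  structure(data.frame(sample_id = sample_ids, group = groups,
                       stringsAsFactors = FALSE),
            class = c("sample_design", "data.frame"))
}

#' @rdname sample_design
#' @param path path to a 2-column TSV `sample_id<TAB>group` with header.
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("sample design file needs columns sample_id and group", call. = FALSE)
  sample_design(df[[1L]], df[[2L]])
}

#' @rdname sample_design
#' @param design a `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sample_design
#' @export
design_groups <- function(design) unique(design$group)

#' @rdname sample_design
#' @param group group label.
#' @export
group_samples <- function(design, group) {
  if (!group %in% design$group)
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  design$sample_id[design$group == group]
}

# check that a design covers all samples of a matrix with >= min_n per group
check_design <- function(x, design, groups = c("case", "control"), min_n = 2L) {
  missing <- setdiff(colnames(x), design$sample_id)
  if (length(missing))
    stop(sprintf("samples missing from design: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (g in groups) {
    n <- length(intersect(design$sample_id[design$group == g], colnames(x)))
    if (n < min_n)
      stop(sprintf("group '%s' has %d sample(s) in the matrix; >= %d required",
                   g, n, min_n), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write per-transcript feature lengths
#'
#' Two-column TSV `transcript_id<TAB>length` with header; lengths are positive
#' integers in base pairs.
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_feature_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  ids <- trimws(as.character(df[[1L]]))
  validate_ids(ids, "transcript")
  len <- as.numeric(df[[2L]])
  if (anyNA(len) || any(len <= 0))
    stop("feature lengths must be positive numbers", call. = FALSE)
  stats::setNames(len, ids)
}

#' @rdname read_feature_lengths
#' @param lengths named numeric vector of lengths.
#' @export
write_feature_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(transcript_id = names(lengths), length = unname(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' RPKM normalization
#'
#' Converts raw counts to reads per kilobase of transcript per million mapped
#' reads: `count / ((length/1000) * (column_sum/1e6))`. The per-sample column
#' sum of the count matrix stands in for the library's million mapped reads.
#'
#' @param counts an [expr_matrix] with metric `"counts"`.
#' @param lengths named numeric vector of transcript lengths in bp, covering
#'   every transcript in `counts`.
#' @return an [expr_matrix] with metric `"FPKM"`.
#' @export
rpkm_normalize <- function(counts, lengths) {
  v <- check_norm_inputs(counts, lengths)
  len_kb <- lengths[rownames(counts)] / 1000
  lib_m <- colSums(v) / 1e6
  out <- sweep(v / len_kb, 2L, lib_m, "/")
  expr_matrix(out, metric = "FPKM")
}

#' TPM normalization
#'
#' Converts raw counts to transcripts per million: length-normalized rates
#' `count/length` are rescaled per sample so every column sums to 1e6.
#'
#' @inheritParams rpkm_normalize
#' @return an [expr_matrix] with metric `"TPM"`; column sums equal 1e6 up to
#'   floating-point rounding.
#' @export
tpm_normalize <- function(counts, lengths) {
  v <- check_norm_inputs(counts, lengths)
  rate <- v / lengths[rownames(counts)]
  out <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  expr_matrix(out, metric = "TPM")
}

check_norm_inputs <- function(counts, lengths) {
  stopifnot(is_expr_matrix(counts))
  if (expr_metric(counts) != "counts")
    stop(sprintf("normalization expects metric 'counts', got '%s'",
                 expr_metric(counts)), call. = FALSE)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop(sprintf("missing length for transcript(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  v <- expr_values(counts)
  zero <- colnames(counts)[colSums(v) == 0]
  if (length(zero))
    stop(sprintf("all-zero sample column(s): %s", paste(zero, collapse = ", ")),
         call. = FALSE)
  v
}
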