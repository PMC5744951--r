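#' Staged reference expression compendium
#'
#' Holds, per expression metric, a per-stage mean expression profile over a
#' common transcript universe together with per-transcript discrimination
#' p-values for every tumour-stage-versus-adjacent-normal pair. The p-values
#' are the basis of the transcript weights used by
#' [stage_correlation_report()]. A `"normal"` stage is always present and has
#' no p-values of its own.
#'
#' @param expr list, one element per metric (e.g. `"TPM"`), each a numeric
#'   matrix transcripts x stages with a `"normal"` column; all values >= 0.
#' @param pvals list parallel to `expr`, each a numeric matrix transcripts x
#'   tumour stages with values in (0, 1].
#' @return an object of class `stage_reference`.
#' @export
stage_reference <- function(expr, pvals) {
  if (!is.list(expr) || !length(expr) || is.null(names(expr)))
    stop("'expr' must be a named list of matrices (one per metric)",
         call. = FALSE)
  if (!identical(names(expr), names(pvals)))
    stop("'expr' and 'pvals' must cover the same metrics", call. = FALSE)
  for (m in names(expr)) {
    e <- expr[[m]]; p <- pvals[[m]]
    if (!"normal" %in% colnames(e))
      stop("reference must contain a 'normal' stage", call. = FALSE)
    if (any(!is.finite(e)) || any(e < 0))
      stop("reference expression must be finite and >= 0", call. = FALSE)
    stages <- setdiff(colnames(e), "normal")
    if (!identical(sort(colnames(p)), sort(stages)))
      stop("p-value matrix must cover exactly the tumour stages", call. = FALSE)
    if (!identical(rownames(e), rownames(p)))
      stop("expression and p-value matrices must share the transcript universe",
           call. = FALSE)
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("discrimination p-values must lie in (0, 1]", call. = FALSE)
    validate_ids(rownames(e), "transcript")
  }
  structure(list(expr = expr, pvals = pvals), class = "stage_reference")
}

#' @rdname stage_reference
#' @param ref a `stage_reference`.
#' @export
ref_metrics <- function(ref) names(ref$expr)

#' @rdname stage_reference
#' @export
ref_stages <- function(ref) {
  setdiff(colnames(ref$expr[[1L]]), "normal")
}

#' @rdname stage_reference
#' @export
ref_transcripts <- function(ref) rownames(ref$expr[[1L]])

#' @export
print.stage_reference <- function(x, ...) {
  cat(sprintf(
    "stage_reference: %d transcripts, stages {%s} + normal, metric(s): %s\n",
    length(ref_transcripts(x)), paste(ref_stages(x), collapse = ", "),
    paste(ref_metrics(x), collapse = ", ")))
  invisible(x)
}

#' Read / write a staged reference compendium
#'
#' Long-format TSV with header and columns `transcript_id`, `stage`,
#' `mean_expr`, `pvalue`, `metric`. Rows with `stage == "normal"` carry an
#' empty/NA `pvalue`.
#'
#' @param path file path.
#' @return a [stage_reference].
#' @export
read_stage_reference <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  need <- c("transcript_id", "stage", "mean_expr", "pvalue", "metric")
  if (!all(need %in% colnames(df)))
    stop("stage reference file needs columns transcript_id, stage, mean_expr, pvalue, metric",
         call. = FALSE)
  df$transcript_id <- trimws(as.character(df$transcript_id))
  df$stage <- trimws(as.character(df$stage))
  df$metric <- trimws(as.character(df$metric))
  expr <- list(); pvals <- list()
  for (m in unique(df$metric)) {
    sub <- df[df$metric == m, ]
    ids <- unique(sub$transcript_id)
    stages <- unique(sub$stage)
    e <- matrix(NA_real_, length(ids), length(stages),
                dimnames = list(ids, stages))
    e[cbind(match(sub$transcript_id, ids), match(sub$stage, stages))] <-
      as.numeric(sub$mean_expr)
    if (anyNA(e))
      stop("stage reference is not complete over transcripts x stages",
           call. = FALSE)
    tum <- setdiff(stages, "normal")
    p <- matrix(NA_real_, length(ids), length(tum), dimnames = list(ids, tum))
    subt <- sub[sub$stage != "normal", ]
    p[cbind(match(subt$transcript_id, ids), match(subt$stage, tum))] <-
      as.numeric(subt$pvalue)
    expr[[m]] <- e
    pvals[[m]] <- p
  }
  stage_reference(expr, pvals)
}

#' @rdname read_stage_reference
#' @param ref a [stage_reference].
#' @export
write_stage_reference <- function(ref, path) {
  rows <- list()
  for (m in ref_metrics(ref)) {
    e <- ref$expr[[m]]; p <- ref$pvals[[m]]
    for (s in colnames(e)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = rownames(e), stage = s,
        mean_expr = signif(e[, s], 6L),
        pvalue = if (s == "normal") NA_real_ else signif(p[, s], 6L),
        metric = m, stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
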