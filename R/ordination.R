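#' Sample-sample correlation matrix
#'
#' Pairwise Pearson or Spearman correlations between sample columns, as used
#' for sample-relatedness heat maps. Optionally restricts transcripts to
#' those with Welch p <= alpha between two design groups before correlating
#' (the "transcripts with a P-value <= 0.05" view).
#'
#' @param x an [expr_matrix].
#' @param method `"pearson"` or `"spearman"`.
#' @param p_filter optional list `list(design = , alpha = , case = ,
#'   control = )`; transcripts are restricted to tested transcripts with
#'   Welch p <= alpha (`case`/`control` default to `"case"`/`"control"`).
#' @param log2_transform apply `log2(value + 1)` before Pearson correlation
#'   (default TRUE; rank-based Spearman is unaffected by this monotone
#'   transform).
#' @return symmetric correlation matrix (samples x samples) with unit
#'   diagonal. Samples with zero variance after filtering get `NA`
#'   correlations with a warning.
#' @export
sample_correlation_matrix <- function(x, method = c("pearson", "spearman"),
                                      p_filter = NULL, log2_transform = TRUE) {
  stopifnot(is_expr_matrix(x))
  method <- match.arg(method)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- filtered_values(x, p_filter)
  if (log2_transform && method == "pearson") v <- log2(v + 1)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    warning(sprintf("zero-variance sample(s) after filtering: %s",
                    paste(colnames(v)[sds == 0], collapse = ", ")))
  r <- suppressWarnings(stats::cor(v, method = method))
  diag(r) <- 1
  r
}

filtered_values <- function(x, p_filter) {
  v <- expr_values(x)
  if (is.null(p_filter)) return(v)
  if (is.null(p_filter$design))
    stop("p_filter needs a 'design' element", call. = FALSE)
  alpha <- if (is.null(p_filter$alpha)) 0.05 else p_filter$alpha
  det <- classify_transcripts(
    x, p_filter$design, alpha = alpha,
    case = if (is.null(p_filter$case)) "case" else p_filter$case,
    control = if (is.null(p_filter$control)) "control" else p_filter$control)
  keep <- det$status == "tested" & !is.na(det$p) & det$p <= alpha
  if (!any(keep))
    stop("no transcripts pass the p-value filter", call. = FALSE)
  v[keep, , drop = FALSE]
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Embeds samples by classical MDS (eigendecomposition of the double-centred
#' squared-distance matrix) on Euclidean distances computed over
#' `log2(value + 1)`-transformed transcripts, optionally restricted to a
#' Welch p-value filter. Coordinates are centred per axis; the orientation of
#' each axis is fixed by making its largest-magnitude coordinate positive,
#' so results are reproducible across platforms.
#'
#' @inheritParams sample_correlation_matrix
#' @param dims number of output dimensions (default 2); needs at least
#'   `dims + 1` samples.
#' @param log2_transform apply `log2(value + 1)` before computing distances
#'   (default TRUE).
#' @return numeric matrix samples x dims with columns `MDS1`, `MDS2`, ...
#' @export
classical_mds <- function(x, dims = 2L, p_filter = NULL,
                          log2_transform = TRUE) {
  stopifnot(is_expr_matrix(x))
  if (ncol(x) < dims + 1L)
    stop(sprintf("need at least %d samples for %d dimensions", dims + 1L, dims),
         call. = FALSE)
  v <- filtered_values(x, p_filter)
  if (log2_transform) v <- log2(v + 1)
  d <- stats::dist(t(v))
  coords <- stats::cmdscale(d, k = dims)
  if (ncol(coords) < dims) {
    # degenerate geometry (fewer positive eigenvalues than dims): pad zeros
    pad <- matrix(0, nrow(coords), dims - ncol(coords))
    coords <- cbind(coords, pad)
  }
  coords <- scale(coords, center = TRUE, scale = FALSE)
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("MDS", seq_len(dims))
  attr(coords, "scaled:center") <- NULL
  coords
}
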