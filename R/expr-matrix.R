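#' Expression matrix with a recorded metric
#'
#' An `expr_matrix` is a numeric matrix (transcripts in rows, samples in
#' columns) carrying a `metric` attribute that records the expression unit
#' (`"counts"`, `"TPM"` or `"FPKM"`). The metric is propagated through every
#' transformation so that downstream steps can check they received the unit
#' they expect. Zeros are meaningful observations (they drive the
#' switched-on/off classification), never missing values.
#'
#' @param values numeric matrix with unique, non-empty rownames (transcript
#'   IDs) and colnames (sample IDs); all values finite and >= 0.
#' @param metric one of `"counts"`, `"TPM"`, `"FPKM"`.
#' @return an object of class `expr_matrix`.
#' @examples
#' m <- expr_matrix(matrix(c(1, 0, 5, 2, 4, 5), nrow = 3,
#'                         dimnames = list(paste0("T", 1:3), c("s1", "s2"))),
#'                  metric = "TPM")
#' expr_metric(m)
#' @export
expr_matrix <- function(values, metric = c("counts", "TPM", "FPKM")) {
  metric <- match.arg(metric)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (transcripts) and colnames (samples)",
         call. = FALSE)
  validate_ids(rownames(values), "transcript")
  validate_ids(colnames(values), "sample")
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "expression values must be finite and >= 0; first offending cell: row '%s', column '%s'",
      rownames(values)[ij[1L]], colnames(values)[ij[2L]]), call. = FALSE)
  }
  structure(values, metric = metric, class = c("expr_matrix", "matrix", "array"))
}

validate_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("%s IDs must be non-empty", what), call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s ID(s): %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  invisible(ids)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_metric <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "metric")
}

#' Test for expr_matrix
#' @param x object.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "metric")))
  n <- min(nrow(x), 6L)
  m <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m)
    cat(sprintf("... (%d rows, %d cols not shown)\n",
                nrow(x) - n, ncol(x) - m))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, metric = attr(x, "metric"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

# strip class for plain-matrix maths
expr_values <- function(x) {
  out <- unclass(x)
  attr(out, "metric") <- NULL
  out
}
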