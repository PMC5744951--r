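#' Group-average expression profile
#'
#' Per-transcript arithmetic mean over the samples of one design group.
#'
#' @param x an [expr_matrix].
#' @param design a [sample_design].
#' @param group group label present in `design`.
#' @return named numeric vector (transcript -> mean expression).
#' @export
group_mean_profile <- function(x, design, group) {
  stopifnot(is_expr_matrix(x))
  samples <- intersect(group_samples(design, group), colnames(x))
  if (!length(samples))
    stop(sprintf("group '%s' has no samples in the matrix", group),
         call. = FALSE)
  rowMeans(expr_values(x)[, samples, drop = FALSE])
}

#' Transcript weights from discrimination p-values
#'
#' Converts per-transcript p-values into normalized weights
#' `w_i = |log10 p_i| / sum_i |log10 p_i|`, so that transcripts that
#' discriminate strongly (small p) dominate the weighted correlation while
#' uninformative transcripts (p near 1) contribute almost nothing.
#'
#' @param p numeric vector of p-values in (0, 1]; values below `floor` are
#'   clamped to `floor` so weights stay finite.
#' @param floor lower clamp for p-values (default 1e-300).
#' @param uniform_fallback if all p equal 1 the denominator is zero; by
#'   default this errors, with `uniform_fallback = TRUE` uniform weights are
#'   returned with a warning.
#' @return numeric weight vector summing to 1 (names preserved).
#' @examples
#' compute_weights(c(0.01, 0.1))  # 2/3, 1/3
#' @export
compute_weights <- function(p, floor = 1e-300, uniform_fallback = FALSE) {
  if (!length(p)) stop("'p' must be non-empty", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p <- pmax(p, floor)
  a <- abs(log10(p))
  s <- sum(a)
  if (s == 0) {
    if (uniform_fallback) {
      warning("all p-values equal 1; falling back to uniform weights")
      return(rep(1 / length(p), length(p)) |> stats::setNames(names(p)))
    }
    stop("all p-values equal 1: weights undefined (see 'uniform_fallback')",
         call. = FALSE)
  }
  a / s
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with per-observation weights `w` (sum 1):
#' weighted means `mu_w(v) = sum w_i v_i`, weighted covariance
#' `cov_w(x, y) = sum w_i (x_i - mu_w(x)) (y_i - mu_w(y))`, and
#' `r = cov_w(x, y) / sqrt(cov_w(x, x) cov_w(y, y))`. With uniform weights
#' this reduces to the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, same length, summing to 1 (tolerance 1e-6).
#' @return correlation in [-1, 1], or `NA` with a warning when either
#'   weighted variance is zero.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("'x', 'y' and 'w' must have equal length", call. = FALSE)
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-6)
    stop("weights must sum to 1", call. = FALSE)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx == 0 || cyy == 0) {
    warning("zero weighted variance: correlation undefined")
    return(NA_real_)
  }
  r <- cxy / sqrt(cxx * cyy)
  min(1, max(-1, r))
}

#' Weighted correlation of group profiles against a staged reference
#'
#' Scores the case (treatment) and control group-average expression profiles
#' against every tumour stage and the adjacent-normal profile of a staged
#' reference compendium. For each stage-versus-normal pair, transcripts are
#' weighted by [compute_weights()] applied to that pair's discrimination
#' p-values, and weighted Pearson correlations are computed on the transcript
#' universe shared between matrix and reference. The report carries, per
#' metric and stage pair, `r(case, stage)`, `r(control, stage)`,
#' `r(case, normal)`, `r(control, normal)`, and summarises the case-control
#' differences both as absolute deltas and as percent of the control
#' correlation.
#'
#' @param x an [expr_matrix].
#' @param design a [sample_design].
#' @param ref a [stage_reference].
#' @param case,control group labels in `design`.
#' @param min_overlap minimum number of shared transcripts (default 100).
#' @param log2_transform apply `log2(v + 1)` to profiles and reference before
#'   correlating (default TRUE). On the raw metric scale
#'   (`log2_transform = FALSE`) the weighted correlation is dominated by the
#'   few highest-abundance transcripts, which makes profile comparisons
#'   unstable; the log scale is the conventional choice for expression
#'   profile correlation.
#' @param floor,uniform_fallback passed to [compute_weights()].
#' @return a `stage_cor_report`: list with element `per_stage` (data frame
#'   with columns `metric`, `stage`, `r_case_stage`, `r_control_stage`,
#'   `r_case_normal`, `r_control_normal`, `delta_stage`, `delta_normal`),
#'   element `summary` (data frame per metric with mean deltas vs normal and
#'   vs tumour stages, absolute and as percent of the control r), and
#'   `n_overlap`.
#' @export
stage_correlation_report <- function(x, design, ref,
                                     case = "case", control = "control",
                                     min_overlap = 100L,
                                     log2_transform = TRUE,
                                     floor = 1e-300,
                                     uniform_fallback = FALSE) {
  stopifnot(is_expr_matrix(x), inherits(ref, "stage_reference"))
  shared <- intersect(rownames(x), ref_transcripts(ref))
  if (length(shared) < min_overlap)
    stop(sprintf("only %d transcripts shared between matrix and reference (>= %d required)",
                 length(shared), min_overlap), call. = FALSE)
  prof_case <- group_mean_profile(x, design, case)[shared]
  prof_ctrl <- group_mean_profile(x, design, control)[shared]
  tf <- if (log2_transform) function(v) log2(v + 1) else identity

  rows <- list()
  for (m in ref_metrics(ref)) {
    e <- ref$expr[[m]][shared, , drop = FALSE]
    pv <- ref$pvals[[m]][shared, , drop = FALSE]
    for (s in ref_stages(ref)) {
      w <- compute_weights(pv[, s], floor = floor,
                           uniform_fallback = uniform_fallback)
      rcs <- weighted_pearson(tf(prof_case), tf(e[, s]), w)
      rks <- weighted_pearson(tf(prof_ctrl), tf(e[, s]), w)
      rcn <- weighted_pearson(tf(prof_case), tf(e[, "normal"]), w)
      rkn <- weighted_pearson(tf(prof_ctrl), tf(e[, "normal"]), w)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, stage = s,
        r_case_stage = rcs, r_control_stage = rks,
        r_case_normal = rcn, r_control_normal = rkn,
        delta_stage = rcs - rks, delta_normal = rcn - rkn,
        stringsAsFactors = FALSE)
    }
  }
  per_stage <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_stage, per_stage$metric), function(d)
    data.frame(
      metric = d$metric[1L],
      mean_delta_normal = mean(d$delta_normal),
      mean_delta_stage = mean(d$delta_stage),
      pct_delta_normal = mean(100 * d$delta_normal / d$r_control_normal),
      pct_delta_stage = mean(100 * d$delta_stage / d$r_control_stage),
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(per_stage = per_stage, summary = summ,
                 n_overlap = length(shared)),
            class = "stage_cor_report")
}

#' @export
print.stage_cor_report <- function(x, ...) {
  cat(sprintf("stage_cor_report: %d shared transcripts\n", x$n_overlap))
  print(format_num_df(x$per_stage), row.names = FALSE)
  cat("summary (mean over stage pairs):\n")
  print(format_num_df(x$summary), row.names = FALSE)
  invisible(x)
}

#' Write a stage correlation report as JSON
#' @param report a `stage_cor_report`.
#' @param path output path.
#' @export
write_stage_cor_report <- function(report, path) {
  jsonlite::write_json(
    list(per_stage = report$per_stage, summary = report$summary,
         n_overlap = report$n_overlap),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
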