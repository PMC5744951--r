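#' Welch's unequal-variances t-test
#'
#' Two-sided two-sample t-test without the equal-variance assumption:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/n + s2y/m)` with Welch-Satterthwaite
#' degrees of freedom. Sample variances use the n-1 denominator.
#'
#' Degenerate inputs follow a fixed convention so that expression matrices
#' with constant transcripts can be processed without dropping rows: if both
#' group variances are zero and the means agree, the result is
#' `(t = 0, df = n + m - 2, p = 1)`; if both variances are zero but the means
#' differ, `t` is `+/-Inf`, `p = 0`, and the result is flagged `degenerate`.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return list with elements `t`, `df`, `p` and logical `degenerate`.
#' @examples
#' welch_t_test(c(10.1, 9.8, 10.4, 10.0), c(8.2, 8.5, 7.9, 8.8))
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  r <- welch_rows(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(t = r$t[1L], df = r$df[1L], p = r$p[1L], degenerate = r$degenerate[1L])
}

# vectorised Welch test over matrix rows (transcripts)
welch_rows <- function(xm, ym) {
  n <- ncol(xm); m <- ncol(ym)
  mx <- rowMeans(xm); my <- rowMeans(ym)
  vx <- rowSums((xm - mx)^2) / (n - 1)
  vy <- rowSums((ym - my)^2) / (m - 1)
  se2 <- vx / n + vy / m
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zerovar <- vx == 0 & vy == 0
  eq <- zerovar & mx == my
  ne <- zerovar & mx != my
  tt[eq] <- 0; df[eq] <- n + m - 2; p[eq] <- 1
  tt[ne] <- sign(mx - my)[ne] * Inf; df[ne] <- n + m - 2; p[ne] <- 0
  list(t = tt, df = df, p = p, degenerate = ne)
}

#' Classify transcripts: differential expression with switched-on/off labels
#'
#' Per-transcript two-group comparison following the transcript-level calling
#' scheme for treatment-versus-control RNA-seq: transcripts that are all-zero
#' in both groups are `excluded`; transcripts expressed in exactly one group
#' are labelled categorically (`switched_off` when all case/treatment values
#' are zero, `switched_on` when all control values are zero) and are not
#' tested; all remaining transcripts are `tested` with [welch_t_test()].
#' A tested transcript is called differentially expressed (DET) when its
#' nominal p-value is below `alpha`; "measurable expression in both groups"
#' is taken at group level (group mean > 0), consistent with the group-level
#' zero rule behind the switched labels.
#'
#' @param x an [expr_matrix].
#' @param design a [sample_design] covering all samples of `x`, with at least
#'   2 samples in each of the `case` and `control` groups.
#' @param alpha nominal significance threshold for the DET call (default
#'   0.05; no multiple-testing correction, matching a nominal-p workflow).
#' @param case,control group labels in `design`.
#' @param pseudo pseudo-count added to both group means in the log2
#'   fold-change, `log2((mean_case + pseudo)/(mean_control + pseudo))`.
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values in column `p_adj`; the DET call then uses `p_adj`.
#' @return a `det_table`: data frame with one row per transcript (input
#'   order), columns `transcript_id`, `status`, `mean_case`, `mean_control`,
#'   `log2fc`, `t`, `df`, `p` (and `p_adj` if requested), `degenerate`,
#'   `det` (logical DET call), plus attributes `alpha` and `counts`
#'   (`n_up`, `n_down`, `n_switched_on`, `n_switched_off`).
#' @export
classify_transcripts <- function(x, design, alpha = 0.05,
                                 case = "case", control = "control",
                                 pseudo = 1e-2,
                                 p_adjust = c("none", "BH")) {
  stopifnot(is_expr_matrix(x))
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]", call. = FALSE)
  check_design(x, design, groups = c(case, control), min_n = 2L)
  v <- expr_values(x)
  cs <- intersect(design$sample_id[design$group == case], colnames(v))
  ks <- intersect(design$sample_id[design$group == control], colnames(v))
  xm <- v[, cs, drop = FALSE]
  ym <- v[, ks, drop = FALSE]

  mean_case <- rowMeans(xm)
  mean_control <- rowMeans(ym)
  case_zero <- rowSums(xm > 0) == 0
  ctrl_zero <- rowSums(ym > 0) == 0
  status <- rep("tested", nrow(v))
  status[case_zero & ctrl_zero] <- "excluded"
  status[case_zero & !ctrl_zero] <- "switched_off"
  status[!case_zero & ctrl_zero] <- "switched_on"

  tt <- df <- p <- rep(NA_real_, nrow(v))
  degen <- rep(FALSE, nrow(v))
  tested <- status == "tested"
  if (any(tested)) {
    r <- welch_rows(xm[tested, , drop = FALSE], ym[tested, , drop = FALSE])
    tt[tested] <- r$t; df[tested] <- r$df; p[tested] <- r$p
    degen[tested] <- r$degenerate
  }

  out <- data.frame(
    transcript_id = rownames(v),
    status = status,
    mean_case = mean_case,
    mean_control = mean_control,
    log2fc = log2((mean_case + pseudo) / (mean_control + pseudo)),
    t = tt, df = df, p = p,
    degenerate = degen,
    stringsAsFactors = FALSE, row.names = NULL)

  p_eff <- p
  if (p_adjust == "BH") {
    out$p_adj <- NA_real_
    out$p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
    p_eff <- out$p_adj
  }
  out$det <- tested & !is.na(p_eff) & p_eff < alpha

  up <- out$det & mean_case > mean_control
  down <- out$det & mean_case < mean_control
  structure(out,
            class = c("det_table", "data.frame"),
            alpha = alpha,
            p_adjust = p_adjust,
            counts = c(n_up = sum(up), n_down = sum(down),
                       n_switched_on = sum(status == "switched_on"),
                       n_switched_off = sum(status == "switched_off")))
}

#' @export
print.det_table <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("det_table: %d transcripts (alpha = %g%s)\n", nrow(x),
              attr(x, "alpha"),
              if (identical(attr(x, "p_adjust"), "BH")) ", BH-adjusted" else ""))
  cat(sprintf("  DETs: %d up, %d down; switched on: %d, switched off: %d; excluded: %d\n",
              cts["n_up"], cts["n_down"], cts["n_switched_on"],
              cts["n_switched_off"], sum(x$status == "excluded")))
  invisible(x)
}

#' @export
summary.det_table <- function(object, ...) {
  cts <- attr(object, "counts")
  c(n_transcripts = nrow(object),
    n_tested = sum(object$status == "tested"),
    n_det = sum(object$det),
    cts,
    n_excluded = sum(object$status == "excluded"))
}

#' Write a det_table to TSV
#' @param x a `det_table`.
#' @param path output path.
#' @export
write_det_table <- function(x, path) {
  utils::write.table(format_num_df(as.data.frame(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num_df <- function(df, digits = 6L) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
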