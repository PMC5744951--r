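#' Case-to-normal expression ratio (CNR)
#'
#' Ratio of case to control/normal group-mean expression with a pseudo-count
#' guarding zero means: `(case_mean + epsilon) / (normal_mean + epsilon)`.
#'
#' @param case_mean,normal_mean group-mean expression values (>= 0);
#'   vectorised.
#' @param epsilon pseudo-count on the expression scale (> 0, default 1).
#' @return positive finite ratio(s).
#' @export
compute_cnr <- function(case_mean, normal_mean, epsilon = 1.0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a single positive number", call. = FALSE)
  if (any(case_mean < 0) || any(normal_mean < 0))
    stop("mean expression values must be >= 0", call. = FALSE)
  (case_mean + epsilon) / (normal_mean + epsilon)
}

#' Beyond-tolerance-interval flag (BTIF)
#'
#' Flags a gene whose case-to-normal ratio falls outside a symmetric
#' tolerance interval on the ratio scale: 1 if `cnr > theta` or
#' `cnr < 1/theta`, else 0. The interval is symmetric under ratio inversion,
#' so `compute_btif(c) == compute_btif(1/c)`.
#'
#' @param cnr positive ratio(s), e.g. from [compute_cnr()].
#' @param theta tolerance-fold threshold (> 1, default 1.5).
#' @return integer 0/1 vector.
#' @export
compute_btif <- function(cnr, theta = 1.5) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 1)
    stop("'theta' must be a single number > 1", call. = FALSE)
  if (any(cnr <= 0)) stop("'cnr' must be > 0", call. = FALSE)
  as.integer(cnr > theta | cnr < 1 / theta)
}

#' Pathway Activation Strength for one pathway
#'
#' Implements the OncoFinder-style score
#' `PAS_p = sum_n ARR_np * BTIF_n * lg(CNR_n)` with `lg` the base-10
#' logarithm: each pathway gene contributes its activator/repressor role
#' times its beyond-tolerance flag times the log10 case-to-normal ratio.
#' Positive PAS indicates pathway activation in the case group.
#'
#' @param pw a [pathway].
#' @param ratios data frame with columns `gene_id`, `cnr`, `btif` (e.g. built
#'   from [compute_cnr()] and [compute_btif()] on group means). Pathway genes
#'   absent from `ratios` contribute 0 and are counted as uncovered.
#' @return a `pas_result`: list with `pathway_id`, `pas`, `contributions`
#'   (named per-gene vector), `n_genes`, `n_flagged` (btif = 1 genes present
#'   in the pathway), `n_missing` (pathway genes without expression data).
#' @export
compute_pas <- function(pw, ratios) {
  stopifnot(inherits(pw, "pathway"))
  need <- c("gene_id", "cnr", "btif")
  if (!all(need %in% colnames(ratios)))
    stop("'ratios' needs columns gene_id, cnr, btif", call. = FALSE)
  idx <- match(names(pw$roles), ratios$gene_id)
  present <- !is.na(idx)
  contrib <- stats::setNames(numeric(length(pw$roles)), names(pw$roles))
  n_flagged <- 0L
  if (any(present)) {
    cnr <- ratios$cnr[idx[present]]
    btif <- ratios$btif[idx[present]]
    if (any(cnr <= 0)) stop("CNR values must be > 0", call. = FALSE)
    contrib[present] <- pw$roles[present] * btif * log10(cnr)
    n_flagged <- sum(btif == 1)
  }
  structure(list(pathway_id = pw$pathway_id,
                 pas = sum(contrib),
                 contributions = contrib,
                 n_genes = length(pw$roles),
                 n_flagged = n_flagged,
                 n_missing = sum(!present)),
            class = "pas_result")
}

#' @export
print.pas_result <- function(x, ...) {
  cat(sprintf("pathway '%s': PAS = %.4g (%d genes, %d flagged, %d missing)\n",
              x$pathway_id, x$pas, x$n_genes, x$n_flagged, x$n_missing))
  invisible(x)
}

#' Pathway activation profile for a two-group experiment
#'
#' Computes the full case-vs-control pathway activation profile: group-mean
#' expression per gene, case-to-normal ratios ([compute_cnr()]),
#' beyond-tolerance flags ([compute_btif()]), and [compute_pas()] per
#' pathway. Pathways are partitioned by sign into up (PAS > 0), down
#' (PAS < 0) and unchanged (PAS = 0). Optionally attaches a permutation
#' p-value per pathway obtained by shuffling sample labels.
#'
#' @param x an [expr_matrix] with genes/transcripts in rows.
#' @param design a [sample_design].
#' @param pathways list of [pathway] objects.
#' @param theta BTIF tolerance fold (see [compute_btif()]).
#' @param epsilon CNR pseudo-count (see [compute_cnr()]).
#' @param case,control group labels.
#' @param n_perm number of label permutations for an optional two-sided
#'   permutation p-value on |PAS| (0 = off, default).
#' @param perm_seed seed for the permutation draw (required when
#'   `n_perm > 0`).
#' @return a `pas_table`: data frame with columns `pathway_id`, `pas`,
#'   `n_genes`, `n_flagged`, `n_missing`, `direction` and optionally
#'   `perm_p`, plus attribute `results` (list of `pas_result`).
#' @export
pas_profile <- function(x, design, pathways, theta = 1.5, epsilon = 1.0,
                        case = "case", control = "control",
                        n_perm = 0L, perm_seed = NULL) {
  stopifnot(is_expr_matrix(x))
  check_design(x, design, groups = c(case, control), min_n = 1L)
  res <- pas_for_labels(x, design$sample_id, design$group, pathways,
                        theta, epsilon, case, control)
  tab <- data.frame(
    pathway_id = vapply(res, `[[`, "", "pathway_id"),
    pas = vapply(res, `[[`, 0, "pas"),
    n_genes = vapply(res, `[[`, 0L, "n_genes"),
    n_flagged = vapply(res, `[[`, 0L, "n_flagged"),
    n_missing = vapply(res, `[[`, 0L, "n_missing"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$direction <- ifelse(tab$pas > 0, "up", ifelse(tab$pas < 0, "down",
                                                    "unchanged"))
  if (n_perm > 0L) {
    if (is.null(perm_seed))
      stop("'perm_seed' is required when n_perm > 0", call. = FALSE)
    obs <- abs(tab$pas)
    exceed <- integer(length(obs))
    in_groups <- design$group %in% c(case, control)
    ids <- design$sample_id[in_groups]
    labs <- design$group[in_groups]
    set.seed(perm_seed)
    for (b in seq_len(n_perm)) {
      perm <- sample(labs)
      pres <- pas_for_labels(x, ids, perm, pathways, theta, epsilon,
                             case, control)
      pabs <- abs(vapply(pres, `[[`, 0, "pas"))
      exceed <- exceed + (pabs >= obs)
    }
    tab$perm_p <- (exceed + 1) / (n_perm + 1)
  }
  structure(tab, class = c("pas_table", "data.frame"), results = res,
            theta = theta, epsilon = epsilon)
}

pas_for_labels <- function(x, sample_ids, groups, pathways, theta, epsilon,
                           case, control) {
  v <- expr_values(x)
  cs <- sample_ids[groups == case]
  ks <- sample_ids[groups == control]
  mean_case <- rowMeans(v[, cs, drop = FALSE])
  mean_ctrl <- rowMeans(v[, ks, drop = FALSE])
  cnr <- compute_cnr(mean_case, mean_ctrl, epsilon)
  ratios <- data.frame(gene_id = rownames(v), cnr = cnr,
                       btif = compute_btif(cnr, theta),
                       stringsAsFactors = FALSE, row.names = NULL)
  lapply(pathways, compute_pas, ratios = ratios)
}

#' @export
print.pas_table <- function(x, ...) {
  cat(sprintf("pas_table: %d pathways (%d up, %d down, %d unchanged)\n",
              nrow(x), sum(x$direction == "up"), sum(x$direction == "down"),
              sum(x$direction == "unchanged")))
  print(format_num_df(as.data.frame(x)), row.names = FALSE)
  invisible(x)
}

#' Write a pas_table to TSV
#' @param x a `pas_table`.
#' @param path output path.
#' @export
write_pas_table <- function(x, path) {
  utils::write.table(format_num_df(as.data.frame(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
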