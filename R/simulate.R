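#' Simulate a two-group expression matrix with known ground truth
#'
#' Generates a treatment/control TPM matrix with the statistical shape of a
#' small bulk RNA-seq experiment: log-normal baseline abundances shared by
#' both groups, a minority of truly shifted (differentially expressed)
#' transcripts, group-specific all-zero ("switched") transcripts,
#' multiplicative log-normal noise, and abundance-dependent dropout that
#' produces a zero-inflated low-expression tail. Columns are rescaled to sum
#' to 1e6 (TPM). With `counts = TRUE` the same cell means are instead
#' Poisson-sampled at per-sample library depths and returned as raw counts
#' together with simulated transcript lengths, for exercising RPKM/TPM
#' normalization.
#'
#' @param n_transcripts number of transcripts (default 2000).
#' @param n_case,n_control group sizes (defaults 6 and 5).
#' @param frac_de fraction of transcripts with a planted expression shift
#'   (default 0.05, half up / half down).
#' @param effect_log2 planted shift magnitude on the log2 scale (default 1.5).
#' @param frac_switched fraction of transcripts zeroed in exactly one group
#'   (default 0.01, half switched_on / half switched_off).
#' @param dispersion standard deviation of the multiplicative log-normal
#'   noise on the natural-log scale (default 0.3).
#' @param baseline_meanlog,baseline_sdlog parameters of the log-normal
#'   baseline abundance distribution (defaults 2 and 1.5, giving the skewed
#'   non-negative shape of TPM data).
#' @param detection_scale scale of the abundance-dependent dropout
#'   `P(zero) = exp(-value / detection_scale)` applied before TPM rescaling
#'   (default 0.5; 0 disables dropout).
#' @param counts return Poisson counts instead of TPM (see above).
#' @param mean_depth mean library size used in counts mode (default 2e5).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list with elements `matrix` (an [expr_matrix]), `design`
#'   (a [sample_design] with groups `case`/`control`), `truth` (a `sim_truth`:
#'   per-transcript labels in \{null, up, down, switched_on, switched_off\},
#'   signed planted effects on the log2 scale, the seed and the parameters),
#'   and in counts mode `lengths` (named vector of transcript lengths in bp).
#' @export
simulate_expression <- function(n_transcripts = 2000L, n_case = 6L,
                                n_control = 5L, frac_de = 0.05,
                                effect_log2 = 1.5, frac_switched = 0.01,
                                dispersion = 0.3,
                                baseline_meanlog = 2, baseline_sdlog = 1.5,
                                detection_scale = 0.5,
                                counts = FALSE, mean_depth = 2e5,
                                seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (frac_de < 0 || frac_de > 0.5 || frac_switched < 0 || frac_switched > 0.5)
    stop("'frac_de' and 'frac_switched' must lie in [0, 0.5]", call. = FALSE)
  if (n_case < 2L || n_control < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))

  ids <- sprintf("T%05d", seq_len(n_transcripts))
  samples <- c(sprintf("case_%d", seq_len(n_case)),
               sprintf("ctrl_%d", seq_len(n_control)))
  design <- sample_design(samples, rep(c("case", "control"),
                                       c(n_case, n_control)))

  baseline <- stats::rlnorm(n_transcripts, baseline_meanlog, baseline_sdlog)
  labels <- rep("null", n_transcripts)
  effects <- numeric(n_transcripts)

  n_de <- round(frac_de * n_transcripts)
  n_sw <- round(frac_switched * n_transcripts)
  special <- sample.int(n_transcripts, n_de + n_sw)
  de_idx <- special[seq_len(n_de)]
  sw_idx <- special[n_de + seq_len(n_sw)]
  up_idx <- de_idx[seq_len(n_de %/% 2)]
  down_idx <- setdiff(de_idx, up_idx)
  labels[up_idx] <- "up"; labels[down_idx] <- "down"
  effects[up_idx] <- effect_log2; effects[down_idx] <- -effect_log2
  on_idx <- sw_idx[seq_len(n_sw %/% 2)]
  off_idx <- setdiff(sw_idx, on_idx)
  labels[on_idx] <- "switched_on"; labels[off_idx] <- "switched_off"

  mean_case <- baseline * 2^effects
  mean_ctrl <- baseline
  n_samples <- n_case + n_control
  mu <- cbind(matrix(mean_case, n_transcripts, n_case),
              matrix(mean_ctrl, n_transcripts, n_control))
  noise <- matrix(stats::rnorm(n_transcripts * n_samples, 0, dispersion),
                  n_transcripts, n_samples)
  raw <- mu * exp(noise)
  v <- raw
  if (detection_scale > 0) {
    drop <- matrix(stats::runif(n_transcripts * n_samples),
                   n_transcripts, n_samples) < exp(-v / detection_scale)
    v[drop] <- 0
  }
  # structural group-specific zeros; the expressed group keeps its pre-dropout
  # values so planted switched transcripts are never all-zero in both groups
  case_cols <- seq_len(n_case)
  ctrl_cols <- n_case + seq_len(n_control)
  v[on_idx, ctrl_cols] <- 0
  v[on_idx, case_cols] <- raw[on_idx, case_cols, drop = FALSE]
  v[off_idx, case_cols] <- 0
  v[off_idx, ctrl_cols] <- raw[off_idx, ctrl_cols, drop = FALSE]
  dimnames(v) <- list(ids, samples)

  truth <- structure(list(
    labels = stats::setNames(labels, ids),
    effect_log2 = stats::setNames(effects, ids),
    baseline = stats::setNames(baseline, ids),
    seed = as.integer(seed),
    params = list(n_transcripts = n_transcripts, n_case = n_case,
                  n_control = n_control, frac_de = frac_de,
                  effect_log2 = effect_log2, frac_switched = frac_switched,
                  dispersion = dispersion)), class = "sim_truth")

  if (counts) {
    lengths <- stats::setNames(
      sample(200:10000, n_transcripts, replace = TRUE), ids)
    depths <- round(mean_depth * exp(stats::rnorm(n_samples, 0, 0.1)))
    rate <- v * lengths  # expected reads proportional to abundance x length
    cm <- vapply(seq_len(n_samples), function(j) {
      pr <- rate[, j] / sum(rate[, j])
      stats::rpois(n_transcripts, depths[j] * pr)
    }, numeric(n_transcripts))
    dimnames(cm) <- list(ids, samples)
    return(list(matrix = expr_matrix(cm, "counts"), design = design,
                truth = truth, lengths = lengths))
  }

  tpm <- sweep(v, 2L, colSums(v), "/") * 1e6
  list(matrix = expr_matrix(tpm, "TPM"), design = design, truth = truth)
}

#' Simulate a staged reference compendium
#'
#' Builds a staged tumour reference (stages I--IV plus adjacent normal) over
#' a transcript universe matching [simulate_expression()]: a log-normal
#' normal-tissue profile, stage profiles in which a subset of informative
#' transcripts shifts progressively away from normal (stage IV farthest,
#' shift `sep * stage_index` on the log2 scale, random direction per
#' transcript), and per-transcript stage-versus-normal discrimination
#' p-values obtained from Welch tests on simulated per-stage replicates.
#' With `sep = 0` stage profiles equal the normal profile and the p-values
#' are approximately uniform.
#'
#' @param n_transcripts transcript universe size.
#' @param stages tumour stage labels, nearest to farthest from normal.
#' @param n_informative number of stage-discriminating transcripts
#'   (default 200).
#' @param sep per-stage separation step on the log2 scale (default 1.0).
#' @param n_replicates simulated replicates per stage used for the
#'   discrimination p-values (default 8).
#' @param replicate_sdlog replicate noise on the natural-log scale
#'   (default 0.12).
#' @param metrics expression metrics to emit (`"TPM"`, optionally also
#'   `"FPKM"`; the FPKM variant is a rescaled profile with independently
#'   re-simulated replicate noise).
#' @param baseline_meanlog,baseline_sdlog baseline abundance distribution
#'   used when no `baseline` is supplied.
#' @param baseline optional named abundance vector (e.g. the `baseline`
#'   recorded in the truth of [simulate_expression()]). When given, the
#'   normal profile is this baseline perturbed by log-normal deviation
#'   `profile_sdlog`, which reproduces the realistic situation where a
#'   reference compendium of the same tissue shares the global abundance
#'   structure of the assayed samples; when `NULL` the normal profile is an
#'   independent draw.
#' @param profile_sdlog natural-log spread of the reference-vs-sample
#'   abundance deviation used with `baseline` (default 0.5).
#' @param seed integer seed.
#' @return list with `ref` (a [stage_reference]) and `truth` (informative
#'   transcript IDs and their shift directions).
#' @export
simulate_stage_reference <- function(n_transcripts = 2000L,
                                     stages = c("I", "II", "III", "IV"),
                                     n_informative = 200L, sep = 1.0,
                                     n_replicates = 8L,
                                     replicate_sdlog = 0.12,
                                     metrics = "TPM",
                                     baseline_meanlog = 2,
                                     baseline_sdlog = 1.5,
                                     baseline = NULL, profile_sdlog = 0.5,
                                     seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_informative > n_transcripts)
    stop("'n_informative' must be <= 'n_transcripts'", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(baseline)) {
    ids <- sprintf("T%05d", seq_len(n_transcripts))
    normal <- stats::setNames(
      stats::rlnorm(n_transcripts, baseline_meanlog, baseline_sdlog), ids)
  } else {
    if (is.null(names(baseline)) || any(baseline < 0))
      stop("'baseline' must be a named non-negative vector", call. = FALSE)
    n_transcripts <- length(baseline)
    if (n_informative > n_transcripts)
      stop("'n_informative' must be <= length(baseline)", call. = FALSE)
    ids <- names(baseline)
    normal <- baseline *
      exp(stats::rnorm(n_transcripts, 0, profile_sdlog))
  }
  info_idx <- sample.int(n_transcripts, n_informative)
  dir <- sample(c(-1, 1), n_informative, replace = TRUE)

  shift_mat <- matrix(0, n_transcripts, length(stages))
  for (k in seq_along(stages))
    shift_mat[info_idx, k] <- dir * sep * k

  expr <- list(); pvals <- list()
  for (m in metrics) {
    scale_m <- if (m == "FPKM") 0.8 else 1
    e <- matrix(NA_real_, n_transcripts, length(stages) + 1L,
                dimnames = list(ids, c(stages, "normal")))
    e[, "normal"] <- normal * scale_m
    p <- matrix(NA_real_, n_transcripts, length(stages),
                dimnames = list(ids, stages))
    for (k in seq_along(stages)) {
      stage_mean <- normal * 2^shift_mat[, k] * scale_m
      e[, stages[k]] <- stage_mean
      reps_stage <- stage_mean * exp(matrix(
        stats::rnorm(n_transcripts * n_replicates, 0, replicate_sdlog),
        n_transcripts, n_replicates))
      reps_normal <- normal * scale_m * exp(matrix(
        stats::rnorm(n_transcripts * n_replicates, 0, replicate_sdlog),
        n_transcripts, n_replicates))
      p[, stages[k]] <- welch_rows(reps_stage, reps_normal)$p
    }
    # Welch p can be exactly 0 only in degenerate cases; keep within (0, 1]
    p <- pmin(pmax(p, 1e-300), 1)
    expr[[m]] <- e
    pvals[[m]] <- p
  }
  list(ref = stage_reference(expr, pvals),
       truth = list(informative = ids[info_idx],
                    direction = stats::setNames(dir, ids[info_idx]),
                    seed = as.integer(seed)))
}

#' Blend case samples toward the reference normal profile
#'
#' Creates the "treatment moves the transcriptome toward normal tissue"
#' scenario: every case-group column is replaced by
#' `(1 - blend) * original + blend * normal_profile`, optionally with
#' multiplicative log-normal noise; control columns are untouched. With
#' `blend = 0` the matrix is returned unchanged.
#'
#' @param x an [expr_matrix].
#' @param ref a [stage_reference] whose normal profile provides the target
#'   (first metric is used); transcripts shared with `x` are blended, others
#'   left as-is.
#' @param design a [sample_design] identifying the case group.
#' @param blend blending coefficient in [0, 1] (default 0.3).
#' @param noise_sdlog multiplicative noise on the blended values
#'   (natural-log scale, default 0.05; 0 disables noise).
#' @param case case group label.
#' @param seed integer seed (used only when `noise_sdlog > 0`).
#' @return the blended [expr_matrix] (same dimensions and metric).
#' @export
simulate_case_blend <- function(x, ref, design, blend = 0.3,
                                noise_sdlog = 0.05, case = "case", seed) {
  stopifnot(is_expr_matrix(x), inherits(ref, "stage_reference"))
  if (blend < 0 || blend > 1) stop("'blend' must be in [0, 1]", call. = FALSE)
  if (blend == 0) return(x)
  shared <- intersect(rownames(x), ref_transcripts(ref))
  normal <- ref$expr[[1L]][shared, "normal"]
  cs <- intersect(group_samples(design, case), colnames(x))
  v <- expr_values(x)
  blended <- (1 - blend) * v[shared, cs, drop = FALSE] + blend * normal
  if (noise_sdlog > 0) {
    if (missing(seed)) stop("'seed' is required when noise_sdlog > 0",
                            call. = FALSE)
    set.seed(as.integer(seed))
    blended <- blended * exp(matrix(
      stats::rnorm(length(blended), 0, noise_sdlog),
      nrow(blended), ncol(blended)))
  }
  v[shared, cs] <- blended
  expr_matrix(v, metric = expr_metric(x))
}

#' Simulate pathways with planted activation
#'
#' Builds a toy pathway set over the genes of an existing matrix and plants
#' known activation: pathways draw disjoint gene sets with mixed
#' activator/repressor roles; in planted activated pathways the case-group
#' expression of activator genes is up-shifted and of repressor genes
#' down-shifted by `shift_log2` (and conversely for planted repressed
#' pathways), so the true PAS sign is known by construction.
#'
#' @param x an [expr_matrix].
#' @param design a [sample_design].
#' @param n_pathways total number of pathways (default 50).
#' @param genes_per genes per pathway (default 20); requires
#'   `n_pathways * genes_per <= nrow(x)`.
#' @param n_active,n_repressed planted activated / repressed pathway counts
#'   (defaults 10 and 10); the rest are null.
#' @param shift_log2 planted shift magnitude on the log2 scale (default 1.5).
#' @param case case group label.
#' @param seed integer seed.
#' @return list with `pathways` (named list of [pathway]), `matrix` (the
#'   adjusted [expr_matrix]) and `truth` (per-pathway planted direction in
#'   \{activated, repressed, null\}).
#' @export
simulate_pathways <- function(x, design, n_pathways = 50L, genes_per = 20L,
                              n_active = 10L, n_repressed = 10L,
                              shift_log2 = 1.5, case = "case", seed) {
  stopifnot(is_expr_matrix(x))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_active + n_repressed > n_pathways)
    stop("'n_active' + 'n_repressed' must be <= 'n_pathways'", call. = FALSE)
  if (n_pathways * genes_per > nrow(x))
    stop("not enough genes in the matrix for disjoint pathways", call. = FALSE)
  set.seed(as.integer(seed))
  pool <- sample(rownames(x), n_pathways * genes_per)
  gene_sets <- split(pool, rep(seq_len(n_pathways), each = genes_per))
  direction <- rep("null", n_pathways)
  direction[seq_len(n_active)] <- "activated"
  direction[n_active + seq_len(n_repressed)] <- "repressed"
  direction <- sample(direction)  # shuffle which IDs carry the planting

  pids <- sprintf("PW%03d", seq_len(n_pathways))
  v <- expr_values(x)
  cs <- intersect(group_samples(design, case), colnames(x))
  pathways <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    roles <- stats::setNames(
      sample(c(-1, -0.5, 0, 0.5, 1), genes_per, replace = TRUE,
             prob = c(0.3, 0.15, 0.1, 0.15, 0.3)),
      gene_sets[[i]])
    if (all(roles == 0)) roles[1L] <- 1  # pathways need signal genes
    pathways[[i]] <- pathway(pids[i], roles)
    if (direction[i] != "null") {
      sgn <- if (direction[i] == "activated") 1 else -1
      fold <- 2^(sgn * shift_log2 * sign(roles))
      v[gene_sets[[i]], cs] <- v[gene_sets[[i]], cs, drop = FALSE] * fold
    }
  }
  list(pathways = stats::setNames(pathways, pids),
       matrix = expr_matrix(v, metric = expr_metric(x)),
       truth = list(direction = stats::setNames(direction, pids),
                    seed = as.integer(seed)))
}

#' Write simulation truth labels as JSON
#' @param truth a `sim_truth` (or compatible list).
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
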