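#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full pipeline run
#' (simulate -> differential calling -> stage correlation -> pathway
#' activation). Every parameter maps to one key in the YAML form written by
#' [write_run_config()], and configs round-trip losslessly through the file.
#'
#' @param preset scenario preset: `"a549"` (TPM, 6 vs 5, with staged
#'   reference, case blend and pathways), `"xenograft"` or `"liver"` (counts,
#'   RPKM normalization, Spearman sample correlations, no staged reference).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param alpha nominal DET threshold in (0, 1].
#' @param theta,epsilon PAS parameters (see [compute_btif()],
#'   [compute_cnr()]).
#' @param p_floor p-value clamp for [compute_weights()].
#' @param pseudo log2 fold-change pseudo-count.
#' @param blend case blend toward the normal profile (a549 preset).
#' @param log_transform use log2(v+1) in the stage correlation.
#' @param bh_correct use Benjamini-Hochberg adjusted p-values for DET calls.
#' @param n_perm permutation count for PAS p-values (0 = off).
#' @param uniform_fallback uniform-weight fallback when all p equal 1.
#' @param n_transcripts,n_case,n_control,frac_de,effect_log2,frac_switched,dispersion
#'   generator parameters (see [simulate_expression()]).
#' @return a validated `run_config` (named list).
#' @export
run_config <- function(preset = c("a549", "xenograft", "liver"),
                       seed = 1L, alpha = 0.05, theta = 1.5, epsilon = 1.0,
                       p_floor = 1e-300, pseudo = 1e-2, blend = 0.3,
                       log_transform = TRUE, bh_correct = FALSE,
                       n_perm = 0L, uniform_fallback = FALSE,
                       n_transcripts = 2000L, n_case = 6L, n_control = 5L,
                       frac_de = 0.05, effect_log2 = 1.5,
                       frac_switched = 0.01, dispersion = 0.3,
                       n_pathways = 50L, genes_per = 20L,
                       n_active = 10L, n_repressed = 10L) {
  cfg <- list(preset = match.arg(preset), seed = as.integer(seed),
              alpha = alpha, theta = theta, epsilon = epsilon,
              p_floor = p_floor, pseudo = pseudo, blend = blend,
              log_transform = isTRUE(log_transform),
              bh_correct = isTRUE(bh_correct), n_perm = as.integer(n_perm),
              uniform_fallback = isTRUE(uniform_fallback),
              n_transcripts = as.integer(n_transcripts),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              frac_de = frac_de, effect_log2 = effect_log2,
              frac_switched = frac_switched, dispersion = dispersion,
              n_pathways = as.integer(n_pathways),
              genes_per = as.integer(genes_per),
              n_active = as.integer(n_active),
              n_repressed = as.integer(n_repressed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  check_range <- function(name, lo, hi, lo_open = FALSE) {
    v <- cfg[[name]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) ||
        (if (lo_open) v <= lo else v < lo) || v > hi)
      stop(sprintf("config: '%s' must be a number in %s%g, %g]",
                   name, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
  if (!cfg$preset %in% c("a549", "xenograft", "liver"))
    stop("config: unknown preset", call. = FALSE)
  check_range("alpha", 0, 1, lo_open = TRUE)
  check_range("blend", 0, 1)
  check_range("frac_de", 0, 0.5)
  check_range("frac_switched", 0, 0.5)
  check_range("dispersion", 0, Inf)
  if (cfg$theta <= 1) stop("config: 'theta' must be > 1", call. = FALSE)
  if (cfg$epsilon <= 0) stop("config: 'epsilon' must be > 0", call. = FALSE)
  if (cfg$n_case < 2L || cfg$n_control < 2L)
    stop("config: group sizes must be >= 2", call. = FALSE)
  if (cfg$n_perm < 0L) stop("config: 'n_perm' must be >= 0", call. = FALSE)
  if (cfg$n_active + cfg$n_repressed > cfg$n_pathways)
    stop("config: 'n_active' + 'n_repressed' must be <= 'n_pathways'",
         call. = FALSE)
  if (cfg$n_pathways * cfg$genes_per > cfg$n_transcripts)
    stop("config: pathways need n_pathways * genes_per <= n_transcripts",
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- do.call(run_config, cfg)
  cfg
}

#' @rdname run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# deterministic child seeds for the pipeline stages (kept below 2^31)
stage_seed <- function(seed, k) (as.integer(seed) * 101L + k) %% 2147483647L

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> differential transcript calling -> sample
#' correlation/MDS -> (a549 preset) stage correlation -> pathway activation,
#' writing every artifact to `outdir`: `config.yaml`, `matrix.tsv`,
#' `design.tsv`, `truth.json`, `det.tsv`, `sample_corr.tsv`, `mds.tsv`,
#' `pathways.tsv`, `pas.tsv`, `ref.tsv` + `stage_corr.json` (a549), and
#' `manifest.json` (package version, config hash, seed). Outputs are pure
#' functions of the configuration: two runs with the same config produce
#' byte-identical files.
#'
#' @param config a [run_config].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`det`, `stage_report` or NULL, `pas`, `truth`, paths).
#' @export
run_pipeline <- function(config, outdir) {
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)
  write_run_config(config, path("config.yaml"))

  counts_mode <- config$preset %in% c("xenograft", "liver")
  sim <- simulate_expression(
    n_transcripts = config$n_transcripts, n_case = config$n_case,
    n_control = config$n_control, frac_de = config$frac_de,
    effect_log2 = config$effect_log2, frac_switched = config$frac_switched,
    dispersion = config$dispersion, counts = counts_mode,
    seed = stage_seed(config$seed, 1L))
  mat <- sim$matrix

  stage_report <- NULL
  if (config$preset == "a549") {
    refsim <- simulate_stage_reference(
      baseline = sim$truth$baseline,
      seed = stage_seed(config$seed, 2L))
    mat <- simulate_case_blend(mat, refsim$ref, sim$design,
                               blend = config$blend,
                               seed = stage_seed(config$seed, 3L))
    write_stage_reference(refsim$ref, path("ref.tsv"))
    stage_report <- stage_correlation_report(
      mat, sim$design, refsim$ref, log2_transform = config$log_transform,
      floor = config$p_floor, uniform_fallback = config$uniform_fallback)
    write_stage_cor_report(stage_report, path("stage_corr.json"))
  } else {
    write_feature_lengths(sim$lengths, path("lengths.tsv"))
    mat <- rpkm_normalize(mat, sim$lengths)
  }

  write_expression_matrix(mat, path("matrix.tsv"))
  write_sample_design(sim$design, path("design.tsv"))
  write_sim_truth(sim$truth, path("truth.json"))

  det <- classify_transcripts(mat, sim$design, alpha = config$alpha,
                              pseudo = config$pseudo,
                              p_adjust = if (config$bh_correct) "BH" else "none")
  write_det_table(det, path("det.tsv"))

  corr_method <- if (counts_mode) "spearman" else "pearson"
  corr <- sample_correlation_matrix(mat, method = corr_method)
  utils::write.table(data.frame(sample_id = rownames(corr),
                                signif(corr, 6L), check.names = FALSE),
                     path("sample_corr.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mds <- classical_mds(mat, dims = 2L)
  utils::write.table(data.frame(sample_id = rownames(mds),
                                signif(mds, 6L), check.names = FALSE),
                     path("mds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pwsim <- simulate_pathways(mat, sim$design,
                             n_pathways = config$n_pathways,
                             genes_per = config$genes_per,
                             n_active = config$n_active,
                             n_repressed = config$n_repressed,
                             seed = stage_seed(config$seed, 4L))
  write_pathways(pwsim$pathways, path("pathways.tsv"))
  pas <- pas_profile(pwsim$matrix, sim$design, pwsim$pathways,
                     theta = config$theta, epsilon = config$epsilon,
                     n_perm = config$n_perm,
                     perm_seed = if (config$n_perm > 0L)
                       stage_seed(config$seed, 5L) else NULL)
  write_pas_table(pas, path("pas.tsv"))

  cfg_hash <- unname(tools::md5sum(path("config.yaml")))
  manifest <- list(package = "oncotx",
                   version = as.character(utils::packageVersion("oncotx")),
                   preset = config$preset, seed = config$seed,
                   config_md5 = cfg_hash,
                   files = sort(setdiff(list.files(outdir), "manifest.json")))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(det = det, stage_report = stage_report, pas = pas,
                 truth = sim$truth, pathway_truth = pwsim$truth,
                 outdir = outdir))
}
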