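# shared fixture builders (everything is generated in code at test time)

rand_expr_matrix <- function(n_tx = 50, n_samples = 4, metric = "TPM",
                             max_val = 100) {
  v <- matrix(stats::runif(n_tx * n_samples, 0, max_val), n_tx, n_samples,
              dimnames = list(sprintf("T%03d", seq_len(n_tx)),
                              sprintf("s%d", seq_len(n_samples))))
  expr_matrix(v, metric = metric)
}

rand_count_matrix <- function(n_tx = 50, n_samples = 4) {
  v <- matrix(stats::rpois(n_tx * n_samples, 40), n_tx, n_samples,
              dimnames = list(sprintf("T%03d", seq_len(n_tx)),
                              sprintf("s%d", seq_len(n_samples))))
  expr_matrix(v, metric = "counts")
}

two_group_design <- function(n_case = 3, n_control = 3) {
  sample_design(c(sprintf("case_%d", seq_len(n_case)),
                  sprintf("ctrl_%d", seq_len(n_control))),
                rep(c("case", "control"), c(n_case, n_control)))
}

# expanded-summation weighted Pearson, the independent check for
# weighted_pearson(): computes r from raw weighted sums instead of centred
# moments
wpearson_expanded <- function(x, y, w) {
  sxy <- sum(w * x * y) - sum(w * x) * sum(w * y)
  sxx <- sum(w * x * x) - sum(w * x)^2
  syy <- sum(w * y * y) - sum(w * y)^2
  sxy / sqrt(sxx * syy)
}
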