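# Independent oracles and fixture builders shared across the suite.

# random valid Richards parameters in plate-reader-realistic ranges
random_params <- function() {
  richards_params(
    abs_min = runif(1, 0, 0.2),
    abs_max = runif(1, 0.5, 1.5),
    mu_max  = runif(1, 0.3, 1.2),
    t_i     = runif(1, 3, 15)
  )
}

# central-difference second derivative of the absorbance curve
second_diff <- function(t, p, h = 1e-3) {
  (richards_abs(t + h, p) - 2 * richards_abs(t, p) +
     richards_abs(t - h, p)) / h^2
}

# inflection located by root-finding on the numeric second derivative,
# independent of the model's own t_i bookkeeping
inflection_oracle <- function(p) {
  stats::uniroot(function(t) second_diff(t, p),
                 interval = c(p$t_i - 3, p$t_i + 3), tol = 1e-9)$root
}

# textbook Welch t-test: statistic, Welch-Satterthwaite df, two-sided p
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

# straight-line fit from the closed-form normal equations
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# least-squares objective for the multi-start fitting oracle
rss_at <- function(time, od, par, m = 0.5) {
  p <- richards_params(par[1], par[2], par[3], par[4], m)
  sum((od - richards_abs(time, p))^2)
}

# multi-start refit oracle: best RSS over `n_starts` random initialisations
multistart_oracle <- function(time, od, n_starts = 50, m = 0.5) {
  best <- Inf
  for (k in seq_len(n_starts)) {
    st <- richards_params(
      abs_min = runif(1, 0, min(od) + 0.05),
      abs_max = runif(1, max(od) * 0.8, max(od) * 1.5),
      mu_max  = runif(1, 0.1, 2),
      t_i     = runif(1, min(time), max(time)),
      m = m)
    f <- try(fit_richards(time, od, m = m, start = st, n_restarts = 0),
             silent = TRUE)
    if (!inherits(f, "try-error") && f$rss < best) best <- f$rss
  }
  best
}

# small noisy plate used by several io/stats tests
toy_plate <- function(seed = 1, noise_sd = 0.003) {
  simulate_plate(
    plate_design(n_test_clones = 4, n_control_clones = 3, n_replicates = 2,
                 noise_sd = noise_sd, clone_cv = 0.02),
    test_params = richards_params(0.05, 1.0, 0.70, 8.3),
    control_params = richards_params(0.05, 1.0, 0.67, 7.5),
    seed = seed)
}

reference_summaries_path <- function() {
  system.file("extdata", "rnpa_experiment_summaries.tsv",
              package = "platefit", mustWork = TRUE)
}

read_reference_summaries <- function() {
  readr::read_tsv(reference_summaries_path(), comment = "#", show_col_types = FALSE)
}
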