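#' Microplate experiment design for the growth simulator
#'
#' Encodes the plate layout the fitness experiments use: one test lineage
#' (23 clonal colonies by default) grown alongside the within-plate control
#' lineage (5 clones), all in triplicate, with OD600 read every full hour
#' from 0 to 22 h. Defaults mirror that design; noise and clone-variability
#' defaults are chosen to produce parameter spreads on the scale seen in
#' real plate-reader runs (replicate SD a few thousandths of an OD, clone
#' SDs of roughly 0.01-0.035 on mu_max).
#'
#' @param n_test_clones,n_control_clones Clonal colonies per lineage.
#' @param n_replicates Wells per clone.
#' @param t_start,t_end,interval Sampling window and spacing (hours).
#' @param noise_sd SD of the additive Gaussian OD noise per reading.
#' @param clone_cv Coefficient of variation of clone-level `mu_max` and
#'   `t_i` around the lineage means (lognormal draws).
#' @param inoculum_sd Lognormal sdlog of each clone's inoculum dilution
#'   factor (the emitted `initial_od` is the lineage baseline times this
#'   factor).
#' @param inoculum_effect Coupling of the inoculum factor to TTI: a clone
#'   inoculated `z`-fold denser reaches inflection
#'   `inoculum_effect * log(z) / mu_max` hours earlier. 0 (default) leaves
#'   initial density independent of TTI; 1 is the full time-shift a denser
#'   starting culture would cause.
#' @return A `plate_design` object (validated named list).
#' @export
plate_design <- function(n_test_clones = 23, n_control_clones = 5,
                         n_replicates = 3, t_start = 0, t_end = 22,
                         interval = 1, noise_sd = 0.005, clone_cv = 0.02,
                         inoculum_sd = 0.15, inoculum_effect = 0) {
  stopifnot(n_test_clones >= 1, n_control_clones >= 1, n_replicates >= 1,
            t_end > t_start, interval > 0, noise_sd >= 0, clone_cv >= 0,
            inoculum_sd >= 0, inoculum_effect >= 0)
  structure(list(n_test_clones = n_test_clones,
                 n_control_clones = n_control_clones,
                 n_replicates = n_replicates,
                 t_start = t_start, t_end = t_end, interval = interval,
                 noise_sd = noise_sd, clone_cv = clone_cv,
                 inoculum_sd = inoculum_sd,
                 inoculum_effect = inoculum_effect),
            class = "plate_design")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# lognormal with mean `mean` and coefficient of variation `cv`
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one plate experiment with known ground truth
#'
#' Draws clone-level `mu_max` and `t_i` lognormally around the lineage-level
#' truth (CV = `design$clone_cv`), evaluates the Richards model on the
#' design's time grid for every well, and adds i.i.d. Gaussian OD noise
#' (SD = `design$noise_sd`) truncated at 0. Each clone also carries a
#' lognormal inoculum dilution factor `z` (sdlog = `design$inoculum_sd`);
#' the emitted per-clone `initial_od` is `z` times the noise-free model
#' value at `t_start`. With `design$inoculum_effect > 0` the factor feeds
#' back into the growth kinetics — the clone's `t_i` is advanced by
#' `inoculum_effect * log(z) / mu_max` hours, so denser inocula genuinely
#' reach inflection earlier; at 0 (the default) initial density varies but
#' is independent of TTI, which is what the initial-density screen should
#' then report.
#'
#' Output is bit-reproducible for a fixed `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param design A [plate_design()].
#' @param test_params,control_params Lineage-level truth: [richards_params()]
#'   for the test and control lineages.
#' @param seed Integer seed.
#' @param experiment Experiment identifier stamped on every row.
#' @param lineages Length-2 names for the test and control lineages.
#' @return A list with `curves` (long tibble: `experiment`, `lineage`,
#'   `clone`, `replicate`, `time`, `od`), `truth` (one row per clone with the
#'   drawn parameters and `initial_od`), and `design`.
#' @examples
#' des <- plate_design(noise_sd = 0)
#' sim <- simulate_plate(des, richards_params(0.05, 1.0, 0.674, 7.54),
#'                       richards_params(0.05, 1.0, 0.661, 7.65), seed = 1)
#' head(sim$curves)
#' @export
simulate_plate <- function(design, test_params, control_params, seed = 1,
                           experiment = "E1",
                           lineages = c(test = "test", control = "control")) {
  stopifnot(inherits(design, "plate_design"))
  test_params <- as_richards_params(test_params)
  control_params <- as_richards_params(control_params)
  times <- seq(design$t_start, design$t_end, by = design$interval)

  with_seed(seed, {
    one_lineage <- function(lineage, p, n_clones) {
      mu <- rlnorm_cv(n_clones, p$mu_max, design$clone_cv)
      ti <- rlnorm_cv(n_clones, p$t_i, design$clone_cv)
      z <- if (design$inoculum_sd > 0) {
        stats::rlnorm(n_clones, 0, design$inoculum_sd)
      } else rep(1, n_clones)
      if (design$inoculum_effect > 0) {
        ti <- ti - design$inoculum_effect * log(z) / mu
      }
      base_od <- richards_abs(design$t_start, p)
      tibble::tibble(
        experiment = experiment, lineage = lineage,
        clone = sprintf("%s_c%02d", lineage, seq_len(n_clones)),
        abs_min = p$abs_min, abs_max = p$abs_max,
        mu_max = mu, t_i = pmax(ti, 1e-3), m = p$m,
        initial_od = z * base_od)
    }
    truth <- dplyr::bind_rows(
      one_lineage(lineages[["test"]], test_params, design$n_test_clones),
      one_lineage(lineages[["control"]], control_params,
                  design$n_control_clones))

    curves <- tidyr::crossing(
      dplyr::select(truth, "experiment", "lineage", "clone"),
      replicate = sprintf("r%d", seq_len(design$n_replicates)),
      time = times)
    curves <- dplyr::left_join(
      curves,
      dplyr::select(truth, "clone", "abs_min", "abs_max", "mu_max",
                    "t_i", "m"),
      by = "clone")
    od_true <- with(curves, abs_min + (abs_max - abs_min) *
                      (1 + m * exp(-mu_max * m * (time - t_i)))^(-1 / m))
    noise <- if (design$noise_sd > 0) {
      stats::rnorm(length(od_true), 0, design$noise_sd)
    } else 0
    curves$od <- pmax(od_true + noise, 0)
    curves <- dplyr::select(curves, "experiment", "lineage", "clone",
                            "replicate", "time", "od")
    list(curves = curves, truth = truth, design = design)
  })
}

#' Simulate an aligned protein pair under the JTT model
#'
#' Ancestral residues are drawn from the JTT equilibrium frequencies; the
#' descendant residue at each site is drawn from the corresponding row of
#' the transition matrix `P(distance) = exp(Q * distance)`. The pair is
#' gap-free and already "aligned" site by site, so the true evolutionary
#' distance separating the two sequences is exactly `distance`.
#'
#' @param length Number of sites (>= 1).
#' @param distance True distance in expected substitutions per site (>= 0).
#' @param seed Integer seed.
#' @return A named list with `seq_a` and `seq_b` (single strings) and the
#'   true `distance`.
#' @export
simulate_jtt_pair <- function(length, distance, seed = 1) {
  stopifnot(length >= 1)
  if (!is.numeric(distance) || distance < 0) {
    stop("`distance` must be >= 0", call. = FALSE)
  }
  jm <- jtt_model()
  with_seed(seed, {
    anc <- sample(AA20, length, replace = TRUE, prob = jm$pi)
    if (distance == 0) {
      des <- anc
    } else {
      P <- jtt_transition_prob(distance)
      des <- character(length)
      for (a in unique(anc)) {
        idx <- which(anc == a)
        des[idx] <- sample(AA20, length(idx), replace = TRUE, prob = P[a, ])
      }
    }
    list(seq_a = paste(anc, collapse = ""),
         seq_b = paste(des, collapse = ""),
         distance = distance)
  })
}

#' Generate a coding sequence with controlled codon bias
#'
#' Draws amino acids uniformly, then picks each codon from a mixture: with
#' probability `bias` the amino acid's optimal codon (w = 1 in the reference
#' table; alphabetically first on ties), otherwise a uniform draw over its
#' synonymous codons. CAI of the result is monotone non-decreasing in
#' `bias`, which makes the generator a direct test harness for [cai()].
#'
#' @param n_codons Number of codons (>= 1); no stop codon is appended.
#' @param bias Mixing weight toward the optimal codon, in `[0, 1]`.
#' @param seed Integer seed.
#' @param w Reference weight table (default the packaged E. coli set).
#' @return A single coding-DNA string of `3 * n_codons` bases.
#' @export
generate_biased_gene <- function(n_codons, bias, seed = 1,
                                 w = cai_weights_ecoli()) {
  stopifnot(n_codons >= 1, bias >= 0, bias <= 1)
  fam <- split(w$codon, w$amino_acid)
  optimal <- vapply(split(w[order(w$codon), ], w$amino_acid[order(w$codon)]),
                    function(tab) tab$codon[which.max(tab$w)], character(1))
  aas <- names(fam)
  with_seed(seed, {
    aa_draw <- sample(aas, n_codons, replace = TRUE)
    use_opt <- stats::runif(n_codons) < bias
    codons <- vapply(seq_len(n_codons), function(i) {
      a <- aa_draw[i]
      if (use_opt[i]) optimal[[a]]
      else sample(fam[[a]], 1)
    }, character(1))
    paste(codons, collapse = "")
  })
}
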