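#' Welch comparison of a test lineage against the control
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on per-clone
#' parameter values, the package's default lineage contrast (clone numbers
#' are unbalanced, typically 23 test vs 5 control). Degenerate samples with
#' zero variance in both groups and equal means return `p = 1` by
#' convention (`statistic = 0`); zero variance with unequal means returns
#' `p = 0`.
#'
#' @param test,control Numeric vectors of per-clone parameter values
#'   (each length >= 2, finite).
#' @param alpha Significance level used for the `significant` flag; the
#'   default 0.001 mirrors the asterisk annotation convention of the
#'   experiments this package targets.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_test`,
#'   `mean_control`, `significant`.
#' @export
compare_lineages <- function(test, control, alpha = 0.001) {
  if (length(test) < 2 || length(control) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (!all(is.finite(test)) || !all(is.finite(control))) {
    stop("all values must be finite", call. = FALSE)
  }
  if (stats::sd(test) == 0 && stats::sd(control) == 0) {
    same <- isTRUE(all.equal(mean(test), mean(control)))
    return(tibble::tibble(statistic = if (same) 0 else Inf,
                          df = NA_real_, p_value = if (same) 1 else 0,
                          mean_test = mean(test),
                          mean_control = mean(control),
                          significant = !same))
  }
  tt <- stats::t.test(test, control, var.equal = FALSE,
                      alternative = "two.sided")
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_test = mean(test),
                 mean_control = mean(control),
                 significant = tt$p.value < alpha)
}

#' Relative-to-control ratios for per-experiment lineage means
#'
#' Appends `relative_mu_max` and `relative_tti` to a table of per-experiment
#' lineage means: each test lineage's mean divided by the mean of the
#' within-plate control lineage of the *same* experiment. The control rows
#' get relative values of exactly 1, the convention under which relative
#' fitness is reported.
#'
#' @param summaries Data frame with columns `experiment`, `lineage`,
#'   `mean_mu_max`, `mean_tti`, and either a `role` column
#'   (`"test"`/`"control"`) or lineage names matching `control`.
#' @param control Lineage identifier of the control (ignored when a `role`
#'   column is present).
#' @return The input tibble with `relative_mu_max` and `relative_tti` added.
#' @export
relative_to_control <- function(summaries, control = "control") {
  s <- dplyr::as_tibble(summaries)
  need <- c("experiment", "lineage", "mean_mu_max", "mean_tti")
  if (!all(need %in% names(s))) {
    stop("`summaries` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  is_control <- if ("role" %in% names(s)) s$role == "control"
                else s$lineage == control
  if (!any(is_control)) {
    stop("control lineage not found in `summaries`", call. = FALSE)
  }
  ctrl <- dplyr::select(s[is_control, ], "experiment",
                        ctrl_mu = "mean_mu_max", ctrl_tti = "mean_tti")
  if (anyDuplicated(ctrl$experiment)) {
    stop("more than one control row per experiment", call. = FALSE)
  }
  missing_ctrl <- setdiff(unique(s$experiment), ctrl$experiment)
  if (length(missing_ctrl) > 0) {
    stop("experiment(s) without a control row: ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(s, ctrl, by = "experiment")
  out <- dplyr::mutate(out,
    relative_mu_max = ifelse(is_control, 1, .data$mean_mu_max / .data$ctrl_mu),
    relative_tti = ifelse(is_control, 1, .data$mean_tti / .data$ctrl_tti))
  dplyr::select(out, -"ctrl_mu", -"ctrl_tti")
}

#' Summarise a plate's fits into per-lineage fitness estimates
#'
#' Aggregates per-well Richards fits into the per-experiment lineage summary
#' used to report relative fitness. Each clone's value is the mean of its
#' replicate wells, so the lineage SD reflects clone-to-clone variability;
#' lineage means and sample SDs are taken over clones; relative `mu_max` and
#' TTI are computed against the within-plate control via
#' [relative_to_control()]; and each test lineage is contrasted with the
#' control by [compare_lineages()] on the clone values.
#'
#' Unconverged wells are dropped (with a message); a lineage needs at least
#' 2 clones with converged fits.
#'
#' @param fits Fits table from [fit_growth_curves()]: columns `experiment`,
#'   `lineage`, `clone`, `mu_max`, `t_i`, `converged` (a `replicate` column
#'   is allowed and averaged over).
#' @param control Control lineage identifier (must be present in every
#'   experiment).
#' @param alpha Significance level for the Welch contrasts.
#' @return A tibble of class `platefit_summary`, one row per experiment x
#'   lineage: `n_clones`, `mean_mu_max`, `sd_mu_max`, `mean_tti`, `sd_tti`,
#'   `relative_mu_max`, `relative_tti`, `p_mu_max`, `p_tti` (`NA` for the
#'   control rows), `significant_mu_max`, `significant_tti`.
#' @export
summarise_fitness <- function(fits, control = "control", alpha = 0.001) {
  f <- dplyr::as_tibble(fits)
  need <- c("experiment", "lineage", "clone", "mu_max", "t_i", "converged")
  if (!all(need %in% names(f))) {
    stop("`fits` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_drop <- sum(!f$converged)
  if (n_drop > 0) {
    message("dropping ", n_drop, " unconverged fit(s) before summarising")
  }
  f <- f[f$converged, ]
  if (!control %in% f$lineage) {
    stop("control lineage '", control, "' has no converged fits", call. = FALSE)
  }

  clone_vals <- dplyr::summarise(
    dplyr::group_by(f, .data$experiment, .data$lineage, .data$clone),
    mu_max = mean(.data$mu_max), t_i = mean(.data$t_i), .groups = "drop")

  lin <- dplyr::summarise(
    dplyr::group_by(clone_vals, .data$experiment, .data$lineage),
    n_clones = dplyr::n(),
    mean_mu_max = mean(.data$mu_max), sd_mu_max = stats::sd(.data$mu_max),
    mean_tti = mean(.data$t_i), sd_tti = stats::sd(.data$t_i),
    .groups = "drop")
  if (any(lin$n_clones < 2)) {
    bad <- lin$lineage[lin$n_clones < 2]
    stop("fewer than 2 clones with converged fits for lineage(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  lin <- relative_to_control(lin, control = control)

  welch <- function(exp_id, lineage_id, what) {
    if (lineage_id == control) return(NA_real_)
    x <- clone_vals[clone_vals$experiment == exp_id &
                      clone_vals$lineage == lineage_id, ][[what]]
    y <- clone_vals[clone_vals$experiment == exp_id &
                      clone_vals$lineage == control, ][[what]]
    compare_lineages(x, y, alpha = alpha)$p_value
  }
  lin$p_mu_max <- purrr::map2_dbl(lin$experiment, lin$lineage, welch,
                                  what = "mu_max")
  lin$p_tti <- purrr::map2_dbl(lin$experiment, lin$lineage, welch,
                               what = "t_i")
  lin$significant_mu_max <- !is.na(lin$p_mu_max) & lin$p_mu_max < alpha
  lin$significant_tti <- !is.na(lin$p_tti) & lin$p_tti < alpha
  class(lin) <- c("platefit_summary", class(lin))
  attr(lin, "control") <- control
  attr(lin, "alpha") <- alpha
  lin
}

#' Ordinary least-squares regression of a fitness proxy on a covariate
#'
#' Straight-line fit (via [stats::lm()]) of one response (e.g. relative
#' `mu_max` or relative TTI) on one covariate (e.g. JTT distance or CAI),
#' reporting the slope, intercept, Pearson r, r-squared and the slope's
#' two-sided p-value.
#'
#' @param data Data frame holding the two columns, or `NULL` when `x`/`y`
#'   vectors are supplied directly.
#' @param covariate,response Column names (strings or bare names) when
#'   `data` is given.
#' @param x,y Alternative direct numeric vectors.
#' @return A one-row tibble: `slope`, `intercept`, `r`, `r_squared`,
#'   `p_slope`, `n`.
#' @examples
#' regress_fitness_on_covariate(x = 1:5, y = 2 * (1:5) + 1)
#' @export
regress_fitness_on_covariate <- function(data = NULL, covariate = NULL,
                                         response = NULL, x = NULL, y = NULL) {
  if (!is.null(data)) {
    covariate <- rlang::as_name(rlang::enquo(covariate))
    response <- rlang::as_name(rlang::enquo(response))
    x <- data[[covariate]]
    y <- data[[response]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("need at least 3 complete (covariate, response) points",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate design: covariate is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- stats::cor(x, y)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r_squared = sm$r.squared,
                 p_slope = sm$coefficients[2, 4], n = length(x))
}

#' Screen for an initial-density artefact in the growth parameters
#'
#' Differences in TTI between experiments could in principle reflect nothing
#' more than different starting cell densities. This screen regresses the
#' per-experiment mean `mu_max` and mean TTI on the initial inoculum OD600
#' and reports both regressions, so an absence of correlation can be
#' demonstrated (or a confound caught).
#'
#' @param data Data frame with one row per experiment: `initial_od`,
#'   `mean_mu_max`, `mean_tti`.
#' @return A two-row tibble (`parameter` = `"mu_max"`, `"tti"`) with the
#'   [regress_fitness_on_covariate()] columns.
#' @export
screen_initial_density <- function(data) {
  need <- c("initial_od", "mean_mu_max", "mean_tti")
  if (!all(need %in% names(data))) {
    stop("`data` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_rows(
    dplyr::mutate(regress_fitness_on_covariate(
      x = data$initial_od, y = data$mean_mu_max), parameter = "mu_max",
      .before = 1),
    dplyr::mutate(regress_fitness_on_covariate(
      x = data$initial_od, y = data$mean_tti), parameter = "tti",
      .before = 1))
}
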