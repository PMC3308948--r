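test_that("Welch contrast matches the textbook formula", {
  x <- c(0.694, 0.671, 0.702, 0.688, 0.715)
  y <- c(0.668, 0.655, 0.674, 0.659, 0.680)
  got <- compare_lineages(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-6)
  expect_equal(got$df, want$df, tolerance = 1e-6)
  expect_equal(got$p_value, want$p, tolerance = 1e-6)
})

test_that("degenerate and undersized samples are handled by convention", {
  same <- compare_lineages(rep(1, 3), rep(1, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ident <- compare_lineages(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
  diffc <- compare_lineages(rep(2, 3), rep(1, 3))
  expect_equal(diffc$p_value, 0)
  expect_error(compare_lineages(1, c(1, 2)), "at least 2")
  expect_error(compare_lineages(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("relative ratios reproduce the published per-experiment arithmetic", {
  tab <- read_reference_summaries()
  rel <- relative_to_control(tab)
  get <- function(exp_id, col) {
    round(rel[[col]][rel$experiment == exp_id & rel$role == "test"], 3)
  }
  expect_equal(get(1, "relative_tti"), 1.015)
  expect_equal(get(3, "relative_tti"), 1.021)
  expect_equal(get(4, "relative_tti"), 1.065)
  expect_equal(get(7, "relative_tti"), 1.138)
  expect_equal(get(8, "relative_tti"), 1.099)
  expect_equal(get(4, "relative_mu_max"), 1.039)
  # control rows are exactly 1
  expect_true(all(rel$relative_tti[rel$role == "control"] == 1))
  expect_true(all(rel$relative_mu_max[rel$role == "control"] == 1))
})

test_that("relative_to_control validates its inputs", {
  tab <- tibble::tibble(experiment = 1, lineage = "a", role = "test",
                        mean_mu_max = 1, mean_tti = 2)
  expect_error(relative_to_control(tab), "control lineage not found")
  two_ctrl <- tibble::tibble(
    experiment = c(1, 1), lineage = c("c1", "c2"),
    role = "control", mean_mu_max = 1, mean_tti = 1)
  expect_error(relative_to_control(two_ctrl), "more than one control")
  # a test lineage identical to its control gets relatives of exactly 1
  eq <- tibble::tibble(experiment = 1, lineage = c("t", "c"),
                       role = c("test", "control"),
                       mean_mu_max = c(0.7, 0.7), mean_tti = c(8, 8))
  rel <- relative_to_control(eq)
  expect_identical(rel$relative_mu_max, c(1, 1))
  expect_identical(rel$relative_tti, c(1, 1))
})

test_that("summarise_fitness averages replicates within clone before lineage stats", {
  fits <- tibble::tibble(
    experiment = "E1",
    lineage = rep(c("test", "control"), c(4, 4)),
    clone = rep(c("t1", "t2", "c1", "c2"), each = 2),
    replicate = rep(c("r1", "r2"), 4),
    mu_max = c(0.70, 0.72, 0.60, 0.62, 0.50, 0.52, 0.40, 0.42),
    t_i = c(8, 8.2, 7, 7.2, 6, 6.2, 5, 5.2),
    converged = TRUE)
  s <- summarise_fitness(fits, control = "control")
  tst <- dplyr::filter(s, lineage == "test")
  # clone means are (0.71, 0.61); lineage mean 0.66, sd over the 2 clones
  expect_equal(tst$mean_mu_max, 0.66)
  expect_equal(tst$sd_mu_max, sd(c(0.71, 0.61)))
  expect_equal(tst$n_clones, 2)
  ctl <- dplyr::filter(s, lineage == "control")
  expect_identical(ctl$relative_mu_max, 1)
  expect_identical(ctl$relative_tti, 1)
  expect_true(is.na(ctl$p_mu_max))
  expect_equal(tst$relative_mu_max, 0.66 / 0.46)
  expect_equal(tst$relative_tti, 7.6 / 5.6)  # clone means (8.1, 7.1) vs (6.1, 5.1)
  # the reported relatives recompute from the reported means to 3 d.p.
  expect_equal(round(tst$relative_tti, 3),
               round(tst$mean_tti / ctl$mean_tti, 3))
})

test_that("summarise_fitness enforces its preconditions", {
  fits <- tibble::tibble(experiment = "E1", lineage = "test",
                         clone = c("a", "b"), replicate = "r1",
                         mu_max = c(0.7, 0.71), t_i = c(8, 8.1),
                         converged = TRUE)
  expect_error(summarise_fitness(fits, control = "control"),
               "control lineage")
  one_clone <- dplyr::bind_rows(
    fits,
    tibble::tibble(experiment = "E1", lineage = "control", clone = "c1",
                   replicate = "r1", mu_max = 0.6, t_i = 7,
                   converged = TRUE))
  expect_error(summarise_fitness(one_clone, control = "control"),
               "fewer than 2 clones")
})

test_that("fitness regression matches the normal-equation oracle", {
  x <- c(1, 2, 3, 4, 5)
  col <- regress_fitness_on_covariate(x = x, y = 2 * x + 1)
  expect_equal(col$slope, 2, tolerance = 1e-12)
  expect_equal(col$intercept, 1, tolerance = 1e-12)
  expect_equal(col$r_squared, 1, tolerance = 1e-12)
  x3 <- c(0.27, 0.9, 1.72); y3 <- c(1.015, 1.065, 1.104)
  got <- regress_fitness_on_covariate(x = x3, y = y3)
  want <- ols_oracle(x3, y3)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$r, cor(x3, y3), tolerance = 1e-10)
  # data-frame interface with bare column names
  df <- tibble::tibble(jtt = x3, rel_tti = y3)
  got2 <- regress_fitness_on_covariate(df, jtt, rel_tti)
  expect_equal(got2$slope, want$slope)
  expect_error(regress_fitness_on_covariate(x = c(1, 1, 1), y = 1:3),
               "degenerate")
  expect_error(regress_fitness_on_covariate(x = 1:2, y = 1:2), "at least 3")
})

test_that("the initial-density screen reports both parameters and catches confounds", {
  d <- tibble::tibble(initial_od = c(0.01, 0.02, 0.03, 0.04),
                      mean_mu_max = c(0.7, 0.71, 0.69, 0.7),
                      mean_tti = c(7, 8, 9, 10))  # perfectly confounded TTI
  s <- screen_initial_density(d)
  expect_equal(s$parameter, c("mu_max", "tti"))
  expect_equal(s$r_squared[s$parameter == "tti"], 1, tolerance = 1e-12)
  expect_error(screen_initial_density(d[1, ]), "at least 3")
  expect_error(screen_initial_density(d[, -1]), "must contain")
})
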