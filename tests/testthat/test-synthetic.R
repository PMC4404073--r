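test_that("locations land inside the region, outside the park holes", {
  cfg <- scenario_config(n = 100, seed = 6)
  pts <- gen_locations(cfg)
  expect_equal(nrow(pts), 100)
  expect_true(all(points_in_shell <- mgcv::in.out(
    cfg$region$rings[[1]], cbind(pts$x_m, pts$y_m))))
  for (hole in cfg$region$rings[-1]) {
    expect_false(any(mgcv::in.out(hole, cbind(pts$x_m, pts$y_m))))
  }
  # determinism: same seed twice, identical coordinates
  expect_identical(pts, gen_locations(cfg))
})

test_that("the whole cohort is reproducible from one master seed", {
  a <- simulate_cohort(scenario_config(n = 120, seed = 8))
  b <- simulate_cohort(scenario_config(n = 120, seed = 8))
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth$true_beta, b$truth$true_beta)
  c <- simulate_cohort(scenario_config(n = 120, seed = 9))
  expect_false(identical(a$participants$counts, c$participants$counts))
})

test_that("the environmental block is two-factor with calibrated noise", {
  cfg <- scenario_config(n = 500, seed = 3)
  pts <- gen_locations(cfg)
  # noiseless limit: correlation matrix has rank ~2
  cfg0 <- scenario_config(n = 500, seed = 3, noise_scale = 1e-6)
  e0 <- gen_environment(pts, cfg0)
  ev <- eigen(cor(as.matrix(e0$env)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(ev[3], 0.05)
  # calibrated default: two-factor eigen share lands in [0.55, 0.75]
  e1 <- gen_environment(pts, cfg)
  ev1 <- eigen(cor(as.matrix(e1$env)), symmetric = TRUE,
               only.values = TRUE)$values
  expect_gt(sum(ev1[1:2]) / 15, 0.55)
  expect_lt(sum(ev1[1:2]) / 15, 0.75)
})

test_that("individual covariates match the emulated cohort marginals", {
  cfg <- scenario_config(n = 4164, seed = 5)
  cov <- gen_individual_covariates(cfg)
  expect_equal(mean(cov$gender_female), 0.78, tolerance = 0.03)
  expect_equal(mean(cov$educ_high), 0.831, tolerance = 0.03)
  expect_equal(mean(cov$parking_work), 0.367, tolerance = 0.04)
  expect_true(all(table(cov$commute_tertile) %in% c(1388, 1388, 1388)))
  expect_true(all(cov$age >= 18 & cov$age <= 87))
  expect_true(all(cov$n_vehicles <= 8) && all(cov$n_bikes <= 4))
})

test_that("a null coefficient vector gives unit-mean counts", {
  cfg <- scenario_config(
    n = 10000, seed = 10,
    surfaces = list("(Intercept)" = surface_constant(0),
                    env1 = surface_constant(0),
                    env2 = surface_constant(0)),
    gamma = c(age_c10 = 0, gender_female = 0, educ_high = 0,
              parking_work = 0, transit_pass = 0, commute_tertile = 0,
              n_vehicles = 0, n_bikes = 0))
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$lambda == 1))
  expect_equal(mean(coh$participants$counts), 1, tolerance = 0.03)
})

test_that("the homogeneous special case is recovered by the global GLM", {
  coh <- simulate_cohort(scenario_stationary(n = 2000, seed = 12))
  d <- coh$participants
  fit <- fit_poisson_glm(d, "counts", c("env1", "env2", GLOBAL_TERMS))
  truth <- c(0.8, 0.05, 0.01, unname(coh$truth$config$gamma))
  z <- (unname(fit$coefficients) - truth) / sqrt(diag(fit$vcov))
  expect_true(all(abs(z) < 2.5))
})

test_that("gradient scenarios vary the true surface; overflow is caught", {
  coh <- simulate_cohort(scenario_g1(n = 300, seed = 2))
  expect_gt(var(coh$truth$true_beta[, "env1"]), 0)
  bad <- scenario_config(n = 100, seed = 1, surfaces = list(
    "(Intercept)" = surface_constant(40),
    env1 = surface_constant(0), env2 = surface_constant(0)))
  expect_error(simulate_cohort(bad), "exceeds 30")
})

test_that("zero inflation adds structural zeros on top of the Poisson", {
  base <- simulate_cohort(scenario_config(n = 3000, seed = 4))
  zi <- simulate_cohort(scenario_config(n = 3000, seed = 4,
                                        zero_inflation = 0.41))
  p0 <- mean(base$participants$counts == 0)
  p1 <- mean(zi$participants$counts == 0)
  expect_equal(p1, 0.41 + 0.59 * p0, tolerance = 0.04)
})

test_that("the jittered-hours mode round-trips through discretization", {
  coh <- simulate_cohort(scenario_config(n = 400, seed = 15,
                                         outcome_mode = "hours_jitter"))
  expect_false(all(coh$participants$hours * 2 ==
                     round(coh$participants$hours * 2)))
  expect_identical(discretize_outcome(coh$participants$hours),
                   coh$participants$counts)
  # and the default counts mode makes discretization the identity
  coh2 <- simulate_cohort(scenario_config(n = 400, seed = 15))
  expect_identical(discretize_outcome(coh2$participants$hours),
                   coh2$participants$counts)
})

test_that("Likert items live on the codebook and mirror the loading signs", {
  cfg <- scenario_config(n = 1000, seed = 20)
  pts <- gen_locations(cfg)
  lik <- gen_likert(pts, cfg)
  for (it in c("bike_safety", "pollution", "aesthetics")) {
    expect_true(all(lik[[it]] %in% 1:5))
  }
  expect_gt(cor(lik$bike_safety, lik$perception_factor), 0)
  expect_lt(cor(lik$aesthetics, lik$perception_factor), 0)
  # noiseless limit: items perfectly rank-correlated
  cfg0 <- scenario_config(n = 1000, seed = 20, likert_noise = 0)
  lik0 <- gen_likert(pts, cfg0)
  expect_equal(abs(cor(lik0$bike_safety, lik0$pollution,
                       method = "spearman")), 1)
  expect_equal(abs(cor(lik0$bike_safety, lik0$aesthetics,
                       method = "spearman")), 1)
})

test_that("Kaiser retention of exactly two components is stable across seeds", {
  retained <- sapply(1:5, function(s) {
    coh <- simulate_cohort(scenario_config(n = 400, seed = 100 + s))
    pca_composites(coh$participants, vars = env_loading_names())$retained_count
  })
  expect_true(all(retained == 2))
})
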