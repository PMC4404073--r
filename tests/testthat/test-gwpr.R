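test_that("uniform weights make the local fit a plain Poisson GLM", {
  set.seed(14)
  d <- tibble::tibble(x = rnorm(60))
  d$y <- rpois(60, exp(0.4 + 0.3 * d$x))
  X <- cbind("(Intercept)" = 1, x = d$x)
  loc <- fit_local_poisson(d$y, X, weights = rep(1, 60))
  ref <- fit_poisson_glm(d, "y", "x")
  expect_equal(loc$estimate, unname(ref$coefficients), tolerance = 1e-7)
})

test_that("a point-mass kernel recovers that observation exactly", {
  y <- c(2L, 7L, 9L)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  w <- c(1, 0, 0)
  loc <- fit_local_poisson(y, X, weights = w)
  expect_equal(loc$estimate, log(2), tolerance = 1e-8)
})

test_that("local fits match generic numeric maximization of the weighted likelihood", {
  set.seed(99)
  for (rep in 1:3) {
    n <- 50
    x <- rnorm(n)
    y <- rpois(n, exp(0.3 + 0.4 * x))
    w <- kernel_weights(runif(n, 0, 1000), 800, "bisquare")
    w[1] <- 1
    off <- rnorm(n, 0, 0.2)
    X <- cbind(1, x)
    loc <- fit_local_poisson(y, X, weights = w, offset = off)
    ref <- weighted_poisson_ml(y, X, w, off)
    expect_equal(loc$estimate, ref, tolerance = 1e-6)
  }
})

test_that("sandwich and naive standard errors differ under unequal weights", {
  set.seed(5)
  n <- 80
  x <- rnorm(n)
  y <- rpois(n, exp(0.3 + 0.3 * x))
  w <- kernel_weights(runif(n, 0, 900), 1000, "bisquare")
  s1 <- fit_local_poisson(y, cbind(1, x), weights = w, se_type = "sandwich")
  s2 <- fit_local_poisson(y, cbind(1, x), weights = w, se_type = "naive")
  expect_false(isTRUE(all.equal(s1$se, s2$se)))
  # with w = 1 the two coincide (W^2 = W)
  u1 <- fit_local_poisson(y, cbind(1, x), weights = rep(1, n),
                          se_type = "sandwich")
  u2 <- fit_local_poisson(y, cbind(1, x), weights = rep(1, n),
                          se_type = "naive")
  expect_equal(u1$se, u2$se, tolerance = 1e-8)
})

test_that("an enormous Gaussian bandwidth reproduces the global model", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  f <- fit_gwpr(d, "counts", c("env1", "env2"), GLOBAL_TERMS,
                kernel = kernel_spec("gaussian", "fixed", bandwidth_m = 1e9))
  g <- fit_poisson_glm(d, "counts", c("env1", "env2", GLOBAL_TERMS))
  glob <- g$coefficients[c("(Intercept)", "env1", "env2")]
  for (j in seq_along(glob)) {
    expect_lt(max(abs(f$beta[, j] - glob[j])), 1e-4)
  }
  expect_equal(unname(f$gamma), unname(g$coefficients[GLOBAL_TERMS]),
               tolerance = 1e-4)
})

test_that("an empty local set degenerates to the global Poisson regression", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  f <- fit_gwpr(d, "counts", character(), GLOBAL_TERMS,
                local_intercept = FALSE)
  g <- fit_poisson_glm(d, "counts", GLOBAL_TERMS)
  expect_true(f$degenerate)
  expect_equal(unname(f$gamma), unname(g$coefficients), tolerance = 1e-10)
  expect_equal(f$deviance + 2 * f$k, g$deviance + 2 * g$p, tolerance = 1e-10)
  expect_equal(effective_parameters(f), length(GLOBAL_TERMS) + 1)
})

test_that("back-fitting reaches a fixed point of the alternation", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  f <- fit_gwpr(d, "counts", c("env1", "env2"), GLOBAL_TERMS,
                kernel = kernel_spec("bisquare", "adaptive",
                                     neighbor_count = 100))
  expect_true(f$converged)
  tr <- f$trace
  # per-cycle coefficient and deviance changes contract to zero
  expect_lt(tr$max_delta[nrow(tr)], 1e-5)
  tail_dev <- utils::tail(tr$deviance, 3)
  expect_lt(max(abs(diff(tail_dev))), 1e-3)
})

test_that("effective parameters shrink as the bandwidth grows", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  ks <- sapply(c(3000, 6000, 12000, 24000, 48000), function(bw) {
    f <- fit_gwpr(d, "counts", "env1", GLOBAL_TERMS,
                  kernel = kernel_spec("gaussian", "fixed", bandwidth_m = bw))
    f$k
  })
  expect_true(all(diff(ks) < 1e-6))
  # in the wide-bandwidth limit, trace(S) approaches p_local
  expect_lt(ks[5] - length(GLOBAL_TERMS), 2 + 0.5)
  expect_gte(ks[5], length(GLOBAL_TERMS))
})

test_that("pseudo-t flags use a strict threshold and report direction", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  f <- fit_gwpr(d, "counts", "env1", GLOBAL_TERMS,
                kernel = kernel_spec("bisquare", "adaptive",
                                     neighbor_count = 100))
  # engineer exact boundary values
  f$beta[1, "env1"] <- 1.96; f$se[1, "env1"] <- 1
  f$beta[2, "env1"] <- 0;    f$se[2, "env1"] <- 1
  f$beta[3, "env1"] <- -2.5; f$se[3, "env1"] <- 1
  pt <- pseudo_t(f)
  r1 <- pt[pt$term == "env1" & pt$id == 1, ]
  expect_false(r1$significant)  # |t| = 1.96 exactly is NOT flagged
  r2 <- pt[pt$term == "env1" & pt$id == 2, ]
  expect_false(r2$significant)
  expect_equal(r2$pseudo_t, 0)
  r3 <- pt[pt$term == "env1" & pt$id == 3, ]
  expect_true(r3$significant)
  expect_equal(r3$sign, "negative")
})

test_that("the default bandwidth grid descends 4000..50 by 50", {
  g <- bandwidth_grid(4000, 50, 50)
  expect_equal(g[1], 4000L)
  expect_equal(g[length(g)], 50L)
  expect_equal(length(g), 80L)
  expect_true(all(diff(g) == -50L))
})

test_that("bandwidth search returns the AICc minimizer over the grid", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  bs <- bandwidth_search(d, "counts", "env1", GLOBAL_TERMS,
                         grid = c(60, 120, 180))
  expect_true(bs$selected %in% c(60, 120, 180))
  expect_equal(bs$selected,
               bs$trace$n_neighbors[which.min(bs$trace$aicc)])
  expect_equal(bs$fit$kernel$neighbor_count, bs$selected)
  # single-value grid returns that value
  one <- bandwidth_search(d, "counts", "env1", GLOBAL_TERMS,
                          grid = 100, keep_best = FALSE)
  expect_equal(one$selected, 100L)
})

test_that("MAICE comparison applies the strict delta > 2 rule", {
  mk <- function(D, k, fp) {
    structure(list(deviance = D, k = k, fingerprint = fp,
                   degenerate = FALSE), class = "gwpr_fit")
  }
  fp <- c(n = 10, s1 = 20, s2 = 110)
  same <- compare_models(mk(100, 5, fp), mk(100, 5, fp))
  expect_equal(same$delta_aicc, 0)
  expect_false(same$substantial)
  # AICc 6757 vs 6556: delta 201, local model preferred
  big2 <- compare_models(mk(6745, 6, fp), mk(6544, 6, fp), "GPR", "GWPR")
  expect_equal(big2$aicc_a, 6757)
  expect_equal(big2$aicc_b, 6556)
  expect_equal(big2$delta_aicc, 201)
  expect_true(big2$substantial)
  expect_equal(big2$preferred, "GWPR")
  # boundary: exactly 2 is not substantial
  edge <- compare_models(mk(100, 5, fp), mk(102, 5, fp))
  expect_equal(edge$delta_aicc, 2)
  expect_false(edge$substantial)
  # mismatched data refused
  expect_error(compare_models(mk(100, 5, fp),
                              mk(100, 5, c(n = 11, s1 = 20, s2 = 110))),
               "refused")
})

test_that("local summaries aggregate odds ratios per the table layout", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  f <- fit_gwpr(d, "counts", "env1", GLOBAL_TERMS,
                kernel = kernel_spec("bisquare", "adaptive",
                                     neighbor_count = 100))
  # constant surface: zero spread
  f0 <- f
  f0$beta[, "env1"] <- 0.25
  s0 <- summarize_local(f0)
  env_row <- s0[s0$term == "env1", ]
  expect_equal(env_row$sd_log_odds, 0)
  expect_equal(env_row$range_or, 0)
  expect_equal(env_row$mean_or, exp(0.25))
  # two-location arithmetic
  f2 <- f
  f2$beta <- matrix(c(0.5, 0.5, -0.1, 0.1), 2, 2,
                    dimnames = list(NULL, c("(Intercept)", "env1")))
  f2$se <- matrix(1, 2, 2); f2$stable <- c(TRUE, TRUE); f2$n <- 2
  f2$local_terms <- c("(Intercept)", "env1")
  s2 <- summarize_local(f2)
  row <- s2[s2$term == "env1", ]
  expect_equal(row$min_or, exp(-0.1))
  expect_equal(row$max_or, exp(0.1))
  expect_equal(row$range_or, exp(0.1) - exp(-0.1))
})

test_that("gwpr tidy/glance expose local estimates and fit statistics", {
  coh <- local_cohort(200, 7)
  d <- coh$participants
  f <- fit_gwpr(d, "counts", "env1", GLOBAL_TERMS,
                kernel = kernel_spec("bisquare", "adaptive",
                                     neighbor_count = 120))
  td <- tidy(f)
  expect_equal(nrow(td), 200 * 2)  # intercept + env1 at every location
  expect_setequal(unique(td$term), c("(Intercept)", "env1"))
  gl <- glance(f)
  expect_equal(gl$bandwidth, 120)
  expect_true(gl$converged)
  expect_equal(gl$aicc, f$deviance + 2 * f$k)
  p <- autoplot(f, term = "env1")
  expect_s3_class(p, "ggplot")
})
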