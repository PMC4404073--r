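# Shared fixtures and independent oracles.

GLOBAL_TERMS <- c("age_c10", "gender_female", "educ_high", "parking_work",
                  "transit_pass", "commute_tertile", "n_vehicles", "n_bikes")

# Independent oracle: maximize the (geographically) weighted Poisson
# log-likelihood by generic quasi-Newton optimization with analytic
# gradient. Deliberately shares no code with the package's Fisher-scoring
# path.
weighted_poisson_ml <- function(y, X, w = rep(1, length(y)),
                                offset = rep(0, length(y)),
                                start = NULL) {
  nll <- function(b) {
    eta <- drop(X %*% b) + offset
    -sum(w * (y * eta - exp(eta)))
  }
  grad <- function(b) {
    eta <- drop(X %*% b) + offset
    -drop(crossprod(X, w * (y - exp(eta))))
  }
  start <- start %||% rep(0, ncol(X))
  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  opt$par
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cohort cache so expensive simulations are shared across tests in
# a file.
local_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n, seed) {
    key <- paste0("n", n, "_s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_cohort(scenario_config(n = n, seed = seed))
    }
    cache[[key]]
  }
})

rand_points <- function(n, seed = 1, extent = 1000) {
  set.seed(seed)
  tibble::tibble(x_m = runif(n, 0, extent), y_m = runif(n, 0, extent))
}
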