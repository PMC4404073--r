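#' Discretize weekly hours into half-hour Poisson counts
#'
#' Weekly active-commuting hours are rounded to the nearest half hour and
#' expressed as a count of half-hour units, so a zero-heavy continuous
#' outcome can be modelled with Poisson regression. Ties (x.25, x.75 hours)
#' round half-away-from-zero.
#'
#' @param hours Non-negative weekly hours.
#' @return Integer vector of half-hour counts.
#' @examples
#' discretize_outcome(c(0, 2.34, 0.25))  # 0, 5, 1
#' @export
discretize_outcome <- function(hours) {
  if (any(!is.finite(hours))) stop("hours must be finite", call. = FALSE)
  if (any(hours < 0)) stop("hours must be non-negative", call. = FALSE)
  as.integer(floor(2 * hours + 0.5))
}

# Build an intercept + terms model matrix from a data frame, with a
# rank check that names the offending columns.
build_design <- function(data, terms, intercept = TRUE) {
  miss <- setdiff(terms, names(data))
  if (length(miss) > 0) {
    stop("columns not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- if (length(terms) > 0) {
    as.matrix(dplyr::select(as.data.frame(data), dplyr::all_of(terms)))
  } else {
    matrix(numeric(0), nrow(data), 0)
  }
  if (length(terms) > 0) storage.mode(X) <- "double"
  if (intercept) {
    X <- cbind("(Intercept)" = rep(1, nrow(data)), X)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

# Full Poisson log-likelihood (including the log y! term, so pseudo-R2
# statistics built from it are invariant to dropping that constant
# consistently).
poisson_loglik <- function(y, mu, w = NULL) {
  w <- w %||% rep(1, length(y))
  sum(w * stats::dpois(y, mu, log = TRUE))
}

#' Fit a global Poisson regression (GPR)
#'
#' Log-linear Poisson model for half-hour active-commuting counts, fitted
#' by iteratively reweighted least squares. The coefficient covariance is
#' the inverse Fisher information at the optimum. An intercept is always
#' included; an intercept-only null model is fitted alongside so deviance
#' explained and Nagelkerke's pseudo-R2 are available.
#'
#' @param data Data frame with one row per participant.
#' @param response Name of the count column (see [discretize_outcome()]).
#' @param terms Character vector of numeric covariate columns.
#' @param prior_weights Optional non-negative observation weights.
#' @param offset Optional offset vector on the log scale.
#' @return A `gpr_fit` object; see [tidy.gpr_fit()], [glance.gpr_fit()],
#'   [wald_summary()], [deviance_stats()].
#' @examples
#' d <- tibble::tibble(y = rpois(100, 2), x = rnorm(100))
#' fit <- fit_poisson_glm(d, "y", "x")
#' glance(fit)
#' @export
fit_poisson_glm <- function(data, response, terms = character(),
                            prior_weights = NULL, offset = NULL) {
  y <- data[[response]]
  if (is.null(y)) stop("response column `", response, "` not found",
                       call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("response must be non-negative integer counts", call. = FALSE)
  }
  X <- build_design(data, terms)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need n > p observations", call. = FALSE)
  w <- prior_weights %||% rep(1, n)
  if (any(w < 0)) stop("prior weights must be >= 0", call. = FALSE)
  if (sum(w > 0) < p) stop("need at least p observations with positive weight",
                           call. = FALSE)
  o <- offset %||% rep(0, n)

  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit <- stats::glm.fit(X, y, weights = w, offset = o,
                        family = stats::poisson(), control = ctl)
  if (!fit$converged) {
    stop("IRLS did not converge within 100 iterations", call. = FALSE)
  }
  null <- stats::glm.fit(X[, 1, drop = FALSE], y, weights = w, offset = o,
                         family = stats::poisson(), control = ctl)
  mu <- fit$fitted.values
  # inverse Fisher information: (X' diag(w * mu) X)^-1
  info <- crossprod(X, X * (w * mu))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    vcov = vcov,
    fitted = mu,
    linear_predictors = fit$linear.predictors,
    deviance = fit$deviance,
    null_deviance = null$deviance,
    loglik = poisson_loglik(y, mu, w),
    loglik_null = poisson_loglik(y, null$fitted.values, w),
    y = y, X = X, prior_weights = w, offset = o,
    n = n, p = p, terms = terms
  ), class = "gpr_fit")
}

#' @export
print.gpr_fit <- function(x, ...) {
  cat(sprintf("<gpr_fit> global Poisson regression: n = %d, p = %d\n",
              x$n, x$p))
  cat(sprintf("  deviance %.1f (null %.1f), AICc (D + 2k) %.1f\n",
              x$deviance, x$null_deviance, x$deviance + 2 * x$p))
  invisible(x)
}

#' Deviance-scale fit statistics
#'
#' Summarises a fitted model by its deviance `D`, the share of null
#' deviance explained `1 - D/D0`, the information criterion
#' `AICc = D + 2k` (deviance plus twice the effective number of
#' parameters, the form used to compare the global and geographically
#' weighted fits), and Nagelkerke's pseudo-R2 computed from full Poisson
#' log-likelihoods. An optional small-sample correction term
#' `2k(k+1)/(n-k-1)` can be added to the criterion; it is off by default
#' because model comparison uses the plain `D + 2k` form.
#'
#' @param fit A `gpr_fit` or `gwpr_fit`, or `NULL` when `deviance` is
#'   given directly.
#' @param k Effective number of parameters; defaults to the fit's own.
#' @param deviance,n Direct numeric inputs, usable without a fitted model
#'   (Nagelkerke's statistic then requires a fit and is returned as `NA`).
#' @param small_sample Add the finite-sample correction term to AICc.
#' @return A one-row tibble with `deviance`, `deviance_explained`, `aicc`,
#'   `nagelkerke_r2`, `k`, `n`.
#' @examples
#' deviance_stats(deviance = 6733, k = 12)$aicc  # 6757
#' @export
deviance_stats <- function(fit = NULL, k = NULL, deviance = NULL, n = NULL,
                           small_sample = FALSE) {
  if (is.null(fit)) {
    stopifnot(!is.null(deviance), !is.null(k))
    aicc <- deviance + 2 * k
    if (small_sample) {
      stopifnot(!is.null(n))
      aicc <- aicc + 2 * k * (k + 1) / (n - k - 1)
    }
    return(tibble::tibble(deviance = deviance, deviance_explained = NA_real_,
                          aicc = aicc, nagelkerke_r2 = NA_real_, k = k,
                          n = n %||% NA_integer_))
  }
  k <- k %||% effective_parameters(fit)
  D <- fit$deviance
  D0 <- fit$null_deviance
  dev_expl <- if (D0 <= 0) 0 else 1 - D / D0
  aicc <- D + 2 * k
  if (small_sample) aicc <- aicc + 2 * k * (k + 1) / (fit$n - k - 1)
  ll <- fit$loglik
  ll0 <- fit$loglik_null
  r2_max <- 1 - exp(2 * ll0 / fit$n)
  r2 <- (1 - exp(2 * (ll0 - ll) / fit$n)) / r2_max
  tibble::tibble(deviance = D, deviance_explained = dev_expl, aicc = aicc,
                 nagelkerke_r2 = r2, k = k, n = fit$n)
}

#' @rdname deviance_stats
#' @export
effective_parameters <- function(fit) UseMethod("effective_parameters")

#' @export
effective_parameters.gpr_fit <- function(fit) fit$p

#' Wald odds-ratio summary of a Poisson fit
#'
#' Per-coefficient table in the shape used to report global model results:
#' log-odds (the coefficient on the log scale), the odds ratio
#' `OR = exp(coef)`, a two-sided Wald confidence interval on the OR scale,
#' and the normal-reference p-value. Coefficients with a non-finite
#' standard error are kept but flagged unstable.
#'
#' @param fit A `gpr_fit`.
#' @param alpha Two-sided level (default 0.05, i.e. 95% CI).
#' @return A tibble with columns `term`, `log_odds`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `unstable`.
#' @export
wald_summary <- function(fit, alpha = 0.05) {
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - alpha / 2)
  est <- fit$coefficients
  unstable <- !is.finite(se) | se <= 0
  pz <- 2 * stats::pnorm(-abs(est / se))
  tibble::tibble(
    term = names(est),
    log_odds = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p_value = unname(pz),
    unstable = unname(unstable)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a global Poisson fit
#'
#' @param x A `gpr_fit`.
#' @param ... Unused.
#' @return One row per coefficient (see [wald_summary()]).
#' @export
tidy.gpr_fit <- function(x, ...) wald_summary(x)

#' One-row summary of a global Poisson fit
#'
#' @param x A `gpr_fit`.
#' @param ... Unused.
#' @export
glance.gpr_fit <- function(x, ...) deviance_stats(x)
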