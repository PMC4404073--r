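#' Fit one local weighted Poisson regression
#'
#' Maximises the geographically weighted Poisson log-likelihood
#' `sum_j w_j [y_j (eta_j + o_j) - exp(eta_j + o_j)]` over the local
#' coefficients by Fisher scoring, where the weights come from a spatial
#' kernel centred on one regression point and the offset carries the fixed
#' (individual-level) part of the linear predictor. Standard errors use the
#' weighted sandwich form
#' `(X'WAX)^-1 (X'W^2AX) (X'WAX)^-1` with `A = diag(fitted mean)` by
#' default; the naive inverse-information form is available.
#'
#' @param y Integer counts.
#' @param X_local Numeric matrix of locally varying columns (including the
#'   local intercept column if wanted).
#' @param weights Geographic weights, one per observation.
#' @param offset Offset on the log scale (default 0).
#' @param se_type `"sandwich"` or `"naive"`.
#' @return A tibble with one row per local column: `term`, `estimate`,
#'   `se`, `pseudo_t`.
#' @export
fit_local_poisson <- function(y, X_local, weights, offset = NULL,
                              se_type = c("sandwich", "naive")) {
  se_type <- match.arg(se_type)
  X_local <- as.matrix(X_local)
  n <- length(y)
  stopifnot(nrow(X_local) == n, length(weights) == n)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(weights > 0) < ncol(X_local)) {
    stop("need at least p observations with positive weight", call. = FALSE)
  }
  o <- offset %||% rep(0, n)
  res <- cpp_local_fits(as.numeric(y), X_local, o,
                        matrix(weights, nrow = 1), tol = 1e-10, maxit = 100,
                        sandwich = (se_type == "sandwich"))
  if (!res$ok[1]) {
    stop("local fit unstable: weighted design rank-deficient or diverged",
         call. = FALSE)
  }
  est <- drop(res$beta)
  se <- drop(res$se)
  nm <- colnames(X_local) %||% paste0("x", seq_along(est))
  tibble::tibble(term = nm, estimate = est, se = se,
                 pseudo_t = est / se)
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

data_fingerprint <- function(y) {
  c(n = length(y), s1 = sum(y), s2 = sum(y * seq_along(y)))
}

#' Fit a semiparametric geographically weighted Poisson regression
#'
#' The model `log lambda_i = sum_k beta_k(u_i, v_i) x_ik + sum_m gamma_m
#' x_im`: environmental coefficients `beta_k` vary with residential
#' location while individual-level coefficients `gamma_m` are spatially
#' constant. One local regression is fitted at every observation site,
#' weighting neighbours with a distance-decay kernel.
#'
#' Estimation is by back-fitting: the fixed coefficients are initialised
#' from a global Poisson fit on all columns, then local fits (with the
#' fixed part as offset) and a global fit of the fixed part (with each
#' observation's own-location local predictor as offset) alternate until
#' the maximum absolute change in any coefficient falls below `tol`.
#'
#' The effective number of parameters is `k = trace(S) + p_global`, where
#' `S` is the hat matrix of the local smoothing step at convergence;
#' `AICc = deviance + 2k` is the criterion used by [bandwidth_search()]
#' and [compare_models()].
#'
#' @param data Data frame with coordinate columns `x_m`, `y_m` (projected
#'   metres), the count response and all model columns.
#' @param response Name of the count column.
#' @param local_terms Columns whose coefficients vary spatially. The local
#'   intercept is included unless `local_intercept = FALSE`.
#' @param global_terms Columns with spatially constant coefficients.
#' @param kernel A [kernel_spec()].
#' @param local_intercept Include a spatially varying intercept (default
#'   `TRUE`). With no local terms and no local intercept the model
#'   degenerates to the global Poisson regression.
#' @param se_type Local standard errors: `"sandwich"` (default) or
#'   `"naive"`.
#' @param tol Back-fitting convergence tolerance on coefficient changes.
#' @param max_cycles Maximum back-fitting cycles. The alternation is a
#'   linearly convergent fixed-point iteration; an Aitken extrapolation
#'   step on the fixed coefficients is applied periodically to
#'   accelerate it.
#' @param dist_matrix Optional precomputed pairwise distance matrix.
#' @return A `gwpr_fit` object; see [tidy.gwpr_fit()], [glance.gwpr_fit()],
#'   [pseudo_t()], [summarize_local()].
#' @export
fit_gwpr <- function(data, response, local_terms = character(),
                     global_terms = character(),
                     kernel = kernel_spec("bisquare", "adaptive",
                                          neighbor_count = 800),
                     local_intercept = TRUE,
                     se_type = c("sandwich", "naive"),
                     tol = 1e-5, max_cycles = 200, dist_matrix = NULL) {
  se_type <- match.arg(se_type)
  if (length(intersect(local_terms, global_terms)) > 0) {
    stop("local and global term sets must be disjoint", call. = FALSE)
  }
  y <- data[[response]]
  n <- length(y)

  # degenerate spec: no spatially varying columns at all -> global GLM
  if (length(local_terms) == 0 && !local_intercept) {
    g <- fit_poisson_glm(data, response, global_terms)
    out <- structure(list(
      degenerate = TRUE, beta = NULL, se = NULL, stable = rep(TRUE, n),
      gamma = g$coefficients, gamma_se = sqrt(diag(g$vcov)),
      local_terms = character(), global_terms = c("(Intercept)", global_terms),
      deviance = g$deviance, null_deviance = g$null_deviance,
      loglik = g$loglik, loglik_null = g$loglik_null,
      k = g$p, n = n, kernel = kernel, bandwidths = NULL,
      se_type = se_type, cycles = 0L, converged = TRUE,
      trace = tibble::tibble(cycle = integer(), deviance = numeric(),
                             max_delta = numeric()),
      points = tibble::tibble(x_m = data$x_m, y_m = data$y_m),
      fingerprint = data_fingerprint(y), fitted = g$fitted
    ), class = "gwpr_fit")
    return(out)
  }

  Xl <- build_design(data, local_terms, intercept = local_intercept)
  Xg <- build_design(data, global_terms, intercept = FALSE)
  if (ncol(Xg) > 0) colnames(Xg) <- global_terms
  pl <- ncol(Xl); pg <- ncol(Xg)
  check_planar(data$x_m, data$y_m, "coordinates (columns x_m, y_m)")

  pts <- tibble::tibble(x_m = data$x_m, y_m = data$y_m)
  gwm <- gw_weight_matrix(pts, kernel, dist_matrix = dist_matrix)
  W <- gwm$weights

  # initialise fixed coefficients from a global fit on all columns
  Xall <- cbind(Xl, Xg)
  qra <- qr(Xall)
  if (qra$rank < ncol(Xall)) {
    bad <- colnames(Xall)[qra$pivot[seq(qra$rank + 1L, ncol(Xall))]]
    stop("combined design rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  init <- stats::glm.fit(Xall, y, family = stats::poisson(), control = ctl)
  gamma <- if (pg > 0) init$coefficients[pl + seq_len(pg)] else numeric(0)
  beta_prev <- matrix(rep(init$coefficients[seq_len(pl)], each = n), n, pl)

  trace <- vector("list", max_cycles)
  converged <- FALSE
  loc <- NULL
  gamma_hist <- list()
  accelerated <- FALSE
  for (cyc in seq_len(max_cycles)) {
    off_g <- if (pg > 0) drop(Xg %*% gamma) else rep(0, n)
    loc <- cpp_local_fits(as.numeric(y), Xl, off_g, W, tol = 1e-8,
                          maxit = 50, sandwich = (se_type == "sandwich"),
                          beta_init = if (cyc > 1) beta_prev else NULL)
    eta_loc <- loc$eta_own
    if (anyNA(eta_loc)) {
      # unstable locations: hold their linear predictor at the previous
      # iterate so the global step still sees all observations
      bad <- which(is.na(eta_loc))
      eta_loc[bad] <- rowSums(Xl[bad, , drop = FALSE] *
                                beta_prev[bad, , drop = FALSE])
    }
    if (pg > 0) {
      gfit <- stats::glm.fit(Xg, y, offset = eta_loc,
                             family = stats::poisson(), control = ctl)
      gamma_new <- gfit$coefficients
    } else {
      gamma_new <- numeric(0)
    }
    d_beta <- max(abs(loc$beta - beta_prev), na.rm = TRUE)
    d_gamma <- if (pg > 0) max(abs(gamma_new - gamma)) else 0
    delta <- max(d_beta, d_gamma)
    mu_cyc <- exp(pmin(eta_loc + (if (pg > 0) drop(Xg %*% gamma_new) else 0),
                       30))
    trace[[cyc]] <- tibble::tibble(cycle = cyc,
                                   deviance = poisson_deviance(y, mu_cyc),
                                   max_delta = delta)
    gamma <- gamma_new
    beta_prev <- loc$beta
    if (delta < tol && !accelerated) { converged <- TRUE; break }
    accelerated <- FALSE
    # Aitken extrapolation on the gamma fixed point: the alternation
    # converges linearly, so jump along the dominant geometric mode
    if (pg > 0) {
      gamma_hist <- c(gamma_hist, list(gamma))
      if (length(gamma_hist) >= 3 && cyc %% 3 == 0) {
        h <- gamma_hist[(length(gamma_hist) - 2):length(gamma_hist)]
        d1 <- h[[2]] - h[[1]]
        d2 <- h[[3]] - h[[2]]
        denom <- d2 - d1
        use <- is.finite(denom) & abs(denom) > 1e-12
        g_acc <- h[[3]]
        g_acc[use] <- h[[3]][use] - d2[use]^2 / denom[use]
        step <- max(abs(g_acc - h[[3]]))
        if (is.finite(step) && step < 50 * max(abs(d2))) {
          gamma <- g_acc
          gamma_hist <- list()
          accelerated <- TRUE
        }
      }
    }
  }
  trace <- dplyr::bind_rows(trace)
  if (!converged) {
    stop(paste0(
      "back-fitting did not converge in ", max_cycles, " cycles; ",
      "last max coefficient change ",
      format(trace$max_delta[nrow(trace)], digits = 3),
      " (deviance trace: ",
      paste(round(utils::tail(trace$deviance, 5), 2), collapse = ", "), ")"
    ), call. = FALSE)
  }

  stable <- as.logical(loc$ok)
  if (any(!stable)) {
    warning(sum(!stable),
            " local fit(s) unstable; excluded from summaries", call. = FALSE)
  }
  eta_loc <- loc$eta_own
  eta_loc[!stable] <- rowSums(Xl[!stable, , drop = FALSE] *
                                beta_prev[!stable, , drop = FALSE])
  off_g <- if (pg > 0) drop(Xg %*% gamma) else rep(0, n)
  mu <- exp(pmin(eta_loc + off_g, 30))
  D <- poisson_deviance(y, mu)
  k <- sum(loc$hat_ii[stable]) + pg

  null <- stats::glm.fit(matrix(1, n, 1), y, family = stats::poisson(),
                         control = ctl)
  gamma_se <- if (pg > 0) {
    wg <- gfit$weights  # IRLS weights at convergence = mu for Poisson
    sqrt(diag(solve(crossprod(Xg, Xg * wg))))
  } else {
    numeric(0)
  }

  beta <- loc$beta; colnames(beta) <- colnames(Xl)
  se <- loc$se; colnames(se) <- colnames(Xl)
  structure(list(
    degenerate = FALSE, beta = beta, se = se, stable = stable,
    gamma = stats::setNames(gamma, colnames(Xg)),
    gamma_se = stats::setNames(gamma_se, colnames(Xg)),
    local_terms = colnames(Xl), global_terms = colnames(Xg),
    deviance = D, null_deviance = null$deviance,
    loglik = poisson_loglik(y, mu),
    loglik_null = poisson_loglik(y, null$fitted.values),
    k = k, n = n, kernel = kernel, bandwidths = gwm$bandwidths,
    se_type = se_type, cycles = nrow(trace), converged = converged,
    trace = trace, points = pts, fingerprint = data_fingerprint(y),
    fitted = mu
  ), class = "gwpr_fit")
}

#' @export
print.gwpr_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<gwpr_fit> degenerate (no local terms): equals the global Poisson fit\n")
  } else {
    bw <- if (x$kernel$mode == "adaptive") {
      sprintf("adaptive N = %d", x$kernel$neighbor_count)
    } else {
      sprintf("fixed %.0f m", x$kernel$bandwidth_m)
    }
    cat(sprintf(
      "<gwpr_fit> semiparametric GWPR: n = %d, %d local + %d fixed terms\n",
      x$n, length(x$local_terms), length(x$global_terms)))
    cat(sprintf("  kernel %s (%s); %d back-fitting cycles\n",
                x$kernel$family, bw, x$cycles))
  }
  cat(sprintf("  deviance %.1f, effective parameters %.1f, AICc %.1f\n",
              x$deviance, x$k, x$deviance + 2 * x$k))
  invisible(x)
}

#' @export
effective_parameters.gwpr_fit <- function(fit) fit$k

#' Pseudo-t significance of local estimates
#'
#' Local coefficient divided by its local standard error; locations where
#' `|t|` strictly exceeds the threshold (default 1.96, the two-sided 5%
#' normal point) are flagged significant. The sign of the estimate is
#' reported separately as the direction of the local association.
#'
#' @param fit A `gwpr_fit`.
#' @param threshold Flagging threshold on `|t|` (default 1.96).
#' @return A tibble with one row per location x local term: `id`, `x_m`,
#'   `y_m`, `term`, `estimate`, `se`, `pseudo_t`, `significant`, `sign`.
#'   Unstable locations carry `NA` and are never flagged.
#' @export
pseudo_t <- function(fit, threshold = 1.96) {
  stopifnot(inherits(fit, "gwpr_fit"))
  if (fit$degenerate) {
    stop("degenerate fit has no local estimates", call. = FALSE)
  }
  out <- tidy(fit)
  out$significant <- !is.na(out$pseudo_t) & is.finite(out$pseudo_t) &
    abs(out$pseudo_t) > threshold
  out$significant[!is.na(out$se) & out$se == 0] <- NA
  out$sign <- dplyr::case_when(
    is.na(out$estimate) ~ NA_character_,
    out$estimate > 0 ~ "positive",
    out$estimate < 0 ~ "negative",
    TRUE ~ "zero"
  )
  out
}

#' Search the adaptive bandwidth over a neighbour-count grid
#'
#' Fits the semiparametric GWPR at every candidate neighbour count and
#' returns the AICc minimiser. The default grid descends from
#' `min(4000, n - 1)` to 50 in steps of 50, clipped to the valid range
#' `[p_local + 2, n - 1]`.
#'
#' @inheritParams fit_gwpr
#' @param family Kernel family for the adaptive kernel.
#' @param grid Integer vector of candidate neighbour counts; default as
#'   above.
#' @param keep_best Return the refitted best model under `$fit`.
#' @param ... Passed to [fit_gwpr()].
#' @return A list with `selected` (neighbour count), `trace` (tibble of
#'   `n_neighbors`, `deviance`, `k`, `aicc`, `converged`) and, when
#'   `keep_best`, `fit`.
#' @export
bandwidth_search <- function(data, response, local_terms = character(),
                             global_terms = character(),
                             family = "bisquare", grid = NULL,
                             local_intercept = TRUE, keep_best = TRUE,
                             dist_matrix = NULL, ...) {
  n <- nrow(data)
  pl <- length(local_terms) + as.integer(local_intercept)
  lo <- pl + 2L
  hi <- n - 1L
  if (is.null(grid)) {
    grid <- bandwidth_grid(from = min(4000L, hi), to = 50L, by = 50L)
  }
  grid <- as.integer(grid)
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) == 0) stop("no valid grid values in [",
                              lo, ", ", hi, "]", call. = FALSE)
  dm <- dist_matrix %||%
    pairwise_distances(tibble::tibble(x_m = data$x_m, y_m = data$y_m))
  fits <- vector("list", length(grid))
  rows <- purrr::map(seq_along(grid), function(j) {
    N <- grid[j]
    f <- tryCatch(
      fit_gwpr(data, response, local_terms, global_terms,
               kernel = kernel_spec(family, "adaptive", neighbor_count = N),
               local_intercept = local_intercept, dist_matrix = dm, ...),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      return(tibble::tibble(n_neighbors = N, deviance = NA_real_,
                            k = NA_real_, aicc = NA_real_, converged = FALSE,
                            message = conditionMessage(f)))
    }
    fits[[j]] <<- f
    tibble::tibble(n_neighbors = N, deviance = f$deviance, k = f$k,
                   aicc = f$deviance + 2 * f$k, converged = TRUE,
                   message = NA_character_)
  })
  trace <- dplyr::bind_rows(rows)
  if (all(is.na(trace$aicc))) {
    stop("all candidate fits failed:\n",
         paste(sprintf("  N=%d: %s", trace$n_neighbors, trace$message),
               collapse = "\n"), call. = FALSE)
  }
  best <- which.min(trace$aicc)
  out <- list(selected = grid[best], trace = trace)
  if (keep_best) out$fit <- fits[[best]]
  class(out) <- "gwpr_bandwidth_search"
  out
}

#' @rdname bandwidth_search
#' @param from,to,by Grid end points and step for the descending
#'   neighbour-count grid.
#' @export
bandwidth_grid <- function(from = 4000L, to = 50L, by = 50L) {
  as.integer(seq(from, to, by = -abs(by)))
}

#' @export
print.gwpr_bandwidth_search <- function(x, ...) {
  cat(sprintf("<bandwidth search> %d candidates, selected N = %d (AICc %.1f)\n",
              nrow(x$trace), x$selected, min(x$trace$aicc, na.rm = TRUE)))
  invisible(x)
}

#' Compare two fits by AICc (MAICE rule)
#'
#' Reports the AICc difference between two models fitted to the same data;
#' the minimum-AICc model (MAICE, the minimum AIC estimator) is preferred,
#' and a difference strictly greater than 2 is labelled substantial.
#'
#' @param fit_a,fit_b `gpr_fit` or `gwpr_fit` objects on identical data.
#' @param label_a,label_b Names used in the verdict.
#' @return One-row tibble: `aicc_a`, `aicc_b`, `delta_aicc`, `substantial`,
#'   `preferred`.
#' @export
compare_models <- function(fit_a, fit_b, label_a = "model_a",
                           label_b = "model_b") {
  fp <- function(f) {
    if (inherits(f, "gpr_fit")) data_fingerprint(f$y) else f$fingerprint
  }
  if (!isTRUE(all.equal(fp(fit_a), fp(fit_b)))) {
    stop("fits are not on identical data; comparison refused", call. = FALSE)
  }
  aic <- function(f) f$deviance + 2 * effective_parameters(f)
  a <- aic(fit_a); b <- aic(fit_b)
  delta <- abs(a - b)
  tibble::tibble(
    aicc_a = a, aicc_b = b, delta_aicc = delta,
    substantial = delta > 2,
    preferred = if (a <= b) label_a else label_b
  )
}

#' Summarise local estimates across locations
#'
#' The spread of the local coefficient surfaces over all stable locations:
#' mean and standard deviation of the log-odds, and mean, minimum, maximum
#' and range of the per-location odds ratios (each local log-odds is
#' exponentiated before aggregating). A wide OR range relative to the mean
#' is the signature of spatial non-stationarity.
#'
#' @param fit A `gwpr_fit`.
#' @return A tibble with one row per local term.
#' @export
summarize_local <- function(fit) {
  stopifnot(inherits(fit, "gwpr_fit"))
  if (fit$degenerate) stop("degenerate fit has no local estimates",
                           call. = FALSE)
  if (!any(fit$stable)) stop("all local fits unstable", call. = FALSE)
  b <- fit$beta[fit$stable, , drop = FALSE]
  ors <- exp(b)
  tibble::tibble(
    term = colnames(b),
    mean_log_odds = unname(colMeans(b)),
    sd_log_odds = unname(apply(b, 2, stats::sd)),
    mean_or = unname(colMeans(ors)),
    min_or = unname(apply(ors, 2, min)),
    max_or = unname(apply(ors, 2, max)),
    range_or = unname(apply(ors, 2, max) - apply(ors, 2, min))
  )
}

#' Tidy a GWPR fit into a long table of local estimates
#'
#' @param x A `gwpr_fit`.
#' @param ... Unused.
#' @return Long tibble, one row per location x local term.
#' @export
tidy.gwpr_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(
      id = integer(), x_m = numeric(), y_m = numeric(), term = character(),
      estimate = numeric(), se = numeric(), pseudo_t = numeric()
    ))
  }
  n <- x$n
  terms <- x$local_terms
  purrr::map_dfr(seq_along(terms), function(j) {
    tibble::tibble(
      id = seq_len(n), x_m = x$points$x_m, y_m = x$points$y_m,
      term = terms[j], estimate = x$beta[, j], se = x$se[, j],
      pseudo_t = x$beta[, j] / x$se[, j]
    )
  })
}

#' One-row summary of a GWPR fit
#'
#' @param x A `gwpr_fit`.
#' @param ... Unused.
#' @export
glance.gwpr_fit <- function(x, ...) {
  dplyr::mutate(
    deviance_stats(x),
    bandwidth = if (x$kernel$mode == "adaptive") {
      as.numeric(x$kernel$neighbor_count)
    } else {
      x$kernel$bandwidth_m
    },
    cycles = x$cycles, converged = x$converged,
    unstable_locations = sum(!x$stable)
  )
}

#' Map a local coefficient (or pseudo-t) surface
#'
#' @param object A `gwpr_fit`.
#' @param term Local term to display (default: first).
#' @param what `"estimate"` or `"pseudo_t"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gwpr_fit <- function(object, term = NULL,
                              what = c("estimate", "pseudo_t"), ...) {
  what <- match.arg(what)
  term <- term %||% object$local_terms[1]
  d <- dplyr::filter(tidy(object), .data$term == !!term)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_m, .data$y_m,
                                  colour = .data[[what]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey90",
                                    high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Local %s: %s", what, term),
                  x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
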