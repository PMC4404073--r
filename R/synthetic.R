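#' True coefficient surfaces
#'
#' Constructors for the spatially varying "true" coefficient surfaces used
#' by the synthetic cohort generator: a constant, a linear gradient across
#' the region, or a Gaussian bump. Each returns a function of planar
#' coordinates `(u, v)` in metres.
#'
#' @param value Constant coefficient value.
#' @return A function `f(u, v)` returning the coefficient surface.
#' @export
surface_constant <- function(value) {
  force(value)
  structure(function(u, v) rep(value, length(u)),
            spec = list(kind = "constant", value = value))
}

#' @rdname surface_constant
#' @param base Surface value at the region centre.
#' @param amplitude Half-range of the gradient: the surface runs from
#'   `base - amplitude` to `base + amplitude` across the region extent.
#' @param direction Unit-direction of increase (default east).
#' @param center,half_extent Region centre and half-extent (metres) used
#'   to scale the gradient.
#' @export
surface_gradient <- function(base = 0, amplitude = 0.3,
                             direction = c(1, 0), center = c(0, 0),
                             half_extent = 15000) {
  direction <- direction / sqrt(sum(direction^2))
  structure(function(u, v) {
    s <- ((u - center[1]) * direction[1] + (v - center[2]) * direction[2]) /
      half_extent
    base + amplitude * pmin(pmax(s, -1), 1)
  }, spec = list(kind = "gradient", base = base, amplitude = amplitude,
                 direction = direction))
}

#' @rdname surface_constant
#' @param sd Bump standard deviation in metres.
#' @export
surface_bump <- function(base = 0, amplitude = 0.3, center = c(0, 0),
                         sd = 5000) {
  structure(function(u, v) {
    base + amplitude *
      exp(-((u - center[1])^2 + (v - center[2])^2) / (2 * sd^2))
  }, spec = list(kind = "bump", base = base, amplitude = amplitude,
                 center = center, sd = sd))
}

# Regular polygon ring (closed) as a two-column matrix.
circle_ring <- function(cx, cy, r, k = 24) {
  th <- seq(0, 2 * pi, length.out = k + 1)
  cbind(x_m = cx + r * cos(th), y_m = cy + r * sin(th))
}

#' Default synthetic study region
#'
#' An irregular urban region roughly 30 km across: a wobbly 24-gon shell
#' with two circular "park" holes (respondents live around, not inside,
#' the large green spaces), mimicking a dense-core metropolitan area.
#'
#' @return A list with `rings` (shell first, then holes), usable wherever
#'   a polygon from [read_geojson_polygons()] is.
#' @export
default_region <- function() {
  k <- 24
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  # fixed wobble pattern: this is geography, not randomness
  r <- 15000 * (1 + 0.18 * sin(3 * th) + 0.10 * cos(5 * th + 1))
  shell <- rbind(cbind(r * cos(th), r * sin(th)),
                 c(r[1] * cos(th[1]), r[1] * sin(th[1])))
  colnames(shell) <- c("x_m", "y_m")
  list(rings = list(shell,
                    circle_ring(-8000, 1500, 2200, 16),
                    circle_ring(9000, -1200, 2500, 16)),
       properties = list(name = "synthetic study region"))
}

#' Scenario configuration for the synthetic cohort
#'
#' Bundles everything the generator needs: cohort size, region geometry,
#' master seed, the true coefficient surface of every locally varying
#' term, the fixed individual-level coefficients, latent-factor spatial
#' ranges, and the optional zero-inflation probability (off by default;
#' the default scenario is the plain-Poisson world the fitted model
#' assumes).
#'
#' @param n Number of participants (default 4164, the analysed cohort
#'   size this generator emulates).
#' @param seed Master seed; fixes every random draw.
#' @param region Region polygon with optional holes (see
#'   [default_region()]).
#' @param surfaces Named list of surface functions for the local terms;
#'   must include `"(Intercept)"`. Defaults to constant surfaces
#'   (intercept 0.8, `env1` 0.05, `env2` 0.01).
#' @param gamma Named fixed coefficients for the individual columns.
#' @param density_range Distance-decay range (m) of residential density
#'   from the core.
#' @param factor_ranges Spatial ranges (m) of the two latent
#'   environmental factors.
#' @param noise_scale Multiplier on the unique (noise) part of the 15
#'   environmental variables (1 = calibrated default).
#' @param likert_noise Multiplier on the unique part of the Likert items.
#' @param zero_inflation Probability of structural zero (default 0).
#' @param outcome_mode `"counts"` generates outcomes directly in
#'   half-hour units (so [discretize_outcome()] is the identity);
#'   `"hours_jitter"` adds sub-rounding jitter to exercise the rounding
#'   path.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n = 4164, seed = 1, region = default_region(),
                            surfaces = NULL, gamma = NULL,
                            density_range = 9000,
                            factor_ranges = c(9000, 12000),
                            noise_scale = 1, likert_noise = 1,
                            zero_inflation = 0,
                            outcome_mode = c("counts", "hours_jitter")) {
  outcome_mode <- match.arg(outcome_mode)
  if (n < 50) stop("n must be at least 50", call. = FALSE)
  surfaces <- surfaces %||% list(
    "(Intercept)" = surface_constant(0.8),
    env1 = surface_constant(0.05),
    env2 = surface_constant(0.01)
  )
  if (!"(Intercept)" %in% names(surfaces)) {
    stop("surfaces must include \"(Intercept)\"", call. = FALSE)
  }
  gamma <- gamma %||% c(
    age_c10 = 0.00, gender_female = 0.04, educ_high = -0.12,
    parking_work = -0.29, transit_pass = -0.05, commute_tertile = 0.34,
    n_vehicles = -0.19, n_bikes = 0.09
  )
  structure(list(
    n = as.integer(n), seed = as.integer(seed), region = region,
    surfaces = surfaces, gamma = gamma,
    density_range = density_range, factor_ranges = factor_ranges,
    noise_scale = noise_scale, likert_noise = likert_noise,
    zero_inflation = zero_inflation, outcome_mode = outcome_mode
  ), class = "scenario_config")
}

#' Named scenarios
#'
#' `scenario_g1()`: an east-west linear gradient in the `env1`
#' coefficient (amplitude 0.3 around a 0.05 centre) — the canonical
#' non-stationary recovery scenario. `scenario_stationary()`: the same
#' generative model with all surfaces constant. `scenario_null()`: the
#' `env1` coefficient is identically zero, for significance-calibration
#' checks.
#'
#' @param n,seed,... Passed to [scenario_config()].
#' @export
scenario_g1 <- function(n = 1000, seed = 1, ...) {
  scenario_config(n = n, seed = seed, surfaces = list(
    "(Intercept)" = surface_constant(0.8),
    env1 = surface_gradient(base = 0.05, amplitude = 0.3),
    env2 = surface_constant(0.01)
  ), ...)
}

#' @rdname scenario_g1
#' @export
scenario_stationary <- function(n = 1000, seed = 1, ...) {
  scenario_config(n = n, seed = seed, ...)
}

#' @rdname scenario_g1
#' @export
scenario_null <- function(n = 1000, seed = 1, ...) {
  scenario_config(n = n, seed = seed, surfaces = list(
    "(Intercept)" = surface_constant(0.8),
    env1 = surface_constant(0),
    env2 = surface_constant(0.01)
  ), ...)
}

region_bbox <- function(region) {
  shell <- region$rings[[1]]
  c(xmin = min(shell[, 1]), ymin = min(shell[, 2]),
    xmax = max(shell[, 1]), ymax = max(shell[, 2]))
}

region_centroid <- function(region) {
  shell <- region$rings[[1]]
  c(mean(shell[-nrow(shell), 1]), mean(shell[-nrow(shell), 2]))
}

#' Generate residential locations
#'
#' Inhomogeneous point pattern over the region: proposal points are
#' accepted with probability decaying in distance from the region
#' centroid (range `density_range`), rejected inside hole polygons, until
#' exactly `n` points are placed. Reproducible for a fixed seed.
#'
#' @param config A [scenario_config()].
#' @return Tibble with `x_m`, `y_m`.
#' @export
gen_locations <- function(config) {
  set.seed(config$seed + 11L)
  bb <- region_bbox(config$region)
  ctr <- region_centroid(config$region)
  n <- config$n
  got <- 0L
  xs <- numeric(n); ys <- numeric(n)
  tries <- 0L
  batch <- max(4L * n, 1000L)
  while (got < n) {
    tries <- tries + batch
    if (tries > 1e6) {
      stop("could not place ", n, " points after 1e6 proposals", call. = FALSE)
    }
    px <- stats::runif(batch, bb["xmin"], bb["xmax"])
    py <- stats::runif(batch, bb["ymin"], bb["ymax"])
    keep <- points_in_polygon(px, py, config$region$rings)
    d <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
    keep <- keep & (stats::runif(batch) < exp(-(d / config$density_range)^2))
    px <- px[keep]; py <- py[keep]
    take <- min(length(px), n - got)
    if (take > 0) {
      xs[got + seq_len(take)] <- px[seq_len(take)]
      ys[got + seq_len(take)] <- py[seq_len(take)]
      got <- got + take
    }
  }
  tibble::tibble(x_m = xs, y_m = ys)
}

# Loading pattern of the 15 observed environmental variables on the two
# latent factors (factor 1: built-up density; factor 2: socio-economic
# level). Magnitudes are rescaled at generation time so the two-factor
# share of variance is 0.64 on average.
env_loading_pattern <- function() {
  tibble::tibble(
    var = c("pop_density", "building_density", "intersection_density",
            "vegetation_cover", "facility_density", "bikeshare_density",
            "bikepath_density", "median_income", "pct_university",
            "pct_unemployed", "pct_foreign", "pct_home_owners",
            "pct_car_owners", "pct_individual_housing",
            "dist_public_transport"),
    l1 = c(0.85, 0.82, 0.75, -0.55, 0.72, 0.70, 0.62,
           0.05, 0.18, 0.12, 0.15, -0.45, -0.60, -0.58, -0.52),
    l2 = c(0.05, 0.10, 0.08, 0.35, 0.15, 0.20, 0.12,
           0.80, 0.74, -0.72, -0.66, 0.58, 0.42, 0.38, -0.30)
  )
}

#' Names of the 15 generated environmental variables
#'
#' @export
env_loading_names <- function() env_loading_pattern()$var

# Standardized latent factor surfaces evaluated at the points:
# F1 radial density (peaks at the core), F2 an independent smooth
# socio-economic surface (fixed Gaussian-bump mixture).
latent_factors <- function(points, config) {
  ctr <- region_centroid(config$region)
  d <- sqrt((points$x_m - ctr[1])^2 + (points$y_m - ctr[2])^2)
  f1 <- exp(-(d / config$factor_ranges[1])^2)
  r2 <- config$factor_ranges[2]
  f2 <- exp(-((points$x_m - 6000)^2 + (points$y_m + 6000)^2) / (2 * (0.6 * r2)^2)) -
    0.9 * exp(-((points$x_m + 7000)^2 + (points$y_m - 7000)^2) / (2 * (0.5 * r2)^2)) +
    0.5 * exp(-((points$x_m - 1000)^2 + (points$y_m - 9000)^2) / (2 * (0.4 * r2)^2))
  cbind(f1 = as.numeric(scale(f1)), f2 = as.numeric(scale(f2)))
}

#' Generate the collinear environmental variable block
#'
#' Fifteen observed variables (7 physical, 8 socio-environmental), each a
#' signed loading times one of two smooth latent spatial factors plus
#' unique noise. Loadings are rescaled so that the two-factor share of
#' total variance is 0.64 in expectation, reproducing the substantial
#' multicollinearity the composite-construction step assumes.
#'
#' @param points Locations from [gen_locations()].
#' @param config A [scenario_config()].
#' @return List with `env` (tibble of the 15 variables), `factors`
#'   (n x 2 matrix of standardized latent factor scores `f1`, `f2`).
#' @export
gen_environment <- function(points, config) {
  set.seed(config$seed + 23L)
  n <- nrow(points)
  Fm <- latent_factors(points, config)
  pat <- env_loading_pattern()
  L <- as.matrix(pat[, c("l1", "l2")])
  # rescale so mean communality = 0.64
  s <- sqrt(0.64 / mean(rowSums(L^2)))
  L <- L * s
  comm <- pmin(rowSums(L^2), 0.95)
  sd_u <- sqrt(1 - comm) * config$noise_scale
  E <- matrix(stats::rnorm(n * nrow(pat)), n, nrow(pat))
  X <- Fm %*% t(L) + E %*% diag(sd_u)
  colnames(X) <- pat$var
  list(env = tibble::as_tibble(as.data.frame(X)), factors = Fm,
       loadings = L)
}

#' Generate individual covariates
#'
#' Marginals emulate the analysed cohort: 78% women, 83.1% with at least
#' high-school education, 36.7% with workplace parking, 45.8% with a
#' transit pass, balanced commuting-time tertiles, household vehicle and
#' bike counts, and age truncated to 18-87 years.
#'
#' @param config A [scenario_config()].
#' @return Tibble of covariates, including the centred `age_c10`
#'   (decades from the cohort mean) used in the outcome model.
#' @export
gen_individual_covariates <- function(config) {
  set.seed(config$seed + 37L)
  n <- config$n
  age <- stats::rnorm(n, 43.6, 13.3)
  while (any(bad <- age < 18 | age > 87)) {
    age[bad] <- stats::rnorm(sum(bad), 43.6, 13.3)
  }
  tert <- sample(rep(0:2, length.out = n))
  tibble::tibble(
    age = age,
    age_c10 = (age - 43.6) / 10,
    gender_female = stats::rbinom(n, 1, 0.780),
    educ_high = stats::rbinom(n, 1, 0.831),
    parking_work = stats::rbinom(n, 1, 0.367),
    transit_pass = stats::rbinom(n, 1, 0.458),
    commute_tertile = tert,
    n_vehicles = pmin(stats::rpois(n, 1.03), 8L),
    n_bikes = pmin(stats::rpois(n, 1.30), 4L)
  )
}

#' Generate perceived-environment Likert items
#'
#' Three items (bike safety, pollution, aesthetics) driven by one latent
#' perception factor with signed loadings (+, +, -), discretized at fixed
#' symmetric cutpoints into the 5-level agreement codebook.
#'
#' @param points Locations (row count sets n; items are iid over
#'   respondents).
#' @param config A [scenario_config()].
#' @return Tibble with `bike_safety`, `pollution`, `aesthetics`
#'   (integers 1-5) and the latent `perception_factor`.
#' @export
gen_likert <- function(points, config) {
  set.seed(config$seed + 53L)
  n <- nrow(points)
  P <- stats::rnorm(n)
  a <- c(bike_safety = 0.55, pollution = 0.53, aesthetics = -0.52)
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  items <- purrr::map(a, function(aj) {
    u_sd <- sqrt(max(1 - aj^2, 0)) * config$likert_noise
    z <- aj * P + u_sd * stats::rnorm(n)
    # standardize by the theoretical sd so the cutpoints sit at the same
    # latent quantiles for every item (noiseless limit: z = sign(a) P)
    z <- z / sqrt(aj^2 + u_sd^2)
    as.integer(findInterval(z, cuts) + 1L)
  })
  tibble::tibble(!!!items, perception_factor = P)
}

#' Generate the active-commuting outcome
#'
#' Poisson half-hour counts from the log-linear intensity
#' `log lambda_i = sum_k beta_k(u_i, v_i) x_ik + sum_m gamma_m x_im`,
#' with spatially varying environmental coefficients evaluated at each
#' residence and spatially constant individual coefficients. Optional
#' zero inflation multiplies by an independent Bernoulli draw.
#'
#' @param points Locations.
#' @param env_scores Tibble/matrix of local-term covariate values
#'   (columns matching `names(config$surfaces)` minus the intercept).
#' @param individual Tibble of individual covariates (columns matching
#'   `names(config$gamma)`).
#' @param config A [scenario_config()].
#' @return List with `hours`, `counts`, `lambda` (true mean),
#'   `true_beta` (n x local-term matrix).
#' @export
gen_outcome <- function(points, env_scores, individual, config) {
  set.seed(config$seed + 71L)
  n <- nrow(points)
  terms <- names(config$surfaces)
  B <- vapply(terms, function(tm) {
    config$surfaces[[tm]](points$x_m, points$y_m)
  }, numeric(n))
  Xl <- cbind("(Intercept)" = rep(1, n),
              as.matrix(as.data.frame(env_scores))[,
                setdiff(terms, "(Intercept)"), drop = FALSE])
  eta <- rowSums(B * Xl[, terms, drop = FALSE])
  gm <- config$gamma
  if (length(gm) > 0) {
    Xg <- as.matrix(as.data.frame(individual))[, names(gm), drop = FALSE]
    eta <- eta + drop(Xg %*% gm)
  }
  if (any(eta > 30)) {
    stop("linear predictor exceeds 30; reduce surface amplitudes",
         call. = FALSE)
  }
  lambda <- exp(eta)
  counts <- stats::rpois(n, lambda)
  if (config$zero_inflation > 0) {
    counts <- counts * stats::rbinom(n, 1, 1 - config$zero_inflation)
  }
  hours <- counts / 2
  if (config$outcome_mode == "hours_jitter") {
    hours <- pmax(0, hours + stats::runif(n, -0.2, 0.2))
  }
  list(hours = hours, counts = as.integer(counts), lambda = lambda,
       true_beta = B)
}

#' Simulate a full synthetic cohort
#'
#' Runs every generator stage under one master seed and assembles the
#' participant table the analysis pipeline consumes, together with the
#' generative truth (latent factors, true coefficient surfaces, true
#' Poisson means) for recovery scoring.
#'
#' @param config A [scenario_config()].
#' @return A `gw_cohort`: list with `participants` (tibble: coordinates,
#'   `hours`, `counts`, `env1`/`env2` latent-factor scores, the 15 raw
#'   environmental variables, Likert items and individual covariates)
#'   and `truth` (true beta surfaces, lambda, factor loadings, config).
#' @examples
#' coh <- simulate_cohort(scenario_config(n = 200, seed = 42))
#' dplyr::glimpse(coh$participants[, 1:8])
#' @export
simulate_cohort <- function(config = scenario_config()) {
  pts <- gen_locations(config)
  envr <- gen_environment(pts, config)
  indiv <- gen_individual_covariates(config)
  lik <- gen_likert(pts, config)
  env_scores <- tibble::tibble(env1 = envr$factors[, "f1"],
                               env2 = envr$factors[, "f2"])
  out <- gen_outcome(pts, env_scores, indiv, config)
  participants <- dplyr::bind_cols(
    pts,
    tibble::tibble(hours = out$hours, counts = out$counts),
    env_scores, envr$env, lik, indiv
  )
  structure(list(
    participants = participants,
    truth = list(true_beta = out$true_beta, lambda = out$lambda,
                 factors = envr$factors, loadings = envr$loadings,
                 config = config)
  ), class = "gw_cohort")
}

#' @export
print.gw_cohort <- function(x, ...) {
  cat(sprintf("<gw_cohort> %d participants, seed %d\n",
              nrow(x$participants), x$truth$config$seed))
  cat(sprintf("  outcome: mean %.2f half-hour units, %.0f%% zeros\n",
              mean(x$participants$counts),
              100 * mean(x$participants$counts == 0)))
  invisible(x)
}
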