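#' Inverse-distance-weighted interpolation of site values
#'
#' Spreads per-location values (typically local coefficient or pseudo-t
#' estimates) onto a regular display grid: each cell takes the
#' inverse-distance-power weighted average of its `max_neighbors` nearest
#' sites. A cell whose centre coincides with a site takes that site's
#' value exactly, and every interpolated value lies within the range of
#' the input values (convex combination).
#'
#' @param sites Tibble with `x_m`, `y_m`, `value`.
#' @param grid A `raster_grid` giving the output extent.
#' @param power Distance-decay exponent (default 2).
#' @param max_neighbors Number of nearest sites used per cell (default 12).
#' @return A `raster_grid`.
#' @export
idw_interpolate <- function(sites, grid, power = 2, max_neighbors = 12) {
  stopifnot(inherits(grid, "raster_grid"))
  if (nrow(sites) == 0) stop("empty site set", call. = FALSE)
  if (!is.finite(power) || power <= 0) stop("`power` must be positive",
                                            call. = FALSE)
  sites <- sites[is.finite(sites$value), , drop = FALSE]
  if (nrow(sites) == 0) stop("no finite site values", call. = FALSE)
  k <- min(max_neighbors, nrow(sites))
  cc <- grid_centers(grid)
  d <- pairwise_distances(cc, sites)
  vals <- vapply(seq_len(nrow(cc)), function(i) {
    di <- d[i, ]
    if (any(di == 0)) return(sites$value[which(di == 0)[1]])
    ord <- order(di)[seq_len(k)]
    w <- di[ord]^(-power)
    sum(w * sites$value[ord]) / sum(w)
  }, numeric(1))
  out <- grid
  out$values <- matrix(vals, grid$n_rows, grid$n_cols, byrow = TRUE)
  out
}

#' Pipeline run configuration
#'
#' Exactly one of `scenario` (synthetic mode) or `participants` (a tibble
#' or CSV path with planar coordinates `x_m`, `y_m`, the outcome and all
#' model columns) must be given.
#'
#' @param scenario A [scenario_config()] for synthetic mode.
#' @param participants Participant table or CSV path (real-input mode).
#' @param hours_column Continuous outcome column to discretize (ignored
#'   when `counts_column` already exists in the data).
#' @param counts_column Count outcome column name.
#' @param local_terms,global_terms Model column lists (environmental
#'   terms vary spatially; individual terms stay fixed).
#' @param local_intercept Spatially varying intercept (default `TRUE`).
#'   With no local terms and no local intercept the run degenerates to
#'   the global model and the bandwidth search is skipped.
#' @param family Kernel family.
#' @param grid Bandwidth-search neighbour-count grid (default: the full
#'   descending grid, see [bandwidth_search()]).
#' @param surface_cell_m Cell size of the interpolated display surfaces.
#' @param idw_power,idw_neighbors IDW display parameters.
#' @param verbose Log stage progress to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, participants = NULL,
                       hours_column = "hours", counts_column = "counts",
                       local_terms = c("env1", "env2"),
                       global_terms = c("age_c10", "gender_female",
                                        "educ_high", "parking_work",
                                        "transit_pass", "commute_tertile",
                                        "n_vehicles", "n_bikes"),
                       local_intercept = TRUE,
                       family = "bisquare", grid = NULL,
                       surface_cell_m = 1000, idw_power = 2,
                       idw_neighbors = 12, verbose = TRUE) {
  if (is.null(scenario) == is.null(participants)) {
    stop("give exactly one of `scenario` (synthetic) or `participants`",
         call. = FALSE)
  }
  structure(list(
    scenario = scenario, participants = participants,
    hours_column = hours_column, counts_column = counts_column,
    local_terms = local_terms, global_terms = global_terms,
    local_intercept = local_intercept,
    family = family, grid = grid, surface_cell_m = surface_cell_m,
    idw_power = idw_power, idw_neighbors = idw_neighbors,
    verbose = verbose
  ), class = "run_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

surface_spec_of <- function(f) attr(f, "spec") %||% list(kind = "custom")

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic cohort generation (or participant-table
#' ingestion), outcome discretization, the global Poisson regression,
#' the adaptive-bandwidth AICc search, the semiparametric GWPR at the
#' selected bandwidth, the MAICE model comparison, odds-ratio and
#' local-summary tables, and IDW display surfaces (one estimate grid and
#' one pseudo-t grid per local term).
#'
#' @param config A [run_config()].
#' @return A `gw_result` bundle: `data`, `gpr`, `search`, `gwpr`,
#'   `comparison`, `wald`, `local_summary`, `surfaces`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  t0 <- Sys.time()

  if (!is.null(config$scenario)) {
    stage_log(v, "simulate: n = %d, seed = %d", config$scenario$n,
              config$scenario$seed)
    cohort <- simulate_cohort(config$scenario)
    data <- cohort$participants
    truth <- cohort$truth
  } else {
    data <- config$participants
    if (is.character(data)) data <- tibble::as_tibble(utils::read.csv(data))
    truth <- NULL
    if (looks_like_degrees(data$x_m, data$y_m)) {
      stop("participant coordinates look like lon/lat degrees; ",
           "project to planar metres first", call. = FALSE)
    }
  }
  if (!config$counts_column %in% names(data)) {
    stage_log(v, "discretize: %s -> %s", config$hours_column,
              config$counts_column)
    data[[config$counts_column]] <-
      discretize_outcome(data[[config$hours_column]])
  }
  n <- nrow(data)
  stage_log(v, "rows: %d", n)

  all_terms <- c(config$local_terms, config$global_terms)
  gpr <- fit_poisson_glm(data, config$counts_column, all_terms)
  stage_log(v, "GPR: deviance %.1f, AICc %.1f", gpr$deviance,
            gpr$deviance + 2 * gpr$p)

  degenerate <- length(config$local_terms) == 0 && !config$local_intercept
  if (degenerate) {
    stage_log(v, "no local terms: degenerate run, skipping bandwidth search")
    gwpr <- fit_gwpr(data, config$counts_column, character(),
                     config$global_terms, local_intercept = FALSE)
    search <- list(selected = NA_integer_,
                   trace = tibble::tibble(n_neighbors = integer(),
                                          deviance = numeric(), k = numeric(),
                                          aicc = numeric(),
                                          converged = logical(),
                                          message = character()))
  } else {
    dm <- pairwise_distances(tibble::tibble(x_m = data$x_m, y_m = data$y_m))
    search <- bandwidth_search(
      data, config$counts_column, config$local_terms, config$global_terms,
      family = config$family, grid = config$grid,
      local_intercept = config$local_intercept, dist_matrix = dm
    )
    gwpr <- search$fit
    stage_log(v, "GWPR: selected N = %d, deviance %.1f, k %.1f, AICc %.1f",
              search$selected, gwpr$deviance, gwpr$k,
              gwpr$deviance + 2 * gwpr$k)
  }

  comparison <- compare_models(gpr, gwpr, "GPR", "GWPR")
  wald <- wald_summary(gpr)
  local_summary <- if (degenerate) NULL else summarize_local(gwpr)

  bb <- c(xmin = min(data$x_m), ymin = min(data$y_m),
          xmax = max(data$x_m), ymax = max(data$y_m))
  disp <- empty_grid(bb["xmin"], bb["ymin"], bb["xmax"], bb["ymax"],
                     cell_size = config$surface_cell_m)
  pt <- if (degenerate) NULL else pseudo_t(gwpr)
  surfaces <- list()
  for (tm in gwpr$local_terms) {
    dsub <- dplyr::filter(pt, .data$term == tm, !is.na(.data$estimate))
    surfaces[[paste0(tm, "_estimate")]] <- idw_interpolate(
      dplyr::transmute(dsub, x_m = .data$x_m, y_m = .data$y_m,
                       value = .data$estimate),
      disp, power = config$idw_power, max_neighbors = config$idw_neighbors)
    surfaces[[paste0(tm, "_pseudo_t")]] <- idw_interpolate(
      dplyr::transmute(dsub, x_m = .data$x_m, y_m = .data$y_m,
                       value = .data$pseudo_t),
      disp, power = config$idw_power, max_neighbors = config$idw_neighbors)
  }
  stage_log(v, "surfaces: %d grids of %.0f m cells", length(surfaces),
            config$surface_cell_m)

  manifest <- list(
    mode = if (is.null(config$scenario)) "real" else "synthetic",
    n = n,
    seed = if (is.null(config$scenario)) NA else config$scenario$seed,
    degenerate = degenerate,
    local_terms = config$local_terms, global_terms = config$global_terms,
    kernel_family = config$family,
    selected_neighbors = search$selected,
    se_type = gwpr$se_type,
    surface_specs = if (!is.null(config$scenario)) {
      purrr::map(config$scenario$surfaces, surface_spec_of)
    } else {
      NULL
    },
    package_version = as.character(utils::packageVersion("gwcommute")),
    r_version = as.character(getRversion()),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  structure(list(
    data = data, truth = truth, gpr = gpr, search = search, gwpr = gwpr,
    comparison = comparison, wald = wald, local_summary = local_summary,
    surfaces = surfaces, manifest = manifest
  ), class = "gw_result")
}

#' @export
print.gw_result <- function(x, ...) {
  cat(sprintf("<gw_result> n = %d (%s mode)\n", x$manifest$n,
              x$manifest$mode))
  cat(sprintf("  GPR  AICc %.1f | GWPR AICc %.1f (N = %d) | dAICc %.1f -> %s\n",
              x$comparison$aicc_a, x$comparison$aicc_b,
              x$manifest$selected_neighbors, x$comparison$delta_aicc,
              x$comparison$preferred))
  invisible(x)
}

#' Export a pipeline result bundle to disk
#'
#' Writes: the per-location local-estimate table (CSV and GeoJSON
#' points), the model reports (JSON mirroring the global odds-ratio
#' table and overall-performance comparison), the bandwidth-search trace
#' (CSV), every interpolated surface (ESRI ASCII grid) and the run
#' manifest (JSON).
#'
#' @param bundle A `gw_result` from [run_pipeline()].
#' @param dir Output directory (created if missing; must be writable).
#' @return Invisibly, the vector of files written.
#' @export
export_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gw_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  if (file.access(dir, mode = 2) != 0) {
    stop("output directory not writable: ", dir, call. = FALSE)
  }
  files <- character(0)
  wr <- function(fn) files <<- c(files, fn)

  if (!bundle$gwpr$degenerate) {
    est <- pseudo_t(bundle$gwpr)
    wide <- tidyr::pivot_wider(
      est, id_cols = c("id", "x_m", "y_m"), names_from = "term",
      values_from = c("estimate", "se", "pseudo_t", "significant"),
      names_glue = "{term}_{.value}")
    f <- file.path(dir, "local_estimates.csv")
    utils::write.csv(wide, f, row.names = FALSE); wr(f)
    f <- file.path(dir, "local_estimates.geojson")
    write_geojson_points(dplyr::select(wide, -"id"), f); wr(f)
  }

  report <- list(
    gpr = list(coefficients = wald_to_list(bundle$wald),
               stats = as.list(deviance_stats(bundle$gpr))),
    gwpr = list(
      fixed_coefficients = as.list(bundle$gwpr$gamma),
      fixed_se = as.list(bundle$gwpr$gamma_se),
      local_summary = if (is.null(bundle$local_summary)) NULL else
        purrr::transpose(as.list(bundle$local_summary)),
      stats = as.list(glance(bundle$gwpr)),
      degenerate = bundle$gwpr$degenerate,
      note = if (bundle$gwpr$degenerate) "degenerate: equals GPR" else NULL
    ),
    comparison = as.list(bundle$comparison)
  )
  f <- file.path(dir, "model_report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE); wr(f)

  f <- file.path(dir, "bandwidth_trace.csv")
  utils::write.csv(bundle$search$trace, f, row.names = FALSE); wr(f)

  for (nm in names(bundle$surfaces)) {
    safe <- gsub("[^A-Za-z0-9_.-]+", "", nm)
    f <- file.path(dir, paste0("surface_", safe, ".asc"))
    write_esri_ascii(bundle$surfaces[[nm]], f); wr(f)
  }

  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE); wr(f)
  invisible(files)
}

wald_to_list <- function(w) {
  purrr::transpose(as.list(w))
}
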