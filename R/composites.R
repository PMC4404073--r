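#' Varimax-rotated principal-component composites of environmental variables
#'
#' Collapses a block of correlated built-environment variables into a small
#' number of uncorrelated composite scores. Components of the correlation
#' matrix are retained by the Kaiser criterion (eigenvalue > 1) and the
#' retained loading block is varimax-rotated (Kaiser-normalised criterion,
#' convergence 1e-8) for interpretability; rotation preserves per-variable
#' communalities. Sampling adequacy is reported as the overall KMO score
#' (partial-correlation formula) and Bartlett's sphericity test
#' (chi-square approximation).
#'
#' @param data Data frame; `vars` columns are standardised internally.
#' @param vars Columns to use (default: all numeric columns).
#' @param kaiser Retain only components with eigenvalue > 1 (default);
#'   otherwise all components are retained.
#' @param rotation `"varimax"` (default) or `"none"`.
#' @return A `pca_composites` object: list with `loadings` (p x m, rotated
#'   if requested), `unrotated_loadings`, `scores` (tibble `pc1..pcm` of
#'   unrotated component scores, variance = eigenvalue), `eigenvalues`,
#'   `variance_fractions`, `retained_count`, `kmo`, `bartlett_chisq`,
#'   `bartlett_df`, `bartlett_p`, `communalities`.
#' @export
pca_composites <- function(data, vars = NULL,
                           kaiser = TRUE, rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  X <- as.matrix(dplyr::select(as.data.frame(data), dplyr::all_of(vars)))
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 variables", call. = FALSE)
  if (p >= n) stop("need more observations than variables", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  V <- eig$vectors
  dimnames(V) <- list(vars, paste0("pc", seq_len(p)))
  m <- if (kaiser) max(1L, sum(ev > 1)) else p
  load_un <- V[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(m)]), m, m)
  colnames(load_un) <- paste0("pc", seq_len(m))
  loadings <- load_un
  rotmat <- diag(m)
  if (rotation == "varimax" && m > 1) {
    vr <- stats::varimax(load_un, normalize = TRUE, eps = 1e-8)
    loadings <- unclass(vr$loadings)
    rotmat <- vr$rotmat
    dimnames(loadings) <- dimnames(load_un)
  }
  scores <- Z %*% V[, seq_len(m), drop = FALSE]
  colnames(scores) <- paste0("pc", seq_len(m))

  # KMO: observed vs partial correlations (anti-image)
  S <- solve(R)
  Pc <- -S / sqrt(outer(diag(S), diag(S)))
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Pc[off]^2))
  # Bartlett sphericity
  chisq <- -(n - 1 - (2 * p + 5) / 6) * determinant(R)$modulus[1]
  df <- p * (p - 1) / 2
  bart_p <- stats::pchisq(chisq, df, lower.tail = FALSE)

  structure(list(
    loadings = loadings, unrotated_loadings = load_un, rotmat = rotmat,
    scores = tibble::as_tibble(as.data.frame(scores)),
    eigenvalues = ev, variance_fractions = ev / p,
    retained_count = m, rotation = rotation,
    kmo = kmo, bartlett_chisq = as.numeric(chisq), bartlett_df = df,
    bartlett_p = bart_p,
    communalities = rowSums(loadings^2), vars = vars, n = n
  ), class = "pca_composites")
}

#' @export
print.pca_composites <- function(x, ...) {
  cat(sprintf(
    "<pca_composites> %d variables, %d retained component(s) (%s)\n",
    length(x$vars), x$retained_count, x$rotation))
  cat(sprintf("  first-%d variance fraction %.3f; KMO %.2f; Bartlett p %.3g\n",
              x$retained_count,
              sum(x$variance_fractions[seq_len(x$retained_count)]),
              x$kmo, x$bartlett_p))
  invisible(x)
}

#' Perceived-environment index from Likert items
#'
#' First principal component of the coded perception items (bike safety in
#' traffic, pollution, aesthetics/cleanliness), each on a 5-level
#' agreement scale. The score is sign-oriented so that higher values mean
#' a safer-perceived cycling environment: the anchor item's loading is
#' forced positive.
#'
#' @param items Data frame of numerically coded Likert items (columns in
#'   codebook order).
#' @param anchor Column whose loading is forced positive (default the
#'   first column, bike safety).
#' @return A `perception_index` object: list with `index` (numeric score
#'   per respondent), `loadings`, `variance_fraction`.
#' @export
perception_index <- function(items, anchor = NULL) {
  X <- as.matrix(as.data.frame(items))
  if (ncol(X) < 2) stop("need at least 2 items", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (nrow(unique(as.data.frame(X))) < 3) {
    stop("need at least 3 distinct response patterns", call. = FALSE)
  }
  anchor <- anchor %||% colnames(X)[1]
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  names(v1) <- colnames(X)
  if (v1[anchor] < 0) v1 <- -v1
  Z <- scale(X)
  structure(list(
    index = drop(Z %*% v1),
    loadings = v1 * sqrt(eig$values[1]),
    variance_fraction = eig$values[1] / ncol(X)
  ), class = "perception_index")
}

#' @export
print.perception_index <- function(x, ...) {
  cat(sprintf(
    "<perception_index> first PC explains %.1f%% of item variance\n",
    100 * x$variance_fraction))
  invisible(x)
}

#' Kernel density raster from point or line features
#'
#' Quartic (biweight) kernel density estimation on a regular grid: each
#' feature spreads its weight over a disc of radius `bandwidth`, and cell
#' values are densities in features (or weight units) per square
#' kilometre. Polylines are densified into points every `spacing` metres,
#' each carrying its represented segment length as weight, so a line
#' layer's total mass is its total length.
#'
#' @param features Either a tibble of points (`x_m`, `y_m`, optional
#'   `weight`) or a list of two-column polyline coordinate matrices (as
#'   from [read_geojson_lines()]).
#' @param grid A `raster_grid` giving the output extent (values ignored).
#' @param bandwidth Kernel support radius in metres (default 500).
#' @param spacing Densification step for polylines (default 10 m).
#' @return A `raster_grid` of densities per km^2.
#' @export
kde_raster <- function(features, grid, bandwidth = 500, spacing = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be positive", call. = FALSE)
  }
  if (is.list(features) && !is.data.frame(features)) {
    features <- densify_lines(features, spacing = spacing)
  }
  cc <- grid_centers(grid)
  dens <- numeric(nrow(cc))
  if (nrow(features) > 0) {
    w <- if ("weight" %in% names(features)) features$weight
         else rep(1, nrow(features))
    # quartic kernel integrating to 1 over the plane: 3/(pi b^2) (1-u^2)^2
    norm <- 3 / (pi * bandwidth^2)
    for (j in seq_len(nrow(features))) {
      dx <- cc$x_m - features$x_m[j]
      dy <- cc$y_m - features$y_m[j]
      d2 <- dx * dx + dy * dy
      inb <- d2 < bandwidth^2
      if (any(inb)) {
        u2 <- d2[inb] / bandwidth^2
        dens[inb] <- dens[inb] + w[j] * norm * (1 - u2)^2
      }
    }
  }
  out <- grid
  out$values <- matrix(dens * 1e6, grid$n_rows, grid$n_cols, byrow = TRUE)
  out
}

#' @rdname kde_raster
#' @param lines List of two-column polyline coordinate matrices.
#' @export
densify_lines <- function(lines, spacing = 10) {
  pts <- purrr::map_dfr(lines, function(m) {
    segs <- purrr::map_dfr(seq_len(nrow(m) - 1), function(i) {
      p0 <- m[i, ]; p1 <- m[i + 1, ]
      len <- sqrt(sum((p1 - p0)^2))
      if (len == 0) return(NULL)
      k <- max(1L, ceiling(len / spacing))
      tt <- (seq_len(k) - 0.5) / k
      tibble::tibble(x_m = p0[1] + tt * (p1[1] - p0[1]),
                     y_m = p0[2] + tt * (p1[2] - p0[2]),
                     weight = len / k)
    })
    segs
  })
  pts
}

#' Disaggregate zone attributes onto a regular grid
#'
#' Each grid cell takes the attribute value of the zone polygon containing
#' its centre (cell-centre rule). Intended for intensive attributes
#' (percentages, income, densities); convert counts to densities before
#' calling. Cells whose centre falls in no zone become nodata; a centre
#' claimed by more than one zone is an invalid (overlapping) zone layer.
#'
#' @param zones List of polygons as from [read_geojson_polygons()].
#' @param grid A `raster_grid` giving the extent.
#' @param attribute Name of the numeric property to transfer.
#' @return A `raster_grid`.
#' @export
disaggregate_to_grid <- function(zones, grid, attribute) {
  stopifnot(inherits(grid, "raster_grid"))
  cc <- grid_centers(grid)
  vals <- rep(NA_real_, nrow(cc))
  claimed <- rep(FALSE, nrow(cc))
  for (z in zones) {
    a <- z$properties[[attribute]]
    if (is.null(a)) stop("zone missing attribute `", attribute, "`",
                         call. = FALSE)
    inside <- points_in_polygon(cc$x_m, cc$y_m, z$rings)
    if (any(inside & claimed)) {
      stop("overlapping zones at ", sum(inside & claimed),
           " cell centre(s); invalid zone layer", call. = FALSE)
    }
    vals[inside] <- as.numeric(a)
    claimed <- claimed | inside
  }
  out <- grid
  out$values <- matrix(vals, grid$n_rows, grid$n_cols, byrow = TRUE)
  out
}

#' Mean raster value within a circular buffer
#'
#' Links a gridded exposure to residential locations: the arithmetic mean
#' of non-nodata cell values whose centres lie within `radius` of each
#' location (Euclidean buffer). Locations with no contributing cell get
#' `NA` and a zero cell count.
#'
#' @param grid A `raster_grid`.
#' @param points Tibble with `x_m`, `y_m`.
#' @param radius Buffer radius in metres (default 500).
#' @return Tibble with `value` and `n_cells`, one row per location.
#' @export
buffer_mean <- function(grid, points, radius = 500) {
  stopifnot(inherits(grid, "raster_grid"))
  if (!is.finite(radius) || radius <= 0) {
    stop("`radius` must be positive", call. = FALSE)
  }
  cc <- grid_centers(grid)
  keep <- is.finite(cc$value)
  purrr::map_dfr(seq_len(nrow(points)), function(i) {
    d2 <- (cc$x_m - points$x_m[i])^2 + (cc$y_m - points$y_m[i])^2
    sel <- keep & d2 <= radius^2
    tibble::tibble(
      value = if (any(sel)) mean(cc$value[sel]) else NA_real_,
      n_cells = sum(sel)
    )
  })
}

#' Distance to the nearest feature
#'
#' Minimum Euclidean distance from each location to a feature layer
#' (e.g. the nearest subway, bus or train station).
#'
#' @param points Tibble with `x_m`, `y_m` (locations).
#' @param features Tibble with `x_m`, `y_m` (stations etc.).
#' @return Numeric vector of metres.
#' @export
nearest_distance <- function(points, features) {
  if (nrow(features) == 0) stop("empty feature set", call. = FALSE)
  d <- pairwise_distances(points, features)
  apply(d, 1, min)
}
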