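#' Kernel specification for geographic weighting
#'
#' Describes the distance-decay weighting scheme used by every local
#' regression: the kernel family (Gaussian or bi-square) and whether its
#' bandwidth is fixed in metres or adapts to enclose a constant number of
#' neighbours.
#'
#' With an adaptive bi-square kernel the bandwidth at each regression point
#' is the distance to its `neighbor_count`-th nearest other point; because
#' the bi-square kernel has support `d < b` (strict), that N-th neighbour
#' itself receives weight zero, so `neighbor_count` counts the points that
#' can receive positive weight plus one.
#'
#' @param family `"bisquare"` (compact support) or `"gaussian"`.
#' @param mode `"adaptive"` (constant neighbour count) or `"fixed"`
#'   (constant metric bandwidth).
#' @param bandwidth_m Bandwidth in metres; required when `mode = "fixed"`.
#' @param neighbor_count Number of neighbours N; required when
#'   `mode = "adaptive"`. Must satisfy `2 <= N <= n` at fit time.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("bisquare", "adaptive", neighbor_count = 800)
#' kernel_spec("gaussian", "fixed", bandwidth_m = 2000)
#' @export
kernel_spec <- function(family = c("bisquare", "gaussian"),
                        mode = c("adaptive", "fixed"),
                        bandwidth_m = NULL, neighbor_count = NULL) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(bandwidth_m) || !is.null(neighbor_count)) {
      stop("fixed mode requires `bandwidth_m` and no `neighbor_count`",
           call. = FALSE)
    }
    if (!is.finite(bandwidth_m) || bandwidth_m <= 0) {
      stop("`bandwidth_m` must be a positive finite number", call. = FALSE)
    }
  } else {
    if (is.null(neighbor_count) || !is.null(bandwidth_m)) {
      stop("adaptive mode requires `neighbor_count` and no `bandwidth_m`",
           call. = FALSE)
    }
    neighbor_count <- as.integer(neighbor_count)
    if (neighbor_count < 2) {
      stop("`neighbor_count` must be at least 2", call. = FALSE)
    }
  }
  structure(
    list(family = family, mode = mode, bandwidth_m = bandwidth_m,
         neighbor_count = neighbor_count),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  bw <- if (x$mode == "fixed") {
    sprintf("bandwidth %.0f m", x$bandwidth_m)
  } else {
    sprintf("N = %d neighbors", x$neighbor_count)
  }
  cat(sprintf("<kernel_spec> %s, %s (%s)\n", x$family, x$mode, bw))
  invisible(x)
}

check_planar <- function(x, y, what = "points") {
  if (length(x) != length(y)) {
    stop("x and y coordinate vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 1L) stop(what, " must be non-empty", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite coordinates in ", what,
         "; coordinates must be planar metres", call. = FALSE)
  }
  invisible(TRUE)
}

# Warn-level guard used by pipeline entry points: coordinates that all look
# like lon/lat degrees are almost certainly unprojected.
looks_like_degrees <- function(x, y) {
  all(abs(x) <= 180) && all(abs(y) <= 90)
}

#' Pairwise Euclidean distances between planar point sets
#'
#' @param a,b Data frames with numeric columns `x_m`, `y_m` (projected
#'   metres). `b` defaults to `a`.
#' @return A numeric `nrow(a)` x `nrow(b)` matrix of distances in metres.
#' @examples
#' pts <- tibble::tibble(x_m = c(0, 3), y_m = c(0, 4))
#' pairwise_distances(pts)
#' @export
pairwise_distances <- function(a, b = a) {
  ax <- as.numeric(a$x_m); ay <- as.numeric(a$y_m)
  bx <- as.numeric(b$x_m); by <- as.numeric(b$y_m)
  check_planar(ax, ay, "point set `a`")
  check_planar(bx, by, "point set `b`")
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  sqrt(dx * dx + dy * dy)
}

#' Adaptive bandwidths: distance to the N-th nearest neighbour
#'
#' For each point, returns the distance to its N-th nearest *other* point
#' (the point itself is excluded; rank 1 is the nearest neighbour). This is
#' the per-location bandwidth of an adaptive kernel with a constant
#' neighbour count, which widens where respondents are sparse (region
#' boundaries) and narrows in the dense core.
#'
#' @param points Data frame with columns `x_m`, `y_m`.
#' @param neighbor_count N, with `2 <= N <= nrow(points)`. (`N = 1`,
#'   nearest-neighbour distance, is also accepted for diagnostics.)
#' @param dist_matrix Optional precomputed square distance matrix.
#' @return Numeric vector of per-location bandwidths (metres).
#' @examples
#' pts <- tibble::tibble(x_m = c(0, 10, 30), y_m = 0)
#' adaptive_bandwidths(pts, neighbor_count = 2)
#' @export
adaptive_bandwidths <- function(points, neighbor_count, dist_matrix = NULL) {
  n <- nrow(points)
  neighbor_count <- as.integer(neighbor_count)
  if (neighbor_count < 1L || neighbor_count > n - 1L) {
    stop(sprintf(
      "`neighbor_count` = %d out of range: need 1 <= N <= n - 1 = %d",
      neighbor_count, n - 1L), call. = FALSE)
  }
  d <- dist_matrix %||% pairwise_distances(points)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    # partial sort: stable for ties because sort() on doubles is
    sort(di, partial = neighbor_count)[neighbor_count]
  }, numeric(1))
}

#' Kernel weights from distances
#'
#' Bi-square: `w = (1 - (d/b)^2)^2` for `d < b`, else 0 (compact support).
#' Gaussian: `w = exp(-0.5 (d/b)^2)`. Both give weight 1 at distance 0 and
#' are non-increasing in distance.
#'
#' @param distances Non-negative distances in metres.
#' @param bandwidth Positive bandwidth in metres.
#' @param family `"bisquare"` or `"gaussian"`.
#' @return Weights in `[0, 1]`, same length as `distances`.
#' @examples
#' kernel_weights(c(0, 500, 1000, 1500), bandwidth = 1000, family = "bisquare")
#' @export
kernel_weights <- function(distances, bandwidth,
                           family = c("bisquare", "gaussian")) {
  family <- match.arg(family)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be positive", call. = FALSE)
  }
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  u <- distances / bandwidth
  if (family == "bisquare") {
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
  } else {
    w <- exp(-0.5 * u^2)
  }
  as.numeric(w)
}

# n x n geographic weight matrix, row i = weights used by the local
# regression at location i. Rows carry w_ii = 1 by construction (d = 0).
gw_weight_matrix <- function(points, spec, dist_matrix = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  d <- dist_matrix %||% pairwise_distances(points)
  n <- nrow(d)
  if (spec$mode == "fixed") {
    bw <- rep(spec$bandwidth_m, n)
  } else {
    if (spec$neighbor_count > n - 1L) {
      stop(sprintf("`neighbor_count` = %d exceeds n - 1 = %d",
                   spec$neighbor_count, n - 1L), call. = FALSE)
    }
    bw <- adaptive_bandwidths(points, spec$neighbor_count, dist_matrix = d)
  }
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w[i, ] <- kernel_weights(d[i, ], bw[i], spec$family)
  }
  list(weights = w, bandwidths = bw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
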