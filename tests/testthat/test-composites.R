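test_that("uncorrelated variables give unit eigenvalues and identity-like loadings", {
  set.seed(42)
  d <- tibble::tibble(a = rnorm(2000), b = rnorm(2000))
  pc <- pca_composites(d, kaiser = FALSE, rotation = "none")
  expect_equal(pc$eigenvalues, c(1, 1), tolerance = 0.1)
  # loadings approximately identity up to sign/permutation
  L <- abs(pc$unrotated_loadings)
  expect_true(all(apply(L, 1, max) > 0.65))
  expect_lt(abs(det(L)) - 1, 0.3)
})

test_that("the synthetic 15-variable block yields two strong components", {
  coh <- simulate_cohort(scenario_config(n = 600, seed = 31))
  pc <- pca_composites(coh$participants, vars = env_loading_names())
  expect_equal(pc$retained_count, 2)
  expect_gt(sum(pc$variance_fractions[1:2]), 0.6)
  # varimax preserves communalities
  expect_equal(rowSums(pc$loadings^2), rowSums(pc$unrotated_loadings^2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # retained scores are orthogonal before rotation
  expect_lt(abs(cor(pc$scores$pc1, pc$scores$pc2)), 1e-10)
  # diagnostics live on their documented scales
  expect_true(pc$kmo >= 0 && pc$kmo <= 1)
  expect_true(pc$bartlett_p >= 0 && pc$bartlett_p <= 1)
})

test_that("pca_composites rejects degenerate inputs", {
  d <- tibble::tibble(a = rnorm(50), b = rep(1, 50))
  expect_error(pca_composites(d), "constant.*b")
  wide <- tibble::as_tibble(as.data.frame(matrix(rnorm(5 * 10), 5, 10)))
  expect_error(pca_composites(wide), "more observations")
})

test_that("perception index is anchored on bike safety and sign-invariant", {
  coh <- simulate_cohort(scenario_config(n = 800, seed = 13))
  items <- coh$participants[, c("bike_safety", "pollution", "aesthetics")]
  pi1 <- perception_index(items)
  expect_gt(pi1$variance_fraction, 0.4)
  expect_lt(pi1$variance_fraction, 0.9)
  expect_gt(pi1$loadings["bike_safety"], 0)
  expect_gt(pi1$loadings["pollution"], 0)
  expect_lt(pi1$loadings["aesthetics"], 0)
  # reversing one item's coding flips its loading, not the index
  rev_items <- items
  rev_items$pollution <- 6L - rev_items$pollution
  pi2 <- perception_index(rev_items)
  expect_lt(pi2$loadings["pollution"], 0)
  expect_equal(pi2$index, pi1$index, tolerance = 1e-10)
})

test_that("perception index rejects degenerate responses", {
  same <- tibble::tibble(a = rep(3L, 20), b = rep(2L, 20), c = rep(4L, 20))
  expect_error(perception_index(same), "zero-variance")
})

test_that("quartic KDE has compact support, conserves mass, and is linear", {
  g <- empty_grid(0, 0, 2000, 2000, cell_size = 50)
  one <- tibble::tibble(x_m = 1000, y_m = 1000)
  k1 <- kde_raster(one, g, bandwidth = 400)
  cc <- grid_centers(k1)
  far <- sqrt((cc$x_m - 1000)^2 + (cc$y_m - 1000)^2) > 400
  expect_true(all(cc$value[far] == 0))
  expect_true(all(cc$value >= 0))
  # mass conservation: density [km^-2] x cell area [km^2] sums to 1
  mass <- sum(cc$value) * (50 / 1000)^2
  expect_equal(mass, 1, tolerance = 0.02)
  # two coincident points double the surface exactly
  two <- dplyr::bind_rows(one, one)
  k2 <- kde_raster(two, g, bandwidth = 400)
  expect_equal(k2$values, 2 * k1$values)
  # empty feature set -> all-zero raster
  k0 <- kde_raster(tibble::tibble(x_m = numeric(), y_m = numeric()), g, 400)
  expect_true(all(k0$values == 0))
})

test_that("polyline densification preserves total length as weight", {
  line <- list(cbind(x_m = c(0, 300, 300), y_m = c(0, 0, 400)))
  pts <- densify_lines(line, spacing = 10)
  expect_equal(sum(pts$weight), 700)
  expect_equal(nrow(pts), 70)
})

test_that("zone attributes disaggregate by the cell-centre rule", {
  g <- empty_grid(0, 0, 2000, 1000, cell_size = 200)
  sq <- function(x0, x1, y0, y1, val) {
    list(rings = list(cbind(x_m = c(x0, x1, x1, x0, x0),
                            y_m = c(y0, y0, y1, y1, y0))),
         properties = list(v = val))
  }
  all7 <- disaggregate_to_grid(list(sq(-10, 2010, -10, 1010, 7)), g, "v")
  expect_true(all(all7$values == 7))
  # two half-planes split at x = 1000: no mixing
  two <- disaggregate_to_grid(list(sq(-10, 1000, -10, 1010, 1),
                                   sq(1000, 2010, -10, 1010, 2)), g, "v")
  cc <- grid_centers(two)
  expect_true(all(cc$value[cc$x_m < 1000] == 1))
  expect_true(all(cc$value[cc$x_m > 1000] == 2))
  # partial coverage: uncovered centres become nodata
  part <- disaggregate_to_grid(list(sq(-10, 1000, -10, 1010, 1)), g, "v")
  expect_equal(sum(!is.finite(part$values)), sum(cc$x_m > 1000))
  # overlapping zones are an invalid layer
  expect_error(
    disaggregate_to_grid(list(sq(-10, 1200, -10, 1010, 1),
                              sq(800, 2010, -10, 1010, 2)), g, "v"),
    "overlap")
})

test_that("buffer means average cell centres inside the radius", {
  g <- raster_grid(matrix(5, 4, 4), x0 = 0, y0 = 0, cell_size = 200)
  anywhere <- tibble::tibble(x_m = c(150, 700), y_m = c(500, 100))
  bm <- buffer_mean(g, anywhere, radius = 500)
  expect_true(all(bm$value == 5))
  # radius 100 centred on one 200-m cell touches exactly that cell
  g2 <- raster_grid(matrix(1:16, 4, 4, byrow = TRUE), 0, 0, 200)
  ctr <- tibble::tibble(x_m = 300, y_m = 700)  # centre of row 1, col 2
  b1 <- buffer_mean(g2, ctr, radius = 100)
  expect_equal(b1$n_cells, 1L)
  expect_equal(b1$value, 2)
  # two symmetric cells valued 0 and 10 average to 5
  g3 <- raster_grid(matrix(c(0, 10), 1, 2), 0, 0, 200)
  mid <- tibble::tibble(x_m = 200, y_m = 100)
  b2 <- buffer_mean(g3, mid, radius = 150)
  expect_equal(b2$value, 5)
  expect_equal(b2$n_cells, 2L)
  # nodata outside the buffer does not leak in
  g4 <- g2
  g4$values[4, 4] <- NA
  expect_equal(buffer_mean(g4, ctr, radius = 100)$value, 2)
  # empty buffer is flagged, not an error
  b0 <- buffer_mean(g2, tibble::tibble(x_m = 1e6, y_m = 1e6), radius = 100)
  expect_true(is.na(b0$value))
  expect_equal(b0$n_cells, 0L)
})

test_that("nearest-feature distances match a brute-force scan", {
  origin <- tibble::tibble(x_m = 0, y_m = 0)
  expect_equal(nearest_distance(origin, tibble::tibble(x_m = 3, y_m = 4)), 5)
  expect_equal(nearest_distance(origin, origin), 0)
  pts <- rand_points(20, seed = 2)
  feats <- rand_points(100, seed = 3)
  got <- nearest_distance(pts, feats)
  ref <- sapply(seq_len(20), function(i) {
    min(sqrt((feats$x_m - pts$x_m[i])^2 + (feats$y_m - pts$y_m[i])^2))
  })
  expect_equal(got, ref)
  expect_error(nearest_distance(pts, tibble::tibble(x_m = numeric(),
                                                    y_m = numeric())),
               "empty")
})
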