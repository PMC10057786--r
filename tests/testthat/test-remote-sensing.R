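test_that("NBR follows its defining ratio and bounds", {
  expect_equal(nbr(0.3, 0.3), 0)
  expect_equal(nbr(0.4, 0), 1)
  expect_equal(nbr(0.5, 0.1), 0.6667, tolerance = 1e-4)
  expect_true(is.na(nbr(0, 0)))
  expect_error(nbr(-0.1, 0.2), ">= 0")
  # antisymmetry and range over random band pairs
  set.seed(1)
  a <- runif(200); b <- runif(200)
  expect_equal(nbr(a, b), -nbr(b, a))
  expect_true(all(abs(nbr(a, b)) <= 1, na.rm = TRUE))
})

test_that("stack statistics match a brute-force per-pixel loop", {
  set.seed(11)
  layers <- lapply(1:5, function(i) matrix(runif(30, -0.5, 0.9), 5, 6))
  layers[[2]][1, 1] <- NA  # one nodata year at one pixel
  layers[[3]][2, 2] <- NA
  st <- stack_from_nbr(layers)
  pr <- stack_stats(st)
  oracle <- brute_stack_stats(pr$nbr)
  expect_equal(pr$nbr_mean, oracle$mean, tolerance = 1e-12)
  expect_equal(pr$nbr_sd, oracle$sd, tolerance = 1e-12)
  expect_equal(pr$n_valid[1, 1], 4)
})

test_that("stack statistics handle constant and two-point series", {
  const <- stack_from_nbr(lapply(1:3, function(i) matrix(0.4, 2, 2)))
  pr <- stack_stats(const)
  expect_true(all(pr$nbr_sd == 0))
  two <- stack_from_nbr(list(matrix(0.2, 2, 2), matrix(0.4, 2, 2)))
  pr2 <- stack_stats(two)
  expect_equal(pr2$nbr_mean[1, 1], 0.3)
  expect_equal(pr2$nbr_sd[1, 1], sd(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(round(pr2$nbr_sd[1, 1], 4), 0.1414)
  one <- stack_from_nbr(list(matrix(0.2, 2, 2)))
  expect_error(stack_stats(one), "two years")
})

test_that("pixels with fewer than two valid years get nodata sd", {
  layers <- list(matrix(0.2, 2, 2), matrix(0.4, 2, 2), matrix(0.3, 2, 2))
  layers[[1]][1, 1] <- NA; layers[[2]][1, 1] <- NA
  pr <- stack_stats(stack_from_nbr(layers))
  expect_true(is.na(pr$nbr_sd[1, 1]))
  expect_equal(pr$nbr_mean[1, 1], 0.3)
})

test_that("site extraction picks the nearest pixel", {
  m <- matrix(as.numeric(outer(1:4, 1:5, function(i, j) (i + j) %% 2)), 4, 5)
  pr <- list(nbr_mean = m, xmin = 0, ymax = 120, res_m = 30)
  centre <- tibble::tibble(site_id = "a", x = 45, y = 105)  # cell (1,2)
  expect_equal(extract_at_sites(pr, centre, "nbr_mean")$nbr_mean, m[1, 2])
  # nudged 0.4 pixel in each direction stays in the same (nearest) cell
  for (dx in c(-12, 12)) for (dy in c(-12, 12)) {
    s <- tibble::tibble(site_id = "a", x = 45 + dx, y = 105 + dy)
    expect_equal(extract_at_sites(pr, s, "nbr_mean")$nbr_mean, m[1, 2])
  }
  const <- list(nbr_mean = matrix(7, 4, 5), xmin = 0, ymax = 120, res_m = 30)
  many <- tibble::tibble(site_id = c("a", "b"), x = c(10, 100), y = c(10, 110))
  expect_equal(extract_at_sites(const, many, "nbr_mean")$nbr_mean, c(7, 7))
  out <- tibble::tibble(site_id = "far", x = 1e5, y = 10)
  expect_error(extract_at_sites(pr, out, "nbr_mean"), "far")
})

test_that("distance to polylines matches geometry and a dense-sampling oracle", {
  seg <- rbind(c(0, 0), c(10, 0))
  expect_equal(distance_to_line(c(5, 0), seg), 0)
  expect_equal(distance_to_line(c(3, 4), seg), 4)
  expect_equal(distance_to_line(c(-2, 3), seg), sqrt(13), tolerance = 1e-12)
  set.seed(5)
  lines <- list(cbind(runif(5, 0, 100), runif(5, 0, 100)),
                cbind(runif(3, 0, 100), runif(3, 0, 100)))
  pts <- tibble::tibble(x = runif(10, -20, 120), y = runif(10, -20, 120))
  d <- distance_to_line(pts, lines)
  for (i in seq_len(nrow(pts))) {
    expect_equal(d[i], brute_line_distance(pts$x[i], pts$y[i], lines),
                 tolerance = 1e-6)
  }
})

test_that("geographic-degree polylines are rejected for distances", {
  lines <- list(rbind(c(101.3, 3.5), c(101.4, 3.6)))
  attr(lines, "crs_units") <- "deg"
  expect_error(distance_to_line(c(101.35, 3.55), lines), "project")
})

test_that("ASCII grids and GeoJSON lines round-trip", {
  m <- matrix(c(0.1, NA, -0.25, 3), 2, 2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, xmin = 10, ymin = 20, res_m = 30)
  g <- read_ascii_grid(path)
  expect_equal(g$m, m, tolerance = 1e-9)
  expect_equal(g$xmin, 10); expect_equal(g$res_m, 30)

  lines <- list(rbind(c(0, 0), c(100, 50), c(200, 30)),
                rbind(c(5, 5), c(5, 80)))
  attr(lines, "crs_units") <- "m"
  jp <- withr::local_tempfile(fileext = ".geojson")
  write_geojson_lines(lines, jp)
  got <- read_geojson_lines(jp)
  expect_equal(length(got), 2)
  expect_equal(got[[1]], lines[[1]])
  expect_equal(attr(got, "crs_units"), "m")
})

test_that("Shapiro-Wilk screening is calibrated on Gaussian series and powered on skewed ones", {
  # Gaussian pixel series: rejection fraction near the nominal 0.05
  set.seed(2)
  gauss <- lapply(1:50, function(i) matrix(rnorm(400, 0.4, 0.1), 20, 20))
  gauss <- lapply(gauss, function(m) clamp_nbr <- pmin(pmax(m, -0.95), 0.95))
  res_g <- normality_check(stack_from_nbr(gauss), sample_size = 400, seed = 9)
  expect_gt(nrow(res_g), 300)
  expect_lt(attr(res_g, "frac_rejected"), 0.12)

  # heavily skewed (exponential) series: most tests reject
  skew <- lapply(1:50, function(i) matrix(pmin(rexp(400, 8), 0.9), 20, 20))
  res_s <- normality_check(stack_from_nbr(skew), sample_size = 400, seed = 9)
  expect_gt(attr(res_s, "frac_rejected"), 0.5)
})

test_that("constant pixel series are flagged as undefined", {
  layers <- lapply(1:5, function(i) matrix(0.4, 3, 3))
  res <- normality_check(stack_from_nbr(layers), sample_size = 5, seed = 1)
  expect_true(all(res$undefined))
  expect_true(all(is.na(res$p_value)))
})
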