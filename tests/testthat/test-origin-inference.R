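test_that("haversine distance behaves like a metric on the sphere", {
  expect_equal(geodesic_distance(0, 0, 0, 90), pi / 2 * 6371.0088,
               tolerance = 1e-9)
  expect_identical(geodesic_distance(-23.5, 125, -23.5, 125), 0)
  expect_equal(geodesic_distance(-20, 120, -25, 130),
               geodesic_distance(-25, 130, -20, 120))
  set.seed(17)
  lat <- stats::runif(3000, -90, 90)
  lon <- stats::runif(3000, -180, 180)
  i <- 1:1000; j <- 1001:2000; k <- 2001:3000
  dij <- geodesic_distance(lat[i], lon[i], lat[j], lon[j])
  djk <- geodesic_distance(lat[j], lon[j], lat[k], lon[k])
  dik <- geodesic_distance(lat[i], lon[i], lat[k], lon[k])
  expect_true(all(dik <= dij + djk + 1e-8))
  expect_error(geodesic_distance(95, 0, 0, 0), "latitude")
})

test_that("make_grid pads the population bounding box", {
  info <- as_sample_info(data.frame(
    sample_id = c("a1", "b1"), population_id = c("a", "b"),
    latitude = c(-30, -20), longitude = c(120, 140),
    ploidy = "diploid", role = "ingroup", stringsAsFactors = FALSE))
  g <- make_grid(info, spacing_deg = 1, padding_fraction = 0.5)
  # bbox spans 10 x 20 degrees; padded box 20 x 40, centred on the original
  expect_equal(range(g$lats), c(-35, -15))
  expect_equal(range(g$lons), c(110, 150))
  g0 <- make_grid(info, spacing_deg = 1, padding_fraction = 0)
  expect_equal(range(g0$lats), c(-30, -20))
  expect_equal(range(g0$lons), c(120, 140))
  # spacing larger than the span: single row/column, no crash
  g1 <- make_grid(info, spacing_deg = 60, padding_fraction = 0)
  expect_equal(nrow(g1$grid), 1L)
  same <- info; same$latitude <- -25; same$longitude <- 130
  expect_error(make_grid(as_sample_info(same), 1, 0.5), "degenerate")
})

test_that("tdoa_fit_at matches closed-form least squares through the origin", {
  info <- line_info(3)
  psi <- plant_linear_psi(info, origin = c(-24, 119), slope = 2e-4)
  # perturb to a generic 3-pair configuration and verify against the
  # closed form slope = sum(psi * dd) / sum(dd^2) computed by hand here
  psi$psi["p01", "p02"] <- 0.10; psi$psi["p02", "p01"] <- -0.10
  psi$psi["p01", "p03"] <- 0.25; psi$psi["p03", "p01"] <- -0.25
  psi$psi["p02", "p03"] <- 0.05; psi$psi["p03", "p02"] <- -0.05
  origin <- c(-24, 119)
  d <- geodesic_distance(origin[1], origin[2], rep(-24, 3),
                         120 + 0.5 * (0:2))
  dd <- c(d[2] - d[1], d[3] - d[1], d[3] - d[2])
  y <- c(0.10, 0.25, 0.05)
  slope_hand <- sum(y * dd) / sum(dd^2)
  rss_hand <- sum((y - slope_hand * dd)^2)
  fit <- tdoa_fit_at(origin[1], origin[2], psi, info)
  expect_equal(fit$slope, slope_hand, tolerance = 1e-12)
  expect_equal(fit$rss, rss_hand, tolerance = 1e-12)
  expect_equal(fit$r2, 1 - rss_hand / sum(y^2), tolerance = 1e-12)
})

test_that("planted linear psi gives a perfect fit at the true origin", {
  info <- line_info(6)
  origin <- c(-24, 120)  # at population p01
  psi <- plant_linear_psi(info, origin, slope = 1e-3)
  fit <- tdoa_fit_at(origin[1], origin[2], psi, info)
  expect_equal(fit$slope, 1e-3, tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  # all-zero psi: flat surface
  psi0 <- plant_linear_psi(info, origin, slope = 0)
  fit0 <- tdoa_fit_at(-23, 121, psi0, info)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$rss, 0)
})

test_that("an equidistant origin is recorded as worst fit", {
  # two mirror populations at the same latitude: any cell on the midpoint
  # meridian is exactly equidistant, so the fit there is undefined and the
  # cell carries infinite RSS in the scanned surface
  info <- as_sample_info(data.frame(
    sample_id = c("a1", "b1"), population_id = c("a", "b"),
    latitude = c(-24, -24), longitude = c(120, 130),
    ploidy = "diploid", role = "ingroup", stringsAsFactors = FALSE))
  psi <- plant_linear_psi(info, c(-24, 121), slope = 1e-4)
  grid <- make_grid(info, spacing_deg = 1, padding_fraction = 0)
  surf <- suppressMessages(origin_scan(psi, info, grid))
  mid <- surf$grid[surf$grid$lon == 125, ]
  expect_true(all(is.infinite(mid$rss)))
  expect_true(all(is.na(mid$slope)))
  expect_true(all(is.finite(surf$grid$rss[surf$grid$lon != 125])))
  # tdoa_fit_at itself refuses under-determined problems
  expect_error(tdoa_fit_at(-24, 125, psi, info), ">=3 defined psi pairs")
})

test_that("origin_scan recovers a planted origin inside the grid", {
  info <- as_sample_info(data.frame(
    sample_id = sprintf("p%02d_s1", 1:10),
    population_id = sprintf("p%02d", 1:10),
    latitude = rep(c(-26, -24.5, -23, -21.5, -20), 2),
    longitude = rep(c(121, 124), each = 5),
    ploidy = "diploid", role = "ingroup", stringsAsFactors = FALSE))
  grid <- make_grid(info, spacing_deg = 0.5, padding_fraction = 0.5)
  # plant the origin exactly on a grid node
  origin <- c(grid$lats[3], grid$lons[4])
  psi <- plant_linear_psi(info, origin, slope = 5e-4)
  surf <- origin_scan(psi, info, grid)
  expect_equal(surf$best$lat, origin[1])
  expect_equal(surf$best$lon, origin[2])
  expect_equal(surf$best$rss, 0, tolerance = 1e-12)
  expect_equal(surf$best$slope, 5e-4, tolerance = 1e-10)
  expect_false(surf$boundary)
  # exhaustive-scan oracle: best cell attains the minimum RSS on the grid
  expect_equal(min(surf$grid$rss), surf$best$rss)

  # planted origin far outside the padded box raises the boundary flag
  psi_out <- plant_linear_psi(info, c(-24, 100), slope = 5e-4)
  surf_out <- suppressMessages(origin_scan(psi_out, info, grid))
  expect_true(surf_out$boundary)

  # mirror-symmetric two-population case with zero psi: tie, flagged
  info2 <- as_sample_info(data.frame(
    sample_id = c("a1", "b1"), population_id = c("a", "b"),
    latitude = c(-24, -24), longitude = c(120, 130),
    ploidy = "diploid", role = "ingroup", stringsAsFactors = FALSE))
  psi2 <- plant_linear_psi(info2, c(-24, 125), slope = 0)
  surf2 <- suppressMessages(origin_scan(psi2, info2,
                                        make_grid(info2, 1, 0.2)))
  expect_true(surf2$tie)
})

test_that("expansion-vs-IBD permutation test calibrates sensibly", {
  info <- as_sample_info(data.frame(
    sample_id = sprintf("p%02d_s1", 1:10),
    population_id = sprintf("p%02d", 1:10),
    latitude = rep(c(-26, -24.5, -23, -21.5, -20), 2),
    longitude = rep(c(121, 124), each = 5),
    ploidy = "diploid", role = "ingroup", stringsAsFactors = FALSE))
  grid <- make_grid(info, spacing_deg = 1, padding_fraction = 0.5)
  psi <- plant_linear_psi(info, c(-23, 122), slope = 5e-4)
  t1 <- test_expansion_vs_ibd(psi, info, grid, n_perm = 999, seed = 2)
  expect_lte(t1$pvalue, 0.01)
  # all-zero psi: no signal
  psi0 <- plant_linear_psi(info, c(-23, 122), slope = 0)
  t0 <- test_expansion_vs_ibd(psi0, info, grid, n_perm = 199, seed = 2)
  expect_gte(t0$pvalue, 0.99)
  # determinism and invariance to population relabelling
  t1b <- test_expansion_vs_ibd(psi, info, grid, n_perm = 999, seed = 2)
  expect_identical(t1$pvalue, t1b$pvalue)
  perm <- rev(seq_len(10))
  psi_p <- psi
  psi_p$populations <- psi$populations[perm]
  psi_p$psi <- psi$psi[perm, perm]
  psi_p$se <- psi$se[perm, perm]
  psi_p$n_informative <- psi$n_informative[perm, perm]
  t1c <- test_expansion_vs_ibd(psi_p, info, grid, n_perm = 999, seed = 2)
  expect_identical(t1$pvalue, t1c$pvalue)
  # underpowered warning below 4 populations
  info3 <- info[1:3, ]
  psi3 <- plant_linear_psi(as_sample_info(as.data.frame(info3)),
                           c(-23, 122), 5e-4)
  expect_warning(test_expansion_vs_ibd(psi3, info3,
                                       make_grid(info3, 1, 0.5),
                                       n_perm = 99, seed = 1),
                 "underpowered")
})
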