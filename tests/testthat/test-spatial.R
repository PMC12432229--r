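test_that("hex grid: tessellation coverage, disjoint interiors, 6 neighbours", {
  g <- make_hex_grid(c(0, 50000, 0, 40000), 10000)
  # interior cells have exactly 6 neighbours
  interior <- which(g$cells$cx > 10000 & g$cells$cx < 40000 &
                      g$cells$cy > 10000 & g$cells$cy < 30000)
  expect_true(all(lengths(g$nb)[interior] == 6L))
  # coverage: random points all land in exactly the cell found by hex_locate,
  # and that cell's polygon contains them
  set.seed(3)
  px <- runif(300, 0, 50000); py <- runif(300, 0, 40000)
  ids <- hex_locate(g, px, py)
  expect_false(anyNA(ids))
  inside <- vapply(seq_along(px), function(i)
    point_in_polygon(px[i], py[i], g$polys[[ids[i]]]), TRUE)
  expect_true(all(inside))
  # disjoint interiors: each point belongs to exactly one hexagon
  n_holding <- vapply(seq_along(px), function(i)
    sum(vapply(g$polys, function(pp) point_in_polygon(px[i], py[i], pp), TRUE)), 0L)
  expect_true(all(n_holding == 1L))
  # hexagon area equals sqrt(3)/2 * s^2 (incircle-diameter convention)
  expect_equal(polygon_area(list(g$polys[[1]])), sqrt(3) / 2 * 10000^2,
               tolerance = 1e-6)
  # degenerate small extent still yields a covering cell
  g1 <- make_hex_grid(c(0, 2000, 0, 2000), 10000)
  expect_gte(nrow(g1$cells), 1L)
  expect_false(anyNA(hex_locate(g1, c(10, 1990), c(10, 1990))))
})

test_that("grid aggregation conserves area and assigns counts by centroid", {
  g <- make_hex_grid(c(0, 30000, 0, 20000), 10000)
  # empty input
  g0 <- aggregate_to_grid(data.frame(x = numeric(0), y = numeric(0),
                                     area_m2 = numeric(0)), g)
  expect_true(all(g0$stats$wood_area_m2 == 0))
  # single deposit wholly inside one cell
  cid <- hex_locate(g, 15000, 10000)
  g1 <- aggregate_to_grid(data.frame(x = 15000, y = 10000, area_m2 = 900), g)
  expect_equal(g1$stats$wood_area_m2[cid], 900)
  expect_equal(g1$stats$deposit_count[cid], 1L)
  expect_equal(sum(g1$stats$wood_area_m2), 900)
  # pixel-backed deposit straddling two cells: area split, count by centroid
  tpl <- mb_raster(matrix(0, 40, 400), xmin = 9000, ymax = 10100, pixel_size = 50)
  m <- matrix(FALSE, 40, 400); m[10:12, 100:140] <- TRUE
  dep <- vectorize_and_measure(m, tpl)
  g2 <- aggregate_to_grid(dep, g)
  expect_equal(sum(g2$stats$wood_area_m2), sum(dep$table$area_m2), tolerance = 1e-9)
  expect_equal(sum(g2$stats$deposit_count), 1L)
})

test_that("global Moran's I matches the checkerboard oracle and the null expectation", {
  nb <- list(c(2, 3), c(1, 4), c(1, 4), c(2, 3))  # 2x2 rook
  r <- global_morans_i(c(1, 0, 0, 1), nb, n_permutations = 99, seed = 1)
  expect_equal(r$statistic, -1)
  expect_error(global_morans_i(c(2, 2, 2, 2), nb), "constant")
  # permutation null mean ~ -1/(n-1) on a bigger random field
  g <- make_hex_grid(c(0, 60000, 0, 60000), 10000)
  set.seed(7)
  vals <- rnorm(nrow(g$cells))
  rr <- global_morans_i(vals, g$nb, n_permutations = 999, seed = 2)
  se <- rr$details$null_sd / sqrt(999)
  expect_lt(abs(rr$details$null_mean - rr$details$expectation), 3 * se)
})

test_that("local Moran's I: signs, quadrants and cluster limit behaviour", {
  nb <- list(c(2, 3), c(1, 4), c(1, 4), c(2, 3))
  lisa <- local_morans_i(c(1, 0, 0, 1), nb, n_permutations = 99, seed = 1)
  expect_true(all(lisa$local$I_i < 0))
  expect_false(any(lisa$local$quadrant == "high_high"))
  # one extreme cell with high neighbours on a hex grid
  g <- make_hex_grid(c(0, 60000, 0, 60000), 10000)
  vals <- rep(0, nrow(g$cells))
  centre <- which.min((g$cells$cx - 30000)^2 + (g$cells$cy - 30000)^2)
  vals[centre] <- 5
  vals[g$nb[[centre]]] <- 4
  vals <- vals + seq_along(vals) * 1e-3   # break exact ties
  lisa2 <- local_morans_i(vals, g$nb, n_permutations = 999, alpha = 0.05, seed = 3)
  expect_equal(lisa2$local$quadrant[centre], "high_high")
  # alpha = 1 degenerates: every high-high cell joins a cluster
  lisa3 <- local_morans_i(vals, g$nb, n_permutations = 99, alpha = 1, seed = 3)
  hh <- which(lisa3$local$quadrant == "high_high")
  expect_setequal(unlist(lisa3$clusters), hh)
})

test_that("local I relates to global I for row-standardised weights", {
  g <- make_hex_grid(c(0, 50000, 0, 50000), 10000)
  set.seed(11)
  vals <- rnorm(nrow(g$cells)) + g$cells$cx / 50000
  lisa <- local_morans_i(vals, g$nb, n_permutations = 9, seed = 1)
  glob <- global_morans_i(vals, g$nb, n_permutations = 9, seed = 1)
  n <- length(vals)
  # sum_i I_i / n equals global I up to the (n vs n-1) variance convention
  expect_equal(sum(lisa$local$I_i) / n * n / (n - 1), glob$statistic,
               tolerance = 1e-8)
})

test_that("Mann-Whitney U: derived examples and brute-force agreement", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)            # 2 of C(6,3)=20 arrangements
  r2 <- mann_whitney_u(1, 2)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  r3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$statistic, 9 / 2)       # n*m/2 under midranks
  # property: exact p equals enumeration for all n, m <= 7 (tie-free draws)
  set.seed(12)
  for (k in 1:12) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    v <- sample(1000, n + m)              # distinct values
    a <- v[seq_len(n)]; b <- v[-seq_len(n)]
    expect_equal(mann_whitney_u(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # with ties the midrank U stays consistent with the normal approximation
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  expect_equal(mann_whitney_u(a, b, mode = "exact")$details$U_a,
               mann_whitney_u(a, b, mode = "normal")$details$U_a)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Spearman's rho: hand triples, reversal, exactness and guards", {
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2))$statistic, 0.5)
  expect_equal(spearman_rho(1:6, (1:6)^3)$statistic, 1)
  expect_equal(spearman_rho(1:5, 5:1)$statistic, -1)
  # exact p agrees with cor.test for small tie-free samples
  set.seed(13)
  for (k in 1:8) {
    x <- sample(100, 7); y <- sample(100, 7)
    expect_equal(spearman_rho(x, y)$p_value,
                 stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "variance")
})

test_that("catchment assignment: forested kept, non-forested move along the coast", {
  catch <- data.frame(id = 1:3, x_min = c(0, 1000, 2000), x_max = c(1000, 2000, 3000),
                      forest_fraction = c(0.8, 0, 0.5),
                      outlet_s = c(500, 1400, 2500))
  dep <- data.frame(x = c(200, 1300, 2600), y = 1, area_m2 = 1)
  asg <- assign_catchments(dep, catch)
  expect_equal(asg$catchment_id, 1:3)
  # middle deposit's catchment (outlet 1400) is nearer the western outlet (500)
  expect_equal(asg$source_catchment_id, c(1, 1, 3))
  # all-forested is the identity
  catch2 <- catch; catch2$forest_fraction <- c(0.8, 0.3, 0.5)
  expect_equal(assign_catchments(dep, catch2)$source_catchment_id, 1:3)
  catch3 <- catch; catch3$forest_fraction <- 0
  expect_error(assign_catchments(dep, catch3), "forested")
})

test_that("distance decay: 3-4-5 geometry, curve monotonicity, closed-form CDF", {
  mouths <- data.frame(x = 0, y = 0)
  dep <- data.frame(x = c(0, 3e5), y = c(0, 4e5), area_m2 = c(1, 1))
  dd <- distance_decay(dep, mouths)
  expect_equal(sort(dd$distances_km), c(0, 500))
  expect_equal(dd$fraction_within(1), 0.5)
  expect_equal(dd$fraction_within(500), 1)
  expect_true(all(diff(dd$curve$cum_fraction) >= 0))
  # exponential draws match the closed-form CDF at the decay scale
  set.seed(14)
  d <- rexp(20000, 1 / 112)
  dep2 <- data.frame(x = d * 1000, y = 0, area_m2 = 1)
  dd2 <- distance_decay(dep2, mouths)
  expect_lt(abs(dd2$fraction_within(200) - (1 - exp(-200 / 112))), 0.03)
})
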