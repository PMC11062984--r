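test_that("ellipse intersection hits closed-form cases", {
  c1 <- unit_circle()
  expect_equal(ellipse_intersection_area(c1, c1), pi, tolerance = 1e-3)
  far <- ellipse_spec(c(100, 0), diag(2))
  expect_equal(ellipse_intersection_area(c1, far), 0)
  big <- ellipse_spec(c(0, 0), 4 * diag(2))
  expect_equal(ellipse_intersection_area(c1, big), pi, tolerance = 1e-3)
  expect_error(ellipse_intersection_area(c1, big, n_vertices = 32),
               class = "isoniche_domain_error")
})

test_that("overlap proportion follows the Jaccard reading", {
  c1 <- unit_circle()
  expect_equal(overlap_proportion(c1, c1), 1, tolerance = 1e-3)
  expect_equal(overlap_proportion(c1, ellipse_spec(c(100, 0), diag(2))), 0)
  big <- ellipse_spec(c(0, 0), 4 * diag(2))
  expect_equal(overlap_proportion(c1, big), 0.25, tolerance = 1e-3)
  # alternative denominator: intersection over summed non-shared area
  expect_equal(overlap_proportion(c1, big, denominator = "nonshared"),
               pi / (pi + 4 * pi - 2 * pi), tolerance = 1e-3)
})

test_that("overlap proportion is symmetric and rigid-motion invariant", {
  set.seed(41)
  for (rep in 1:5) {
    e1 <- ellipse_spec(runif(2, -2, 2), random_cov())
    e2 <- ellipse_spec(runif(2, -2, 2), random_cov())
    expect_equal(overlap_proportion(e1, e2), overlap_proportion(e2, e1),
                 tolerance = 1e-10)
    shift <- runif(2, -20, 20)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    move <- function(e) ellipse_spec(drop(R %*% e$mean) + shift,
                                     R %*% e$cov %*% t(R))
    expect_equal(overlap_proportion(move(e1), move(e2)),
                 overlap_proportion(e1, e2), tolerance = 1e-6)
  }
})

test_that("Bayesian overlap separates identical from disjoint populations", {
  set.seed(55)
  a <- rmvn2(200, c(0, 0), diag(2))
  b <- rmvn2(200, c(0, 0), diag(2))
  same <- bayesian_overlap(a, b, n_draws = 300, seed = 5)
  expect_gt(same$mode, 0.6)
  far <- bayesian_overlap(a, sweep(b, 2, c(-50, 0)), n_draws = 200, seed = 5)
  expect_lt(far$mode, 0.01)
  # determinism contract
  again <- bayesian_overlap(a, b, n_draws = 300, seed = 5)
  expect_identical(same$draws, again$draws)
  expect_error(bayesian_overlap(a[1:2, ], b),
               class = "isoniche_insufficient_data_error")
})

test_that("union area matches closed forms for simple configurations", {
  c1 <- unit_circle()
  expect_equal(union_area(list(c1), 512, check_convergence = FALSE), pi,
               tolerance = 0.005)
  two <- list(c1, unit_circle(c(10, 0)))
  expect_equal(union_area(two, 512, check_convergence = FALSE), 2 * pi,
               tolerance = 0.005)
  twin <- list(c1, unit_circle())
  expect_equal(union_area(twin, 512, check_convergence = FALSE), pi,
               tolerance = 0.005)
  expect_error(union_area(list()), class = "isoniche_domain_error")
})

test_that("union area is monotone in the ellipse set", {
  set.seed(61)
  ells <- lapply(1:6, function(i) ellipse_spec(runif(2, -3, 3), random_cov()))
  areas <- vapply(1:6, function(k) {
    union_area(ells[1:k], 256, check_convergence = FALSE)
  }, numeric(1))
  # grid tolerance: allow a hair of slack
  expect_true(all(diff(areas) > -1e-3 * areas[-6]))
})

test_that("grid and Monte Carlo union estimates agree on random sets", {
  set.seed(71)
  for (rep in 1:5) {
    k <- sample(2:8, 1)
    ells <- lapply(seq_len(k), function(i)
      ellipse_spec(runif(2, -4, 4), random_cov()))
    g <- union_area(ells, 512, check_convergence = FALSE)
    m <- union_area_mc(ells, n_points = 1e6, seed = 80 + rep)
    expect_lt(abs(g - m) / g, 0.01)
  }
})

test_that("relative niche indices are proportions of the combined union", {
  # one individual: its ellipse is the union
  set.seed(81)
  pts <- rmvn2(10, c(-24, 8), diag(2))
  solo <- tibble::tibble(site = "Wilmot", species = "tasmanian_devil",
                         individual_id = "a", section_index = 0:9,
                         d13C = pts[, 1], d15N = pts[, 2], tissue = "whisker")
  cn <- relative_niche_index(solo, grid_resolution = 256)
  expect_equal(cn$members$relative_index, 1, tolerance = 0.01)

  # two individuals with identical points: both indices 1
  twin <- dplyr::bind_rows(solo, dplyr::mutate(solo, individual_id = "b"))
  cn2 <- relative_niche_index(twin, grid_resolution = 256)
  expect_equal(cn2$members$relative_index, c(1, 1), tolerance = 0.01)

  # k disjoint equal-area ellipses: each index ~ 1/k
  k <- 4
  base <- rmvn2(12, c(0, 0), 0.25 * diag(2))
  parts <- lapply(seq_len(k), function(i) {
    tibble::tibble(site = "Wilmot", species = "tasmanian_devil",
                   individual_id = paste0("ind", i), section_index = 0:11,
                   d13C = base[, 1] + 10 * i, d15N = base[, 2],
                   tissue = "whisker")
  })
  cnk <- relative_niche_index(dplyr::bind_rows(parts), grid_resolution = 512)
  expect_equal(cnk$members$relative_index, rep(1 / k, k), tolerance = 0.02)
  expect_true(all(cnk$members$relative_index > 0 &
                    cnk$members$relative_index <= 1))
  expect_gte(cnk$union_area, max(cnk$members$SEA_C))
  expect_lte(cnk$union_area, sum(cnk$members$SEA_C) * 1.005)
})

test_that("individuals below the section minimum are excluded with a warning", {
  set.seed(91)
  pts <- rmvn2(8, c(-24, 8), diag(2))
  ok <- tibble::tibble(site = "Wilmot", species = "tasmanian_devil",
                       individual_id = "a", section_index = 0:7,
                       d13C = pts[, 1], d15N = pts[, 2], tissue = "whisker")
  short <- ok[1:2, ]
  short$individual_id <- "b"
  expect_warning(cn <- relative_niche_index(dplyr::bind_rows(ok, short),
                                            grid_resolution = 128),
                 "excluded")
  expect_equal(cn$members$individual_id, "a")
})
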