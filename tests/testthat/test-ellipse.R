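test_that("fit_ellipse returns the sample mean and unbiased covariance", {
  e <- fit_ellipse(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(e$mean, c(0.5, 0.5))
  expect_equal(e$cov, diag(c(1 / 3, 1 / 3)))
  expect_equal(e$n, 4L)
  expect_error(fit_ellipse(rbind(c(0, 0), c(1, 1))),
               class = "isoniche_insufficient_data_error")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))),
               class = "isoniche_degeneracy_error")
})

test_that("fitted covariance recovers the truth on a large Monte Carlo draw", {
  truth <- matrix(c(2, 1, 1, 2), 2, 2)
  set.seed(31)
  e <- fit_ellipse(rmvn2(10000, c(-24, 8), truth))
  expect_true(all(abs(e$cov - truth) / abs(truth) < 0.05))
})

test_that("standard ellipse areas follow the determinant formula", {
  expect_equal(sea(ellipse_spec(c(0, 0), diag(2))), pi)
  expect_equal(sea(ellipse_spec(c(0, 0), diag(c(4, 1)))), 2 * pi)
  expect_equal(sea(ellipse_spec(c(0, 0), matrix(c(2, 1, 1, 2), 2, 2))),
               pi * sqrt(3))
})

test_that("the small-sample correction scales by (n-1)/(n-2)", {
  expect_equal(sea_c(ellipse_spec(c(0, 0), diag(2), n = 3)), 2 * pi)
  expect_equal(sea_c(ellipse_spec(c(0, 0), diag(2), n = 102)), pi * 101 / 100)
  expect_equal(sea_c(ellipse_spec(c(0, 0), diag(2), n = 1e6)) / pi, 1,
               tolerance = 1e-5)
  expect_error(sea_c(ellipse_spec(c(0, 0), diag(2), n = 2)),
               class = "isoniche_insufficient_data_error")
})

test_that("SEA is invariant under translation and rotation", {
  set.seed(5)
  pts <- rmvn2(50, c(-24, 8), random_cov())
  a0 <- sea(fit_ellipse(pts))
  for (rep in 1:5) {
    shift <- runif(2, -30, 30)
    expect_equal(sea(fit_ellipse(sweep(pts, 2, -shift))), a0,
                 tolerance = 1e-10)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(sea(fit_ellipse(pts %*% R)), a0, tolerance = 1e-10)
  }
})

test_that("SEA_B draws are reproducible and recover a known area", {
  set.seed(11)
  pts <- rmvn2(500, c(0, 0), diag(2))
  a <- sea_b(pts, n_draws = 1000, seed = 42)
  b <- sea_b(pts, n_draws = 1000, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_true(a$ci_low <= a$mode && a$mode <= a$ci_high)
  expect_true(all(a$draws > 0))
  expect_equal(length(a$draws), 1000L)
  big <- sea_b(pts, n_draws = 10000, seed = 7)
  expect_lt(abs(big$mode - pi) / pi, 0.1)
  expect_error(sea_b(pts[1:2, ], 1000), class = "isoniche_insufficient_data_error")
  expect_error(sea_b(pts, n_draws = 50), class = "isoniche_domain_error")
})

test_that("SEA_B is insensitive to the prior scatter scale at moderate n", {
  set.seed(12)
  pts <- rmvn2(100, c(-24, 8), matrix(c(2, 0.5, 0.5, 1), 2, 2))
  modes <- vapply(c(1e-3, 1e-2, 1), function(s) {
    sea_b(pts, n_draws = 5000, seed = 9, prior = niw_prior(s))$mode
  }, numeric(1))
  expect_lt(max(modes) / min(modes) - 1, 0.1)
})

test_that("SEA_C, SEA and the SEA_B mode agree asymptotically", {
  truth <- matrix(c(1.8, 0.6, 0.6, 1.2), 2, 2)
  true_area <- pi * sqrt(det(truth))
  set.seed(21)
  pts <- rmvn2(1000, c(0, 0), truth)
  e <- fit_ellipse(pts)
  expect_equal(sea_c(e) / sea(e), 1, tolerance = 1e-2)
  pb <- sea_b(pts, 5000, seed = 3)
  expect_lt(abs(pb$mode - sea_c(e)) / sea_c(e), 0.05)
  # consistency toward the true area
  set.seed(22)
  big <- fit_ellipse(rmvn2(1e5, c(0, 0), truth))
  expect_equal(sea(big), true_area, tolerance = 0.02)
})

test_that("95% HDIs cover the true area in most replicates", {
  truth <- matrix(c(2, 0.8, 0.8, 1.5), 2, 2)
  true_area <- pi * sqrt(det(truth))
  set.seed(202)
  cover <- 0
  for (r in 1:100) {
    pts <- rmvn2(50, c(0, 0), truth)
    p <- sea_b(pts, 2000, seed = 300 + r)
    cover <- cover + (p$ci_low <= true_area && true_area <= p$ci_high)
  }
  expect_gte(cover, 90)
})

test_that("averaging two basal sections leaves SEA_B unchanged when they are identical", {
  set.seed(17)
  basal <- rmvn2(30, c(-24, 8), matrix(c(2, 0.4, 0.4, 1), 2, 2))
  samp <- tibble::tibble(
    site = "Wilmot", species = "tasmanian_devil",
    individual_id = rep(sprintf("d%02d", 1:30), each = 2),
    section_index = rep(0:1, 30),
    d13C = rep(basal[, 1], each = 2),
    d15N = rep(basal[, 2], each = 2),
    tissue = "whisker")
  out <- basal_sensitivity(samp, n_draws = 10000, seed = 4)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$mode_diff) / out$mode_one, 0.02)
})

test_that("averaging sections shrinks the niche under along-whisker drift", {
  # large within-individual dispersion: the two-section mean has half the
  # within variance, so its SEA_B should usually be smaller
  set.seed(23)
  smaller <- 0
  for (r in 1:20) {
    centres <- rmvn2(25, c(-24, 8), 0.3 * diag(2))
    pts0 <- centres + rmvn2(25, c(0, 0), 2.5 * diag(2))
    pts1 <- centres + rmvn2(25, c(0, 0), 2.5 * diag(2))
    samp <- tibble::tibble(
      site = "Wilmot", species = "tasmanian_devil",
      individual_id = rep(sprintf("d%02d", 1:25), 2),
      section_index = rep(0:1, each = 25),
      d13C = c(pts0[, 1], pts1[, 1]), d15N = c(pts0[, 2], pts1[, 2]),
      tissue = "whisker")
    out <- basal_sensitivity(samp, n_draws = 1000, seed = 600 + r)
    smaller <- smaller + (out$mode_two <= out$mode_one)
  }
  expect_gte(smaller, 16)  # >= 80% of replicates
})

test_that("individuals with a single section are excluded with a warning", {
  samp <- tibble::tibble(
    site = "Wilmot", species = "tasmanian_devil",
    individual_id = c(rep(sprintf("d%02d", 1:10), each = 2), "solo"),
    section_index = c(rep(0:1, 10), 0L),
    d13C = rnorm(21, -24), d15N = rnorm(21, 8), tissue = "whisker")
  expect_warning(out <- basal_sensitivity(samp, n_draws = 500, seed = 1),
                 "excluded")
  expect_equal(out$n_individuals, 10)
})

test_that("niche_metrics produces one row per group with coherent columns", {
  samp <- generate_isotope_study(scenario_config(seed = 3))
  std <- standardize_samples(
    samp, site_baseline_offsets(dplyr::filter(samp, species %in% iso_prey_species())))
  nm <- niche_metrics(dplyr::filter(std, species == "tasmanian_devil"),
                      n_draws = 500, seed = 8)
  expect_equal(nrow(nm), 5)
  expect_true(all(nm$SEA_C > nm$SEA))
  expect_true(all(nm$SEAB_low <= nm$SEAB_mode & nm$SEAB_mode <= nm$SEAB_high))
  expect_true(all(!is.na(nm$seed)))
})
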