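test_that("the study-shaped generator reproduces the sampling design exactly", {
  samp <- generate_isotope_study(scenario_config(seed = 2))
  counts <- samp |>
    dplyr::filter(tissue == "whisker") |>
    dplyr::group_by(site, species) |>
    dplyr::summarise(n_ind = dplyr::n_distinct(individual_id),
                     .groups = "drop")
  design <- study_design_counts()
  merged <- dplyr::left_join(design, counts, by = c("site", "species"))
  expect_equal(merged$n_ind, merged$n_total)
  # fully subsampled individuals respect the published section ranges
  secs <- samp |>
    dplyr::filter(tissue == "whisker") |>
    dplyr::group_by(site, species, individual_id) |>
    dplyr::summarise(k = dplyr::n(), .groups = "drop") |>
    dplyr::filter(k > 1)
  devil_k <- secs$k[secs$species == "tasmanian_devil"]
  quoll_k <- secs$k[secs$species == "spotted_tailed_quoll"]
  expect_true(all(devil_k >= 3 & devil_k <= 30))
  expect_true(all(quoll_k >= 3 & quoll_k <= 7))
  n_full <- secs |>
    dplyr::count(site, species) |>
    dplyr::left_join(design, by = c("site", "species"))
  expect_equal(n_full$n, n_full$n_individual_study)
  # prey present at every site under both baseline species labels
  prey <- dplyr::filter(samp, tissue == "muscle")
  expect_setequal(unique(prey$species), iso_prey_species())
  expect_equal(dplyr::n_distinct(prey$site), 5)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- scenario_config(seed = 9)
  expect_equal(generate_isotope_study(cfg), generate_isotope_study(cfg),
               ignore_attr = TRUE)
  a <- generate_detections(cfg)
  b <- generate_detections(cfg)
  expect_equal(a$timestamp, b$timestamp)
  expect_false(isTRUE(all.equal(
    generate_isotope_study(cfg, seed = 10)$d13C,
    generate_isotope_study(cfg, seed = 11)$d13C)))
})

test_that("a null scenario yields homogeneous niches across sites", {
  cfg <- scenario_config(effect_human_modified_on_logSEA = 0, seed = 4)
  samp <- generate_isotope_study(cfg)
  devils <- dplyr::filter(samp, species == "tasmanian_devil",
                          section_index == 0)
  seas <- devils |>
    dplyr::group_by(site) |>
    dplyr::group_map(~ sea_c(fit_ellipse(cbind(.x$d13C, .x$d15N))))
  seas <- unlist(seas)
  true_sea <- pi * sqrt(det(cfg$species_params$tasmanian_devil$cov))
  # all sites share the generating area; allow generous sampling error
  expect_true(all(abs(seas - true_sea) / true_sea < 0.5))
})

test_that("with no specialisation all individuals share one niche centre", {
  cfg <- scenario_config(specialisation = 0, seed = 6)
  cfg$species_params <- cfg$species_params["tasmanian_devil"]
  cfg$species_params$tasmanian_devil$n_individuals <- c(Wilmot = 15)
  cfg$species_params$tasmanian_devil$n_full <- c(Wilmot = 15)
  cfg$species_params$tasmanian_devil$section_median <- 28
  cfg$species_params$tasmanian_devil$section_range <- c(25, 30)
  cfg$sites <- cfg$sites[cfg$sites$site == "Wilmot", ]
  samp <- generate_isotope_study(cfg)
  devils <- dplyr::filter(samp, tissue == "whisker")
  cn <- relative_niche_index(devils, grid_resolution = 256)
  idx <- cn$members$relative_index
  expect_lt(sd(idx) / mean(idx), 0.3)
})

test_that("the human-modification effect scales true areas multiplicatively", {
  cfg <- scenario_config(seed = 3)
  samp <- generate_isotope_study(cfg)
  truth <- attr(samp, "truth")
  devil <- dplyr::filter(truth$groups, species == "tasmanian_devil")
  hm <- cfg$sites$human_modified_pct[match(devil$site, cfg$sites$site)]
  base_sea <- pi * sqrt(det(cfg$species_params$tasmanian_devil$cov))
  expect_equal(log(devil$true_sea), log(base_sea) +
                 cfg$effect_human_modified_on_logSEA * hm, tolerance = 1e-9)
})

test_that("reference-mean generator is exact at zero noise and unbiased with noise", {
  exact <- simulate_from_reference_means(noise_sd = 0, n_per_group = 3, seed = 1)
  ref <- study_reference_means()
  dev <- exact |>
    dplyr::filter(site == "Freycinet", species == "tasmanian_devil")
  expect_equal(mean(dev$d13C), -22.67)
  expect_equal(mean(dev$d15N), 8.86)
  noisy <- simulate_from_reference_means(noise_sd = 0.3, n_per_group = 200,
                                         seed = 2)
  se <- 0.3 / sqrt(200)
  # z-scores of every group mean against its reference value: individually
  # ~N(0,1), so the pooled mean is tightly centred and few exceed 3
  z <- noisy |>
    dplyr::filter(tissue == "whisker") |>
    dplyr::group_by(site, species) |>
    dplyr::summarise(mC = mean(d13C), mN = mean(d15N), .groups = "drop") |>
    dplyr::inner_join(study_reference_means(), by = c("site", "species")) |>
    dplyr::mutate(zC = (mC - d13C_raw) / se, zN = (mN - d15N_raw) / se)
  zs <- c(z$zC, z$zN)
  expect_lt(abs(mean(zs)), 4 / sqrt(length(zs)))
  expect_gte(mean(abs(zs) < 3), 0.85)
  expect_equal(simulate_from_reference_means(0.2, 5, seed = 7),
               simulate_from_reference_means(0.2, 5, seed = 7))
  expect_error(simulate_from_reference_means(-0.1, 5),
               class = "isoniche_domain_error")
  expect_error(simulate_from_reference_means(0, 0),
               class = "isoniche_domain_error")
})

test_that("detection generator exercises bursts and respects zero rates", {
  cfg <- scenario_config(seed = 21)
  cfg$detection_rates[] <- 0
  expect_equal(nrow(generate_detections(cfg)), 0)
  cfg$detection_rates[] <- 0
  cfg$detection_rates["medium_macropods"] <- 0.5
  det <- generate_detections(cfg, burst_prob = 1)
  expect_setequal(unique(det$group), "medium_macropods")
  # bursts exist: deduplication must remove rows
  expect_lt(nrow(dedupe_detections(det)), nrow(det))
  # a 5-detection burst within 4 minutes collapses to a single record
  burst <- detections_at(c(0, 1, 2, 3, 4))
  expect_equal(nrow(dedupe_detections(burst)), 1)
  # one surviving group per site gives H = 0 downstream
  div <- shannon_diversity(det)
  expect_true(all(div$shannon_H == 0))
})

test_that("camera layout mirrors the survey design", {
  cfg <- scenario_config(seed = 30)
  det <- generate_detections(cfg)
  cams <- det |>
    dplyr::group_by(site) |>
    dplyr::summarise(k = dplyr::n_distinct(camera_id))
  expect_equal(cams$k[cams$site == "Freycinet"], 13)
  expect_true(all(cams$k[cams$site != "Freycinet"] == 12))
})
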