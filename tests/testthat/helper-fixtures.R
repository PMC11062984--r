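# fixture builders shared across the test files

# a tiny well-formed isotope sample table
tiny_samples <- function() {
  tibble::tibble(
    site = c("Wilmot", "Wilmot", "Freycinet"),
    species = c("tasmanian_devil", "tasmanian_devil", "spotted_tailed_quoll"),
    individual_id = c("a1", "a1", "b1"),
    section_index = c(0L, 1L, 0L),
    d13C = c(-24.5, -24.7, -22.1),
    d15N = c(7.8, 7.9, 9.1),
    tissue = "whisker")
}

write_tmp_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path)
  path
}

# prey table with exactly-known site means:
# two samples per site symmetric around the target mean
prey_with_means <- function(means) {
  # means: tibble(site, d13C, d15N)
  purrr::list_rbind(lapply(seq_len(nrow(means)), function(i) {
    m <- means[i, ]
    tibble::tibble(
      site = m$site,
      species = rep(c("bennetts_wallaby", "tasmanian_pademelon"), 2),
      individual_id = paste0(tolower(gsub(" ", "", m$site)), "_p", 1:4),
      section_index = 0L,
      d13C = m$d13C + c(-0.5, 0.5, -0.25, 0.25),
      d15N = m$d15N + c(-0.3, 0.3, -0.15, 0.15),
      tissue = "muscle")
  }))
}

# n draws from a bivariate normal (uses the package's internal generator)
rmvn2 <- function(n, mean, cov) isoniche:::.rmvnorm2(n, mean, cov)

# ellipse helpers
unit_circle <- function(centre = c(0, 0)) ellipse_spec(centre, diag(2))

# random positive-definite 2x2 covariance
random_cov <- function(max_scale = 3) {
  a <- stats::runif(1, 0.3, max_scale)
  b <- stats::runif(1, 0.3, max_scale)
  r <- stats::runif(1, -0.8, 0.8)
  matrix(c(a, r * sqrt(a * b), r * sqrt(a * b), b), 2, 2)
}

# detection log fixture at given minute offsets for one stream
detections_at <- function(minutes, site = "Wilmot", camera = "cam01",
                          group = "medium_macropods") {
  origin <- as.POSIXct("2018-11-20 18:00:00", tz = "UTC")
  tibble::tibble(site = site, camera_id = camera,
                 timestamp = origin + minutes * 60, group = group)
}
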