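# Prey-anchored cross-site standardisation. Whisker d13C/d15N of consumers
# are not directly comparable across sites because the isotopic baseline
# (primary production) differs; the two staple herbivore prey (Bennett's
# wallaby, a grazer, and Tasmanian pademelon, a browser) are used as a
# common anchor: all values at a site are translated by the difference
# between that site's pooled prey mean and the baseline site's pooled prey
# mean, so pooled prey means coincide across sites after standardisation.

#' Convert an isotope ratio to delta notation
#'
#' \deqn{\delta X = (R_{sample} / R_{standard} - 1) \times 1000}
#' expressed per mil relative to the international standard (Vienna Pee Dee
#' Belemnite for carbon, atmospheric N2 for nitrogen).
#'
#' @param r_sample Heavy-to-light isotope ratio of the sample (> 0).
#' @param r_standard Heavy-to-light isotope ratio of the standard (> 0).
#' @return The delta value in permil.
#' @export
#' @examples
#' delta_value(1.1, 1)   # 100 permil
delta_value <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    abort("isotope ratios must be strictly positive",
          class = "isoniche_domain_error")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Per-site baseline offsets from pooled prey samples
#'
#' Pools the baseline prey species within each site (raw samples pooled
#' unweighted by default), takes site means of d13C and d15N, and returns
#' each site's offset from the baseline site. The baseline site's offset is
#' exactly (0, 0).
#'
#' @param prey_samples Data frame of isotope samples restricted to the
#'   baseline prey species (see [iso_prey_species()]).
#' @param baseline_site Site label used as the common baseline.
#' @param pooling `"pooled"` (default) pools raw prey samples before taking
#'   the site mean; `"species_mean"` averages per-species means instead.
#' @return A tibble with columns site, offset_d13C, offset_d15N, n_prey.
#' @export
site_baseline_offsets <- function(prey_samples,
                                  baseline_site = "Wilmot",
                                  pooling = c("pooled", "species_mean")) {
  pooling <- match.arg(pooling)
  prey_samples <- as_tibble(prey_samples)
  baseline_site <- .canonicalise(baseline_site, iso_sites(), "site")
  if (nrow(prey_samples) == 0) {
    abort("no prey samples supplied", class = "isoniche_config_error")
  }
  if (pooling == "pooled") {
    site_means <- prey_samples |>
      group_by(.data$site) |>
      summarise(mean_d13C = mean(.data$d13C),
                mean_d15N = mean(.data$d15N),
                n_prey = dplyr::n(), .groups = "drop")
  } else {
    site_means <- prey_samples |>
      group_by(.data$site, .data$species) |>
      summarise(mean_d13C = mean(.data$d13C),
                mean_d15N = mean(.data$d15N),
                n_prey = dplyr::n(), .groups = "drop") |>
      group_by(.data$site) |>
      summarise(mean_d13C = mean(.data$mean_d13C),
                mean_d15N = mean(.data$mean_d15N),
                n_prey = sum(.data$n_prey), .groups = "drop")
  }
  if (!baseline_site %in% site_means$site) {
    abort(sprintf("baseline site '%s' has no prey samples", baseline_site),
          class = "isoniche_config_error")
  }
  base <- site_means[site_means$site == baseline_site, ]
  out <- site_means |>
    mutate(offset_d13C = .data$mean_d13C - base$mean_d13C,
           offset_d15N = .data$mean_d15N - base$mean_d15N) |>
    select("site", "offset_d13C", "offset_d15N", "n_prey")
  # the baseline row is identically zero by construction; pin it exactly
  out$offset_d13C[out$site == baseline_site] <- 0
  out$offset_d15N[out$site == baseline_site] <- 0
  attr(out, "baseline_site") <- baseline_site
  out
}

#' Standardise isotope samples to the baseline site
#'
#' Subtracts each site's baseline offset from both isotope axes of every
#' sample (consumers and prey alike): a rigid per-site translation of the
#' isotope plane. After standardisation the pooled prey mean at every site
#' equals the baseline-site prey mean, and all within-site dispersion
#' metrics (covariances, ellipse areas, overlaps) are unchanged.
#'
#' The returned table carries a `standardized` attribute; passing an
#' already-standardised table in again is an error, since double
#' translation would silently corrupt the data.
#'
#' @param samples Data frame of isotope samples.
#' @param offsets Offsets from [site_baseline_offsets()].
#' @return A tibble like `samples` with translated d13C/d15N.
#' @export
standardize_samples <- function(samples, offsets) {
  samples <- as_tibble(samples)
  if (isTRUE(attr(samples, "standardized"))) {
    abort("samples are already standardized; refusing to apply offsets twice",
          class = "isoniche_double_standardize_error")
  }
  missing_sites <- setdiff(unique(samples$site), offsets$site)
  if (length(missing_sites) > 0) {
    abort(sprintf("no baseline offset for site(s): %s",
                  paste(missing_sites, collapse = ", ")),
          class = "isoniche_lookup_error")
  }
  idx <- match(samples$site, offsets$site)
  out <- samples |>
    mutate(d13C = .data$d13C - offsets$offset_d13C[idx],
           d15N = .data$d15N - offsets$offset_d15N[idx])
  attr(out, "standardized") <- TRUE
  attr(out, "baseline_site") <- attr(offsets, "baseline_site")
  out
}
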