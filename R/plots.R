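# Simple ggplot2 figures: the classic isotope biplot with 1-SD standard
# ellipses per group, and posterior-distribution plots for SEA_B and
# Bayesian overlap results.

#' Isotope biplot with standard ellipses
#'
#' Scatter of (d13C, d15N) values with the SEA_C-scaled 1-SD standard
#' ellipse per group, faceted by site.
#'
#' @param samples Data frame of isotope samples.
#' @param group Column used for colour (default species).
#' @param basal_only Keep only basal sections (default TRUE).
#' @return A ggplot object.
#' @export
plot_niche_ellipses <- function(samples, group = "species",
                                basal_only = TRUE) {
  samples <- as_tibble(samples)
  if (basal_only && "section_index" %in% names(samples)) {
    samples <- filter(samples, .data$section_index == 0)
  }
  grp_cols <- c("site", group)
  grouped <- samples |> group_by(across(all_of(grp_cols)))
  keys <- dplyr::group_keys(grouped)
  parts <- dplyr::group_split(grouped)
  polys <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- parts[[i]]
    if (nrow(sub) < 3) next
    e <- fit_ellipse(cbind(sub$d13C, sub$d15N))
    ec <- ellipse_spec(e$mean, e$cov * (e$n - 1) / (e$n - 2), e$n)
    P <- ellipse_polygon(ec, 180)
    polys[[i]] <- dplyr::bind_cols(
      keys[rep(i, nrow(P)), , drop = FALSE],
      tibble(d13C = P[, 1], d15N = P[, 2]))
  }
  polys <- list_rbind(polys[!vapply(polys, is.null, logical(1))])
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$d13C, y = .data$d15N,
                               colour = .data[[group]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_path(data = polys,
                       ggplot2::aes(group = .data[[group]])) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = expression(delta^13 * C ~ "(‰)"),
                  y = expression(delta^15 * N ~ "(‰)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot posterior_areas
#' @export
autoplot.posterior_areas <- function(object, ...) {
  df <- tibble(area = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = 3) +
    ggplot2::labs(x = expression(SEA[B] ~ ("‰"^2)), y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @method autoplot overlap_result
#' @export
autoplot.overlap_result <- function(object, ...) {
  df <- tibble(overlap = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = 3) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "overlap proportion", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
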