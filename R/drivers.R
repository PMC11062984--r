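# Ecological drivers of niche breadth and overlap: camera-trap detection
# deduplication, functional-group Shannon diversity, and the six
# single-predictor linear models per response with Bonferroni control.

#' Deduplicate camera-trap detections
#'
#' Within each (site, camera, functional group) stream, sorted by time, a
#' detection is kept if and only if strictly more than `window_min` minutes
#' have elapsed since the previously *kept* detection of that stream (greedy
#' from the earliest). Two detections exactly `window_min` apart count as
#' dependent. The rule is idempotent.
#'
#' @param detections Tibble with site, camera_id, timestamp (POSIXct), group.
#' @param window_min Independence window in minutes (default 20, >= 0).
#' @return The kept detections, sorted within streams.
#' @export
dedupe_detections <- function(detections, window_min = 20) {
  if (window_min < 0) {
    abort("window_min must be non-negative", class = "isoniche_domain_error")
  }
  detections <- as_tibble(detections)
  detections |>
    group_by(.data$site, .data$camera_id, .data$group) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    filter(.greedy_keep(as.numeric(.data$timestamp) / 60, window_min)) |>
    ungroup()
}

# greedy independence filter on times in minutes
.greedy_keep <- function(t_min, window) {
  keep <- logical(length(t_min))
  if (length(t_min) == 0) return(keep)
  keep[1] <- TRUE
  last <- t_min[1]
  for (i in seq_along(t_min)[-1]) {
    if (t_min[i] - last > window) {
      keep[i] <- TRUE
      last <- t_min[i]
    }
  }
  keep
}

#' Shannon diversity index of functional-group counts
#'
#' \eqn{H = -\sum p_i \ln p_i} over groups with nonzero counts.
#'
#' @param counts Named or unnamed vector of non-negative counts, at least
#'   one nonzero.
#' @return The Shannon index (natural log).
#' @export
shannon_index <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    abort("all counts are zero", class = "isoniche_domain_error")
  }
  p <- counts / sum(counts)
  unname(-sum(p * log(p)))
}

#' Per-site Shannon diversity from a detection log
#'
#' Deduplicates detections with [dedupe_detections()] and computes the
#' Shannon index of functional-group counts per site.
#'
#' @inheritParams dedupe_detections
#' @return A tibble: site, n_detections, n_groups, shannon_H.
#' @export
shannon_diversity <- function(detections, window_min = 20) {
  dedupe_detections(detections, window_min) |>
    group_by(.data$site) |>
    summarise(n_detections = dplyr::n(),
              n_groups = dplyr::n_distinct(.data$group),
              shannon_H = shannon_index(table(.data$group)),
              .groups = "drop")
}

#' Bonferroni-corrected critical p-value
#'
#' @param m Number of models in the family.
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return The critical p-value at full precision, with a `display`
#'   attribute giving the 3-decimal presentation (e.g. "0.008" for m = 6).
#' @export
bonferroni_alpha <- function(m, family_alpha = 0.05) {
  a <- family_alpha / m
  structure(a, display = sprintf("%.3f", a))
}

#' Single-predictor driver models with Bonferroni control
#'
#' Fits one ordinary least-squares model per candidate predictor of a niche
#' response (SEA_B mode per site x species, or modal overlap per site):
#' species, DFTD category, human-modified habitat %, road cover, Shannon
#' diversity, and prey SEA_B mode. Each model's p-value is the overall
#' F-test; the family-wise critical value is 0.05 divided by the number of
#' models actually fitted plus any skipped (six per response). For a
#' per-site response the species predictor is constant by construction and
#' is skipped with a note (its p-value is reported as 1).
#'
#' @param response_table Tibble with a `site` column, the response column,
#'   and (for the niche-breadth response) a `species` column.
#' @param covariates Site covariates as from [read_site_covariates()].
#' @param response Name of the response column (e.g. `"SEAB_mode"`).
#' @param predictors Candidate predictors; defaults to the six study
#'   variables.
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return A tibble with one row per predictor: response, predictor,
#'   p_value, statistic (F), df, n, alpha_bonferroni, significant, note, and
#'   a list-column `coefficients` of per-term estimates.
#' @export
driver_models <- function(response_table, covariates, response,
                          predictors = c("species", "dftd_category",
                                         "human_modified_pct", "road_cover",
                                         "shannon_H", "prey_seab_mode"),
                          family_alpha = 0.05) {
  dat <- left_join(as_tibble(response_table), as_tibble(covariates),
                   by = "site")
  if (!response %in% names(dat)) {
    abort(sprintf("response column '%s' not found", response),
          class = "isoniche_domain_error")
  }
  m <- length(predictors)
  alpha <- bonferroni_alpha(m, family_alpha)
  if ("dftd_category" %in% names(dat)) {
    dat$dftd_category <- factor(dat$dftd_category,
                                levels = sort(unique(dat$dftd_category)))
  }
  rows <- lapply(predictors, function(pred) {
    skipped <- FALSE
    note <- NA_character_
    if (!pred %in% names(dat) ||
        dplyr::n_distinct(dat[[pred]]) < 2) {
      skipped <- TRUE
      note <- sprintf("predictor '%s' constant or absent; skipped", pred)
    }
    if (skipped) {
      return(tibble(response = response, predictor = pred,
                    p_value = 1, statistic = NA_real_, df = NA_real_,
                    n = nrow(dat), alpha_bonferroni = as.numeric(alpha),
                    significant = FALSE, note = note,
                    coefficients = list(tibble())))
    }
    f <- as.formula(paste(response, "~", pred))
    fit <- lm(f, data = dat)
    if (fit$df.residual < 1) {
      abort(sprintf("model '%s' is rank deficient: %d rows for %d coefficients",
                    deparse(f), nrow(dat), length(coef(fit))),
            class = "isoniche_rank_error")
    }
    an <- anova(fit)
    sm <- summary(fit)$coefficients
    tibble(response = response, predictor = pred,
           p_value = an$`Pr(>F)`[1], statistic = an$`F value`[1],
           df = an$Df[1], n = nrow(dat),
           alpha_bonferroni = as.numeric(alpha),
           significant = an$`Pr(>F)`[1] < as.numeric(alpha),
           note = note,
           coefficients = list(tibble(term = rownames(sm),
                                      estimate = unname(sm[, 1]),
                                      std_error = unname(sm[, 2]),
                                      statistic = unname(sm[, 3]),
                                      p_value = unname(sm[, 4]))))
  })
  out <- list_rbind(rows)
  attr(out, "alpha_display") <- attr(alpha, "display")
  out
}
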