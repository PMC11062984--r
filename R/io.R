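# Readers, writers and validation for the three input tables: isotope
# samples, site covariates and camera-trap detections. All readers return
# tibbles; labels are canonicalised case-insensitively against a fixed
# vocabulary so that tables typed in different label styles join cleanly.

#' Canonical label vocabularies
#'
#' Site, species and camera functional-group labels are matched
#' case-insensitively on read (spaces, hyphens and underscores are
#' interchangeable) and canonicalised to these fixed spellings.
#'
#' @return A character vector of canonical labels.
#' @export
iso_sites <- function() {
  c("Freycinet", "Midlands", "West Pencil Pine", "Wilmot", "Arthur River")
}

#' @rdname iso_sites
#' @export
iso_species <- function() {
  c("tasmanian_devil", "spotted_tailed_quoll", "eastern_quoll",
    "bennetts_wallaby", "tasmanian_pademelon")
}

#' @rdname iso_sites
#' @export
iso_prey_species <- function() c("bennetts_wallaby", "tasmanian_pademelon")

#' @rdname iso_sites
#' @export
iso_dftd_categories <- function() c("long-term", "mid-term", "dftd-free")

#' @rdname iso_sites
#' @export
iso_functional_groups <- function() {
  c("large_exotics", "large_marsupial_herbivores", "medium_macropods",
    "medium_arboreal_marsupials", "medium_terrestrial_marsupials",
    "monotremes", "small_mammals", "native_rodents", "non_native_rodents",
    "birds", "reptiles", "other")
}

# fold a label to a comparison key: lower case, separators collapsed
.label_key <- function(x) {
  gsub("[ _-]+", "_", tolower(trimws(as.character(x))))
}

# canonicalise `x` against vocabulary `vocab`; unknown labels pass through
# unchanged unless strict = TRUE
.canonicalise <- function(x, vocab, what, strict = FALSE) {
  key <- .label_key(x)
  vkey <- .label_key(vocab)
  idx <- match(key, vkey)
  if (strict && anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    abort(sprintf("unknown %s label(s): %s", what,
                  paste(bad, collapse = ", ")),
          class = "isoniche_vocab_error")
  }
  out <- ifelse(is.na(idx), as.character(x), vocab[idx])
  out
}

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("file '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "isoniche_schema_error")
  }
  invisible(df)
}

.check_duplicates <- function(df, key_cols, path) {
  keys <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  if (any(dup)) {
    abort(sprintf(
      "file '%s' contains duplicate keys (%s) at rows: %s",
      path, paste(key_cols, collapse = ", "),
      paste(which(dup), collapse = ", ")),
      class = "isoniche_duplicate_error")
  }
  invisible(df)
}

#' Read a table of whisker-section isotope samples
#'
#' Reads a long-format CSV of per-section isotope measurements. Required
#' columns: `site`, `species`, `individual_id`, `section_index`, `d13C`,
#' `d15N`; an optional `tissue` column defaults to `"whisker"`. The key
#' (site, species, individual_id, section_index, tissue) must be unique.
#' Values of d13C outside \eqn{[-40, 0]} permil or d15N outside
#' \eqn{[-5, 20]} permil trigger a plausibility warning but are kept.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per whisker-section (or muscle) measurement.
#' @export
read_isotope_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(df, c("site", "species", "individual_id",
                         "section_index", "d13C", "d15N"), path)
  if (!"tissue" %in% names(df)) df$tissue <- "whisker"
  df <- as_tibble(df)
  df$site <- .canonicalise(df$site, iso_sites(), "site")
  df$species <- .canonicalise(df$species, iso_species(), "species")
  df$tissue <- .label_key(df$tissue)
  bad_tissue <- !df$tissue %in% c("whisker", "muscle")
  if (any(bad_tissue)) {
    abort(sprintf("unknown tissue label(s): %s",
                  paste(unique(df$tissue[bad_tissue]), collapse = ", ")),
          class = "isoniche_vocab_error")
  }
  validate_isotope_samples(df, path = path)
}

#' Validate an isotope-sample table
#'
#' Checks the invariants of the sample table: numeric finite isotope values,
#' non-negative integer section indices, unique
#' (site, species, individual_id, section_index, tissue) keys, and soft
#' plausibility ranges for d13C and d15N.
#'
#' @param samples A data frame of isotope samples.
#' @param path Label used in error messages.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_isotope_samples <- function(samples, path = "<samples>") {
  samples <- as_tibble(samples)
  bad <- !is.finite(samples$d13C) | !is.finite(samples$d15N)
  if (any(bad)) {
    abort(sprintf("file '%s': non-finite isotope values at rows: %s",
                  path, paste(which(bad), collapse = ", ")),
          class = "isoniche_validation_error")
  }
  if (any(samples$section_index < 0) ||
      any(samples$section_index != round(samples$section_index))) {
    abort(sprintf("file '%s': section_index must be a non-negative integer",
                  path),
          class = "isoniche_validation_error")
  }
  .check_duplicates(samples,
                    c("site", "species", "individual_id",
                      "section_index", "tissue"), path)
  out13 <- samples$d13C < -40 | samples$d13C > 0
  out15 <- samples$d15N < -5 | samples$d15N > 20
  if (any(out13) || any(out15)) {
    warn(sprintf(
      "%d d13C value(s) outside [-40, 0] and %d d15N value(s) outside [-5, 20] permil; kept but implausible",
      sum(out13), sum(out15)))
  }
  samples
}

#' Read a table of per-site covariates
#'
#' Required columns: `site`, `dftd_category` (one of long-term, mid-term,
#' dftd-free), `human_modified_pct` (0-100), `road_cover` (>= 0, km per
#' square km), `shannon_H` (>= 0) and `prey_seab_mode` (> 0, permil^2).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per site.
#' @export
read_site_covariates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(df, c("site", "dftd_category", "human_modified_pct",
                         "road_cover", "shannon_H", "prey_seab_mode"), path)
  df <- as_tibble(df)
  df$site <- .canonicalise(df$site, iso_sites(), "site")
  df$dftd_category <- .canonicalise(df$dftd_category, iso_dftd_categories(),
                                    "dftd_category", strict = TRUE)
  .check_duplicates(df, "site", path)
  if (any(df$human_modified_pct < 0 | df$human_modified_pct > 100)) {
    abort("human_modified_pct must lie in [0, 100]",
          class = "isoniche_validation_error")
  }
  if (any(df$road_cover < 0) || any(df$shannon_H < 0) ||
      any(df$prey_seab_mode <= 0)) {
    abort("road_cover and shannon_H must be >= 0 and prey_seab_mode > 0",
          class = "isoniche_validation_error")
  }
  df
}

#' Read a camera-trap detection log
#'
#' Required columns: `site`, `camera_id`, `timestamp` (ISO-8601, minute
#' resolution) and `group` (one of the configured functional groups).
#'
#' @param path Path to a CSV file.
#' @param groups Vocabulary of allowed functional-group labels.
#' @return A tibble with one row per detection, timestamps as POSIXct (UTC).
#' @export
read_detections <- function(path, groups = iso_functional_groups()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(timestamp = readr::col_character()))
  .require_columns(df, c("site", "camera_id", "timestamp", "group"), path)
  df <- as_tibble(df)
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(df$timestamp[miss], fmt, tz = "UTC"),
                           tz = "UTC")
  }
  if (anyNA(ts)) {
    abort(sprintf("file '%s': unparseable timestamp(s) at rows: %s",
                  path, paste(which(is.na(ts)), collapse = ", ")),
          class = "isoniche_parse_error")
  }
  df$timestamp <- ts
  df$site <- .canonicalise(df$site, iso_sites(), "site")
  df$group <- .canonicalise(df$group, groups, "functional group",
                            strict = TRUE)
  df
}

#' Write a results table to CSV
#'
#' Columns are written in their current (deterministic) order; numeric
#' values are serialised at full precision so that re-reading reproduces
#' them to at least 12 significant digits.
#'
#' @param records A non-empty data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0) {
    abort("refusing to write an empty results table",
          class = "isoniche_empty_error")
  }
  out <- as_tibble(records)
  # POSIXct -> ISO-8601 text; doubles survive via readr's full-precision grisu
  is_time <- vapply(out, function(x) inherits(x, "POSIXct"), logical(1))
  out[is_time] <- lapply(out[is_time], format,
                         format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
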