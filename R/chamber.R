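#' Assemble chamber-experiment data
#'
#' Bundles the tables produced by one campaign of sea-spray chamber
#' experiments into a single validated object. Each experiment is a ~30 h
#' chamber run: the chamber water is sampled in triplicate for PFAAs and
#' once for Na+, while the SSA is collected on impactor membranes and
#' reported per size fraction, again with a per-fraction Na+ mass on the
#' same sampled-air-volume basis. Concentrations below the method detection
#' limit (MDL) carry `censored = TRUE`.
#'
#' @param water Tibble: `experiment`, `homolog`, `replicate`, `conc`
#'   (pg L^-1), `censored` (logical).
#' @param ssa Tibble: `experiment`, `homolog`, `fraction`, `conc`
#'   (mass per sampled air volume, any consistent basis), `censored`.
#' @param water_na Tibble: `experiment`, `na_conc` (g L^-1).
#' @param ssa_na Tibble: `experiment`, `fraction`, `na_conc` (same basis as
#'   `ssa$conc`).
#' @param mdl_water Tibble: `homolog`, `mdl` (pg L^-1).
#' @param mdl_ssa Tibble: `homolog`, `fraction`, `mdl` (same basis as
#'   `ssa$conc`).
#' @param meta Optional tibble of per-experiment metadata (`experiment`,
#'   `lat`, `lon`, `water_temp_c`, `salinity_psu`, ...).
#' @return A `chamber_data` object (a named list of the validated tibbles).
#' @seealso [substitute_censored()], [ef_fit()], [gen_chamber_experiments()]
#' @export
chamber_data <- function(water, ssa, water_na, ssa_na,
                         mdl_water, mdl_ssa, meta = NULL) {
  water <- as_tibble(water)
  ssa <- as_tibble(ssa)
  water_na <- as_tibble(water_na)
  ssa_na <- as_tibble(ssa_na)
  mdl_water <- as_tibble(mdl_water)
  mdl_ssa <- as_tibble(mdl_ssa)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("%s is missing column(s): %s", what,
                    paste(miss, collapse = ", ")))
    }
  }
  need(water, c("experiment", "homolog", "replicate", "conc", "censored"),
       "water")
  need(ssa, c("experiment", "homolog", "fraction", "conc", "censored"), "ssa")
  need(water_na, c("experiment", "na_conc"), "water_na")
  need(ssa_na, c("experiment", "fraction", "na_conc"), "ssa_na")
  need(mdl_water, c("homolog", "mdl"), "mdl_water")
  need(mdl_ssa, c("homolog", "fraction", "mdl"), "mdl_ssa")

  if (any(water$conc < 0, na.rm = TRUE) || any(ssa$conc < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0")
  }
  if (any(water_na$na_conc <= 0) || any(ssa_na$na_conc <= 0)) {
    abort("Na+ concentrations must be > 0")
  }

  structure(
    list(water = water, ssa = ssa, water_na = water_na, ssa_na = ssa_na,
         mdl_water = mdl_water, mdl_ssa = mdl_ssa, meta = meta),
    class = "chamber_data"
  )
}

#' @export
print.chamber_data <- function(x, ...) {
  cat("<chamber_data>\n")
  cat("  experiments:", dplyr::n_distinct(x$water$experiment), "\n")
  cat("  homologs:   ", dplyr::n_distinct(x$water$homolog), "\n")
  cat("  fractions:  ", dplyr::n_distinct(x$ssa$fraction), "\n")
  invisible(x)
}

#' Handle left-censored chamber concentrations
#'
#' Applies the study's censoring rules: chamber-water concentrations below
#' their MDL are substituted by the MDL (and flagged `"substituted"`), while
#' SSA concentrations below their per-fraction MDL are marked excluded and
#' are dropped from all regressions and per-experiment EF calculations.
#' Uncensored values are unchanged.
#'
#' @param chamber A [chamber_data()] object.
#' @return The same object with `water` gaining a `flag` column
#'   (`"measured"`/`"substituted"`) and `ssa` gaining a logical `excluded`
#'   column.
#' @examples
#' ch <- gen_chamber_experiments(chamber_config(seed = 1))
#' sub <- substitute_censored(ch$chamber)
#' table(sub$water$flag)
#' @export
substitute_censored <- function(chamber) {
  stopifnot(inherits(chamber, "chamber_data"))

  w <- chamber$water %>%
    left_join(chamber$mdl_water, by = "homolog")
  bad <- w %>% filter(.data$censored & is.na(.data$mdl))
  if (nrow(bad)) {
    abort(sprintf("no MDL_water for censored homolog(s): %s",
                  paste(unique(bad$homolog), collapse = ", ")))
  }
  w <- w %>%
    mutate(
      sub = .data$censored | (!is.na(.data$mdl) & .data$conc < .data$mdl),
      flag = ifelse(.data$sub, "substituted", "measured"),
      conc = ifelse(.data$sub, .data$mdl, .data$conc),
      censored = .data$sub
    ) %>%
    select(-"mdl", -"sub")

  s <- chamber$ssa %>%
    left_join(chamber$mdl_ssa, by = c("homolog", "fraction"))
  bad <- s %>% filter(.data$censored & is.na(.data$mdl))
  if (nrow(bad)) {
    abort(sprintf(
      "no MDL_SSA for censored homolog/fraction: %s",
      paste(unique(paste0(bad$homolog, "/f", bad$fraction)), collapse = ", ")
    ))
  }
  s <- s %>%
    mutate(
      excluded = .data$censored | (!is.na(.data$mdl) & .data$conc < .data$mdl),
      censored = .data$excluded
    ) %>%
    select(-"mdl")

  chamber$water <- w
  chamber$ssa <- s
  chamber
}

#' Detection-frequency gate for EF calculation
#'
#' EFs are only calculated for homologs whose detection frequency in the
#' chamber water exceeds the threshold (strict `>`; a homolog detected in
#' exactly 30% of experiments is not eligible at the default threshold).
#' An experiment counts as a detection if at least one of its triplicate
#' water samples is uncensored.
#'
#' @param water The `water` tibble of a [chamber_data()] object (after or
#'   before substitution; the `censored` flag is used).
#' @param threshold Detection-frequency threshold in (0, 1); default 0.30.
#' @return Tibble `homolog`, `n_detected`, `n_total`, `frequency`,
#'   `eligible`.
#' @export
detection_frequency_gate <- function(water, threshold = 0.30) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (!nrow(water)) abort("no water samples")
  water %>%
    group_by(.data$homolog, .data$experiment) %>%
    summarise(detected = any(!.data$censored), .groups = "drop") %>%
    group_by(.data$homolog) %>%
    summarise(
      n_detected = sum(.data$detected),
      n_total = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      frequency = .data$n_detected / .data$n_total,
      eligible = .data$frequency > .env$threshold
    )
}
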