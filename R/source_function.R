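#' Log-normal modes of the SSA source function
#'
#' Constructs the mass-mode table of the sea spray source function. Each
#' mode is a log-normal mass-size distribution with a mass-median diameter,
#' a geometric standard deviation (GSD) and a mass weight (the fraction of
#' total emitted dry sea-salt mass carried by the mode); weights must sum
#' to 1.
#'
#' @param median_um Mass-median diameters in micrometres.
#' @param gsd Geometric standard deviations (> 1).
#' @param mass_weight Mass weights summing to 1.
#' @return Tibble with columns `mode`, `median_um`, `gsd`, `mass_weight`.
#' @seealso [default_source_modes()]
#' @export
source_modes <- function(median_um, gsd, mass_weight) {
  if (length(median_um) != length(gsd) ||
      length(gsd) != length(mass_weight)) {
    abort("median_um, gsd and mass_weight must have equal length")
  }
  if (any(median_um <= 0)) abort("median diameters must be > 0")
  if (any(gsd <= 1)) abort("GSDs must be > 1")
  if (abs(sum(mass_weight) - 1) > 1e-9) {
    abort("mode mass weights must sum to 1")
  }
  tibble(mode = seq_along(median_um), median_um = median_um, gsd = gsd,
         mass_weight = mass_weight)
}

#' Default three-mode SSA source function
#'
#' The chamber-derived inorganic SSA source function consists of three
#' log-normal modes with number-median diameters 0.095, 0.6 and 1.5 um.
#' Their GSDs and mass weights are not part of this package's estimation
#' and are configuration with documented defaults: GSDs 2.10, 1.72 and
#' 1.60 follow the published source-function parameterisation, the
#' mass-median diameters are obtained from the number medians by the
#' Hatch-Choate conversion `d_mass = d_number * exp(3 * log(gsd)^2)`, and
#' the mass weights are set so that the source function places about 2.5%
#' of emitted salt mass below 1 um, consistent with the sea-salt mass
#' partitioning this source function produces in Earth-system-model runs.
#'
#' @param number_median_um Number-median diameters (um).
#' @param gsd Geometric standard deviations.
#' @param mass_weight Mass weights summing to 1.
#' @return A [source_modes()] tibble.
#' @examples
#' default_source_modes()
#' submicron_mass_share(default_source_modes())
#' @export
default_source_modes <- function(number_median_um = c(0.095, 0.6, 1.5),
                                 gsd = c(2.10, 1.72, 1.60),
                                 mass_weight = c(0.003, 0.045, 0.952)) {
  mass_median <- number_median_um * exp(3 * log(gsd)^2)
  source_modes(mass_median, gsd, mass_weight)
}

#' Per-fraction mass weights of one source mode
#'
#' Integrates a mode's log-normal mass-size distribution over each size
#' fraction of the impactor scheme (area under the mass-size distribution
#' curve between the fraction's diameter bounds, with the outermost bounds
#' extended to 0 and +Inf) and normalises by the total mode mass.
#'
#' @param mode One row of a [source_modes()] tibble (or a list with
#'   `median_um` and `gsd`).
#' @param scheme A [size_fraction_scheme()].
#' @return Tibble `fraction`, `weight` with `sum(weight) == 1` when the
#'   scheme spans the mode's full support.
#' @examples
#' mode_mass_fractions(default_source_modes()[3, ], size_fraction_scheme())
#' @export
mode_mass_fractions <- function(mode, scheme) {
  if (any(scheme$lower_int_um >= scheme$upper_int_um)) {
    abort("degenerate fraction bounds: lower >= upper")
  }
  mu <- log(mode$median_um[[1]])
  sl <- log(mode$gsd[[1]])
  w <- plnorm(scheme$upper_int_um, mu, sl) - plnorm(scheme$lower_int_um, mu, sl)
  tibble(fraction = scheme$fraction, weight = w / sum(w))
}

#' Mode-level enrichment factor
#'
#' Aggregates size-fraction EFs to one EF per source mode as the
#' mass-weighted mean over fractions: the mean EF enters the `"mean"`
#' scenario, and the lower/upper 95% CI bounds enter the `"low"`/`"high"`
#' scenarios. Weights are renormalised over the fractions that carry an EF;
#' a missing fraction holding more than `max_missing_weight` of the mode's
#' mass is an error.
#'
#' @param records EF records for one homolog (columns `fraction`, `ef`,
#'   `ci_low`, `ci_high`).
#' @param weights Per-fraction weights from [mode_mass_fractions()].
#' @param scenario `"mean"`, `"low"` or `"high"`.
#' @param max_missing_weight Largest tolerated weight of a fraction without
#'   an EF (default 0.01).
#' @return The mode EF (scalar).
#' @export
mode_ef <- function(records, weights, scenario = c("mean", "low", "high"),
                    max_missing_weight = 0.01) {
  scenario <- match.arg(scenario)
  col <- switch(scenario, mean = "ef", low = "ci_low", high = "ci_high")
  d <- weights %>%
    left_join(records %>% select("fraction", value = all_of(col)),
              by = "fraction")
  missing <- d %>% filter(is.na(.data$value))
  if (any(missing$weight > max_missing_weight)) {
    abort(sprintf(
      "fraction(s) %s lack an EF but carry weight > %g",
      paste(missing$fraction[missing$weight > max_missing_weight],
            collapse = ", "),
      max_missing_weight
    ))
  }
  d <- d %>% filter(!is.na(.data$value))
  sum(d$weight * d$value) / sum(d$weight)
}

#' Mode EFs for every homolog, mode and scenario
#'
#' Convenience wrapper computing [mode_ef()] for all homologs in an EF
#' table across all modes and the three emission scenarios.
#'
#' @param records EF records (e.g. `tidy(ef_fit(...))`), one row per
#'   homolog x fraction; rows with `method == "not_calculated"` or missing
#'   EFs are dropped.
#' @param modes A [source_modes()] tibble.
#' @param scheme A [size_fraction_scheme()].
#' @param scenarios Character vector of scenarios to compute.
#' @inheritParams mode_ef
#' @return Tibble `homolog`, `mode`, `scenario`, `ef`.
#' @export
mode_efs <- function(records, modes, scheme = size_fraction_scheme(),
                     scenarios = c("mean", "low", "high"),
                     max_missing_weight = 0.01) {
  records <- records %>% filter(!is.na(.data$ef))
  grid <- tidyr::expand_grid(homolog = unique(records$homolog),
                             mode = modes$mode, scenario = scenarios)
  purrr::pmap_dfr(grid, function(homolog, mode, scenario) {
    w <- mode_mass_fractions(modes[modes$mode == mode, ], scheme)
    ef <- mode_ef(records[records$homolog == homolog, ], w,
                  scenario = scenario,
                  max_missing_weight = max_missing_weight)
    tibble(homolog = homolog, mode = mode, scenario = scenario, ef = ef)
  })
}

#' Submicron mass share of the source function
#'
#' The fraction of total emitted salt mass below a diameter cutoff:
#' the mass-weighted sum of each mode's log-normal CDF at the cutoff.
#'
#' @param modes A [source_modes()] tibble.
#' @param cutoff_um Diameter cutoff in micrometres (default 1).
#' @return A fraction in \[0, 1\].
#' @export
submicron_mass_share <- function(modes, cutoff_um = 1) {
  sum(modes$mass_weight *
        plnorm(cutoff_um, log(modes$median_um), log(modes$gsd)))
}
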