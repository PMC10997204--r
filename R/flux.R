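# Gridded flux estimation: the PFAA flux is the sodium flux scaled by the
# enrichment factor and the sodium-normalised seawater concentration,
#   Flux_PFAA = EF * Flux_Na * [PFAA]_sw / [Na]_sw,
# evaluated per cell and per source-function mode, for emission and for wet
# and dry deposition.

#' Physical constants of the flux calculation
#'
#' @param na_fraction Na+ fraction of dry sea-salt mass (default 0.307).
#' @param na_seawater_g_l Mean surface-seawater Na+ concentration in
#'   g L^-1 (default 10.8).
#' @param sec_per_year Seconds in a model year (365-day calendar, no leap
#'   days).
#' @param ng_per_tonne Nanograms per tonne (10^15); fixes the ng -> t
#'   conversion used by [global_total()].
#' @return A named list of constants.
#' @export
ssa_constants <- function(na_fraction = 0.307, na_seawater_g_l = 10.8,
                          sec_per_year = 365 * 86400,
                          ng_per_tonne = 1e15) {
  stopifnot(na_fraction > 0, na_fraction < 1, na_seawater_g_l > 0)
  list(na_fraction = na_fraction, na_seawater_g_l = na_seawater_g_l,
       sec_per_year = sec_per_year, ng_per_tonne = ng_per_tonne)
}

#' Annualise monthly salt flux fields
#'
#' Converts monthly-mean fluxes (kg m^-2 s^-1) into a day-weighted annual
#' mean rate times the seconds in the model year (365-day calendar), then
#' averages over the years present.
#'
#' @param monthly Tibble: `cell`, `year`, `month`, `value` (kg m^-2 s^-1).
#' @param constants A [ssa_constants()] list.
#' @return Tibble `cell`, `value` (kg m^-2 yr^-1).
#' @export
annualize <- function(monthly, constants = ssa_constants()) {
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  chk <- monthly %>%
    distinct(.data$year, .data$month) %>%
    dplyr::count(.data$year)
  if (any(chk$n != 12L)) {
    abort(sprintf("year(s) with missing months: %s",
                  paste(chk$year[chk$n != 12L], collapse = ", ")))
  }
  monthly %>%
    mutate(w = days[.data$month] / sum(days)) %>%
    group_by(.data$cell, .data$year) %>%
    summarise(value = sum(.data$value * .data$w) *
                constants$sec_per_year, .groups = "drop") %>%
    group_by(.data$cell) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}

# Split a total salt field across modes by mass weight unless it already
# carries a `mode` column.
#' @noRd
per_mode_salt <- function(salt, modes) {
  if ("mode" %in% names(salt)) return(salt)
  tidyr::expand_grid(mode = modes$mode, salt) %>%
    left_join(modes %>% select("mode", "mass_weight"), by = "mode") %>%
    mutate(value = .data$value * .data$mass_weight) %>%
    select(-"mass_weight")
}

#' Gridded PFAA flux from a salt flux field
#'
#' Applies `Flux_PFAA = EF_mode * (na_fraction * Flux_salt) *
#' C / [Na]_sw` per cell, homolog and mode. With the salt flux in
#' kg m^-2 yr^-1, concentrations in pg L^-1 and seawater Na+ in g L^-1 the
#' result is in ng m^-2 yr^-1 with no further constant (kg x pg / g = ng).
#'
#' @param salt Salt flux tibble: `cell`, `value` (kg m^-2 yr^-1),
#'   optionally `mode` (otherwise split by mode mass weights).
#' @param efs Mode EFs for one scenario: `homolog`, `mode`, `ef`.
#' @param conc Per-cell concentrations: `cell`, `homolog`, `conc`
#'   (pg L^-1).
#' @param modes A [source_modes()] tibble.
#' @param constants A [ssa_constants()] list.
#' @return Tibble `cell`, `homolog`, `mode`, `value` (ng m^-2 yr^-1); one
#'   row per combination present in all inputs.
#' @export
pfaa_flux_field <- function(salt, efs, conc, modes,
                            constants = ssa_constants()) {
  if (any(conc$conc < 0)) abort("negative seawater concentration")
  salt <- per_mode_salt(salt, modes)
  salt %>%
    inner_join(conc, by = "cell",
               relationship = "many-to-many") %>%
    inner_join(efs, by = c("homolog", "mode")) %>%
    mutate(value = .data$ef * constants$na_fraction * .data$value *
             .data$conc / constants$na_seawater_g_l) %>%
    select("cell", "homolog", "mode", "value") %>%
    arrange(.data$homolog, .data$mode, .data$cell)
}

#' Sum per-mode fluxes and combine isomer homologs into species
#'
#' @param field Output of [pfaa_flux_field()].
#' @param species_map Tibble `homolog`, `species` (default
#'   [pfaa_homologs()]), used to sum linear and branched isomers.
#' @return Tibble `cell`, `species`, `value`.
#' @export
combine_species <- function(field, species_map = pfaa_homologs()) {
  field %>%
    left_join(species_map %>% select("homolog", "species"), by = "homolog") %>%
    mutate(species = dplyr::coalesce(.data$species, .data$homolog)) %>%
    group_by(.data$cell, .data$species) %>%
    summarise(value = sum(.data$value), .groups = "drop")
}

#' Global total of a gridded flux in tonnes per year
#'
#' `sum(value * area) * 1e-15` over the cells of the field (ng -> t).
#' Grouping columns other than `cell`/`value` (e.g. `homolog`, `species`,
#' `mode`) are preserved.
#'
#' @param field Tibble with `cell`, `value` (ng m^-2 yr^-1) and optional
#'   grouping columns.
#' @param grid A [grid_spec()].
#' @param constants A [ssa_constants()] list.
#' @return Tibble of totals in t yr^-1 (column `total_t_yr`).
#' @export
global_total <- function(field, grid, constants = ssa_constants()) {
  groups <- setdiff(names(field), c("cell", "value"))
  field %>%
    left_join(grid$cells %>% select("cell", "area_m2"), by = "cell") %>%
    group_by(across(all_of(groups))) %>%
    summarise(total_t_yr = sum(.data$value * .data$area_m2) /
                constants$ng_per_tonne, .groups = "drop")
}

#' Global total of a salt field in kg per year
#'
#' @param field Tibble `cell`, `value` (kg m^-2 yr^-1).
#' @param grid A [grid_spec()].
#' @return Total in kg yr^-1.
#' @export
global_salt_total <- function(field, grid) {
  f <- field %>%
    left_join(grid$cells %>% select("cell", "area_m2"), by = "cell")
  sum(f$value * f$area_m2)
}

#' Emission and deposition breakdown statistics
#'
#' Computes, per species, the headline percentages of the estimation:
#' the share of emission from coastal-province cells, the share of emission
#' associated with submicrometre SSA (per-mode totals weighted by each
#' mode's submicron mass share), the shares of total deposition reaching
#' inland and coastline cells, and the dry share of deposition.
#'
#' @param emission Per-mode emission field (`cell`, `homolog`, `mode`,
#'   `value`).
#' @param wet_dep,dry_dep Deposition fields in the same layout.
#' @param raster A `province_raster` (for the coastal-province mask).
#' @param mask Output of [classify_cells()].
#' @param modes A [source_modes()] tibble.
#' @param grid A [grid_spec()].
#' @param species_map Tibble `homolog`, `species`.
#' @param cutoff_um Submicron cutoff (default 1).
#' @return Tibble `species`, `metric`, `value` (percent), with metrics
#'   `coastal_emission_pct`, `submicron_emission_pct`,
#'   `inland_deposition_pct`, `coast_deposition_pct`,
#'   `dry_deposition_pct`.
#' @export
flux_breakdowns <- function(emission, wet_dep, dry_dep, raster, mask,
                            modes, grid, species_map = pfaa_homologs(),
                            cutoff_um = 1) {
  areas <- grid$cells %>% select("cell", "area_m2")
  sp <- function(field) {
    combine_species(field, species_map) %>% left_join(areas, by = "cell")
  }
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, 0)

  em <- sp(emission)
  coastal_ids <- raster$meta$province[raster$meta$coastal]
  coastal_cells <- raster$cells$cell[!is.na(raster$cells$province) &
                                       raster$cells$province %in% coastal_ids]
  em_tot <- em %>%
    group_by(.data$species) %>%
    summarise(total = sum(.data$value * .data$area_m2),
              coastal = sum(.data$value * .data$area_m2 *
                              (.data$cell %in% coastal_cells)),
              .groups = "drop")

  sub_share <- modes %>%
    mutate(share = plnorm(cutoff_um, log(.data$median_um),
                          log(.data$gsd))) %>%
    select("mode", "share")
  em_sub <- emission %>%
    left_join(species_map %>% select("homolog", "species"), by = "homolog") %>%
    mutate(species = dplyr::coalesce(.data$species, .data$homolog)) %>%
    left_join(areas, by = "cell") %>%
    left_join(sub_share, by = "mode") %>%
    group_by(.data$species) %>%
    summarise(submicron = sum(.data$value * .data$area_m2 * .data$share),
              .groups = "drop")

  wet <- sp(wet_dep)
  dry <- sp(dry_dep)
  dep <- bind_rows(wet, dry) %>%
    group_by(.data$cell, .data$species) %>%
    summarise(value = sum(.data$value), area_m2 = .data$area_m2[1],
              .groups = "drop")
  inland_cells <- mask$cell[mask$inland]
  coast_cells <- mask$cell[mask$coast]
  dep_tot <- dep %>%
    group_by(.data$species) %>%
    summarise(total = sum(.data$value * .data$area_m2),
              inland = sum(.data$value * .data$area_m2 *
                             (.data$cell %in% inland_cells)),
              coastline = sum(.data$value * .data$area_m2 *
                                (.data$cell %in% coast_cells)),
              .groups = "drop")
  dry_tot <- dry %>%
    group_by(.data$species) %>%
    summarise(dry = sum(.data$value * .data$area_m2), .groups = "drop")

  em_tot %>%
    left_join(em_sub, by = "species") %>%
    left_join(dep_tot, by = "species", suffix = c("_em", "_dep")) %>%
    left_join(dry_tot, by = "species") %>%
    dplyr::transmute(
      species = .data$species,
      coastal_emission_pct = pct(.data$coastal, .data$total_em),
      submicron_emission_pct = pct(.data$submicron, .data$total_em),
      inland_deposition_pct = pct(.data$inland, .data$total_dep),
      coast_deposition_pct = pct(.data$coastline, .data$total_dep),
      dry_deposition_pct = pct(.data$dry, .data$total_dep)
    ) %>%
    tidyr::pivot_longer(-"species", names_to = "metric",
                        values_to = "value")
}

#' Difference between deposition and emission fluxes
#'
#' Per-cell `deposition - emission`; positive values mean net deposition,
#' matching the sign convention of the study's difference maps.
#'
#' @param emission,deposition Species-level fields (`cell`, `species`,
#'   `value`) on the same grid.
#' @return Tibble `cell`, `species`, `value` (signed, ng m^-2 yr^-1).
#' @export
net_difference <- function(emission, deposition) {
  full <- dplyr::full_join(
    deposition %>% rename(dep = "value"),
    emission %>% rename(em = "value"),
    by = c("cell", "species")
  ) %>%
    mutate(dep = dplyr::coalesce(.data$dep, 0),
           em = dplyr::coalesce(.data$em, 0),
           value = .data$dep - .data$em)
  full %>% select("cell", "species", "value") %>%
    arrange(.data$species, .data$cell)
}
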