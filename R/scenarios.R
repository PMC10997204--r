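# End-to-end orchestration: build the world once, then run the mean, low
# and high scenarios (EF central value or CI bound paired with the province
# concentration median or quartile) and consolidate the results.

#' Assemble a gridded world from its raw ingredients
#'
#' Runs the spatial preprocessing chain: classify land/coast/inland cells,
#' rasterise the provinces over the ocean cells, bin the measurements to
#' cell medians, merge data-sparse provinces, assign scenario
#' concentrations with quartiles, complete data-free provinces by the
#' neighbour/latitude fallback rules, extend coastal provinces inland for
#' the deposition concentrations, and annualise the monthly salt emission.
#'
#' @param grid A [grid_spec()].
#' @param polygons,meta Province polygons and metadata
#'   (see [rasterize_provinces()]).
#' @param land,coastline Land polygons and coastline polylines
#'   (see [classify_cells()]).
#' @param measurements Located seawater measurements
#'   (see [cell_medians()]).
#' @param salt_monthly Monthly salt emission (kg m^-2 s^-1), or `NULL` if
#'   `salt_emission` is given directly.
#' @param salt_emission Annual salt emission (kg m^-2 yr^-1); computed from
#'   `salt_monthly` when missing.
#' @param salt_wet_dep,salt_dry_dep Annual salt deposition fields
#'   (kg m^-2 yr^-1).
#' @param extend_n Coastal-extension depth in cells (default 2).
#' @param min_cells Province data threshold (default 3).
#' @param constants A [ssa_constants()] list.
#' @return An object of class `ssa_world`: list with `grid`, `raster`
#'   (merged), `mask`, `conc` (completed province scenario table),
#'   `dep_assign`, the salt fields and `constants`.
#' @export
build_world <- function(grid, polygons, meta, land, coastline, measurements,
                        salt_monthly = NULL, salt_emission = NULL,
                        salt_wet_dep, salt_dry_dep,
                        extend_n = 2, min_cells = 3,
                        constants = ssa_constants()) {
  mask <- classify_cells(grid, land, coastline)
  raster <- rasterize_provinces(grid, polygons, meta, ocean = !mask$land)
  medians <- cell_medians(measurements, grid)
  raster <- merge_sparse_provinces(raster, medians, min_cells = min_cells)
  conc <- province_concentrations(medians, raster, min_cells = min_cells,
                                  drop_sparse = TRUE)
  conc <- fallback_concentrations(raster, conc)
  dep_assign <- extend_coastal(raster, mask, n = extend_n)
  if (is.null(salt_emission)) {
    if (is.null(salt_monthly)) {
      abort("supply either salt_monthly or salt_emission")
    }
    salt_emission <- annualize(salt_monthly, constants)
  }
  structure(
    list(grid = grid, raster = raster, mask = mask, conc = conc,
         dep_assign = dep_assign, salt_emission = salt_emission,
         salt_wet_dep = salt_wet_dep, salt_dry_dep = salt_dry_dep,
         constants = constants),
    class = "ssa_world"
  )
}

#' @export
print.ssa_world <- function(x, ...) {
  cat("<ssa_world>\n")
  cat(sprintf("  grid: %d x %d\n", x$grid$nlat, x$grid$nlon))
  cat("  provinces:",
      dplyr::n_distinct(stats::na.omit(x$raster$cells$province)), "\n")
  cat("  homologs:", paste(unique(x$conc$homolog), collapse = ", "), "\n")
  invisible(x)
}

# Per-cell concentration tables for one scenario: emission uses each ocean
# cell's own province; deposition uses the coastal-extension assignment.
#' @noRd
scenario_cell_conc <- function(world, scenario) {
  col <- switch(scenario, mean = "mean", low = "low", high = "high")
  conc <- world$conc %>%
    select("province", "homolog", conc = all_of(col))
  emis <- world$raster$cells %>%
    filter(!is.na(.data$province)) %>%
    inner_join(conc, by = "province",
               relationship = "many-to-many") %>%
    select("cell", "homolog", "conc")
  dep <- world$dep_assign %>%
    filter(!is.na(.data$dep_province)) %>%
    inner_join(conc, by = c(dep_province = "province"),
               relationship = "many-to-many") %>%
    select("cell", "homolog", "conc")
  list(emission = emis, deposition = dep)
}

#' Run one emission/deposition scenario
#'
#' Pairs the scenario's EFs (central value for `"mean"`, lower/upper 95% CI
#' bound for `"low"`/`"high"`) with the matching province concentration
#' statistic (median, Q1, Q3), computes the gridded PFAA emission, wet and
#' dry deposition fields, and reduces them to global totals and breakdown
#' percentages.
#'
#' @param efs Mode-EF table from [mode_efs()] covering the requested
#'   scenario.
#' @param modes A [source_modes()] tibble.
#' @param world An [build_world()] result.
#' @param scenario `"mean"`, `"low"` or `"high"`.
#' @param species_map Tibble `homolog`, `species` for isomer summing.
#' @return An object of class `scenario_result`: list with `scenario`,
#'   `totals` (tibble `species`, `kind`, `total_t_yr`), `breakdowns`,
#'   `fields` (species-level emission/deposition and the net difference),
#'   and `salt` (global salt totals and shares).
#' @export
run_scenario <- function(efs, modes, world,
                         scenario = c("mean", "low", "high"),
                         species_map = pfaa_homologs()) {
  scenario <- match.arg(scenario)
  for (part in c("raster", "conc", "dep_assign", "salt_emission",
                 "salt_wet_dep", "salt_dry_dep")) {
    if (is.null(world[[part]])) {
      abort(sprintf("world is missing stage `%s`", part))
    }
  }
  efs <- efs %>% filter(.data$scenario == .env$scenario)
  if (!nrow(efs)) abort(sprintf("no EFs for scenario %s", scenario))
  cc <- scenario_cell_conc(world, scenario)
  cst <- world$constants

  emission <- pfaa_flux_field(world$salt_emission, efs, cc$emission,
                              modes, cst)
  wet <- pfaa_flux_field(world$salt_wet_dep, efs, cc$deposition, modes, cst)
  dry <- pfaa_flux_field(world$salt_dry_dep, efs, cc$deposition, modes, cst)

  em_sp <- combine_species(emission, species_map)
  dep_sp <- combine_species(bind_rows(wet, dry), species_map)

  totals <- bind_rows(
    global_total(em_sp, world$grid, cst) %>% mutate(kind = "emission"),
    global_total(dep_sp, world$grid, cst) %>% mutate(kind = "deposition")
  ) %>% select("species", "kind", "total_t_yr")

  breakdowns <- flux_breakdowns(emission, wet, dry, world$raster,
                                world$mask, modes, world$grid, species_map)

  salt_em <- global_salt_total(world$salt_emission, world$grid)
  salt_dep <- global_salt_total(bind_rows(world$salt_wet_dep,
                                          world$salt_dry_dep) %>%
                                  group_by(.data$cell) %>%
                                  summarise(value = sum(.data$value),
                                            .groups = "drop"),
                                world$grid)
  coastal_ids <- world$raster$meta$province[world$raster$meta$coastal]
  coastal_cells <- world$raster$cells$cell[
    !is.na(world$raster$cells$province) &
      world$raster$cells$province %in% coastal_ids]
  se <- world$salt_emission %>%
    left_join(world$grid$cells %>% select("cell", "area_m2"), by = "cell")
  salt <- list(
    emission_kg_yr = salt_em,
    na_emission_kg_yr = cst$na_fraction * salt_em,
    deposition_kg_yr = salt_dep,
    coastal_pct = 100 * sum(se$value * se$area_m2 *
                              (se$cell %in% coastal_cells)) /
      sum(se$value * se$area_m2),
    submicron_pct = 100 * submicron_mass_share(modes)
  )

  structure(
    list(scenario = scenario, totals = totals, breakdowns = breakdowns,
         fields = list(emission = em_sp, deposition = dep_sp,
                       net = net_difference(em_sp, dep_sp)),
         salt = salt),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: %s>\n", x$scenario))
  print(x$totals)
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  bind_rows(
    x$totals %>%
      mutate(metric = paste0(.data$kind, "_t_yr")) %>%
      select("species", "metric", value = "total_t_yr"),
    x$breakdowns
  ) %>%
    mutate(scenario = x$scenario, .before = 1)
}

#' @rdname run_scenario
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble(scenario = x$scenario,
         n_species = dplyr::n_distinct(x$totals$species),
         salt_emission_kg_yr = x$salt$emission_kg_yr,
         salt_coastal_pct = x$salt$coastal_pct)
}

#' Run the mean, low and high scenarios end to end
#'
#' Aggregates size-fraction EF records to mode EFs and runs the three
#' scenarios on a built world. Scenario pairing is joint: the low scenario
#' pairs CI-low EFs with first-quartile concentrations, the high scenario
#' CI-high EFs with third-quartile concentrations.
#'
#' @param records EF records (`tidy()` of an [ef_fit()], or an externally
#'   supplied table with `homolog`, `fraction`, `ef`, `ci_low`, `ci_high`).
#' @param world A [build_world()] result.
#' @param modes A [source_modes()] tibble.
#' @param scheme A [size_fraction_scheme()].
#' @param species_map Tibble `homolog`, `species`.
#' @param scenarios Scenarios to run.
#' @return An object of class `scenario_set`: list of `scenario_result`s
#'   plus the consolidated tidy table (`tidy()` method).
#' @export
run_scenarios <- function(records, world, modes = default_source_modes(),
                          scheme = size_fraction_scheme(),
                          species_map = pfaa_homologs(),
                          scenarios = c("mean", "low", "high")) {
  efs <- mode_efs(records, modes, scheme, scenarios = scenarios)
  results <- lapply(scenarios, function(sc) {
    run_scenario(efs, modes, world, scenario = sc,
                 species_map = species_map)
  })
  names(results) <- scenarios
  structure(
    list(results = results,
         table = purrr::map_dfr(results, tidy),
         mode_efs = efs),
    class = "scenario_set"
  )
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set>\n")
  wide <- x$table %>%
    filter(grepl("_t_yr$", .data$metric)) %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "value")
  print(wide)
  invisible(x)
}

#' @rdname run_scenarios
#' @param x A `scenario_set`.
#' @param ... Unused.
#' @method tidy scenario_set
#' @export
tidy.scenario_set <- function(x, ...) x$table

#' @rdname run_scenarios
#' @method glance scenario_set
#' @export
glance.scenario_set <- function(x, ...) {
  purrr::map_dfr(x$results, glance)
}
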