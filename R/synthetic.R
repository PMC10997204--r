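# Synthetic-data generators: chamber campaigns with known true EFs and a
# toy gridded ocean world with provinces, land masks and closed salt
# budgets. Both return their truth records so parameter-recovery tests need
# no re-derivation.

#' Configuration of a synthetic chamber campaign
#'
#' Defaults emulate the field campaign the estimation rests on: 19 chamber
#' runs along a meridional transect, water concentrations varying
#' log-uniformly across runs, true EFs following a power law in particle
#' diameter at the 10^4-10^5 level, and multiplicative log-normal noise
#' with GSD 1.5 on the SSA concentrations.
#'
#' @param seed Integer seed fixing all draws.
#' @param n_experiments Number of chamber runs (default 19).
#' @param homologs Character vector of homolog ids.
#' @param scheme A [size_fraction_scheme()].
#' @param ef_scale Named (or recycled) EF at 1 um per homolog.
#' @param ef_exponent Power-law exponent of EF in diameter.
#' @param water_range_pg_l Log-uniform range of true water concentrations.
#' @param noise_gsd Geometric standard deviation of the SSA noise (>= 1;
#'   1 means noiseless).
#' @param replicate_gsd GSD of the triplicate water-cartridge noise.
#' @param water_na_g_l Chamber-water Na+ concentration.
#' @param ssa_na_scale Total SSA Na+ collected per run (arbitrary
#'   per-air-volume units), distributed over fractions by the source
#'   function's mass-size distribution.
#' @param mdl_water_pg_l Water MDL (scalar or per homolog).
#' @param mdl_ssa MDL for SSA samples (same units as the SSA
#'   concentrations; scalar, or per homolog x fraction).
#' @return A list of class `chamber_config`.
#' @export
chamber_config <- function(seed,
                           n_experiments = 19,
                           homologs = c("PFOA", "PFNA", "L-PFOS", "B-PFOS"),
                           scheme = size_fraction_scheme(),
                           ef_scale = 3e4,
                           ef_exponent = 1.2,
                           water_range_pg_l = c(50, 2000),
                           noise_gsd = 1.5,
                           replicate_gsd = 1.05,
                           water_na_g_l = 10.8,
                           ssa_na_scale = 100,
                           mdl_water_pg_l = 5,
                           mdl_ssa = 0) {
  stopifnot(noise_gsd >= 1, replicate_gsd >= 1, n_experiments >= 1)
  structure(
    list(seed = as.integer(seed), n_experiments = n_experiments,
         homologs = homologs, scheme = scheme,
         ef_scale = rep_len(ef_scale, length(homologs)),
         ef_exponent = ef_exponent,
         water_range_pg_l = water_range_pg_l, noise_gsd = noise_gsd,
         replicate_gsd = replicate_gsd, water_na_g_l = water_na_g_l,
         ssa_na_scale = ssa_na_scale, mdl_water_pg_l = mdl_water_pg_l,
         mdl_ssa = mdl_ssa),
    class = "chamber_config"
  )
}

# log-normal multiplier with geometric standard deviation `gsd` (gsd = 1
# degenerates to exactly 1)
#' @noRd
rlnorm_gsd <- function(n, gsd) {
  if (gsd <= 1) return(rep(1, n))
  exp(rnorm(n, 0, log(gsd)))
}

#' Generate a synthetic chamber campaign
#'
#' Water concentrations are drawn log-uniformly per experiment and homolog;
#' the SSA concentration of a fraction is
#' `EF_true * (water / Na_water) * Na_SSA * noise` with multiplicative
#' log-normal noise; censoring is applied at the configured MDLs (values
#' below an MDL are flagged, not altered).
#'
#' @param cfg A [chamber_config()].
#' @return List with `chamber` (a [chamber_data()] object) and `truth`
#'   (list with `ef` -- tibble `homolog`, `fraction`, `ef_true` -- and
#'   `water` -- tibble of true per-experiment water concentrations).
#' @export
gen_chamber_experiments <- function(cfg) {
  stopifnot(inherits(cfg, "chamber_config"))
  set.seed(cfg$seed)
  scheme <- cfg$scheme
  nf <- nrow(scheme)
  exps <- sprintf("E%02d", seq_len(cfg$n_experiments))

  truth_ef <- tidyr::expand_grid(homolog = cfg$homologs,
                                 fraction = scheme$fraction) %>%
    left_join(scheme %>% select("fraction", "dp_um"), by = "fraction") %>%
    mutate(ef_true = cfg$ef_scale[match(.data$homolog, cfg$homologs)] *
             .data$dp_um^cfg$ef_exponent) %>%
    select(-"dp_um")

  water_true <- tidyr::expand_grid(experiment = exps,
                                   homolog = cfg$homologs) %>%
    mutate(conc_true = exp(runif(dplyr::n(),
                                 log(cfg$water_range_pg_l[1]),
                                 log(cfg$water_range_pg_l[2]))))

  mdl_water <- tibble(homolog = cfg$homologs,
                      mdl = rep_len(cfg$mdl_water_pg_l,
                                    length(cfg$homologs)))
  water <- tidyr::expand_grid(water_true, replicate = 1:3) %>%
    mutate(conc = .data$conc_true *
             rlnorm_gsd(dplyr::n(), cfg$replicate_gsd)) %>%
    left_join(mdl_water, by = "homolog") %>%
    mutate(censored = .data$conc < .data$mdl) %>%
    select("experiment", "homolog", "replicate", "conc", "censored")

  water_na <- tibble(experiment = exps, na_conc = cfg$water_na_g_l)

  # distribute collected SSA sodium over fractions like the coarse mode's
  # mass-size distribution (most sampled salt mass is supermicrometre)
  coarse <- default_source_modes()[3, ]
  na_frac <- mode_mass_fractions(coarse, scheme)
  ssa_na <- tidyr::expand_grid(experiment = exps,
                               fraction = scheme$fraction) %>%
    left_join(na_frac, by = "fraction") %>%
    mutate(na_conc = cfg$ssa_na_scale * pmax(.data$weight, 1e-6)) %>%
    select("experiment", "fraction", "na_conc")

  if (is.data.frame(cfg$mdl_ssa)) {
    mdl_ssa <- cfg$mdl_ssa
  } else {
    mdl_ssa <- tidyr::expand_grid(homolog = cfg$homologs,
                                  fraction = scheme$fraction) %>%
      mutate(mdl = rep_len(cfg$mdl_ssa, dplyr::n()))
  }

  ssa <- tidyr::expand_grid(experiment = exps, homolog = cfg$homologs,
                            fraction = scheme$fraction) %>%
    left_join(water_true, by = c("experiment", "homolog")) %>%
    left_join(ssa_na, by = c("experiment", "fraction")) %>%
    left_join(truth_ef, by = c("homolog", "fraction")) %>%
    mutate(conc = .data$ef_true * (.data$conc_true / cfg$water_na_g_l) *
             .data$na_conc * rlnorm_gsd(dplyr::n(), cfg$noise_gsd)) %>%
    left_join(mdl_ssa, by = c("homolog", "fraction")) %>%
    mutate(censored = .data$conc < .data$mdl) %>%
    select("experiment", "homolog", "fraction", "conc", "censored")

  chamber <- chamber_data(water = water, ssa = ssa, water_na = water_na,
                          ssa_na = ssa_na, mdl_water = mdl_water,
                          mdl_ssa = mdl_ssa)
  list(chamber = chamber,
       truth = list(ef = truth_ef, water = water_true))
}

#' Configuration of the toy gridded world
#'
#' A coarse global grid with two rectangular continents and one island,
#' twelve ocean provinces (four coastal strips hugging the continents,
#' open-ocean latitude bands, an Atlantic and a Pacific basin side), a
#' mid-latitude-peaked salt emission profile, and a closed salt budget:
#' global salt deposition equals global salt emission, split into the
#' configured wet/dry shares. Some provinces are left without measurements
#' and one is kept data-sparse, so the merging and fallback rules are
#' exercised by the default world.
#'
#' @param seed Integer seed.
#' @param nlat,nlon Grid size (default 30 x 40).
#' @param salt_total_kg_yr Global annual salt emission (default 3e12).
#' @param wet_fraction Wet share of total salt deposition (default 0.6).
#' @param years Years of monthly emission fields to generate.
#' @param conc_coastal_pg_l,conc_open_pg_l Reference PFOA concentrations in
#'   coastal and open provinces; other homologs scale from these.
#' @param meas_gsd GSD of measurement scatter around province truth.
#' @param homologs Homologs carried by the measurement table.
#' @return A list of class `world_config`.
#' @export
world_config <- function(seed, nlat = 30, nlon = 40,
                         salt_total_kg_yr = 3e12,
                         wet_fraction = 0.6,
                         years = 2008:2009,
                         conc_coastal_pg_l = 400,
                         conc_open_pg_l = 60,
                         meas_gsd = 1.4,
                         homologs = c("PFOA", "L-PFOS", "B-PFOS")) {
  stopifnot(wet_fraction > 0, wet_fraction < 1)
  structure(
    list(seed = as.integer(seed), nlat = nlat, nlon = nlon,
         salt_total_kg_yr = salt_total_kg_yr, wet_fraction = wet_fraction,
         years = years, conc_coastal_pg_l = conc_coastal_pg_l,
         conc_open_pg_l = conc_open_pg_l, meas_gsd = meas_gsd,
         homologs = homologs),
    class = "world_config"
  )
}

#' @noRd
rect_poly <- function(id, lon_lo, lon_hi, lat_lo, lat_hi) {
  tibble(id = id,
         lon = c(lon_lo, lon_hi, lon_hi, lon_lo),
         lat = c(lat_lo, lat_lo, lat_hi, lat_hi))
}

#' Generate the toy gridded world
#'
#' @param cfg A [world_config()].
#' @return A list with `grid`, `polygons` (province polygons), `meta`
#'   (province metadata), `land`, `coastline` (shapes), `measurements`,
#'   `salt_monthly` (monthly emission, kg m^-2 s^-1), `salt_emission`
#'   (annualised, kg m^-2 yr^-1), `salt_wet_dep`, `salt_dry_dep`
#'   (kg m^-2 yr^-1) and `truth` (province concentrations and budget
#'   checks).
#' @export
gen_grid_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  set.seed(cfg$seed + 1L)
  grid <- grid_spec(cfg$nlat, cfg$nlon)
  cells <- grid$cells

  # -- land and coastline ---------------------------------------------------
  land <- bind_rows(
    rect_poly("continentA", -150, -110, -41, 53),
    rect_poly("continentB", -15, 25, -29, 41),
    rect_poly("island", 101, 109, -4, 4)
  )
  coastline <- land %>%
    group_by(.data$id) %>%
    dplyr::group_modify(~ bind_rows(.x, .x[1, ])) %>%
    ungroup()

  # -- provinces ------------------------------------------------------------
  prov_rects <- list(
    rect_poly("PACE", -180, -162, -90, 90),
    rect_poly("ACW", -162, -131, -90, 90),
    rect_poly("ACE", -131, -98, -90, 90),
    rect_poly("ATLS", -98, -27, -90, -44),
    rect_poly("ATLTS", -98, -27, -44, 2),
    rect_poly("ATLTN", -98, -27, 2, 46),
    rect_poly("ATLN", -98, -27, 46, 90),
    rect_poly("BCW", -27, 5, -90, 90),
    rect_poly("BCE", 5, 36, -90, 90),
    rect_poly("PACS", 36, 180, -90, -30),
    rect_poly("PACT", 36, 180, -30, 30),
    rect_poly("PACN", 36, 180, 30, 90)
  )
  polygons <- purrr::map_dfr(prov_rects, ~ rename(.x, province = "id"))
  meta <- tibble::tribble(
    ~province, ~coastal, ~basin,
    "PACE",  FALSE, "pacific",
    "ACW",   TRUE,  "pacific",
    "ACE",   TRUE,  "atlantic",
    "ATLS",  FALSE, "atlantic",
    "ATLTS", FALSE, "atlantic",
    "ATLTN", FALSE, "atlantic",
    "ATLN",  FALSE, "atlantic",
    "BCW",   TRUE,  "atlantic",
    "BCE",   TRUE,  "pacific",
    "PACS",  FALSE, "pacific",
    "PACT",  FALSE, "pacific",
    "PACN",  FALSE, "pacific"
  )

  mask <- classify_cells(grid, land, coastline)
  ocean <- !mask$land
  raster <- rasterize_provinces(grid, polygons, meta, ocean = ocean)

  # -- true province concentrations ----------------------------------------
  homolog_scale <- setNames(rep(1, length(cfg$homologs)), cfg$homologs)
  if ("L-PFOS" %in% cfg$homologs) homolog_scale["L-PFOS"] <- 0.5
  if ("B-PFOS" %in% cfg$homologs) homolog_scale["B-PFOS"] <- 0.175
  prov_mult <- setNames(exp(runif(nrow(meta), log(0.6), log(1.7))),
                        meta$province)
  truth_conc <- tidyr::expand_grid(province = meta$province,
                                   homolog = cfg$homologs) %>%
    left_join(meta, by = "province") %>%
    mutate(conc_true = ifelse(.data$coastal, cfg$conc_coastal_pg_l,
                              cfg$conc_open_pg_l) *
             homolog_scale[.data$homolog] *
             prov_mult[.data$province]) %>%
    select("province", "homolog", "conc_true")

  # -- measurements: populated provinces, one sparse, several empty ---------
  n_cells_with_data <- c(ATLTS = 5L, ATLTN = 4L, ATLN = 4L, ACE = 4L,
                         BCW = 4L, PACT = 3L, ATLS = 2L)
  measurements <- purrr::imap_dfr(n_cells_with_data, function(k, p) {
    pc <- cells$cell[!is.na(raster$cells$province) &
                       raster$cells$province == p]
    pick <- pc[round(seq(1, length(pc), length.out = min(k, length(pc))))]
    pts <- cells[match(pick, cells$cell), ]
    # duplicate the first location so some cell holds multiple measurements
    pts <- pts[c(1, seq_len(nrow(pts))), ]
    tidyr::expand_grid(idx = seq_len(nrow(pts)), homolog = cfg$homologs) %>%
      mutate(lat = pts$lat[.data$idx], lon = pts$lon[.data$idx],
             province = p) %>%
      left_join(truth_conc, by = c("province", "homolog")) %>%
      mutate(value = .data$conc_true *
               rlnorm_gsd(dplyr::n(), cfg$meas_gsd),
             censored = FALSE, mdl = 0, year = 2019L) %>%
      select("lat", "lon", "homolog", "value", "censored", "mdl", "year")
  })

  # -- salt fluxes ----------------------------------------------------------
  profile <- 0.2 + exp(-((abs(cells$lat) - 40) / 18)^2)
  emis_raw <- ifelse(ocean, profile, 0)
  scale <- cfg$salt_total_kg_yr / sum(emis_raw * cells$area_m2)
  emis_annual <- emis_raw * scale
  salt_emission <- tibble(cell = cells$cell, value = emis_annual) %>%
    filter(.data$value > 0)

  # monthly fields whose day-weighted annualisation reproduces the annual
  # rate exactly
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  seas <- 1 + 0.3 * cos(2 * pi * (seq_len(12) - 1) / 12)
  seas <- seas / sum(seas * days / 365)
  sec_yr <- 365 * 86400
  salt_monthly <- tidyr::expand_grid(year = cfg$years,
                                     month = 1:12,
                                     salt_emission) %>%
    mutate(value = .data$value / sec_yr * seas[.data$month]) %>%
    select("cell", "year", "month", "value")

  # deposition: ocean cells echo the emission pattern plus a uniform
  # background; land cells decay away from the ocean; the global budget is
  # closed exactly
  shore <- bfs_label(grid,
                     seeds = tibble(cell = cells$cell[ocean],
                                    label = "ocean"))
  depth <- rep(NA_integer_, nrow(cells))
  depth[shore$cell] <- shore$depth
  dep_raw <- ifelse(ocean, 0.8 * emis_raw + 0.2 * mean(emis_raw[ocean]),
                    0.5 * mean(profile) * exp(-0.9 * depth))
  dep_raw[is.na(dep_raw)] <- 0
  dep_scale <- sum(emis_annual * cells$area_m2) /
    sum(dep_raw * cells$area_m2)
  dep_annual <- dep_raw * dep_scale
  salt_wet_dep <- tibble(cell = cells$cell,
                         value = cfg$wet_fraction * dep_annual)
  salt_dry_dep <- tibble(cell = cells$cell,
                         value = (1 - cfg$wet_fraction) * dep_annual)

  list(grid = grid, polygons = polygons, meta = meta, land = land,
       coastline = coastline, mask = mask, raster = raster,
       measurements = measurements,
       salt_monthly = salt_monthly, salt_emission = salt_emission,
       salt_wet_dep = salt_wet_dep, salt_dry_dep = salt_dry_dep,
       truth = list(conc = truth_conc,
                    salt_total_kg_yr = cfg$salt_total_kg_yr,
                    wet_fraction = cfg$wet_fraction))
}
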