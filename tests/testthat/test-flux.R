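test_that("annualisation is day-weighted and averages years", {
  cst <- ssa_constants()
  const <- tidyr::expand_grid(cell = 1:3, year = 2008:2009, month = 1:12) |>
    dplyr::mutate(value = 1)
  ann <- annualize(const, cst)
  expect_equal(ann$value, rep(cst$sec_per_year, 3))

  # one nonzero month contributes its day-weight share
  one <- const |>
    dplyr::mutate(value = ifelse(month == 1, 2e-6, 0))
  ann1 <- annualize(one, cst)
  expect_equal(ann1$value, rep(2e-6 * 31 / 365 * cst$sec_per_year, 3))

  # random fixture vs a plain loop
  set.seed(14)
  rnd <- tidyr::expand_grid(cell = 1:5, year = 2008:2010, month = 1:12) |>
    dplyr::mutate(value = runif(dplyr::n()))
  ann_r <- annualize(rnd, cst)
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  for (cc in 1:5) {
    per_year <- sapply(2008:2010, function(y) {
      v <- rnd$value[rnd$cell == cc & rnd$year == y]
      sum(v * days / 365) * cst$sec_per_year
    })
    expect_equal(ann_r$value[ann_r$cell == cc], mean(per_year),
                 tolerance = 1e-12)
  }

  expect_error(annualize(rnd[rnd$month != 6, ], cst), "missing months")
})

test_that("the flux formula has the exact unit identity", {
  # EF = 1, salt flux 1 kg m^-2 yr^-1, C = 10.8 pg/L -> 1 ng m^-2 yr^-1
  modes <- source_modes(1, 1.5, 1)
  salt <- tibble::tibble(cell = 1L, mode = 1L, value = 1 / 0.307)
  efs <- tibble::tibble(homolog = "PFOA", mode = 1L, ef = 1)
  conc <- tibble::tibble(cell = 1L, homolog = "PFOA", conc = 10.8)
  f <- pfaa_flux_field(salt, efs, conc, modes)
  expect_identical(f$value, 1)

  # direct substitution: EF 1e5, Na flux 1, C = 100 -> 9.26e5
  salt2 <- tibble::tibble(cell = 1L, mode = 1L, value = 1 / 0.307)
  efs2 <- tibble::tibble(homolog = "PFOA", mode = 1L, ef = 1e5)
  conc2 <- tibble::tibble(cell = 1L, homolog = "PFOA", conc = 100)
  f2 <- pfaa_flux_field(salt2, efs2, conc2, modes)
  expect_equal(f2$value, 1e5 * 100 / 10.8)

  expect_error(
    pfaa_flux_field(salt, efs,
                    tibble::tibble(cell = 1L, homolog = "PFOA", conc = -1),
                    modes),
    "negative")
})

test_that("gridded fluxes match a cell-by-cell scalar oracle", {
  modes <- default_source_modes()
  set.seed(23)
  cells <- 1:40
  salt <- tibble::tibble(cell = cells, value = runif(40, 0, 0.05))
  conc <- tidyr::expand_grid(cell = cells,
                             homolog = c("PFOA", "L-PFOS")) |>
    dplyr::mutate(conc = rlnorm(dplyr::n(), 4, 1))
  efs <- tidyr::expand_grid(homolog = c("PFOA", "L-PFOS"),
                            mode = modes$mode) |>
    dplyr::mutate(ef = exp(runif(dplyr::n(), log(1e4), log(1e5))))
  f <- pfaa_flux_field(salt, efs, conc, modes)

  for (k in sample(nrow(f), 25)) {
    row <- f[k, ]
    w <- modes$mass_weight[modes$mode == row$mode]
    s <- salt$value[salt$cell == row$cell] * w
    cc <- conc$conc[conc$cell == row$cell & conc$homolog == row$homolog]
    e <- efs$ef[efs$homolog == row$homolog & efs$mode == row$mode]
    expect_equal(row$value, e * 0.307 * s * cc / 10.8, tolerance = 1e-12)
  }
})

test_that("global totals integrate area and convert ng to tonnes", {
  grid <- grid_spec(5, 5)
  # single cell at 1 ng m^-2 yr^-1 with area A -> A * 1e-15 t
  f1 <- tibble::tibble(cell = 13L, species = "PFOA", value = 1)
  tot <- global_total(f1, grid)
  expect_equal(tot$total_t_yr,
               grid$cells$area_m2[13] * 1e-15)

  set.seed(9)
  f <- tibble::tibble(cell = grid$cells$cell, species = "PFOA",
                      value = runif(25))
  tot2 <- global_total(f, grid)
  oracle <- 0
  for (k in seq_len(25)) {
    oracle <- oracle + f$value[k] * grid$cells$area_m2[f$cell[k]]
  }
  expect_equal(tot2$total_t_yr, oracle * 1e-15, tolerance = 1e-12)
})

test_that("sodium emission is exactly the sodium fraction of salt emission", {
  dw <- default_world(seed = 3)
  cst <- ssa_constants()
  salt_em <- global_salt_total(dw$world$salt_emission, dw$world$grid)
  sim <- gen_chamber_experiments(chamber_config(seed = 7))
  rec <- tidy(ef_fit(sim$chamber, n_boot = 100, seed = 1))
  sres <- run_scenario(mode_efs(rec, default_source_modes()),
                       default_source_modes(), dw$world, "mean")
  expect_identical(sres$salt$na_emission_kg_yr, cst$na_fraction * salt_em)
})

test_that("degenerate breakdowns hit their closed forms", {
  grid <- grid_spec(5, 5)
  modes <- source_modes(2, 1.5, 1)
  cells <- grid$cells$cell
  # all emission in coastal provinces -> coastal share 100%
  raster <- structure(list(
    grid = grid,
    cells = tibble::tibble(cell = cells, province = "c1"),
    meta = tibble::tibble(province = "c1", coastal = TRUE,
                          basin = "atlantic"),
    merged_from = tibble::tibble(from = character(), to = character())),
    class = "province_raster")
  mask <- tibble::tibble(cell = cells, land = FALSE, coast = FALSE,
                         inland = FALSE)
  em <- tibble::tibble(cell = cells, homolog = "PFOA", mode = 1L,
                       value = 1)
  wet <- em
  dry <- em  # wet = dry everywhere -> dry share 50%
  b <- flux_breakdowns(em, wet, dry, raster, mask, modes, grid)
  get <- function(metric) b$value[b$metric == metric]
  expect_equal(get("coastal_emission_pct"), 100)
  expect_equal(get("dry_deposition_pct"), 50)
  # submicron share of a single-mode field is the mode CDF below 1 um
  expect_equal(get("submicron_emission_pct"),
               100 * stats::plnorm(1, log(2), log(1.5)))
  # empty masks give defined zero percentages
  expect_equal(get("inland_deposition_pct"), 0)
  expect_equal(get("coast_deposition_pct"), 0)
})

test_that("toy-world breakdowns equal mask-filtered loop oracles", {
  dw <- default_world(seed = 3)
  world <- dw$world
  modes <- default_source_modes()
  sim <- gen_chamber_experiments(chamber_config(seed = 7))
  rec <- tidy(ef_fit(sim$chamber, n_boot = 100, seed = 1))
  efs <- mode_efs(rec, modes)
  res <- run_scenario(efs, modes, world, "mean")
  b <- res$breakdowns

  areas <- world$grid$cells$area_m2
  emi <- res$fields$emission
  dep <- res$fields$deposition
  coastal_ids <- world$raster$meta$province[world$raster$meta$coastal]
  coastal_cells <- world$raster$cells$cell[
    !is.na(world$raster$cells$province) &
      world$raster$cells$province %in% coastal_ids]
  for (spc in unique(emi$species)) {
    e <- emi[emi$species == spc, ]
    num <- sum(e$value[e$cell %in% coastal_cells] *
                 areas[e$cell[e$cell %in% coastal_cells]])
    den <- sum(e$value * areas[e$cell])
    expect_equal(b$value[b$species == spc &
                           b$metric == "coastal_emission_pct"],
                 100 * num / den, tolerance = 1e-12)
    d <- dep[dep$species == spc, ]
    inl <- world$mask$cell[world$mask$inland]
    cst_cells <- world$mask$cell[world$mask$coast]
    expect_equal(b$value[b$species == spc &
                           b$metric == "inland_deposition_pct"],
                 100 * sum(d$value[d$cell %in% inl] *
                             areas[d$cell[d$cell %in% inl]]) /
                   sum(d$value * areas[d$cell]), tolerance = 1e-12)
    expect_equal(b$value[b$species == spc &
                           b$metric == "coast_deposition_pct"],
                 100 * sum(d$value[d$cell %in% cst_cells] *
                             areas[d$cell[d$cell %in% cst_cells]]) /
                   sum(d$value * areas[d$cell]), tolerance = 1e-12)
  }
})

test_that("net difference is deposition minus emission, cell by cell", {
  em <- tibble::tibble(cell = 1:4, species = "PFOA", value = c(1, 2, 3, 4))
  same <- net_difference(em, em)
  expect_true(all(same$value == 0))
  zero <- em |> dplyr::mutate(value = 0)
  dep_only <- net_difference(zero, em)
  expect_equal(dep_only$value, em$value)
  set.seed(2)
  dep <- em |> dplyr::mutate(value = runif(4))
  nd <- net_difference(em, dep)
  expect_equal(nd$value, dep$value - em$value)
})

test_that("fluxes are linear in concentrations and EFs", {
  modes <- default_source_modes()
  set.seed(33)
  salt <- tibble::tibble(cell = 1:20, value = runif(20, 0, 0.05))
  conc <- tibble::tibble(cell = 1:20, homolog = "PFOA",
                         conc = rlnorm(20, 4, 1))
  efs <- tidyr::expand_grid(homolog = "PFOA", mode = modes$mode) |>
    dplyr::mutate(ef = 1e4)
  base <- pfaa_flux_field(salt, efs, conc, modes)
  dbl_conc <- pfaa_flux_field(salt, efs,
                              conc |> dplyr::mutate(conc = conc * 2), modes)
  dbl_ef <- pfaa_flux_field(salt, efs |> dplyr::mutate(ef = ef * 2),
                            conc, modes)
  expect_equal(dbl_conc$value, 2 * base$value)
  expect_equal(dbl_ef$value, 2 * base$value)
})

test_that("a uniform closed world conserves the salt-scaled budget", {
  dw <- default_world(seed = 3)
  world <- dw$world
  # force a uniform concentration and a flat EF across modes/fractions
  world$conc <- world$conc |>
    dplyr::mutate(mean = 100, low = 100, high = 100)
  modes <- default_source_modes()
  efs <- tidyr::expand_grid(homolog = c("PFOA", "L-PFOS", "B-PFOS"),
                            mode = modes$mode, scenario = "mean") |>
    dplyr::mutate(ef = 1e5)
  res <- run_scenario(efs, modes, world, "mean")
  tot <- res$totals
  em <- tot$total_t_yr[tot$kind == "emission" & tot$species == "PFOA"]
  de <- tot$total_t_yr[tot$kind == "deposition" & tot$species == "PFOA"]
  ratio_salt <- res$salt$deposition_kg_yr / res$salt$emission_kg_yr
  expect_equal(de, em * ratio_salt, tolerance = 1e-9)
})
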