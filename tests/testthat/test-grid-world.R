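test_that("spherical cell areas tile the globe", {
  for (g in list(grid_spec(5, 5), grid_spec(30, 40))) {
    expect_equal(sum(g$cells$area_m2), 4 * pi * g$radius_m^2,
                 tolerance = 1e-9)
    expect_true(all(g$cells$area_m2 > 0))
  }
})

test_that("province rasterisation assigns cells by centre containment", {
  grid <- grid_spec(10, 10)
  polys <- rbind(
    data.frame(province = "north", lon = c(-180, 180, 180, -180),
               lat = c(0, 0, 90, 90)),
    data.frame(province = "south", lon = c(-180, 180, 180, -180),
               lat = c(-90, -90, 0, 0))
  )
  meta <- data.frame(province = c("north", "south"),
                     coastal = FALSE, basin = "atlantic")
  r <- rasterize_provinces(grid, polys, meta)
  joined <- dplyr::left_join(r$cells, grid$cells, by = "cell")
  expect_true(all(joined$province[joined$lat > 0] == "north"))
  expect_true(all(joined$province[joined$lat < 0] == "south"))
})

test_that("rasterisation matches a brute-force point-in-polygon oracle", {
  grid <- grid_spec(10, 10)
  set.seed(19)
  # an irregular convex-ish polygon in the western hemisphere
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- data.frame(province = "blob",
                     lon = -90 + 60 * cos(ang),
                     lat = 40 * sin(ang))
  meta <- data.frame(province = "blob", coastal = FALSE,
                     basin = "atlantic")
  r <- rasterize_provinces(grid, poly, meta)
  inside_oracle <- oracle_point_in_polygon(grid$cells$lon, grid$cells$lat,
                                           poly$lon, poly$lat)
  expect_equal(!is.na(r$cells$province), inside_oracle)
})

test_that("uncovered ocean cells fall back to the nearest province", {
  grid <- grid_spec(10, 10)
  polys <- data.frame(province = "west", lon = c(-180, 0, 0, -180),
                      lat = c(-90, -90, 90, 90))
  meta <- data.frame(province = "west", coastal = FALSE,
                     basin = "atlantic")
  expect_message(
    r <- rasterize_provinces(grid, polys, meta,
                             ocean = rep(TRUE, 100)),
    "nearest"
  )
  expect_true(all(r$cells$province == "west"))
})

test_that("cell medians follow the sort-based oracle", {
  grid <- grid_spec(10, 10)
  m1 <- data.frame(lat = 5, lon = 5, homolog = "PFOA", value = 42)
  expect_equal(cell_medians(m1, grid)$conc, 42)

  m3 <- data.frame(lat = 5, lon = 5, homolog = "PFOA",
                   value = c(10, 20, 90))
  expect_equal(cell_medians(m3, grid)$conc, 20)

  set.seed(8)
  mr <- data.frame(lat = runif(60, -80, 80), lon = runif(60, -170, 170),
                   homolog = "PFOA", value = rlnorm(60, 3, 1))
  cm <- cell_medians(mr, grid)
  mr$cell <- grid_locate(grid, mr$lon, mr$lat)
  oracle <- tapply(mr$value, mr$cell, stats::median)
  expect_equal(cm$conc, as.numeric(oracle[as.character(cm$cell)]))
})

test_that("censored field measurements are replaced by their study MDL", {
  grid <- grid_spec(10, 10)
  m <- data.frame(lat = 5, lon = 5, homolog = "PFOA",
                  value = c(0.01, 30), censored = c(TRUE, FALSE),
                  mdl = c(10, 10))
  expect_equal(cell_medians(m, grid)$conc, (10 + 30) / 2)
})

test_that("province quartiles follow the linear-interpolation convention", {
  grid <- grid_spec(10, 10)
  polys <- data.frame(province = "p", lon = c(-180, 180, 180, -180),
                      lat = c(-90, -90, 90, 90))
  meta <- data.frame(province = "p", coastal = FALSE, basin = "atlantic")
  r <- rasterize_provinces(grid, polys, meta)

  vals5 <- c(1, 2, 3, 4, 5)
  m <- data.frame(lat = seq(-40, 40, length.out = 5),
                  lon = seq(-40, 40, length.out = 5),
                  homolog = "PFOA", value = vals5)
  conc <- province_concentrations(cell_medians(m, grid), r)
  expect_equal(conc$mean, 3)
  expect_equal(conc$low, 2)
  expect_equal(conc$high, 4)

  vals4 <- c(2, 4, 8, 16)
  m4 <- data.frame(lat = seq(-40, 40, length.out = 4),
                   lon = seq(-40, 40, length.out = 4),
                   homolog = "PFOA", value = vals4)
  conc4 <- province_concentrations(cell_medians(m4, grid), r)
  expect_equal(conc4$mean, 6)
  expect_equal(conc4$low, oracle_quartile(vals4, 0.25))
  expect_equal(conc4$high, oracle_quartile(vals4, 0.75))

  const <- m4 |> transform(value = 9)
  concc <- province_concentrations(cell_medians(const, grid), r)
  expect_equal(c(concc$mean, concc$low, concc$high), c(9, 9, 9))
})

test_that("sparse provinces merge into their best-populated neighbour", {
  grid <- grid_spec(10, 10)
  polys <- rbind(
    data.frame(province = "rich", lon = c(-180, 0, 0, -180),
               lat = c(-90, -90, 90, 90)),
    data.frame(province = "poor", lon = c(0, 180, 180, 0),
               lat = c(-90, -90, 90, 90))
  )
  meta <- data.frame(province = c("rich", "poor"), coastal = FALSE,
                     basin = "atlantic")
  r <- rasterize_provinces(grid, polys, meta)
  m <- rbind(
    data.frame(lat = seq(-60, 60, length.out = 10), lon = -90,
               homolog = "PFOA", value = 50),
    data.frame(lat = c(-20, 30), lon = 90, homolog = "PFOA",
               value = c(200, 400))
  )
  med <- cell_medians(m, grid)
  merged <- merge_sparse_provinces(r, med)
  expect_equal(merged$merged_from,
               tibble::tibble(from = "poor", to = "rich"))
  expect_false(any(merged$cells$province == "poor", na.rm = TRUE))
  conc <- province_concentrations(med, merged)
  expect_equal(conc$provenance, "merged")
  expect_equal(conc$n_cells,
               dplyr::n_distinct(grid_locate(grid, m$lon, m$lat)))

  # nothing sparse -> identity
  m_ok <- rbind(m[1:10, ],
                data.frame(lat = c(-20, 0, 30), lon = 90,
                           homolog = "PFOA", value = 100))
  r2 <- merge_sparse_provinces(r, cell_medians(m_ok, grid))
  expect_equal(nrow(r2$merged_from), 0L)
  expect_equal(r2$cells, r$cells)

  # unmerged sparse province reaching concentration assignment errors
  expect_error(province_concentrations(med, r), "unmerged")
})

test_that("data-free provinces copy neighbours or Atlantic latitude bands", {
  grid <- grid_spec(10, 10)
  polys <- rbind(
    data.frame(province = "atl_mid", lon = c(-60, 0, 0, -60),
               lat = c(20, 20, 50, 50)),
    data.frame(province = "atl_south", lon = c(-60, 0, 0, -60),
               lat = c(-90, -90, 20, 20)),
    data.frame(province = "atl_north", lon = c(-60, 0, 0, -60),
               lat = c(50, 50, 90, 90)),
    data.frame(province = "coastal_east", lon = c(0, 30, 30, 0),
               lat = c(-90, -90, 90, 90)),
    data.frame(province = "pac_band", lon = c(90, 150, 150, 90),
               lat = c(20, 20, 50, 50))
  )
  meta <- data.frame(
    province = c("atl_mid", "atl_south", "atl_north", "coastal_east",
                 "pac_band"),
    coastal = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    basin = c("atlantic", "atlantic", "atlantic", "atlantic", "pacific")
  )
  r <- rasterize_provinces(grid, polys, meta)
  m <- rbind(
    data.frame(lat = c(25, 35, 45, 30), lon = c(-50, -40, -30, -20),
               homolog = "PFOA", value = c(10, 20, 30, 40)),
    data.frame(lat = c(-30, -40, -50, -60), lon = c(-50, -40, -30, -20),
               homolog = "PFOA", value = c(1, 2, 3, 4))
  )
  conc <- province_concentrations(cell_medians(m, grid), r)
  full <- fallback_concentrations(r, conc)

  # coastal province with a populated noncoastal neighbour copies it
  ce <- full[full$province == "coastal_east", ]
  expect_equal(ce$provenance, "neighbor_fallback")
  expect_equal(ce$mean, conc$mean[conc$province == "atl_south"])

  # isolated pacific band takes the Atlantic band at matching latitudes
  pb <- full[full$province == "pac_band", ]
  expect_equal(pb$provenance, "latitude_fallback")
  expect_equal(pb$mean, conc$mean[conc$province == "atl_mid"])

  # atl_north has no data; its populated neighbour atl_mid is the donor
  an <- full[full$province == "atl_north", ]
  expect_equal(an$provenance, "neighbor_fallback")
  expect_equal(an$mean, conc$mean[conc$province == "atl_mid"])

  # fully populated table passes through unchanged
  expect_identical(fallback_concentrations(r, full), full)
})

test_that("a 3x3 island yields one inland and eight coastal land cells", {
  iw <- make_island_world()
  mask <- classify_cells(iw$grid, iw$land, iw$coastline)
  expect_equal(sum(mask$land), 9)
  expect_equal(sum(mask$inland), 1)
  expect_equal(sum(mask$land & mask$coast), 8)
  # the inland cell is the centre of the 5x5 grid
  centre <- iw$grid$cells$cell[iw$grid$cells$i == 3 & iw$grid$cells$j == 3]
  expect_true(mask$inland[mask$cell == centre])
  expect_true(all(mask$inland == (mask$land & !mask$coast)))
})

test_that("an all-ocean world has empty masks", {
  grid <- grid_spec(5, 5)
  empty <- data.frame(id = character(), lon = numeric(), lat = numeric())
  mask <- classify_cells(grid, empty, empty)
  expect_false(any(mask$land | mask$coast | mask$inland))
})

test_that("coastal extension follows a queen-dilation BFS oracle", {
  iw <- make_island_world()
  grid <- iw$grid
  mask <- classify_cells(grid, iw$land, iw$coastline)
  # one coastal province covering the ocean ring
  polys <- data.frame(province = "ring", lon = c(-180, 180, 180, -180),
                      lat = c(-90, -90, 90, 90))
  meta <- data.frame(province = "ring", coastal = TRUE, basin = "atlantic")
  r <- rasterize_provinces(grid, polys, meta, ocean = !mask$land)

  # n = 0: no land cell carries a deposition province
  dep0 <- extend_coastal(r, mask, n = 0)
  expect_true(all(is.na(dep0$dep_province[mask$land])))

  # n = 2 covers exactly the 2-step dilation of the province cells
  dep2 <- extend_coastal(r, mask, n = 2)
  seeds <- cbind(grid$cells$i, grid$cells$j)[!is.na(r$cells$province), ]
  reach <- oracle_dilate(seeds, grid$nlat, grid$nlon, 2)
  reach_cells <- (reach[, 1] - 1) * grid$nlon + reach[, 2]
  covered_land <- mask$cell[mask$land &
                              mask$cell %in% reach_cells]
  got <- dep2$cell[mask$land & !is.na(dep2$dep_province)]
  expect_setequal(got, covered_land)
})

test_that("equidistant inland cells break ties to the smaller province id", {
  grid <- grid_spec(5, 9)
  # land band across the middle latitude row, ocean north and south
  cells <- grid$cells
  land_mask <- cells$i == 3
  mask <- tibble::tibble(cell = cells$cell, land = land_mask,
                         coast = FALSE, inland = land_mask)
  r <- structure(list(
    grid = grid,
    cells = tibble::tibble(
      cell = cells$cell,
      province = dplyr::case_when(cells$i < 3 ~ "bbb",
                                  cells$i > 3 ~ "aaa",
                                  TRUE ~ NA_character_)),
    meta = tibble::tibble(province = c("aaa", "bbb"), coastal = FALSE,
                          basin = "atlantic"),
    merged_from = tibble::tibble(from = character(), to = character())),
    class = "province_raster")
  dep <- extend_coastal(r, mask, n = 2)
  expect_true(all(dep$dep_province[land_mask] == "aaa"))
})

test_that("longitude wrap makes provinces at the dateline adjacent", {
  grid <- grid_spec(6, 12)
  polys <- rbind(
    data.frame(province = "west_edge", lon = c(-180, -150, -150, -180),
               lat = c(-90, -90, 90, 90)),
    data.frame(province = "east_edge", lon = c(150, 180, 180, 150),
               lat = c(-90, -90, 90, 90)),
    data.frame(province = "middle", lon = c(-150, 150, 150, -150),
               lat = c(-90, -90, 90, 90))
  )
  meta <- data.frame(province = c("west_edge", "east_edge", "middle"),
                     coastal = FALSE, basin = "pacific")
  r <- rasterize_provinces(grid, polys, meta)
  adj <- seasprayr:::province_adjacency(r)
  expect_true(any(adj$province == "west_edge" &
                    adj$neighbour == "east_edge"))
})

test_that("scenario triples scale linearly with the measurements", {
  grid <- grid_spec(10, 10)
  polys <- data.frame(province = "p", lon = c(-180, 180, 180, -180),
                      lat = c(-90, -90, 90, 90))
  meta <- data.frame(province = "p", coastal = FALSE, basin = "atlantic")
  r <- rasterize_provinces(grid, polys, meta)
  set.seed(2)
  m <- data.frame(lat = runif(12, -60, 60), lon = runif(12, -170, 170),
                  homolog = "PFOA", value = rlnorm(12, 4, 1))
  c1 <- province_concentrations(cell_medians(m, grid), r)
  m2 <- m; m2$value <- m$value * 7
  c2 <- province_concentrations(cell_medians(m2, grid), r)
  expect_equal(c2$mean, 7 * c1$mean)
  expect_equal(c2$low, 7 * c1$low)
  expect_equal(c2$high, 7 * c1$high)
})
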