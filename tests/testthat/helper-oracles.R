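# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force through-origin orthogonal regression: minimise the summed
# squared orthogonal distances over the line angle, then locate the zero of
# the numerical derivative. Independent of the closed-form solution.
oracle_tls_slope <- function(x, y) {
  f <- function(theta) {
    s <- tan(theta)
    sum((y - s * x)^2) / (1 + s^2)
  }
  opt <- optimize(f, interval = c(-pi / 2 + 1e-9, pi / 2 - 1e-9),
                  tol = 1e-10)
  h <- 1e-7
  df <- function(theta) (f(theta + h) - f(theta - h)) / (2 * h)
  lo <- opt$minimum - 1e-4
  hi <- opt$minimum + 1e-4
  if (df(lo) < 0 && df(hi) > 0) {
    theta <- uniroot(df, c(lo, hi), tol = 1e-13)$root
  } else {
    theta <- opt$minimum
  }
  tan(theta)
}

# Sort-based quartile oracle (linear interpolation between order
# statistics, matching the documented convention).
oracle_quartile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Even-odd point-in-polygon by an independent method: sum of signed angles
# (winding number).
oracle_point_in_polygon <- function(px, py, poly_x, poly_y) {
  vapply(seq_along(px), function(k) {
    dx <- poly_x - px[k]
    dy <- poly_y - py[k]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# Queen-neighbourhood BFS dilation oracle on an explicit (i, j) lattice
# with longitude wrap; returns the set of cells within `n` steps of any
# seed cell.
oracle_dilate <- function(seeds_ij, nlat, nlon, n) {
  current <- unique(seeds_ij)
  all_cells <- current
  for (step in seq_len(n)) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(current)), function(r) {
      i <- current[r, 1]; j <- current[r, 2]
      expand.grid(i = i + (-1:1), j = j + (-1:1))
    }))
    nxt$j <- (nxt$j - 1) %% nlon + 1
    nxt <- nxt[nxt$i >= 1 & nxt$i <= nlat, ]
    nxt <- unique(as.matrix(nxt))
    new <- nxt[!paste(nxt[, 1], nxt[, 2]) %in%
                 paste(all_cells[, 1], all_cells[, 2]), , drop = FALSE]
    if (!nrow(new)) break
    all_cells <- rbind(all_cells, new)
    current <- new
  }
  all_cells
}

# A small hand-built chamber campaign with exact, planted censoring:
# 2 homologs x 2 fractions x n experiments, constant Na, known true EFs.
make_tiny_chamber <- function(n_exp = 6, ef_true = c(A = 100, B = 1000),
                              water_conc = NULL,
                              mdl_water = 0, mdl_ssa = 0,
                              water_na = 10, ssa_na = 5) {
  exps <- sprintf("E%02d", seq_len(n_exp))
  homologs <- names(ef_true)
  if (is.null(water_conc)) {
    water_conc <- seq(10, 10 * n_exp, length.out = n_exp)
  }
  water <- do.call(rbind, lapply(seq_along(exps), function(e) {
    expand.grid(experiment = exps[e], homolog = homologs,
                replicate = 1:3, stringsAsFactors = FALSE)
  }))
  water$conc <- water_conc[match(water$experiment, exps)]
  water$censored <- water$conc < mdl_water
  ssa <- expand.grid(experiment = exps, homolog = homologs, fraction = 1:2,
                     stringsAsFactors = FALSE)
  ssa$conc <- ef_true[ssa$homolog] *
    (water_conc[match(ssa$experiment, exps)] / water_na) * ssa_na
  ssa$censored <- ssa$conc < mdl_ssa
  chamber_data(
    water = water,
    ssa = ssa,
    water_na = data.frame(experiment = exps, na_conc = water_na),
    ssa_na = expand.grid(experiment = exps, fraction = 1:2) |>
      transform(na_conc = ssa_na),
    mdl_water = data.frame(homolog = homologs, mdl = mdl_water),
    mdl_ssa = expand.grid(homolog = homologs, fraction = 1:2) |>
      transform(mdl = mdl_ssa)
  )
}

# A 5x5 grid holding a single 3x3-cell island, with the land polygon and
# its boundary coastline placed strictly inside the outer cell ring.
make_island_world <- function() {
  grid <- grid_spec(5, 5)
  cells <- grid$cells
  # island spans the inner 3x3 cells: strictly inside the outer ring
  lon_lo <- cells$lon_lo[cells$j == 2][1] + 1
  lon_hi <- cells$lon_hi[cells$j == 4][1] - 1
  lat_lo <- cells$lat_lo[cells$i == 2][1] + 1
  lat_hi <- cells$lat_hi[cells$i == 4][1] - 1
  land <- data.frame(id = "isle",
                     lon = c(lon_lo, lon_hi, lon_hi, lon_lo),
                     lat = c(lat_lo, lat_lo, lat_hi, lat_hi))
  coastline <- rbind(land, land[1, ])
  list(grid = grid, land = land, coastline = coastline)
}

default_world <- function(seed = 3) {
  w <- gen_grid_world(world_config(seed = seed))
  world <- suppressMessages(build_world(
    w$grid, w$polygons, w$meta, w$land, w$coastline, w$measurements,
    salt_monthly = w$salt_monthly,
    salt_wet_dep = w$salt_wet_dep, salt_dry_dep = w$salt_dry_dep
  ))
  list(raw = w, world = world)
}
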