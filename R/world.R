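# The gridded world: province raster, concentration assignment with the
# merging and fallback rules, land/coast/inland classification, and the
# two-cell coastal extension used for deposition concentrations.

#' Rasterise ocean provinces onto a grid
#'
#' Assigns every ocean cell the province whose polygon contains its centre.
#' Cells whose centre falls in several polygons (boundary cases) are broken
#' by the largest sampled overlap (a `sample_k` x `sample_k` subgrid of
#' points per cell), then lexicographic province id. Ocean cells covered by
#' no polygon are assigned the nearest assigned province by breadth-first
#' search over the queen-adjacent (longitude-wrapping) grid and reported
#' via `message()`.
#'
#' @param grid A [grid_spec()].
#' @param polygons Tibble of province polygons: `province`, `lon`, `lat`
#'   (ordered vertices per province).
#' @param meta Tibble of province metadata: `province`, `coastal` (logical),
#'   `basin` (e.g. `"atlantic"`).
#' @param ocean Optional logical vector (one per cell): which cells are
#'   ocean and must receive a province. Default: cells whose centre lies in
#'   at least one polygon.
#' @param sample_k Side of the overlap-sampling subgrid (default 8).
#' @return An object of class `province_raster`: list with `grid`, `cells`
#'   (tibble `cell`, `province`), `meta`, and `merged_from` (empty mapping).
#' @export
rasterize_provinces <- function(grid, polygons, meta, ocean = NULL,
                                sample_k = 8) {
  cells <- grid$cells
  ids <- sort(unique(polygons$province))
  if (!all(ids %in% meta$province)) {
    abort("every polygon province needs a row in `meta`")
  }

  polys <- split(polygons, polygons$province)[ids]
  hits <- lapply(polys, function(p) {
    point_in_polygon(cells$lon, cells$lat, p$lon, p$lat)
  })
  hitmat <- do.call(cbind, hits)
  nhit <- rowSums(hitmat)

  assigned <- rep(NA_character_, nrow(cells))
  one <- which(nhit == 1)
  assigned[one] <- ids[apply(hitmat[one, , drop = FALSE], 1, which.max)]

  for (k in which(nhit > 1)) {
    cand <- ids[hitmat[k, ]]
    xs <- seq(cells$lon_lo[k], cells$lon_hi[k], length.out = sample_k + 2)
    ys <- seq(cells$lat_lo[k], cells$lat_hi[k], length.out = sample_k + 2)
    xs <- xs[-c(1, length(xs))]; ys <- ys[-c(1, length(ys))]
    pts <- tidyr::expand_grid(x = xs, y = ys)
    ov <- vapply(cand, function(id) {
      sum(point_in_polygon(pts$x, pts$y, polys[[id]]$lon, polys[[id]]$lat))
    }, numeric(1))
    assigned[k] <- cand[order(-ov, cand)][1]
  }

  if (is.null(ocean)) ocean <- nhit > 0
  orphans <- which(ocean & is.na(assigned))
  if (length(orphans)) {
    lab <- bfs_label(grid,
                     seeds = tibble(cell = which(!is.na(assigned)),
                                    label = assigned[!is.na(assigned)]),
                     allowed = ocean | !is.na(assigned))
    assigned[orphans] <- lab$label[match(orphans, lab$cell)]
    rlang::inform(sprintf(
      "%d ocean cell(s) outside all province polygons assigned to nearest province",
      length(orphans)))
  }
  assigned[!ocean] <- NA_character_

  structure(
    list(grid = grid,
         cells = tibble(cell = cells$cell, province = assigned),
         meta = as_tibble(meta),
         merged_from = tibble(from = character(), to = character())),
    class = "province_raster"
  )
}

#' @export
print.province_raster <- function(x, ...) {
  cat("<province_raster>\n")
  cat("  provinces:", dplyr::n_distinct(stats::na.omit(x$cells$province)),
      "\n")
  cat("  ocean cells:", sum(!is.na(x$cells$province)), "of",
      nrow(x$cells), "\n")
  if (nrow(x$merged_from)) {
    cat("  merged:", paste(x$merged_from$from, "->", x$merged_from$to,
                           collapse = "; "), "\n")
  }
  invisible(x)
}

# Deterministic multi-source BFS over the grid. `seeds` is a tibble
# (cell, label); labels spread one ring per step through `allowed` cells
# (queen adjacency, longitude wrap). Equidistant cells take the
# lexicographically smallest neighbouring label. Returns (cell, label,
# depth) for every cell reached within `max_depth`.
#' @noRd
bfs_label <- function(grid, seeds, allowed = NULL, max_depth = Inf,
                      queen = TRUE) {
  ncell <- grid$nlat * grid$nlon
  if (is.null(allowed)) allowed <- rep(TRUE, ncell)
  nb <- grid_neighbours(grid, queen = queen)
  label <- rep(NA_character_, ncell)
  depth <- rep(NA_integer_, ncell)
  seeds <- seeds %>% arrange(.data$cell, .data$label) %>%
    distinct(.data$cell, .keep_all = TRUE)
  label[seeds$cell] <- seeds$label
  depth[seeds$cell] <- 0L
  frontier <- seeds$cell
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    cand <- unique(unlist(nb[frontier]))
    cand <- cand[is.na(label[cand]) & allowed[cand]]
    if (!length(cand)) break
    newlab <- vapply(cand, function(cc) {
      ls <- label[nb[[cc]]]
      min(ls[!is.na(ls) & depth[nb[[cc]]] == d - 1L])
    }, character(1))
    label[cand] <- newlab
    depth[cand] <- d
    frontier <- cand
  }
  keep <- !is.na(label)
  tibble(cell = which(keep), label = label[keep], depth = depth[keep])
}

#' Per-cell medians of located seawater measurements
#'
#' Bins located field measurements onto the grid; where several
#' measurements share a cell the median is used. If the table carries
#' `censored` and `mdl` columns, censored values are replaced by the
#' reporting study's MDL first.
#'
#' @param measurements Tibble: `lat`, `lon`, `homolog`, `value` (pg L^-1),
#'   optionally `censored`, `mdl`.
#' @param grid A [grid_spec()].
#' @return Tibble `cell`, `homolog`, `conc`, `n_meas`.
#' @export
cell_medians <- function(measurements, grid) {
  m <- as_tibble(measurements)
  if (all(c("censored", "mdl") %in% names(m))) {
    m <- m %>% mutate(value = ifelse(.data$censored, .data$mdl, .data$value))
  }
  m %>%
    mutate(cell = grid_locate(grid, .data$lon, .data$lat)) %>%
    group_by(.data$cell, .data$homolog) %>%
    summarise(conc = median(.data$value), n_meas = dplyr::n(),
              .groups = "drop")
}

# Province adjacency: provinces sharing at least one raster cell edge
# (rook neighbours, wrapping in longitude). Returns tibble (province,
# neighbour).
#' @noRd
province_adjacency <- function(raster) {
  grid <- raster$grid
  nb <- grid_neighbours(grid, queen = FALSE)
  prov <- raster$cells$province
  pairs <- purrr::map_dfr(which(!is.na(prov)), function(cc) {
    nn <- nb[[cc]]
    nn <- nn[!is.na(prov[nn]) & prov[nn] != prov[cc]]
    if (!length(nn)) return(NULL)
    tibble(province = prov[cc], neighbour = prov[nn])
  })
  distinct(pairs)
}

#' Merge provinces with sparse concentration data
#'
#' Provinces whose measurements occupy fewer than `min_cells` grid cells
#' (but at least one) are merged into the adjacent province with the
#' greatest number of occupied cells, iterating until none remain below the
#' threshold or no adjacent province has data. Adjacency is sharing a cell
#' edge; ties are broken by lexicographic province id; the smallest-count
#' province is processed first so the fixed point is order-independent.
#' Provinces with no data at all are left for [fallback_concentrations()].
#'
#' @param raster A [rasterize_provinces()] result.
#' @param medians Output of [cell_medians()].
#' @param min_cells Occupied-cell threshold (default 3).
#' @return The raster with merged provinces relabelled; the `merged_from`
#'   mapping records every absorbed province.
#' @export
merge_sparse_provinces <- function(raster, medians, min_cells = 3) {
  occupied <- medians %>%
    semi_join(raster$cells %>% filter(!is.na(.data$province)), by = "cell") %>%
    distinct(.data$cell)

  mapping <- raster$merged_from
  repeat {
    prov <- raster$cells$province
    counts <- tibble(cell = raster$cells$cell, province = prov) %>%
      filter(!is.na(.data$province)) %>%
      semi_join(occupied, by = "cell") %>%
      dplyr::count(.data$province, name = "n_cells")
    all_prov <- sort(unique(stats::na.omit(prov)))
    counts <- tibble(province = all_prov) %>%
      left_join(counts, by = "province") %>%
      mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L))

    sparse <- counts %>%
      filter(.data$n_cells >= 1L, .data$n_cells < min_cells) %>%
      arrange(.data$n_cells, .data$province)
    if (!nrow(sparse)) break

    adj <- province_adjacency(raster)
    done <- TRUE
    for (p in sparse$province) {
      nbs <- adj$neighbour[adj$province == p]
      cand <- counts %>%
        filter(.data$province %in% nbs, .data$n_cells >= 1L) %>%
        arrange(-.data$n_cells, .data$province)
      if (!nrow(cand)) next
      target <- cand$province[1]
      raster$cells$province[raster$cells$province %in% p] <- target
      mapping <- bind_rows(mapping, tibble(from = p, to = target)) %>%
        mutate(to = ifelse(.data$to == p, target, .data$to))
      done <- FALSE
      break
    }
    if (done) break
  }
  raster$merged_from <- mapping
  raster
}

#' Scenario concentrations per province
#'
#' For every province x homolog with data in at least `min_cells` grid
#' cells, the mean scenario takes the median of the occupied-cell values,
#' and the low/high scenarios the first and third quartiles (linear
#' interpolation between order statistics, quantile type 7). Provinces that
#' absorbed others through merging are flagged `"merged"`, the rest
#' `"measured"`.
#'
#' @param medians Output of [cell_medians()].
#' @param raster A (possibly merged) `province_raster`.
#' @param min_cells Data threshold (default 3).
#' @param drop_sparse If `TRUE`, provinces still below the threshold are
#'   dropped (they are completed by [fallback_concentrations()]); if
#'   `FALSE` (default) they are an error, since they should have been
#'   merged first.
#' @return Tibble `province`, `homolog`, `mean`, `low`, `high`, `n_cells`,
#'   `provenance`.
#' @export
province_concentrations <- function(medians, raster, min_cells = 3,
                                    drop_sparse = FALSE) {
  d <- medians %>%
    inner_join(raster$cells, by = "cell") %>%
    filter(!is.na(.data$province))
  out <- d %>%
    group_by(.data$province, .data$homolog) %>%
    summarise(
      mean = median(.data$conc),
      low = quantile(.data$conc, 0.25, names = FALSE, type = 7),
      high = quantile(.data$conc, 0.75, names = FALSE, type = 7),
      n_cells = dplyr::n_distinct(.data$cell),
      .groups = "drop"
    )
  sparse <- out %>%
    group_by(.data$province) %>%
    summarise(n = max(.data$n_cells), .groups = "drop") %>%
    filter(.data$n < min_cells)
  if (nrow(sparse)) {
    if (!drop_sparse) {
      abort(sprintf(
        "province(s) below the %d-cell data threshold reached concentration assignment unmerged: %s",
        min_cells, paste(sparse$province, collapse = ", ")))
    }
    out <- out %>% filter(!.data$province %in% sparse$province)
  }
  merged_into <- unique(raster$merged_from$to)
  out %>%
    mutate(provenance = ifelse(.data$province %in% merged_into,
                               "merged", "measured")) %>%
    arrange(.data$province, .data$homolog)
}

#' Complete the concentration table for data-free provinces
#'
#' Provinces without concentration data take the scenario triple of an
#' adjacent noncoastal province with data (the one with the most occupied
#' cells; lexicographic tie-break), or, when no neighbouring province has
#' data, of the Atlantic province whose latitude band overlaps theirs the
#' most. Provenance is recorded as `"neighbor_fallback"` or
#' `"latitude_fallback"`.
#'
#' @param raster A `province_raster`.
#' @param conc Output of [province_concentrations()].
#' @return The completed tibble (same columns), covering every province in
#'   the raster.
#' @export
fallback_concentrations <- function(raster, conc) {
  all_prov <- sort(unique(stats::na.omit(raster$cells$province)))
  have <- unique(conc$province)
  missing <- setdiff(all_prov, have)
  if (!length(missing)) return(conc)

  meta <- raster$meta
  adj <- province_adjacency(raster)
  counts <- conc %>%
    group_by(.data$province) %>%
    summarise(n_cells = max(.data$n_cells), .groups = "drop")

  lat_range <- raster$cells %>%
    filter(!is.na(.data$province)) %>%
    inner_join(raster$grid$cells %>% select("cell", "lat_lo", "lat_hi"),
               by = "cell") %>%
    group_by(.data$province) %>%
    summarise(lat_lo = min(.data$lat_lo), lat_hi = max(.data$lat_hi),
              .groups = "drop")

  atlantic <- meta %>%
    filter(.data$basin == "atlantic", .data$province %in% have) %>%
    pull(.data$province)

  added <- purrr::map_dfr(missing, function(p) {
    nbs <- adj$neighbour[adj$province == p]
    noncoastal <- meta$province[!meta$coastal]
    cand <- counts %>%
      filter(.data$province %in% intersect(nbs, noncoastal)) %>%
      arrange(-.data$n_cells, .data$province)
    if (nrow(cand)) {
      donor <- cand$province[1]
      prov <- "neighbor_fallback"
    } else {
      if (!length(atlantic)) {
        abort(sprintf("province %s has no data, no populated neighbour and no Atlantic reference", p))
      }
      me <- lat_range %>% filter(.data$province == p)
      ov <- lat_range %>%
        filter(.data$province %in% atlantic) %>%
        mutate(overlap = pmax(0, pmin(.data$lat_hi, me$lat_hi) -
                                pmax(.data$lat_lo, me$lat_lo))) %>%
        arrange(-.data$overlap, .data$province)
      if (!nrow(ov) || max(ov$overlap) <= 0) {
        # no overlapping band: fall back to the closest band edge
        ov <- ov %>%
          mutate(gap = pmax(.data$lat_lo - me$lat_hi,
                            me$lat_lo - .data$lat_hi)) %>%
          arrange(.data$gap, .data$province)
      }
      donor <- ov$province[1]
      prov <- "latitude_fallback"
    }
    conc %>%
      filter(.data$province == donor) %>%
      mutate(province = p, provenance = prov, n_cells = 0L)
  })

  bind_rows(conc, added) %>% arrange(.data$province, .data$homolog)
}

#' Classify grid cells as land, coast and inland
#'
#' Cells whose rectangle intersects a land polygon are land cells; cells
#' intersecting the coastline polylines are coast cells (this can include
#' ocean-side cells touching the coastline); land cells that do not touch
#' the coastline are inland cells.
#'
#' @param grid A [grid_spec()].
#' @param land Tibble of land polygons: `id`, `lon`, `lat`.
#' @param coastline Tibble of coastline polylines: `id`, `lon`, `lat`.
#' @return Tibble `cell`, `land`, `coast`, `inland`.
#' @export
classify_cells <- function(grid, land, coastline) {
  cells <- grid$cells
  land_polys <- if (nrow(land)) split(land, land$id) else list()
  coast_lines <- if (nrow(coastline)) split(coastline, coastline$id) else
    list()

  land_hit <- vapply(seq_len(nrow(cells)), function(k) {
    any(vapply(land_polys, polygon_intersects_rect,
               logical(1),
               cells$lon_lo[k], cells$lon_hi[k],
               cells$lat_lo[k], cells$lat_hi[k]))
  }, logical(1))
  coast_hit <- vapply(seq_len(nrow(cells)), function(k) {
    any(vapply(coast_lines, polyline_intersects_rect,
               logical(1),
               cells$lon_lo[k], cells$lon_hi[k],
               cells$lat_lo[k], cells$lat_hi[k]))
  }, logical(1))

  tibble(cell = cells$cell, land = land_hit, coast = coast_hit,
         inland = land_hit & !coast_hit)
}

#' Extend coastal-province concentrations inland
#'
#' Builds the deposition-concentration province assignment: ocean cells
#' keep their own province; land cells within `n` queen-dilation steps of a
#' cell belonging to a coastal province take that province (nearest source
#' wins, lexicographic id on ties); all remaining land cells take the
#' nearest noncoastal province (again by BFS distance, lexicographic on
#' ties).
#'
#' @param raster A `province_raster`.
#' @param mask Output of [classify_cells()].
#' @param n Dilation depth in cells (default 2).
#' @return Tibble `cell`, `dep_province` (`NA` only if the grid has no
#'   provinces at all).
#' @export
extend_coastal <- function(raster, mask, n = 2) {
  grid <- raster$grid
  prov <- raster$cells$province
  coastal_ids <- raster$meta$province[raster$meta$coastal]
  land <- mask$land[match(seq_along(prov), mask$cell)]

  dep <- prov
  if (n > 0 && any(!is.na(prov) & prov %in% coastal_ids)) {
    seeds <- tibble(cell = which(!is.na(prov) & prov %in% coastal_ids),
                    label = prov[!is.na(prov) & prov %in% coastal_ids])
    ext <- bfs_label(grid, seeds, allowed = land | !is.na(prov),
                     max_depth = n)
    ext <- ext %>% filter(.data$depth > 0, land[.data$cell],
                          is.na(prov[.data$cell]))
    dep[ext$cell] <- ext$label
  }

  noncoastal_cells <- which(!is.na(prov) & !(prov %in% coastal_ids))
  rest <- which(land & is.na(dep))
  if (length(rest) && length(noncoastal_cells)) {
    lab <- bfs_label(grid, tibble(cell = noncoastal_cells,
                                  label = prov[noncoastal_cells]))
    dep[rest] <- lab$label[match(rest, lab$cell)]
  }
  tibble(cell = raster$cells$cell, dep_province = dep)
}
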