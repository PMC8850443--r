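#' Half-degree climate grid
#'
#' A lat/lon raster of climate normals on the standard half-degree grid with
#' cell centers at `±0.25 + k·0.5`. Values are either annual mean temperature
#' (degrees C) or annual total precipitation (mm).
#'
#' @param values Numeric matrix, rows = latitudes (south to north),
#'   columns = longitudes (west to east). `NA` marks masked (e.g. ocean) cells.
#' @param lats,lons Cell-center coordinates, ascending, step 0.5.
#' @param variable `"annual_mean_temp_C"` or `"annual_total_precip_mm"`.
#' @param period_label Free-text label, e.g. `"2001-2010"`.
#' @return Object of class `climate_grid`.
#' @export
climate_grid <- function(values, lats, lons,
                         variable = c("annual_mean_temp_C",
                                      "annual_total_precip_mm"),
                         period_label = "") {
  variable <- match.arg(variable)
  values <- as.matrix(values)
  if (nrow(values) != length(lats) || ncol(values) != length(lons)) {
    stop("grid dimensions do not match coordinate vectors")
  }
  check_half_degree(lats, "lats")
  check_half_degree(lons, "lons")
  v <- values[!is.na(values)]
  if (variable == "annual_mean_temp_C" && length(v) &&
      (min(v) < -90 || max(v) > 60)) {
    stop("temperature values outside [-90, 60] degrees C")
  }
  if (variable == "annual_total_precip_mm" && length(v) && min(v) < 0) {
    stop("negative precipitation")
  }
  structure(list(values = values, lats = as.numeric(lats),
                 lons = as.numeric(lons), variable = variable,
                 period_label = period_label),
            class = "climate_grid")
}

check_half_degree <- function(x, what) {
  if (length(x) > 1 && any(abs(diff(x) - 0.5) > 1e-9)) {
    stop(what, " must ascend in 0.5-degree steps")
  }
  if (any(abs((x - 0.25) %% 0.5) > 1e-9)) {
    stop(what, " must be half-degree cell centers (0.25 + k*0.5)")
  }
}

#' Harvested-area weight grid
#'
#' Harvested area (ha) per half-degree cell, used to weight climate normals
#' toward growing regions when aggregating over countries.
#'
#' @param harvested_area Non-negative matrix, same geometry as the paired
#'   [climate_grid()].
#' @param lats,lons Cell-center coordinates.
#' @return Object of class `weight_grid`.
#' @export
weight_grid <- function(harvested_area, lats, lons) {
  harvested_area <- as.matrix(harvested_area)
  if (any(harvested_area < 0, na.rm = TRUE)) stop("negative harvested area")
  if (nrow(harvested_area) != length(lats) ||
      ncol(harvested_area) != length(lons)) {
    stop("grid dimensions do not match coordinate vectors")
  }
  check_half_degree(lats, "lats")
  check_half_degree(lons, "lons")
  structure(list(harvested_area = harvested_area, lats = as.numeric(lats),
                 lons = as.numeric(lons)),
            class = "weight_grid")
}

#' Climate normals from a multi-year series
#'
#' Averages per-cell annual values over a window of years, producing the
#' climate-normal grid (e.g. the 2001-2010 mean annual temperature used as
#' the current temperature level).
#'
#' @param series 3-d array `lat x lon x year` of annual values, with year
#'   labels in `dimnames(series)[[3]]`.
#' @param lats,lons Cell-center coordinates.
#' @param window Integer years to average over, e.g. `2001:2010`.
#' @param variable,period_label Passed to [climate_grid()].
#' @return A [climate_grid()] of window means.
#' @export
build_climatology <- function(series, lats, lons, window,
                              variable = "annual_mean_temp_C",
                              period_label = paste(range(window),
                                                   collapse = "-")) {
  years <- as.integer(dimnames(series)[[3]])
  if (is.null(years)) stop("series must carry year labels in dimnames")
  if (!all(window %in% years)) {
    stop("window years outside series coverage: ",
         paste(setdiff(window, years), collapse = ", "))
  }
  sel <- series[, , match(window, years), drop = FALSE]
  m <- apply(sel, c(1, 2), mean)
  climate_grid(m, lats, lons, variable = variable,
               period_label = period_label)
}

# row/col of the half-degree cell containing (lat, lon); coordinates exactly
# on a cell boundary resolve to the cell north-east of the corner
cell_index <- function(grid, lat, lon) {
  if (lat < -90 || lat > 90 || lon < -180 || lon > 180) {
    stop("coordinates out of range")
  }
  i <- floor((lat - (grid$lats[1] - 0.25)) / 0.5) + 1
  j <- floor((lon - (grid$lons[1] - 0.25)) / 0.5) + 1
  i <- min(max(i, 1), length(grid$lats)) # top edge of the last cell
  j <- min(max(j, 1), length(grid$lons))
  if (abs(grid$lats[i] - lat) > 0.25 + 1e-9 ||
      abs(grid$lons[j] - lon) > 0.25 + 1e-9) {
    stop("coordinates outside grid extent")
  }
  c(i, j)
}

#' Extract the grid value at a point
#'
#' Returns the value of the half-degree cell containing the coordinate, the
#' extraction used to attach current climate levels to simulation sites.
#'
#' @param grid A [climate_grid()].
#' @param lat,lon Coordinates in degrees.
#' @return The cell value. Masked (missing-data) cells raise an error.
#' @export
extract_point <- function(grid, lat, lon) {
  ij <- cell_index(grid, lat, lon)
  v <- grid$values[ij[1], ij[2]]
  if (is.na(v)) stop("point falls in a missing-data (masked) cell")
  v
}

#' Harvested-area-weighted mean over a cell set
#'
#' `sum(w * v) / sum(w)` over the masked cells, the aggregation used to
#' compute growing-area-weighted current climate for countries whose
#' centroid poorly represents the cropped area.
#'
#' @param grid A [climate_grid()].
#' @param weights A [weight_grid()] with matching geometry.
#' @param mask Logical matrix (same shape) selecting cells, or a 2-column
#'   matrix of (row, col) indices.
#' @return Weighted mean; always within the range of the masked values.
#' @export
area_weighted_mean <- function(grid, weights, mask) {
  if (!identical(dim(grid$values), dim(weights$harvested_area))) {
    stop("grid and weight geometries differ")
  }
  if (is.matrix(mask) && ncol(mask) == 2 && !is.logical(mask)) {
    sel <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
    sel[mask] <- TRUE
    mask <- sel
  }
  if (!any(mask)) stop("empty mask")
  v <- grid$values[mask]
  w <- weights$harvested_area[mask]
  keep <- !is.na(v) & !is.na(w)
  tw <- sum(w[keep])
  if (!is.finite(tw) || tw <= 0) stop("zero total weight over mask")
  sum(w[keep] * v[keep]) / tw
}

#' Scenario CO2-concentration trajectory
#'
#' @param scenario Scenario label, e.g. `"RCP8.5"`.
#' @param years,ppm Tabulated concentration points; years strictly
#'   increasing, at least two points, ppm positive.
#' @return Object of class `scenario_trajectory`.
#' @export
scenario_trajectory <- function(scenario, years, ppm) {
  if (length(years) < 2) stop("need at least 2 points for interpolation")
  if (any(diff(years) <= 0)) stop("years must strictly increase")
  if (any(ppm <= 0)) stop("ppm must be positive")
  structure(list(scenario = scenario, years = as.numeric(years),
                 ppm = as.numeric(ppm)),
            class = "scenario_trajectory")
}

#' CO2 concentration for a year under a scenario
#'
#' Exact table value at tabulated years, linear interpolation between; no
#' extrapolation outside the tabulated span.
#'
#' @param trajectory A [scenario_trajectory()].
#' @param year Year(s) within the trajectory span.
#' @return ppm. Vectorized over `year`.
#' @export
co2_concentration <- function(trajectory, year) {
  if (any(year < trajectory$years[1] |
          year > trajectory$years[length(trajectory$years)])) {
    stop("year outside trajectory span; extrapolation not supported")
  }
  stats::approx(trajectory$years, trajectory$ppm, xout = year,
                method = "linear", rule = 1)$y
}

#' Bundled representative CO2 trajectories
#'
#' Loads the packaged lookup of representative decadal CO2 concentrations per
#' emission scenario (RCPs and two SRES families). These are rounded
#' representative values for interpolation mechanics and the synthetic
#' generator, not a redistribution of any scenario database.
#'
#' @return Named list of [scenario_trajectory()] objects.
#' @export
co2_trajectories <- function() {
  path <- system.file("extdata", "co2_trajectories.csv", package = "cropclim")
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(tb, tb$scenario), function(d) {
    d <- d[order(d$year), ]
    scenario_trajectory(d$scenario[1], d$year, d$ppm)
  })
  out
}

#' Absolute precipitation change from a relative change
#'
#' Studies often report precipitation change only as a percentage; the
#' absolute change is reconstructed against the current annual precipitation
#' level: `rel_change / 100 * Pr_base`.
#'
#' @param rel_change Relative change, percent.
#' @param Pr_base Current annual precipitation, mm (>= 0).
#' @return Change in mm. Vectorized.
#' @export
precip_change_from_relative <- function(rel_change, Pr_base) {
  if (any(!is.na(Pr_base) & Pr_base < 0)) stop("Pr_base must be non-negative")
  rel_change / 100 * Pr_base
}

#' Read / write a CSV raster
#'
#' Plain-text raster interchange used for fixtures: first column `lat`,
#' remaining column names the longitudes, one row per latitude.
#'
#' @param path CSV file.
#' @param variable,period_label Passed to [climate_grid()].
#' @return A [climate_grid()].
#' @export
read_grid_csv <- function(path, variable = "annual_mean_temp_C",
                          period_label = "") {
  tb <- utils::read.csv(path, check.names = FALSE)
  lats <- as.numeric(tb[[1]])
  lons <- as.numeric(names(tb)[-1])
  o <- order(lats)
  climate_grid(as.matrix(tb[o, -1, drop = FALSE]), lats[o], lons,
               variable = variable, period_label = period_label)
}

#' @param grid A [climate_grid()] to serialize.
#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(grid, path) {
  tb <- data.frame(lat = grid$lats, grid$values, check.names = FALSE)
  names(tb) <- c("lat", format(grid$lons, trim = TRUE))
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}
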