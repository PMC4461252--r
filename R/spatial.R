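#' Speed and spike filtering of satellite tracking fixes
#'
#' Removes implausible Argos-style fixes per bird: (i) any fix implying a
#' travel speed above `max_speed` from its retained predecessor, and (ii)
#' 'spike' fixes, where the track goes out and straight back (the angle at
#' the fix between the legs to its retained neighbours is below
#' `spike_angle`) with both legs longer than `spike_dist`. Distances are
#' great-circle. The two filters are applied alternately until a fixed
#' point, so filtering an already-filtered track changes nothing. Birds with
#' fewer than two fixes pass through untouched; the input table is not
#' modified.
#'
#' @param fixes Tibble with `bird_id`, `t` (POSIXct), `lon`, `lat` and
#'   optionally `stage`.
#' @param max_speed Maximum plausible speed, km/h.
#' @param spike_angle Spike angle threshold, degrees.
#' @param spike_dist Minimum leg length for a spike, km.
#' @return Filtered tibble, time-sorted within bird.
#' @export
filter_fixes <- function(fixes, max_speed = 100, spike_angle = 15, spike_dist = 2.5) {
  stopifnot(all(c("bird_id", "t", "lon", "lat") %in% names(fixes)))
  fixes <- arrange(as_tibble(fixes), .data$bird_id, .data$t)
  fixes %>%
    group_by(.data$bird_id) %>%
    dplyr::group_modify(~ filter_one_track(.x, max_speed, spike_angle, spike_dist)) %>%
    ungroup()
}

filter_one_track <- function(tr, max_speed, spike_angle, spike_dist) {
  if (nrow(tr) < 2) return(tr)
  repeat {
    n0 <- nrow(tr)
    tr <- tr[speed_keep(tr, max_speed), , drop = FALSE]
    if (nrow(tr) >= 3) tr <- tr[!spike_flag(tr, spike_angle, spike_dist), , drop = FALSE]
    if (nrow(tr) == n0 || nrow(tr) < 2) return(tr)
  }
}

# forward pass: keep a fix only if speed from the last *retained* fix is
# plausible. Consecutive distances are computed in one vectorized call;
# distances across a dropped fix are recomputed individually (rare).
speed_keep <- function(tr, max_speed) {
  n <- nrow(tr)
  p <- cbind(tr$lon, tr$lat)
  dd <- geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE]) / 1000
  tt <- as.numeric(tr$t)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1
  for (i in 2:n) {
    d_km <- if (last == i - 1) dd[i - 1] else geosphere::distHaversine(p[last, ], p[i, ]) / 1000
    dt_h <- (tt[i] - tt[last]) / 3600
    sp <- if (dt_h > 0) d_km / dt_h else Inf
    if (sp <= max_speed) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep
}

spike_flag <- function(tr, spike_angle, spike_dist) {
  n <- nrow(tr)
  p <- cbind(tr$lon, tr$lat)
  mid <- p[2:(n - 1), , drop = FALSE]
  prv <- p[1:(n - 2), , drop = FALSE]
  nxt <- p[3:n, , drop = FALSE]
  d1 <- geosphere::distHaversine(mid, prv) / 1000
  d2 <- geosphere::distHaversine(mid, nxt) / 1000
  b1 <- geosphere::bearing(mid, prv)
  b2 <- geosphere::bearing(mid, nxt)
  ang <- abs(((b1 - b2 + 180) %% 360) - 180)
  c(FALSE, d1 > spike_dist & d2 > spike_dist & ang < spike_angle, FALSE)
}

#' Linear interpolation of track gaps
#'
#' Inserts linearly interpolated positions at `step`-hour resolution inside
#' any per-bird gap strictly longer than `min_gap` and strictly shorter than
#' `max_gap` hours, giving an even spread of locations before kernel
#' density estimation. Gaps outside that range are left unfilled.
#'
#' @param fixes Tibble with `bird_id`, `t`, `lon`, `lat` (and optional
#'   `stage`), time-sorted within bird.
#' @param min_gap,max_gap Gap bounds in hours (exclusive).
#' @param step Insertion resolution in hours.
#' @return Tibble with original plus interpolated rows (flagged by the
#'   logical column `interpolated`), time-sorted within bird.
#' @export
interpolate_track <- function(fixes, min_gap = 1, max_gap = 24, step = 1) {
  stopifnot(all(c("bird_id", "t", "lon", "lat") %in% names(fixes)))
  fixes <- arrange(as_tibble(fixes), .data$bird_id, .data$t)
  fixes$interpolated <- FALSE
  new_rows <- fixes %>%
    group_by(.data$bird_id) %>%
    dplyr::group_modify(function(tr, key) {
      if (nrow(tr) < 2) return(tr[0, , drop = FALSE])
      out <- list()
      for (i in seq_len(nrow(tr) - 1)) {
        dt <- as.numeric(difftime(tr$t[i + 1], tr$t[i], units = "hours"))
        if (dt > min_gap && dt < max_gap) {
          k <- seq(step, dt - 1e-9, by = step)
          k <- k[k < dt - 1e-9]
          if (length(k) == 0) next
          frac <- k / dt
          row <- tr[rep(i, length(k)), , drop = FALSE]
          row$t <- tr$t[i] + k * 3600
          row$lon <- tr$lon[i] + frac * (tr$lon[i + 1] - tr$lon[i])
          row$lat <- tr$lat[i] + frac * (tr$lat[i + 1] - tr$lat[i])
          row$interpolated <- TRUE
          out[[length(out) + 1]] <- row
        }
      }
      if (length(out) == 0) tr[0, , drop = FALSE] else bind_rows(out)
    }) %>%
    ungroup()
  bind_rows(fixes, new_rows) %>% arrange(.data$bird_id, .data$t)
}

grid_cells <- function(region = ALB_REGION) {
  expand_grid(
    cell_lon = seq(region[["lon_min"]], region[["lon_max"]] - 1),
    cell_lat = seq(region[["lat_min"]], region[["lat_max"]] - 1)
  )
}

#' Kernel utilisation distribution on the 1-degree grid
#'
#' Gaussian kernel density over fix locations, evaluated at the centres of
#' the 1-degree cells of the model region (45S-30S, 123E-151E by default)
#' and renormalized to sum to one over retained cells. Cells are indexed by
#' their lower-left (west/south) corner with half-open extent
#' `[lon, lon + 1) x [lat, lat + 1)`. Cells whose land fraction exceeds
#' `land_threshold` are excluded (weight 0) before renormalization.
#' Distances inside the kernel are planar in degrees, an adequate
#' approximation over this small latitude span.
#'
#' @param fixes Tibble with `lon`, `lat` (filtered and interpolated).
#' @param bandwidth Kernel standard deviation in degrees.
#' @param region Named vector `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param land_mask Optional tibble `cell_lon`, `cell_lat`, `land_fraction`.
#' @param land_threshold Exclude cells with land fraction above this.
#' @param stage Life stage label to record (`"adult"` or `"juvenile"`).
#' @return A `utility_grid` tibble: `cell_lon`, `cell_lat`, `weight`,
#'   `excluded`, with attributes `stage`, `bandwidth`, `region`.
#' @export
kernel_utility <- function(fixes, bandwidth = 1.0, region = ALB_REGION,
                           land_mask = NULL, land_threshold = 0.5,
                           stage = "adult") {
  if (nrow(fixes) == 0) abort("no fixes supplied to kernel_utility")
  cells <- grid_cells(region)
  cx <- cells$cell_lon + 0.5
  cy <- cells$cell_lat + 0.5
  # Gaussian kernel sum over fixes, planar degrees
  dens <- numeric(nrow(cells))
  h2 <- 2 * bandwidth^2
  for (i in seq_len(nrow(fixes))) {
    dens <- dens + exp(-((cx - fixes$lon[i])^2 + (cy - fixes$lat[i])^2) / h2)
  }
  # boundary correction: divide by the kernel mass falling inside the region
  # around each cell centre, so a uniform distribution of fixes yields a
  # uniform surface right up to the region edge
  edge <- (pnorm((region[["lon_max"]] - cx) / bandwidth) -
             pnorm((region[["lon_min"]] - cx) / bandwidth)) *
    (pnorm((region[["lat_max"]] - cy) / bandwidth) -
       pnorm((region[["lat_min"]] - cy) / bandwidth))
  dens <- dens / edge
  excluded <- rep(FALSE, nrow(cells))
  if (!is.null(land_mask)) {
    key <- paste(cells$cell_lon, cells$cell_lat)
    mkey <- paste(land_mask$cell_lon, land_mask$cell_lat)
    lf <- land_mask$land_fraction[match(key, mkey)]
    excluded <- !is.na(lf) & lf > land_threshold
  }
  dens[excluded] <- 0
  tot <- sum(dens)
  if (tot <= 0) abort("all kernel mass fell on excluded cells")
  out <- mutate(cells, weight = dens / tot, excluded = excluded)
  class(out) <- c("utility_grid", class(out))
  attr(out, "stage") <- stage
  attr(out, "bandwidth") <- bandwidth
  attr(out, "region") <- region
  out
}

#' Effort-weighted utilisation overlap indices
#'
#' For each fleet and year, the overlap index is the sum over grid cells of
#' fleet effort times the utilisation weight of the cell: the effort
#' 'seen' by the average bird of that stage, in fleet-native effort units.
#' Linear in both effort and utilisation; excluded cells carry weight 0 and
#' contribute nothing.
#'
#' @param effort Effort tibble: `fleet`, `year`, `cell_lon`, `cell_lat`,
#'   `effort` (and optionally `unit`).
#' @param util A [kernel_utility()] grid.
#' @param years Optional years to restrict to.
#' @return Tibble `fleet`, `year`, `stage`, `value`.
#' @export
compute_overlap <- function(effort, util, years = NULL) {
  stopifnot(all(c("fleet", "year", "cell_lon", "cell_lat", "effort") %in% names(effort)))
  if (!is.null(years)) effort <- filter(effort, .data$year %in% years)
  w <- setNames(util$weight, paste(util$cell_lon, util$cell_lat))
  effort$w <- w[paste(effort$cell_lon, effort$cell_lat)]
  effort$w[is.na(effort$w)] <- 0
  effort %>%
    group_by(.data$fleet, .data$year) %>%
    summarise(value = sum(.data$effort * .data$w), .groups = "drop") %>%
    mutate(stage = attr(util, "stage") %||% "adult") %>%
    select("fleet", "year", "stage", "value")
}

#' Overlap series for both life stages
#'
#' Convenience wrapper binding [compute_overlap()] of the juvenile and adult
#' utilisation grids over all years present in the effort table.
#'
#' @param effort Effort tibble (see [compute_overlap()]).
#' @param util_juvenile,util_adult Utilisation grids for the two stages.
#' @return Tibble `fleet`, `year`, `stage`, `value`.
#' @export
overlap_series <- function(effort, util_juvenile, util_adult) {
  bind_rows(
    compute_overlap(effort, util_juvenile),
    compute_overlap(effort, util_adult)
  )
}

#' @method autoplot utility_grid
#' @export
autoplot.utility_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$cell_lon + 0.5, y = .data$cell_lat + 0.5)) +
    geom_tile(aes(fill = 100 * .data$weight)) +
    geom_tile(
      data = filter(object, .data$excluded), fill = NA,
      colour = "black", linewidth = 0.4
    ) +
    scale_fill_viridis_c(name = "% utilisation") +
    coord_fixed() +
    labs(
      x = "Longitude", y = "Latitude",
      title = paste(attr(object, "stage") %||% "", "utilisation distribution")
    ) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
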