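resolve_window <- function(response, window) {
  if (is.null(window)) window <- response$window
  if (length(window) != 2 || diff(window) <= 0)
    stop("window must be c(t0, t1) with t1 > t0")
  window
}

get_response <- function(response, direction) {
  r <- response$responses[[direction]]
  if (is.null(r)) stop("no response recorded for direction ", direction)
  r
}

#' Population mean firing rate
#'
#' Total spike count of one direction population inside the window, divided
#' by the number of units and the window length: the whole-population MFR in
#' Hz, normalized by all units (responding or not). With
#' `active_only = TRUE` the count is normalized by the units that spiked
#' instead.
#'
#' @param response a `population_response` from [run_network()].
#' @param direction population to measure (`"LR"`, `"RL"`, `"TB"`, `"BT"`).
#' @param window `c(t0, t1)` in ms; defaults to the response's analysis
#'   window (stimulus span + 5 membrane time constants).
#' @param active_only normalize by active units only (default `FALSE`).
#' @return MFR in Hz.
#' @examples
#' # 50 spikes from a 100-unit population in a 500 ms window -> 1 Hz
#' @export
mean_firing_rate <- function(response, direction, window = NULL,
                             active_only = FALSE) {
  stopifnot(inherits(response, "population_response"))
  w <- resolve_window(response, window)
  r <- get_response(response, direction)
  sel <- r$spikes$t >= w[1] & r$spikes$t <= w[2]
  denom <- if (active_only) max(1L, length(unique(r$spikes$unit[sel]))) else r$n_units
  sum(sel) / (denom * diff(w) / 1000)
}

#' Instantaneous population rate with across-unit variance
#'
#' Bins one population's spikes over the analysis window and reports, per
#' bin, the population rate (spikes per unit per second) and the variance of
#' the per-unit rates across units (silent units included).
#'
#' @inheritParams mean_firing_rate
#' @param bin_ms bin width in ms (> 0).
#' @return data.frame with `t_ms` (bin midpoints), `rate_hz`, `var_hz2` and
#'   `count`.
#' @export
instantaneous_rate <- function(response, direction, bin_ms = 10,
                               window = NULL) {
  stopifnot(bin_ms > 0)
  w <- resolve_window(response, window)
  r <- get_response(response, direction)
  breaks <- seq(w[1], w[2] + bin_ms, by = bin_ms)
  sel <- r$spikes$t >= w[1] & r$spikes$t <= w[2]
  sp <- r$spikes[sel, , drop = FALSE]
  bin <- findInterval(sp$t, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  counts <- tabulate(bin, nbins = nb)
  scale <- 1000 / bin_ms                      # per-unit counts -> Hz
  # across-unit variance from the sparse (unit, bin) count table
  var_hz2 <- numeric(nb)
  if (nrow(sp)) {
    ub <- paste(sp$unit, bin)
    cnt <- table(ub)
    bin_of <- as.integer(vapply(strsplit(names(cnt), " "),
                                `[`, "", 2))
    sum1 <- counts                            # sum of per-unit counts
    sum2 <- vapply(seq_len(nb), function(b) sum(cnt[bin_of == b]^2), 0)
    n <- r$n_units
    var_hz2 <- (sum2 / n - (sum1 / n)^2) * scale^2
  }
  data.frame(t_ms = breaks[-length(breaks)] + bin_ms / 2,
             rate_hz = counts / r$n_units * scale,
             var_hz2 = var_hz2, count = counts)
}

#' Spatial map of per-unit mean firing rates
#'
#' Places every TDE unit's MFR at its trigger RF's center, yielding a
#' rasterizable map of where in the visual field the population responded.
#'
#' @inheritParams mean_firing_rate
#' @return a `spatial_map`: data.frame with `unit`, `x`, `y` (trigger RF
#'   center, px), `ring`, `mfr_hz`; geometry kept as attributes.
#' @export
spatial_map <- function(response, direction, window = NULL) {
  w <- resolve_window(response, window)
  r <- get_response(response, direction)
  sel <- r$spikes$t >= w[1] & r$spikes$t <= w[2]
  counts <- tabulate(r$spikes$unit[sel], nbins = r$n_units)
  out <- data.frame(unit = r$units$unit, x = r$units$cx, y = r$units$cy,
                    ring = r$units$ring,
                    mfr_hz = counts / (diff(w) / 1000))
  attr(out, "width") <- response$width
  attr(out, "height") <- response$height
  class(out) <- c("spatial_map", "data.frame")
  out
}

#' Rasterize a spatial map to a pixel image
#' @param map a `spatial_map`.
#' @return numeric matrix (height x width); unit MFRs are added at the
#'   nearest pixel to each trigger-RF center.
#' @export
as_image <- function(map) {
  w <- attr(map, "width"); h <- attr(map, "height")
  img <- matrix(0, nrow = h, ncol = w)
  px <- pmin(pmax(round(map$x + 0.5), 1), w)
  py <- pmin(pmax(round(map$y + 0.5), 1), h)
  for (i in seq_len(nrow(map)))
    img[py[i], px[i]] <- img[py[i], px[i]] + map$mfr_hz[i]
  img
}

unit_distance <- function(map, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  cx <- (attr(map, "width") - 1) / 2
  cy <- (attr(map, "height") - 1) / 2
  dx <- abs(map$x - cx); dy <- abs(map$y - cy)
  if (metric == "chebyshev") pmax(dx, dy) else sqrt(dx^2 + dy^2)
}

#' Center of mass of the response eccentricity
#'
#' MFR-weighted mean distance of the units from the field center. The
#' default metric is the Chebyshev distance (max of the coordinate
#' offsets), matching the square-ring geometry of the eccentric grid.
#'
#' @param map a `spatial_map` from [spatial_map()].
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return eccentricity in px.
#' @export
center_of_mass <- function(map, metric = c("chebyshev", "euclidean")) {
  if (all(map$mfr_hz == 0))
    stop("center of mass undefined: all units silent")
  d <- unit_distance(map, metric)
  sum(map$mfr_hz * d) / sum(map$mfr_hz)
}

#' MFR statistics by eccentricity
#'
#' Mean and variance of per-unit MFR in distance bins from the field
#' center (silent units included).
#'
#' @inheritParams center_of_mass
#' @param n_bins number of equal-width distance bins (default 20).
#' @return data.frame with `d_mid` (px), `mean_mfr_hz`, `var_mfr_hz2`,
#'   `n_units`.
#' @export
eccentricity_profile <- function(map, n_bins = 20,
                                 metric = c("chebyshev", "euclidean")) {
  d <- unit_distance(map, metric)
  breaks <- seq(0, max(d) + 1e-9, length.out = n_bins + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  out <- lapply(seq_len(n_bins), function(b) {
    v <- map$mfr_hz[bin == b]
    data.frame(d_mid = (breaks[b] + breaks[b + 1]) / 2,
               mean_mfr_hz = if (length(v)) mean(v) else NA_real_,
               var_mfr_hz2 = if (length(v) > 1) stats::var(v) else 0,
               n_units = length(v))
  })
  do.call(rbind, out)
}

#' Run the full pipeline on one stimulus
#'
#' Convenience wrapper: filter an event stream through a sampling scheme and
#' simulate the given populations.
#'
#' @param stream an [event_stream()].
#' @param scheme a `sampling_scheme`.
#' @param populations populations from [wire_network()] /
#'   [wire_population()].
#' @return a `population_response`.
#' @export
run_pipeline <- function(stream, scheme, populations) {
  run_network(rf_integrate(stream, scheme), populations)
}

#' Speed sweep characterization
#'
#' Runs a moving-bar stimulus at each speed through the pipeline and
#' collects per-population MFRs, the center of mass of the response of the
#' population preferring the stimulus direction, and the decoded direction.
#'
#' @param speeds numeric vector of bar speeds, px/ms.
#' @param scheme a `sampling_scheme`.
#' @param populations populations from [wire_network()] (all four needed
#'   for decoding; a subset is accepted, disabling decode).
#' @param direction stimulus direction (default `"LR"`).
#' @param bar_length bar length in px; default full field.
#' @param verbose print progress (default `FALSE`).
#' @return data.frame with one row per speed: `speed`, `mfr_<dir>_hz` for
#'   each simulated population, `com_px` (NA if the preferred population is
#'   silent), `decoded`.
#' @export
speed_sweep <- function(speeds, scheme, populations, direction = "LR",
                        bar_length = NULL, verbose = FALSE) {
  rows <- lapply(speeds, function(v) {
    if (verbose) message("  speed ", v, " px/ms")
    stream <- moving_bar(direction, v, bar_length = bar_length,
                         geometry = c(scheme$width, scheme$height))
    resp <- run_pipeline(stream, scheme, populations)
    mfr <- vapply(names(resp$responses),
                  function(d) mean_firing_rate(resp, d), 0)
    names(mfr) <- paste0("mfr_", tolower(names(mfr)), "_hz")
    pref <- if (direction %in% names(resp$responses)) direction
            else names(resp$responses)[1]
    map <- spatial_map(resp, pref)
    com <- if (all(map$mfr_hz == 0)) NA_real_ else center_of_mass(map)
    decoded <- if (all(DIRECTIONS_CARDINAL %in% names(resp$responses)))
      decode_direction(resp)$direction else NA_character_
    cbind(data.frame(speed = v), as.data.frame(as.list(mfr)),
          data.frame(com_px = com, decoded = decoded))
  })
  do.call(rbind, rows)
}

#' Bar-length experiment
#'
#' MFR of the population preferring the stimulus direction for bars of
#' different lengths at a fixed speed.
#'
#' @param lengths bar lengths in px (0 is allowed and reports 0 MFR).
#' @param speed bar speed, px/ms (default 0.3).
#' @inheritParams speed_sweep
#' @return data.frame with `length_px` and `mfr_hz`.
#' @export
bar_length_experiment <- function(lengths, scheme, populations,
                                  speed = 0.3, direction = "LR") {
  rows <- lapply(lengths, function(L) {
    if (L == 0) return(data.frame(length_px = 0, mfr_hz = 0))
    stream <- moving_bar(direction, speed, bar_length = L,
                         geometry = c(scheme$width, scheme$height))
    resp <- run_pipeline(stream, scheme, populations)
    data.frame(length_px = L,
               mfr_hz = mean_firing_rate(resp, direction))
  })
  do.call(rbind, rows)
}
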