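#' Eccentric grid specification
#'
#' Parameters of the retina-inspired receptive-field grid: a central fovea of
#' single-pixel RFs covering `fovea_fraction` of the layer, framed by
#' concentric square rings of RFs whose side length grows linearly from 1 px
#' at the fovea edge to `max_rf` px at the field border, with consecutive
#' rings overlapping by about half an RF.
#'
#' @param geometry `c(width, height)` in pixels (square for the eccentric
#'   grid).
#' @param fovea_fraction fraction of the layer covered by the fovea
#'   (0 < f < 1; default 0.10).
#' @param max_rf side of the largest (outermost) RF in px (default 10).
#' @param norm_fraction fraction of the RF area used as the integration
#'   normalization factor `R_nf = max(1, norm_fraction * size^2)`
#'   (default 0.60).
#' @param tau_rf_ms membrane decay time constant of the RF integrator
#'   (default 1000 ms).
#' @param threshold RF spike threshold on the normalized membrane potential
#'   (default 1).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(geometry = c(160L, 160L), fovea_fraction = 0.10,
                      max_rf = 10L, norm_fraction = 0.60,
                      tau_rf_ms = 1000, threshold = 1) {
  w <- as.integer(geometry[1]); h <- as.integer(geometry[2])
  if (w != h) stop("the eccentric grid requires a square geometry")
  if (!(fovea_fraction > 0 && fovea_fraction < 1))
    stop("fovea_fraction must be in (0, 1)")
  max_rf <- as.integer(max_rf)
  if (max_rf < 2L) stop("max_rf must be >= 2")
  fs <- fovea_side(w, fovea_fraction)
  d_fovea <- (w - fs) / 2
  if (d_fovea <= 0) stop("fovea covers the whole layer; nothing to ring")
  structure(list(width = w, height = h, fovea_fraction = fovea_fraction,
                 max_rf = max_rf, fovea_side = fs, d_fovea = d_fovea,
                 norm_fraction = norm_fraction, tau_rf_ms = tau_rf_ms,
                 threshold = threshold),
            class = "grid_spec")
}

# nearest integer to sqrt(fraction)*side with the parity of `side`, so the
# foveal block can be centered on whole pixels
fovea_side <- function(side, fraction) {
  target <- sqrt(fraction) * side
  lo <- floor(target)
  if ((lo - side) %% 2L != 0L) lo <- lo - 1L
  hi <- lo + 2L
  fs <- if (abs(target - lo) <= abs(hi - target)) lo else hi
  fs <- max(2L, min(as.integer(fs), side - 2L))
  as.integer(fs)
}

#' Receptive-field size at a given depth into the periphery
#'
#' Linear size law of the eccentric grid: RF side decreases from `max_rf` at
#' the field border (`x_dist = 0`) to 1 px at the fovea edge
#' (`x_dist = d_fovea`), rounded to the nearest integer and clamped to >= 1.
#'
#' @param x_dist distance in px from the field border toward the fovea, in
#'   `[0, d_fovea]`.
#' @param spec a [grid_spec()].
#' @return integer RF side length in px.
#' @examples
#' sp <- grid_spec()
#' rf_size(0, sp)               # 10, the outermost ring
#' rf_size(sp$d_fovea / 2, sp)  # 5, halfway in
#' rf_size(sp$d_fovea, sp)      # 1, the foveal limit
#' @export
rf_size <- function(x_dist, spec) {
  if (any(x_dist < 0 | x_dist > spec$d_fovea))
    stop("x_dist must lie in [0, d_fovea]")
  pmax(1L, as.integer(round(spec$max_rf * (1 - x_dist / spec$d_fovea))))
}

# 1-D ring layout along one axis: anchors (0-based top/left pixel of each
# ring band) and sizes for the `n_rings` peripheral bands on the low side.
# Real-valued half-overlap recursion a' = a + s(a)/2, scaled so the covered
# span ends exactly at the fovea edge, then rounded to pixels.
ring_layout <- function(spec) {
  d <- spec$d_fovea; m <- spec$max_rf
  n0 <- max(1L, as.integer(round(4 * d / m)))
  # try ring counts near the nominal one until an integer tiling exists
  offsets <- c(0L, as.vector(rbind(-(1:8), 1:8)))
  for (n_rings in unique(pmax(1L, n0 + offsets))) {
    lay <- try(ring_schedule(d, m, n_rings, spec), silent = TRUE)
    if (!inherits(lay, "try-error")) return(lay)
  }
  stop("ring construction failed: no valid ring tiling for a periphery of ",
       "depth ", d, " px with max RF ", m, " px")
}

# integer anchor schedule for a fixed ring count: ideal real-valued anchors
# from the half-overlap recursion, rescaled to span the periphery, then
# rounded sequentially under the constraints a_{k-1} < a_k <= a_{k-1}+s_{k-1}
# (strictly increasing, no coverage gap)
ring_schedule <- function(d, m, n_rings, spec) {
  a_real <- numeric(n_rings + 1L)
  for (k in seq_len(n_rings)) {
    s <- max(1, m * (1 - a_real[k] / d))
    a_real[k + 1L] <- a_real[k] + s / 2
  }
  ideal <- a_real[seq_len(n_rings)] * d / a_real[n_rings + 1L]
  anchors <- integer(n_rings)
  sizes <- integer(n_rings)
  sizes[1L] <- rf_size(0, spec)
  for (k in seq_len(n_rings)[-1L]) {
    a <- round(ideal[k])
    a <- max(a, anchors[k - 1L] + 1L)
    a <- min(a, anchors[k - 1L] + sizes[k - 1L])
    if (a >= d) stop("rings overshoot the fovea")
    anchors[k] <- as.integer(a)
    sizes[k] <- rf_size(a, spec)
  }
  if (anchors[n_rings] + sizes[n_rings] < d)
    stop("innermost ring does not reach the fovea")
  list(n_rings = n_rings, anchors = anchors, sizes = sizes)
}

# full per-axis band table for lattice indices 0..L-1: anchor/size/center of
# the ring bands, the 1-px foveal bands, and the mirrored high side
axis_bands <- function(spec, layout) {
  w <- spec$width; fs <- spec$fovea_side; nr <- layout$n_rings
  d <- as.integer(spec$d_fovea)
  anchor <- c(layout$anchors,
              d + 0:(fs - 1L),
              w - rev(layout$anchors) - rev(layout$sizes))
  size <- c(layout$sizes, rep(1L, fs), rev(layout$sizes))
  data.frame(anchor = as.integer(anchor), size = as.integer(size),
             center = anchor + size / 2)
}

#' Build the eccentric sampling scheme
#'
#' Constructs the full space-variant receptive-field grid: a centered block
#' of 1-px foveal RFs framed by concentric square rings whose RF side
#' follows [rf_size()], consecutive rings overlapping by about half an RF.
#' Every lattice position `(row, col)` holds one RF whose side is set by its
#' ring (the Chebyshev band index) and whose center follows the per-axis
#' band centers, so that horizontal and vertical trajectories are lattice
#' rows and columns. For the default 160x160 / 10% / 10 px configuration the
#' lattice is 94x94 (8836 RFs) with a 50x50 foveal block.
#'
#' @param spec a [grid_spec()].
#' @return a `sampling_scheme` object; see [build_uniform()] for the shared
#'   structure.
#' @examples
#' sch <- build_eccentric(grid_spec())
#' nrow(sch$rfs)  # 8836
#' @export
build_eccentric <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  layout <- ring_layout(spec)
  bands <- axis_bands(spec, layout)
  L <- nrow(bands)
  idx <- 0:(L - 1L)
  g <- expand.grid(col = idx, row = idx)  # id = row-major, column fastest
  band_min <- pmin(g$row, g$col, L - 1L - g$row, L - 1L - g$col)
  peripheral <- band_min < layout$n_rings
  size <- ifelse(peripheral, layout$sizes[pmin(band_min, layout$n_rings - 1L) + 1L], 1L)
  ring <- ifelse(peripheral, layout$n_rings - band_min, 0L)
  cx <- bands$center[g$col + 1L]
  cy <- bands$center[g$row + 1L]
  x0 <- as.integer(pmin(pmax(round(cx - size / 2), 0), spec$width - size))
  y0 <- as.integer(pmin(pmax(round(cy - size / 2), 0), spec$height - size))
  rfs <- data.frame(id = seq_len(L * L), row = g$row, col = g$col,
                    ring = as.integer(ring), size = as.integer(size),
                    x0 = x0, y0 = y0,
                    cx = x0 + size / 2, cy = y0 + size / 2,
                    rnf = pmax(1, spec$norm_fraction * size^2))
  new_scheme("eccentric", spec, rfs, c(L, L),
             extra = list(fovea_side = spec$fovea_side,
                          d_fovea = spec$d_fovea,
                          n_rings = layout$n_rings,
                          ring_anchors = layout$anchors,
                          ring_sizes = layout$sizes))
}

#' Build the uniform (baseline) sampling scheme
#'
#' Partitions the pixel array into non-overlapping `n x n` neighborhoods,
#' one RF per block, integrated with the same event-driven leaky integrator
#' as the eccentric scheme. The spatio-temporal coincidence rule (a fraction
#' of the neighborhood must fire within the membrane time constant) is
#' expressed through `coincidence_fraction`: `R_nf = coincidence_fraction *
#' n^2`.
#'
#' @param geometry `c(width, height)` in pixels.
#' @param n neighborhood side in px; must divide both sides.
#' @param coincidence_fraction fraction of the neighborhood required for a
#'   spike (default 0.66).
#' @param tau_rf_ms,threshold integrator constants as in [grid_spec()].
#' @return a `sampling_scheme`: list with `kind`, geometry, `rfs`
#'   (data.frame: `id`, `row`, `col`, `ring`, `size`, `x0`, `y0`, `cx`,
#'   `cy`, `rnf`), `lattice` (`c(rows, cols)`), integrator constants and the
#'   pixel->RF membership map.
#' @examples
#' sch <- build_uniform(c(160, 160), 4)
#' nrow(sch$rfs)  # 1600
#' @export
build_uniform <- function(geometry, n, coincidence_fraction = 0.66,
                          tau_rf_ms = 1000, threshold = 1) {
  w <- as.integer(geometry[1]); h <- as.integer(geometry[2])
  n <- as.integer(n)
  if (n < 1L || w %% n != 0L || h %% n != 0L)
    stop("neighborhood side must divide both geometry sides")
  rows <- h %/% n; cols <- w %/% n
  g <- expand.grid(col = 0:(cols - 1L), row = 0:(rows - 1L))
  rfs <- data.frame(id = seq_len(rows * cols), row = g$row, col = g$col,
                    ring = 0L, size = n,
                    x0 = g$col * n, y0 = g$row * n,
                    cx = g$col * n + n / 2, cy = g$row * n + n / 2,
                    rnf = pmax(1, coincidence_fraction * n^2))
  spec <- list(width = w, height = h, norm_fraction = coincidence_fraction,
               tau_rf_ms = tau_rf_ms, threshold = threshold)
  new_scheme("uniform", spec, rfs, c(rows, cols))
}

new_scheme <- function(kind, spec, rfs, lattice, extra = list()) {
  pm <- cpp_pixel_map(rfs$x0, rfs$y0, rfs$size, spec$width, spec$height)
  out <- c(list(kind = kind, width = spec$width, height = spec$height,
                rfs = rfs, lattice = as.integer(lattice),
                norm_fraction = spec$norm_fraction,
                tau_rf_ms = spec$tau_rf_ms, threshold = spec$threshold,
                pixel_ptr = pm$ptr, pixel_rf = pm$ids),
           extra)
  structure(out, class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme: %s> %d RFs on a %dx%d lattice over %dx%d px\n",
              x$kind, nrow(x$rfs), x$lattice[1], x$lattice[2],
              x$width, x$height))
  if (x$kind == "eccentric")
    cat(sprintf("  fovea %dx%d (1-px RFs), %d rings, RF sizes %d..%d px\n",
                x$fovea_side, x$fovea_side, x$n_rings,
                min(x$ring_sizes), max(x$ring_sizes)))
  invisible(x)
}

#' Lattice (row, col) -> RF id
#' @param scheme a `sampling_scheme`.
#' @param row,col 0-based lattice coordinates.
#' @return integer RF ids (row-major, column fastest).
#' @export
rf_id_at <- function(scheme, row, col) {
  as.integer(row * scheme$lattice[2] + col + 1L)
}

#' Filter an event stream into per-RF spike trains
#'
#' Event-driven leaky integration: each event entering an RF updates its
#' membrane potential `M <- M * exp(-dt/tau) + 1/R_nf` (dt = time since the
#' previous event in that RF); when `M` reaches the threshold the RF emits
#' an output spike at the event's time and resets to 0. Polarity is ignored
#' (ON and OFF events both integrate). Because `R_nf` scales with RF area,
#' response is normalized across eccentricities.
#'
#' @param stream an [event_stream()]; geometry must match the scheme.
#' @param scheme a `sampling_scheme` from [build_eccentric()] or
#'   [build_uniform()].
#' @return an `rf_spike_trains` object: list with `spikes` (data.frame `rf`,
#'   `t`, sorted by time), `n_rf`, `lattice`, `kind`, `t_span` and geometry.
#' @export
rf_integrate <- function(stream, scheme) {
  stopifnot(inherits(stream, "event_stream"),
            inherits(scheme, "sampling_scheme"))
  if (stream$width != scheme$width || stream$height != scheme$height)
    stop("stream geometry does not match the sampling scheme")
  ev <- stream$events
  res <- cpp_rf_integrate(ev$t, ev$y * stream$width + ev$x,
                          scheme$pixel_ptr, scheme$pixel_rf,
                          scheme$rfs$rnf, scheme$tau_rf_ms, scheme$threshold)
  t_span <- if (nrow(ev)) range(ev$t) else c(0, 0)
  structure(list(spikes = data.frame(rf = res$rf, t = res$t),
                 n_rf = nrow(scheme$rfs), lattice = scheme$lattice,
                 kind = scheme$kind, width = scheme$width,
                 height = scheme$height, t_span = t_span),
            class = "rf_spike_trains")
}

#' @export
print.rf_spike_trains <- function(x, ...) {
  cat(sprintf("<rf_spike_trains> %d spikes from %d/%d RFs (%s scheme)\n",
              nrow(x$spikes), length(unique(x$spikes$rf)), x$n_rf, x$kind))
  invisible(x)
}

#' Spike times of one RF
#' @param trains an `rf_spike_trains` object.
#' @param rf RF id.
#' @return sorted numeric spike times (ms).
#' @export
rf_train <- function(trains, rf) {
  sort(trains$spikes$t[trains$spikes$rf == rf])
}
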