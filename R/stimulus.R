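#' @keywords internal
DIRECTIONS_CARDINAL <- c("LR", "RL", "TB", "BT")
#' @keywords internal
DIRECTIONS_DIAGONAL <- c("TL_BR", "TR_BL", "BL_TR", "BR_TL")

#' Synthetic moving-bar event stream
#'
#' Reproduces the activity of an event-driven sensor watching a bar (a 1-px
#' moving edge) cross the pixel array at constant speed. Cardinal directions
#' are `LR`, `RL` (horizontal), `TB`, `BT` (vertical); diagonal directions
#' (`TL_BR`, `TR_BL`, `BL_TR`, `BR_TL`) move the edge along both axes
#' simultaneously, at `speed` px/ms along each axis, so that the horizontal
#' and vertical projections of the motion match the cardinal case.
#'
#' For `LR` at speed `v`, every pixel `(x, y)` on the bar's path emits one ON
#' event at `t = x/v`; the bar is centered on the axis perpendicular to the
#' motion. With `edge_model = "on_off"` a trailing OFF event is added one
#' pixel-crossing later at the same pixel.
#'
#' @param direction one of the four cardinal or four diagonal direction codes.
#' @param speed bar speed in px/ms (> 0; the characterization range is
#'   0.01-1.0).
#' @param bar_length bar extent in pixels perpendicular to the motion
#'   (1..max(geometry)); the bar itself is a 1-px edge.
#' @param geometry `c(width, height)` of the pixel array.
#' @param edge_model `"on"` (single ON event per pixel crossing, default) or
#'   `"on_off"` (leading ON plus trailing OFF).
#' @param noise_rate homogeneous Poisson background rate in events/px/s
#'   superimposed via [add_noise()]; default 0.
#' @param seed RNG seed for the noise process (required if `noise_rate > 0`).
#' @param quantize_ms optional timestamp quantum in ms; event times are
#'   rounded to multiples of it. Default `NULL` (exact kinematic times).
#' @return an [event_stream()], time-sorted, starting at t = 0.
#' @examples
#' s <- moving_bar("LR", speed = 0.5, bar_length = 4, geometry = c(8, 8))
#' n_events(s)  # 4 x 8 = 32
#' @export
moving_bar <- function(direction, speed, bar_length = NULL,
                       geometry = c(160L, 160L), edge_model = c("on", "on_off"),
                       noise_rate = 0, seed = NULL, quantize_ms = NULL) {
  direction <- match.arg(direction, c(DIRECTIONS_CARDINAL, DIRECTIONS_DIAGONAL))
  edge_model <- match.arg(edge_model)
  if (!is.numeric(speed) || length(speed) != 1 || !is.finite(speed) ||
      speed <= 0)
    stop("speed must be a single positive number (px/ms)")
  w <- as.integer(geometry[1]); h <- as.integer(geometry[2])
  if (is.null(bar_length)) bar_length <- max(w, h)
  bar_length <- as.integer(bar_length)
  if (bar_length < 1L || bar_length > max(w, h))
    stop("bar_length must be in [1, max(geometry)]")

  if (direction %in% DIRECTIONS_CARDINAL) {
    if (direction %in% c("LR", "RL")) {
      y0 <- (h - min(bar_length, h)) %/% 2L
      ys <- y0 + seq_len(min(bar_length, h)) - 1L
      g <- expand.grid(x = 0:(w - 1L), y = ys)
      tt <- if (direction == "LR") g$x / speed else (w - 1L - g$x) / speed
    } else {
      x0 <- (w - min(bar_length, w)) %/% 2L
      xs <- x0 + seq_len(min(bar_length, w)) - 1L
      g <- expand.grid(x = xs, y = 0:(h - 1L))
      tt <- if (direction == "TB") g$y / speed else (h - 1L - g$y) / speed
    }
  } else {
    g <- expand.grid(x = 0:(w - 1L), y = 0:(h - 1L))
    # bar oriented perpendicular to the motion; extent limited along it
    keep <- switch(direction,
      TL_BR = , BR_TL = abs(g$x - g$y - (w - h) %/% 2L) <= bar_length - 1L,
      TR_BL = , BL_TR = abs((g$x + g$y) - (w + h) %/% 2L + 1L) <= bar_length - 1L)
    g <- g[keep, , drop = FALSE]
    tt <- switch(direction,
      TL_BR = (g$x + g$y) / speed,
      TR_BL = ((w - 1L - g$x) + g$y) / speed,
      BL_TR = (g$x + (h - 1L - g$y)) / speed,
      BR_TL = ((w - 1L - g$x) + (h - 1L - g$y)) / speed)
    tt <- tt - min(tt)
  }

  t_ev <- tt; x_ev <- g$x; y_ev <- g$y; p_ev <- rep(1L, length(tt))
  if (edge_model == "on_off") {
    t_ev <- c(t_ev, tt + 1 / speed)
    x_ev <- c(x_ev, g$x); y_ev <- c(y_ev, g$y)
    p_ev <- c(p_ev, rep(0L, length(tt)))
  }
  if (!is.null(quantize_ms))
    t_ev <- round(t_ev / quantize_ms) * quantize_ms
  out <- event_stream(t = t_ev, x = x_ev, y = y_ev, p = p_ev,
                      width = w, height = h)
  if (noise_rate > 0) {
    if (is.null(seed)) stop("a seed is required when noise_rate > 0")
    out <- add_noise(out, rate = noise_rate, seed = seed)
  }
  out
}

#' Superimpose homogeneous Poisson background noise on a stream
#'
#' Adds independent background events at a fixed rate per pixel over the
#' stream's time span, emulating silicon-retina noise. The original events
#' are preserved; the result is re-sorted. Deterministic given `seed`.
#'
#' @param stream an [event_stream()].
#' @param rate noise rate in events/px/s (>= 0; 0 returns the input).
#' @param seed integer RNG seed.
#' @param duration_ms time span over which to draw noise; defaults to the
#'   stream's span (last event time, or 0 for an empty stream).
#' @return an [event_stream()] with the noise merged in.
#' @export
add_noise <- function(stream, rate, seed, duration_ms = NULL) {
  stopifnot(inherits(stream, "event_stream"))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0)
    stop("rate must be a single non-negative number (events/px/s)")
  if (rate == 0) return(stream)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(stream$events)) max(stream$events$t) else 0
  if (duration_ms <= 0) return(stream)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  lambda <- rate * stream$width * stream$height * duration_ms / 1000
  n <- stats::rpois(1, lambda)
  if (n == 0) return(stream)
  event_stream(
    t = c(stream$events$t, stats::runif(n, 0, duration_ms)),
    x = c(stream$events$x, sample.int(stream$width, n, TRUE) - 1L),
    y = c(stream$events$y, sample.int(stream$height, n, TRUE) - 1L),
    p = c(stream$events$p, sample(0:1, n, TRUE)),
    width = stream$width, height = stream$height)
}
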