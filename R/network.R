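#' Wire one direction-selective TDE population onto a sampling scheme
#'
#' Creates one TDE unit per pair of lattice-adjacent receptive fields along
#' the direction's axis: for `LR` the facilitator is the left lattice
#' neighbor of the trigger, mirrored for `RL`, and analogously along columns
#' for `TB` / `BT`. RFs on the downstream edge have no trigger successor and
#' simply contribute no unit, so a `rows x cols` lattice yields
#' `rows * (cols - 1)` horizontal units (and transposed for vertical).
#'
#' @param scheme a `sampling_scheme` with lattice coordinates.
#' @param direction one of `"LR"`, `"RL"`, `"TB"`, `"BT"`.
#' @param params a [tde_params()] used when the population is simulated.
#' @return a `direction_population`: list with `direction`, `fac` / `trig`
#'   (RF ids per unit), `n_units`, `units` (data.frame with the trigger RF's
#'   center, ring and lattice position, used for spatial maps), `params`.
#' @export
wire_population <- function(scheme, direction, params = tde_params()) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  direction <- match.arg(direction, DIRECTIONS_CARDINAL)
  if (is.null(scheme$lattice)) stop("scheme has no lattice coordinates")
  rows <- scheme$lattice[1]; cols <- scheme$lattice[2]
  if (direction %in% c("LR", "RL")) {
    # neighbor pairs along lattice rows: low = (r, c-1), high = (r, c)
    g <- expand.grid(col = 1:(cols - 1L), row = 0:(rows - 1L))
    low <- rf_id_at(scheme, g$row, g$col - 1L)
    high <- rf_id_at(scheme, g$row, g$col)
  } else {
    # neighbor pairs along lattice columns: low = (r-1, c), high = (r, c)
    g <- expand.grid(col = 0:(cols - 1L), row = 1:(rows - 1L))
    low <- rf_id_at(scheme, g$row - 1L, g$col)
    high <- rf_id_at(scheme, g$row, g$col)
  }
  if (direction %in% c("LR", "TB")) {
    fac <- low; trig <- high   # motion toward increasing coordinate
  } else {
    fac <- high; trig <- low   # mirrored
  }
  meta <- scheme$rfs[trig, c("cx", "cy", "ring", "row", "col")]
  rownames(meta) <- NULL
  structure(list(direction = direction, fac = fac, trig = trig,
                 n_units = length(fac),
                 units = cbind(unit = seq_along(fac), meta),
                 params = params, kind = scheme$kind,
                 lattice = scheme$lattice),
            class = "direction_population")
}

#' @export
print.direction_population <- function(x, ...) {
  cat(sprintf("<direction_population %s> %d TDE units (%s scheme, %dx%d lattice)\n",
              x$direction, x$n_units, x$kind, x$lattice[1], x$lattice[2]))
  invisible(x)
}

#' Wire the four cardinal direction populations
#' @inheritParams wire_population
#' @return named list of four `direction_population`s (`LR`, `RL`, `TB`,
#'   `BT`).
#' @export
wire_network <- function(scheme, params = tde_params()) {
  stats::setNames(lapply(DIRECTIONS_CARDINAL, wire_population,
                         scheme = scheme, params = params),
                  DIRECTIONS_CARDINAL)
}

#' Run direction populations on RF spike trains
#'
#' Simulates every TDE unit of each population with its facilitator and
#' trigger RF trains (the facilitator input delayed by
#' `params$fac_delay_ms`). Deterministic for fixed inputs and parameters.
#'
#' @param rf_spikes an `rf_spike_trains` from [rf_integrate()], built from
#'   the same scheme the populations were wired on.
#' @param populations a single `direction_population` or a list of them,
#'   e.g. from [wire_network()].
#' @return a `population_response`: list with `responses` (per direction: a
#'   list with `spikes` (data.frame `unit`, `t`), `n_units`, `units` meta),
#'   `t_span` (stimulus span) and `window` (the default analysis window,
#'   stimulus span extended by 5 membrane time constants).
#' @export
run_network <- function(rf_spikes, populations) {
  stopifnot(inherits(rf_spikes, "rf_spike_trains"))
  if (inherits(populations, "direction_population"))
    populations <- list(populations)
  n_rf <- rf_spikes$n_rf
  sp <- rf_spikes$spikes
  ord <- order(sp$rf, sp$t)
  sp_t <- sp$t[ord]
  counts <- tabulate(sp$rf, nbins = n_rf)
  rf_ptr <- c(0L, cumsum(counts))
  responses <- list()
  tau_m <- NULL
  for (pop in populations) {
    stopifnot(inherits(pop, "direction_population"))
    if (pop$n_units > 0 &&
        (max(pop$fac, pop$trig) > n_rf || !identical(pop$lattice, rf_spikes$lattice)))
      stop("population was wired on a different scheme than the spike trains")
    res <- cpp_tde_population(sp_t, rf_ptr, pop$fac, pop$trig,
                              unclass(pop$params))
    responses[[pop$direction]] <- list(
      spikes = data.frame(unit = res$unit, t = res$t),
      n_units = pop$n_units, units = pop$units, direction = pop$direction)
    tau_m <- pop$params$tau_m_ms
  }
  window <- c(rf_spikes$t_span[1], rf_spikes$t_span[2] + 5 * tau_m)
  structure(list(responses = responses, t_span = rf_spikes$t_span,
                 window = window, width = rf_spikes$width,
                 height = rf_spikes$height),
            class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  cat("<population_response>\n")
  for (r in x$responses)
    cat(sprintf("  %s: %d spikes from %d/%d units\n", r$direction,
                nrow(r$spikes), length(unique(r$spikes$unit)), r$n_units))
  invisible(x)
}

#' Decode motion direction from the four population responses
#'
#' Computes each population's mean firing rate over the analysis window. A
#' cardinal direction is declared when one population dominates the
#' runner-up by at least `rho`; a diagonal when the two leading populations
#' lie on orthogonal axes and agree within a factor `delta` (their
#' combination names the diagonal, e.g. `LR` + `TB` = `TL_BR`). An all-
#' silent response decodes as `"none"`.
#'
#' @param response a `population_response` holding all four cardinal
#'   populations.
#' @param rho cardinal dominance ratio (default 10, the order-of-magnitude
#'   preferred/anti-preferred separation).
#' @param delta diagonal balance factor (default 2).
#' @param window optional `c(t0, t1)` ms; defaults to the response window.
#' @return list with `direction` (one of the 8 codes, `"none"` or
#'   `"ambiguous"`) and `mfr_hz` (named per-population vector).
#' @export
decode_direction <- function(response, rho = 10, delta = 2, window = NULL) {
  stopifnot(inherits(response, "population_response"))
  dirs <- DIRECTIONS_CARDINAL
  if (!all(dirs %in% names(response$responses)))
    stop("decoding requires all four cardinal populations")
  mfr <- vapply(dirs, function(d) mean_firing_rate(response, d, window), 0)
  if (all(mfr == 0))
    return(list(direction = "none", mfr_hz = mfr))
  o <- order(mfr, decreasing = TRUE)
  top <- dirs[o[1]]; second <- dirs[o[2]]
  if (mfr[o[2]] == 0 || mfr[o[1]] / mfr[o[2]] >= rho)
    return(list(direction = top, mfr_hz = mfr))
  horizontal <- c("LR", "RL")
  orthogonal <- xor(top %in% horizontal, second %in% horizontal)
  if (orthogonal && mfr[o[1]] / mfr[o[2]] <= delta) {
    h <- if (top %in% horizontal) top else second
    v <- if (top %in% horizontal) second else top
    diag <- if (h == "LR") {
      if (v == "TB") "TL_BR" else "BL_TR"
    } else {
      if (v == "TB") "TR_BL" else "BR_TL"
    }
    return(list(direction = diag, mfr_hz = mfr))
  }
  list(direction = "ambiguous", mfr_hz = mfr)
}
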