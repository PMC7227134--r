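#' Construct an AER event stream
#'
#' An event stream is the universal input currency of the package: a
#' time-ordered sequence of sensor events, each carrying a timestamp (ms),
#' a pixel address and a polarity, together with the pixel-array geometry.
#'
#' @param t numeric vector of timestamps in milliseconds (>= 0).
#' @param x,y integer vectors of 0-based pixel coordinates; `x` is the column
#'   (increasing rightward), `y` the row (increasing downward), origin at the
#'   top-left corner.
#' @param p polarity vector, `1` for ON (contrast increment) and `0` for OFF
#'   (decrement). Recycled if scalar.
#' @param width,height pixel-array geometry.
#' @return An object of class `event_stream`: a list with elements `events`
#'   (data.frame with columns `t`, `x`, `y`, `p`, sorted non-decreasing in
#'   `t`) and `width`, `height`.
#' @examples
#' s <- event_stream(t = c(1, 0), x = c(1, 0), y = 0, p = 1,
#'                   width = 2, height = 2)
#' s$events$t  # sorted ascending
#' @export
event_stream <- function(t = numeric(), x = integer(), y = integer(),
                         p = integer(), width, height) {
  n <- max(length(t), length(x), length(y), length(p))
  if (n > 0) {
    t <- rep_len(as.numeric(t), n)
    x <- rep_len(as.integer(x), n)
    y <- rep_len(as.integer(y), n)
    p <- rep_len(as.integer(p), n)
  } else {
    t <- numeric(); x <- integer(); y <- integer(); p <- integer()
  }
  width <- as.integer(width); height <- as.integer(height)
  if (length(width) != 1L || length(height) != 1L ||
      is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("geometry must be two positive integers (width, height)")
  ev <- data.frame(t = t, x = x, y = y, p = p)
  validate_events(ev, width, height)
  if (is.unsorted(ev$t)) ev <- ev[order(ev$t), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, width = width, height = height),
            class = "event_stream")
}

validate_events <- function(ev, width, height) {
  if (anyNA(ev)) stop("events contain missing values")
  if (any(ev$t < 0)) stop("timestamps must be >= 0")
  bad <- which(ev$x < 0L | ev$x >= width | ev$y < 0L | ev$y >= height)
  if (length(bad))
    stop(sprintf("event %d at (%d, %d) outside %dx%d geometry",
                 bad[1], ev$x[bad[1]], ev$y[bad[1]], width, height))
  if (!all(ev$p %in% c(0L, 1L)))
    stop("polarity must be 0 (OFF) or 1 (ON)")
  invisible(TRUE)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events on %dx%d px", nrow(x$events),
              x$width, x$height))
  if (nrow(x$events))
    cat(sprintf(", t in [%.4g, %.4g] ms", min(x$events$t), max(x$events$t)))
  cat("\n")
  invisible(x)
}

#' Number of events in a stream
#' @param stream an `event_stream`.
#' @return integer event count.
#' @export
n_events <- function(stream) nrow(stream$events)

#' Read an event stream from a CSV event file
#'
#' The on-disk format is a plain-text CSV with a one-line header comment
#' carrying the geometry (`# geometry <width> <height>`), a column header
#' `t_ms,x,y,p`, and one event per row. Timestamps are milliseconds; `p` is
#' 1 for ON and 0 for OFF events. Rows need not be time-sorted on disk; the
#' returned stream always is.
#'
#' @param path path to the event file.
#' @param geometry optional `c(width, height)` override; required if the file
#'   has no geometry header.
#' @return a validated, time-sorted [event_stream()].
#' @export
read_events <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop("no such event file: ", path)
  lines <- readLines(path)
  gi <- grep("^#[[:space:]]*geometry", lines)
  if (length(gi)) {
    gv <- suppressWarnings(as.integer(
      strsplit(trimws(sub("^#[[:space:]]*geometry[:,]?", "", lines[gi[1]])),
               "[,[:space:]]+")[[1]]))
    gv <- gv[!is.na(gv)]
    if (length(gv) != 2) stop("malformed geometry header in ", path)
    if (is.null(geometry)) geometry <- gv
  }
  if (is.null(geometry))
    stop("event file has no geometry header and no override was supplied")
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) == 0 || !grepl("^t_ms", body[1]))
    stop("event file must carry a 't_ms,x,y,p' column header")
  body <- body[-1]
  if (length(body) == 0)
    return(event_stream(width = geometry[1], height = geometry[2]))
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("malformed event row (line content '%s'): expected 4 fields",
                 body[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 4,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("malformed event row (line content '%s'): non-numeric field",
                 body[bad]))
  }
  event_stream(t = m[, 1], x = m[, 2], y = m[, 3], p = m[, 4],
               width = geometry[1], height = geometry[2])
}

#' Write an event stream to a CSV event file
#'
#' Inverse of [read_events()]: `read_events(write_events(s, path))`
#' reproduces `s` exactly (timestamps are written with enough digits for the
#' 0.1 ms internal resolution and beyond).
#'
#' @param stream an `event_stream`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# geometry %d %d", stream$width, stream$height), con)
  writeLines("t_ms,x,y,p", con)
  ev <- stream$events
  if (nrow(ev))
    writeLines(sprintf("%.6f,%d,%d,%d", ev$t, ev$x, ev$y, ev$p), con)
  invisible(path)
}
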