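# Shared, lazily built pipeline objects so the slower characterization
# tests reuse schemes, wiring and stimulus runs.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

paper_scheme <- function() cached("ecc", build_eccentric(grid_spec()))
uniform_scheme <- function() cached("unif", build_uniform(c(160, 160), 4))

paper_pops <- function() cached("ecc_pops", wire_network(paper_scheme()))
uniform_pops <- function() cached("unif_pops", wire_network(uniform_scheme()))

# full pipeline run on a moving bar, memoised on (scheme, direction, speed)
run_bar <- function(direction, speed, scheme = c("eccentric", "uniform"),
                    bar_length = NULL) {
  scheme <- match.arg(scheme)
  key <- paste("run", scheme, direction, speed,
               if (is.null(bar_length)) "full" else bar_length)
  cached(key, {
    sch <- if (scheme == "eccentric") paper_scheme() else uniform_scheme()
    pops <- if (scheme == "eccentric") paper_pops() else uniform_pops()
    run_pipeline(moving_bar(direction, speed, bar_length = bar_length),
                 sch, pops)
  })
}

mfr_all <- function(resp) {
  vapply(c("LR", "RL", "TB", "BT"),
         function(d) mean_firing_rate(resp, d), 0)
}
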