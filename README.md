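# retinemd

Spiking motion detection on event-camera streams with a retina-inspired,
space-variant front end — in simulation, end to end.

Event (AER) cameras report asynchronous per-pixel events instead of
frames, which makes them attractive for robots that must react to motion,
but raw event streams are still too dense to process naively. `retinemd`
implements and characterizes a two-stage spiking architecture for this
problem:

1. **Eccentric down-sampling.** Square receptive fields (RFs) whose side
   shrinks linearly from `max_rf` px at the field border to a single
   pixel in a central fovea, mimicking the photoreceptor density gradient
   of the mammalian retina. Each RF is an event-driven leaky integrator,
   `M <- M e^{-dt/tau} + 1/R_nf`, spiking at threshold 1 with the
   area-proportional normalization `R_nf = max(1, 0.6 * size^2)`. For a
   160×160 array with a 10% fovea and 10×10 peripheral RFs this yields
   8836 RFs on a 94×94 lattice (a non-overlapping 4×4 uniform grid of
   1600 RFs serves as baseline).
2. **Spiking elementary motion detectors (sEMD).** Each unit is a
   time-difference encoder (TDE): a *facilitator* RF opens a gain trace
   `g(t) = e^{-(t-t_f)/tau_gain}` and a lattice-adjacent *trigger* RF
   injects an EPSC of amplitude `w_syn * g(t_t)` into a leaky
   integrate-and-fire soma, so the output spike count encodes the
   RF-to-RF travel time `Δt = t_t - t_f` (many spikes for small positive
   `Δt`, none for negative). Four populations wired along lattice rows
   and columns (LR, RL, TB, BT) encode direction; their combination
   decodes diagonals.

The package also provides the synthetic moving-bar stimulus generator, a
plain-text AER event file format, and the full characterization suite:
direction selectivity, speed tuning, spatial firing-rate maps,
eccentricity profiles, center-of-mass-of-response analysis and bar-length
experiments. See the vignette (`vignettes/eccentric-motion-detection.Rmd`)
for the model details and design decisions.

## Worked example

A full-field bar sweeping left-to-right at 0.3 px/ms through the
eccentric pipeline:

```r
library(retinemd)

scheme <- build_eccentric(grid_spec())   # 160x160, 10% fovea, max RF 10 px
scheme
#> <sampling_scheme: eccentric> 8836 RFs on a 94x94 lattice over 160x160 px
#>   fovea 50x50 (1-px RFs), 22 rings, RF sizes 1..10 px

pops <- wire_network(scheme)             # LR, RL, TB, BT populations
stream <- moving_bar("LR", speed = 0.3)  # 25600 events over 530 ms
resp <- run_pipeline(stream, scheme, pops)

sapply(names(resp$responses), function(d) mean_firing_rate(resp, d))
#>     LR     RL     TB     BT
#> 32.467  0.000  1.579  1.579

decode_direction(resp)$direction
#> [1] "LR"
```

The preferred (LR) population fires at ~32.5 Hz averaged over all 8742
units and the traversal window, the anti-preferred population is silent,
and the two perpendicular populations are suppressed more than
twenty-fold by the 1 ms facilitator delay. The first output spike arrives
36.3 ms after stimulus onset — the time for the bar to cross one
peripheral 10×10 RF and charge the trigger — and the response's center of
mass sits 34.5 px from the field center. Slower bars concentrate activity
in the fovea, faster ones push it to the periphery:

```r
center_of_mass(spatial_map(run_pipeline(moving_bar("LR", 0.03), scheme, pops), "LR"))
#> [1] 27.4
center_of_mass(spatial_map(run_pipeline(moving_bar("LR", 1.0), scheme, pops), "LR"))
#> [1] 51.5
```

A command-line wrapper for the same operations lives in
`inst/cli/retinemd.R` (subcommands `generate`, `sample`, `tde-curve`,
`run`, `sweep`).

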