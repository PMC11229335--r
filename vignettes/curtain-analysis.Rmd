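---
title: "Analysing single-molecule DNA curtain experiments with curtainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing single-molecule DNA curtain experiments with curtainr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(curtainr)
library(dplyr)
```

## The experimental system

DNA curtains tether hundreds of ~48.5 kb lambda DNA molecules between
chrome barriers in a flow cell and image them by prism TIRF microscopy.
A presynaptic complex (PSC) — a Rad51 filament on a short ssDNA, bound by
GFP-tagged Rad54 — is injected, binds the duplex, and translocates along it
while searching for a sequence homologous to its ssDNA. Three channels are
acquired in alternation under shuttered illumination: GFP-Rad54 (green),
the Atto647N-labelled 90-mer ssDNA carried by the PSC (blue) and
RPA-mCherry (magenta), whose recruitment marks duplex DNA transiently
underwound behind the translocating motor. Each DNA molecule is reduced to
a kymograph: a time-by-position intensity matrix read along a 1-pixel-wide
line.

`curtainr` implements the full quantitative chain for this assay — a
generative simulator standing in for the microscope, kymograph track
segmentation, population mixture fitting, RPA colocalization and
stoichiometry analysis, homology-search target scoring — plus the red/white
colony assay that scores recombination outcomes (crossover, non-crossover,
break-induced replication, chromosome loss) in diploid yeast.

## The synthetic-data generator

`simulate_tracks()` draws ground-truth trajectories:

* **Binding.** New molecules arrive as a Poisson process
  (`binding_rate` per DNA per frame) during an injection window
  (`bind_window_frames`, default 100 frames = 40 s): protein is delivered
  by flow at the start of acquisition and then washed out. The default
  density (`binding_rate = 0.02`, about two molecules per DNA) matches the
  sparse single-molecule occupancy the assay is designed for; crowded
  curtains make single-particle tracking ambiguous in real data for the
  same reason they do here.
* **Velocity.** Drawn from a Gaussian mixture truncated below at zero.
  Defaults are the wild-type PSC populations: 114.3 +/- 73 and
  394 +/- 183 bp/s at equal weight. Components may be specified through
  `truncnorm_match()`, which finds the underlying normal whose *truncated*
  moments match a published sample mean and SD; for populations whose
  printed coefficient of variation reaches or exceeds 1 (e.g. the
  Rad54-alone 65 +/- 67 bp/s population) the mean is matched exactly and
  the SD as closely as the zero-truncated family permits.
  An optional `velocity_floor_bp_s` truncates the draw at the assay's
  resolution floor: a molecule that cannot cover the ~5 pixels needed to
  call and time a translocation within the observation window is scored
  *immobile* in this assay, not slow, so a generator emulating a measured
  velocity population should carry no mass below that floor.
* **Distance.** An independent truncated-Gaussian mixture (defaults 4.1
  +/- 0.9 and 6.2 +/- 1.9 kb); the motor stops at its drawn distance, or
  earlier at a tether end (ends stall the motor; no reflection).
* **Pauses.** Each moving frame starts a pause with probability
  `pause_prob_per_frame` (default 0.005), lasting 2-4 frames. Pauses are
  kept rare by default because the endpoint velocity formula includes
  pause time: the printed velocity populations are endpoint measurements
  and already fold typical pausing in.
* **Homology capture.** With a target coordinate set, a molecule crossing
  the site is captured with `p_capture_1d` (1D alignment), and a fraction
  of binders lands directly on the site (`p_capture_3d`, 3D alignment);
  captured molecules may release and leave after `dwell_release_s` with
  probability `p_transient_release`.

`simulate_rpa()` attaches at most one RPA episode to each moving track
(molecule count from `stoich_probs`; `stoich_probs_nbinom()` builds a
shifted negative-binomial with a requested conditional mean and SD —
defaults 2.5 +/- 1.5 molecules with a 30% chance of no visible episode),
with an association delay after PSC binding (default exponential, mean
12.1 s, i.e. median ~8.4 s = 0.14 min) and an exponential bound lifetime
(default mean 300 s, chosen so that roughly half of wild-type episodes end
within a 4-minute movie). Episodes that outlast the observable span are
censored.

`render_kymograph()` converts truth into the three intensity matrices:
each fluorophore deposits `unit_intensity` through a 1-D Gaussian PSF
integrated over 1000-bp pixel bins (pixel *p*, 0-based, covers
`[p, p+1) * 1000` bp), multi-molecule RPA episodes contribute one unit per
unbleached molecule, every fluorophore bleaches independently with
geometric survival (`bleach_rate_per_frame`, default 2e-4 — shuttered
illumination makes bleaching slow relative to a movie), and Gaussian camera
background is added. The generating truth is retained on the object so that
every downstream stage can be tested as a round trip.

What the generator deliberately does **not** emulate: flow or tether
failures, stage drift, chromatin or other roadblocks, camera blooming,
channel bleed-through (the real instrument suppresses it by shuttering and
filters), 2-D imaging beyond the 1-pixel line, or multiple RPA episodes
per molecule. Passing tests therefore demonstrate that the analysis
recovers what this idealised instrument produced; they do not certify
performance on drifting, bleed-through-contaminated real data.

## Track segmentation

`detect_tracks()` finds per-frame intensity peaks above
`background + detection_snr * noise` (background and noise estimated by the
median and MAD of the whole matrix, which is overwhelmingly signal-free),
localizes each peak by a 3-point centroid, and links detections across
frames by nearest-position association within `link_gate_px` (default
3 px/frame), tolerating `max_gap_frames` missed frames. Two measures keep
identities honest at this pixel scale, where no real molecule moves more
than ~0.3 px/frame:

* association is *predictive* — each track extrapolates its recent drift,
  which keeps two crossing molecules on their own paths;
* a frame-to-frame jump larger than `max_step_px` (default 2 px) cannot be
  motion and splits the track at that point: such jumps arise when a
  detection is momentarily claimed by a neighbouring molecule.

The translocation rules then annotate each track:

* **Start**: the first frame whose net displacement from the binding pixel
  exceeds 2 px (strictly). The start pixel `Yi` is the pixel at that frame.
* **Pause**: a stall of 2-4 frames after the start.
* **Termination**: the *final* static plateau, longer than 10 frames, that
  the molecule never leaves; the stop frame `Xf` is the plateau's first
  frame. The plateau is anchored at the molecule's final position and
  tolerates +/-1 px localization jitter. Anchoring at the end matters at
  ~1 kb/pixel: a 114 bp/s molecule dwells ~22 frames in every pixel it
  crosses, so a rule that terminated a track at *any* long static run
  would cut every slow molecule off at its start frame and make slow
  populations unmeasurable; the final-plateau reading preserves the rule's
  meaning (a molecule that stops and never moves again) at any speed.

Positions are pixel-rounded for all rule evaluation and for the endpoint
formula (sub-pixel centroids are retained on the track table, but the
3-point centroid is compressed toward pixel centres — "pixel locking" —
which distorts short displacements, so the formula sticks to the pixel
positions its thresholds are stated in).

`compute_velocity()` implements the endpoint formula
`|Yf - Yi| * 1000 bp / ((Xf - Xi) * frame interval)`; pauses are included
in the elapsed time (a pause-excluded variant is available but not the
default), a track that never starts has no velocity, and population
analyses pass `min_displacement_px = 2`: a molecule that moved a single
pixel between its endpoints has not moved far enough for an accurate
velocity, its estimate being dominated by pixel quantisation.
`compute_distance()` is `|Yf - Yi|` in kb.

## Population fitting

`fit_mixture()` is a univariate Gaussian-mixture EM with 10 restarts
(quantile-split initialisation first, random data points after), an SD
floor of 1e-6 times the sample SD, and a degeneracy guard: a restart in
which a component collapses onto fewer than two effective observations (a
likelihood spike on duplicated values — endpoint velocities are ratios of
small integers and contain exact duplicates) is never preferred over a
proper optimum. `select_model()` compares single-Gaussian, lognormal
(closed-form MLE), and two- and three-component fits by BIC, breaking ties
toward fewer parameters. BIC was chosen over AIC to penalise the
three-component fit's extra parameters on samples of a few hundred tracks.
`tidy()`/`glance()` expose components and fit statistics;
`autoplot()` overlays the component densities on the sample histogram.

## RPA colocalization and stoichiometry

`detect_colocalization()` calls an RPA episode when the magenta channel has
a peak within `tolerance_px` (2 px) of a segmented track for at least two
consecutive frames; single-frame coincidences are noise. Association and
dissociation are the first and last colocalized frames, and an episode
still present in the movie's last observable frame is censored.
`association_times()` converts the binding-to-colocalization lag to
seconds and reports the median (robust against the long delay tail);
`fraction_dissociated()` reports the share of uncensored episodes — a
decay-rate fit is deliberately not used because dissociation curves from
different variants do not share an end point.

Event intensity is the background-subtracted intensity integrated over a
+/-3 px window, divided by the captured PSF mass (aperture correction) and
summarised as the median of the first five colocalized frames — early
frames, before appreciable photobleaching, and a median rather than a
maximum because the maximum of a noisy series is biased upward.
`estimate_stoichiometry()` divides by the calibrated single-fluorophore
intensity, floors at zero, quantizes to the bracketing integer counts
(with a 0.01-molecule tolerance so a noiseless integer count does not
straddle the boundary) and multiplies by the 30-nt RPA footprint to give
the underwound-DNA extent: 2-3 molecules correspond to 60-90 nt of opened
duplex. Molecules whose PSF partially falls off the imaged line (within
~3 px of a DNA end) lose flux and are under-estimated; mid-DNA events are
unbiased.

## Homology-search scoring

`binding_profile()` histograms PSC positions at a snapshot time (default
900 s of observation) into 1000-bp bins — one bin per pixel, since
positions are pixel-resolved. `enrichment_at_target()` divides the target
bin's probability by the mean off-target probability, or by the same bin
of a reference profile (a non-homologous DNA control);
`fold_enrichment()` is the bare ratio. `classify_search_mode()` labels
each track ending within one bin of the target as 1D when it translocated
more than `min_1d_kb` (2 kb) before stabilizing, otherwise 3D — a
translocation faster or shorter than the resolution cannot be excluded and
is classed 3D by this operational definition. `transient_fraction()`
reports, among molecules that dwelt at the target for at least
`min_dwell_s`, the share that subsequently released. The default threshold
is 20 s; 10 s is an alternative convention in circulation for the same
quantity, so the threshold is an argument rather than a constant.

## Colony outcomes

`simulate_colony_assay()` generates red/white assay records: colony colour
(white, red, or red/white sectored from the two sister chromatids' gene
conversion tract lengths), per-sector hygromycin and nourseothricin
resistance, and growth on -Ura/-Met as the chromosome-segregation control.
`classify_colony()` applies the marker decision tree: failed segregation
control = chromosome loss (checked first); sectors each resistant to
exactly one, different, antibiotic = crossover; red sector doubly
resistant with a singly-resistant white sector = break-induced
replication; unchanged double resistance = non-crossover; anything else
lands in an explicit `unclassifiable` category rather than being dropped —
real plates contain ambiguous colonies. BIR is only *inferable* from
sectored colonies (a solid colony's BIR marker pattern is identical to
NCO), so the simulator rejects BIR probability mass on solid or white
classes. `tally_outcomes()` computes per-replicate fractions within the
chosen population (sectored, solid red, or total) and their mean +/- SD
across replicates; `compare_strains()` tests a category between strains
with Welch's t-test on replicate fractions (robust to unequal variance),
with a label-permutation alternative used to validate it.

## Worked example

A small end-to-end run — simulate a curtain, segment it, and fit the
velocity population:

```{r example, eval = FALSE}
op <- optics_params(n_frames = 600)
mo <- motor_params()                       # wild-type PSC defaults
sim <- simulate_curtain(mo, op, rpa = rpa_gen_params(),
                        n_dna = 50, seed = 1)

seg <- bind_rows(lapply(sim$kymographs, detect_tracks)) |>
  compute_velocity(op, min_displacement_px = 2) |>
  compute_distance(op)

v <- seg$velocity_bp_s[!is.na(seg$velocity_bp_s)]
fit <- fit_mixture(v, k = 2, seed = 1)
tidy(fit)
autoplot(fit)
```

## Numerical and scale choices

* Pixel-bp mapping fixed at 1000 bp/pixel; lambda DNA defaults to
  48,502 bp on 49 pixels. Coordinates are 0-based with half-open pixel
  bins; positions are stored in bp and converted at render time.
* The per-channel frame interval defaults to 0.4 s (200 ms integration
  plus 200 ms shutter delay); the true per-channel cadence under
  alternating three-colour excitation is instrument-dependent, so it is a
  parameter.
* "Moved > 2 pixels" is read as *net* displacement from the binding pixel,
  robust to localization jitter, rather than cumulative path length.
* The "x frame rate" factor of the endpoint velocity formula is treated as
  the frames-to-seconds conversion; no extra factor is applied when times
  are already in seconds.
* Parameter-recovery analyses in the test suite and in
  `scripts/acceptance.R` use movies of 1125-1200 frames (7.5-8 min) with a
  100-frame injection window, 380-2600 DNA molecules per condition (500 to
  over 2500 simulated trajectories, of which the measurable subset is
  typically 25-45%; the Rad54-alone harness uses singly occupied DNAs,
  the cleanest tracking regime), 300-420 molecules for RPA event
  statistics and 6 x 500 colonies for outcome statistics. These sizes put the recovery
  sampling error well inside the tolerances being checked while keeping a
  full run in minutes on one core.
* Mean recovery of a heavy-tailed velocity population is intrinsically
  noisy: the measured Rad54-alone population has a near-exponential right
  tail, so sample means over a few hundred molecules scatter by several
  bp/s. The recovery analyses therefore use the largest simulation sizes
  the runtime budget allows rather than a robust location estimate, since
  the published quantity is a plain mean.

## Known limitations

* Endpoint velocities are quantized by the 1 kb pixel; displacements of
  2-3 px carry 20-30% per-molecule error, and measured populations are
  conditioned on covering ~5 px within the observation window. Slow
  molecules below the resolution floor are scored immobile, exactly as
  they are invisible to the real assay.
* Linking is nearest-position with prediction; two molecules dwelling
  within ~2 px of each other for long stretches can still exchange
  identity. Track splitting at impossible jumps removes the resulting
  artifacts at the cost of fragmenting such tracks.
* The intensity model is linear with Gaussian background; EMCCD
  excess noise and gain nonlinearity are not modelled, so absolute
  stoichiometry accuracy on real cameras depends on the single-fluorophore
  calibration absorbing those effects.
* The colony simulator encodes long- versus short-tract conversion only
  through colony colour; tract lengths, I-SceI cutting kinetics and
  galactose induction are out of scope.
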