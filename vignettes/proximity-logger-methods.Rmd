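---
title: "Models and methods behind proxlogr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proxlogr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxlogr)
library(dplyr)
```

proxlogr simulates and analyses data from animal-borne proximity loggers:
small radio transceiver tags that broadcast an identification pulse on a
fixed schedule, listen for the pulses of other tags, and save a compact
"encounter log" (partner id, start/end time, minimum/mean/maximum RSSI)
for every contiguous bout of mutual proximity. The package has two halves
that meet in the middle:

* a **generative half** — a seeded world simulator (movement, radio
  propagation, tag firmware) that produces synthetic deployments with the
  statistical structure real deployments show, and
* an **analysis half** — the log-reconciliation pipeline (merging, dyad
  calling, broken/staggered classification), calibration-fitting,
  reliability statistics, and RSSI-thresholded contact networks.

Because the generative half is explicit, every analysis can be validated
against known ground truth. This vignette records the models, their
assumptions, the tunable parameters, and the design decisions taken where
the design was genuinely open.

## The radio model

Expected RSSI for a link at distance $d$ (m), relative antenna angle
$\theta$, and mount $m$ is

$$\mu(d, \theta, m) = r_\mathrm{ref} + s\,\log_{10} g(d)
  + G\,[m = \mathrm{body}]
  - P_\mathrm{max}\left(1 - e^{-d/\lambda}\right)\sin\theta,$$

a log-distance path-loss law with three structural refinements.

**Effective distance.** $g(d) = d_\mathrm{sat}(1 - e^{-d/d_\mathrm{sat}})$
with $d_\mathrm{sat} = 3.5$ m: essentially the true distance within a few
meters, flattening mildly in the far field. Fixed, not estimated.

**Anchors.** The two defaults that matter most are distance anchors used
for network thresholds: a body-mounted pair with parallel antennae reads
RSSI 40 at 0.1 m (body contact) and RSSI 0 at 5 m (social proximity).
Solving the curve through those anchors gives the default slope
$s = -27.90$ per decade of effective distance and body reference
$+11.93$ at 1 m. Overriding `d_sat` re-solves the anchors, so the
threshold semantics survive reparameterization.

**Orientation.** Dipole antennae couple best when parallel. The penalty
is $P_\mathrm{max}\sin\theta$ (axial: angles fold onto $[0, \pi/2]$),
developing with distance over $\lambda = 0.13$ m — at contact orientation
barely matters, by a meter the full penalty (default 19.5 RSSI) applies.

**Mounts.** An animal (or saline-filled) body amplifies the signal
relative to a bare tag on a pole; a single additive gain (default +5)
captures this, with carcass and saline mounts treated as equivalent.

**Floor and ceiling.** Reported RSSI lives in $[-17, 57]$. The ceiling is
a reporting clamp. The floor is the receiver's *sensitivity limit* and is
treated asymmetrically on purpose: in a static calibration trial the
repeater reports the floor value, but in a moving deployment a pulse whose
momentary RSSI falls below the floor simply fails to decode — no
detection happens at all. This one mechanism produces several observed
phenomena at once: far-field distance bins pile up on the floor (which is
why they look flat and mutually indistinguishable), encounters end when a
link degrades rather than logging ever-lower values, and recorded minima
bottom out near the floor.

**Noise.** Per-pulse noise is Gaussian with SD
$\sigma(d) = \sigma_0 (1 + \min(d, 10)/6)$, $\sigma_0 = 2.5$: tight at
close range (long close encounters keep high minima), growing through the
mid-range, capped beyond 10 m. Readings are rounded to integers.

**Shadow fading.** Real links are blocked by bodies and structures for
stretches of time, not per pulse. Each *directed* link (listener hearing
source) carries an AR(1) bias with stationary SD 8 and correlation time
600 s, independent per direction — the wearer's own body obstructs its
receiver regardless of the reverse link. Persistent one-sided blockage is
the dominant mechanism by which a genuine two-bird encounter ends up
recorded by only one of the tags.

**Flight posture.** A bird flying between perches holds its antenna
cross-polarized relative to perched birds; links with a flying endpoint
lose `flight_attenuation` (12 RSSI). This keeps fleeting transits past
occupied nests from generating strong spurious detections while still
allowing the occasional brief on-the-wing log at low RSSI.

**Ranges.** Receiver stations (elevated, clean antennae) decode out to
100 m. Body-worn tags at perch height in clutter decode each other only
to `tag_range_m` (12 m); pole-mounted line-of-sight calibration grids
reach much farther, which is why static trials can span 40 m while
deployed tags never log distant neighbours.

```{r curve, fig.width = 6, fig.height = 3.5}
p <- propagation_params()
autoplot(fit_propagation(simulate_calibration(p, seed = 1)),
         records = simulate_calibration(p, seed = 1), true_params = p)
```

## The movement model

No movement statistics exist for the study system, so the trajectory
generator is a deliberately simple stand-in whose purpose is to produce
the *kinds* of proximity structure the logging hardware has to cope with,
not to be a behavioural model:

* **Home range.** Each tag is attracted to its nest; displacement follows
  a mean-reverting (OU) process (stationary SD 1.5 m, relaxation 20 s)
  hard-limited to `home_radius_m` (7 m), plus brief in-range flight
  excursions. Because nests sit at least `nest_spacing_m` (20 m) apart,
  non nest-mates can never meet without a visit — a property the tests
  rely on.
* **Visits.** At rate `visit_rate_per_h`, a bird relocates (at 8 m/s
  flight speed, so transits are fleeting) to another bird's nest and the
  visit holds both birds at the colony. About 40% of visits are
  side-by-side contact perching (0.1 m offset, antennae aligned, longer
  duration); the rest perch a few meters off (4–7 m, own orientation,
  shorter). The two visit classes generate the two ends of the encounter
  spectrum: strong contact dyads and marginal, fragment-prone proximity.
* **Foraging absences.** Birds alternate at-colony and away bouts
  (exponential, means 600 s / 900 s); an away bird is beyond radio range
  of everything. Absences produce the long separations and sparse
  cross-pair logging of real deployments.

What the generator does *not* emulate: three-dimensional posture,
terrain or obstacle-specific radio paths, coordinated group movement, and
any calibrated species-specific behaviour. Passing tests therefore show
that the pipeline is correct for data with this structure, not that the
movement model describes any particular animal.

## The firmware state machine

Tags pulse every 20 s at unsynchronized per-tag phases and process each
decoded detection through a deterministic state machine:

* A detection at or above the RSSI threshold (default 0) with no open
  encounter for that partner **opens** one (subject to the 30-partner
  concurrency limit). A detection below the threshold with no open
  encounter is ignored.
* Once an encounter is open, **every decoded pulse** updates the running
  minimum/maximum/sum — including pulses below the threshold, down to the
  sensitivity floor. The threshold gates initiation, not continuation,
  which is why saved logs carry minima well below the threshold while
  every saved log's maximum is at least the threshold.
* A missed pulse slot (gap greater than the pulse interval) **closes** the
  encounter with its end at the last detected pulse; recorded duration is
  last-minus-first pulse, so a one-pulse log has duration exactly 0.
  Reaching the 300 s cap closes the log and the next detection reopens —
  the gap left behind is exactly one pulse interval, which the merge step
  later reverses.
* Closed logs are **saved** to a 300-log memory; overflow drops the
  newest log (counted). Daily download windows move memory to permanent
  storage. Past its battery life a tag keeps pulsing but resets at random
  times, wiping memory — and a download never reaches a dead tag before
  a reset does, so its logs are lost, which is what converts its
  encounters into single logs on the healthy partner's side.
* Clocks drift (default 3 s/day) and re-zero whenever a receiver-station
  time broadcast (every 15 min) is in range; after a reset the clock
  saver restores time to the last save plus half the save period plus two
  seconds.

One accounting identity holds exactly and is asserted in the tests: every
tag-side detection is either absorbed into a saved log, dropped with a
full memory, wiped by a reset, refused by the concurrency limit, or
skipped below-threshold with no open encounter.

## The reconciliation pipeline

* **Merging** recombines same-logger same-partner logs separated by at
  most 20 s (the pulse rate); merged minima/maxima are extrema, means are
  pulse-count-weighted. Merging is idempotent, and output logs per pair
  are separated by more than the merge gap.
* **Dyad calling** matches complementary merged logs whose closed time
  intervals overlap — endpoint touching included, a convention chosen
  because integer-second timestamps make half-open rules ambiguous.
  Overlap chains: when one side's continuous log spans several fragments
  on the other side, the whole set is one encounter record (implemented
  as connected components of the interval-overlap graph, verified against
  a brute-force matcher over ~20,000 enumerated fragment topologies).
  Records partition exactly into dyadic and single.
* **Broken** records have one continuous side and a fragmented side with
  an internal gap above 21 s; **staggered** records have a start or end
  overhang above 21 s. Both thresholds are deliberately distinct from the
  20 s merge gap and configurable.
* **Uptime restriction** intersects all tags' operational intervals and
  keeps only records contained in the intersection — records straddling a
  cutoff are removed, so network matrices only describe periods when
  every tag could have logged.
* Zero-duration logs are retained throughout; no minimum-duration filter
  exists by default, because one-pulse logs with high maxima are genuine
  close contacts.

## Calibration analyses

`simulate_calibration()` emulates a field trial: 11 tag pairs at
0/0.1/0.5/1/2/5/10 m, both orientations, three replicate readings per
setup, plus pair- and tag-level random intercepts. A key term is the
**between-placement (multipath) effect**: each pair × distance ×
orientation setup carries a random offset with SD
$10\,(1 - e^{-(d/4)^2})$. Ground-reflection interference makes mid-range
readings depend sensitively on exact antenna placement while the direct
path dominates near contact; replicates within one setup share the
offset. Together with the floor pile-up this is what makes the 5 m and
10 m bins statistically indistinguishable at the trial's design size
while every closer pair of bins separates — the qualitative pattern a
well-run trial shows.

`fit_propagation()` fits linear mixed models (lme4/lmerTest) with pair-
and setup-level random intercepts, in both the log-effective-distance
parameterization (whose distance coefficient is the propagation slope)
and the conventional linear-in-meters one. Readings at the hardware
floor or ceiling are censored, not noisy: bins with more than 25% clipped
readings are dropped, then remaining clipped rows — without this the
ceiling-saturated contact bin biases the slope by roughly 15% and the
nominal standard errors collapse. With it, the slope is recovered with a
median relative error near 2% and close-to-nominal 2-SE coverage at the
trial design size.

`distance_bin_discriminability()` compares every pair of distance bins by
Welch tests on orientation-adjusted readings with Holm correction;
`infer_distance_bin()` maps a maximum RSSI to the coarse bins the
thresholds define (closer than 0.1 m / closer than 5 m / 5 m or farther)
plus a per-bin likelihood profile marginalized over orientation — never a
point distance, which single RSSI values cannot support.
`receiver_variability()` summarizes station-to-station spread; its CV
uses the station-facing (parallel) readings because pooling orientations
drives the mean RSSI through zero where a CV is meaningless.

## Reliability statistics

`reciprocity_stats()` summarizes the absolute between-side differences of
dyadic records for each of maximum, minimum, mean RSSI and duration, with
paired mean-difference tests.

`fit_dyad_probability()` models dyadic-vs-single status by logistic
regression on encounter covariates restricted to cap-length (≤ 300 s)
records. Two decisions deserve explanation:

* **Covariates average the two sides** of a dyad rather than taking the
  min/max over both sides. Taking the minimum over both sides adds an
  extra order statistic that one-sided singles cannot have and biases the
  minimum-RSSI coefficient downward; side averages estimate the same
  encounter-level quantity on both record types. (Network construction
  deliberately keeps max-over-sides: an encounter counts by its best
  evidence of proximity.)
* **The informative model is minimum RSSI + duration.** The four
  candidate RSSI covariates of one encounter are strongly collinear, and
  the encounter minimum is additionally entangled with duration through
  an order-statistic effect (longer records sweep lower minima at any
  censoring point). In the full four-predictor fit the minimum-RSSI
  coefficient is therefore sign-unstable even when, within every duration
  stratum, the probability of a dyad *increases* with the minimum — a
  textbook adjustment artifact. The reduced fit
  (`predictors = c("min_rssi", "duration")`) carries the interpretable
  effects and recovers both expected positive signs essentially always in
  simulation. The `predictors` argument makes either choice explicit.

`match_broken_logs()` pairs each broken record with the unmatched
unbroken record of nearest duration (ties: earlier start), removing the
duration confound before `broken_vs_unbroken_summary()` compares RSSI
statistics between the groups with Welch tests and Cohen's d. The
comparison is made on cap-length records; chained super-records beyond
the cap mix contact and marginal segments and dilute the contrast.

## Networks

`build_network()` counts threshold-passing encounters per unordered pair
(dyadic records once, by their larger side; singles once, by their own
maximum) into a symmetric integer matrix. Thresholds nest by
construction: every edge at 40+ exists at 0+, and density is monotone
non-increasing in the threshold. Exports (edge list, matrix, GraphML via
igraph) round-trip losslessly including isolated nodes and the `sex` node
attribute; the force-directed plot is a convenience view, not part of the
analytical contract.

## Numerical conventions and degenerate inputs

* Time is integer seconds from a configurable epoch; CSV interchange uses
  ISO-8601 UTC and round-trips exactly. All randomness flows from one
  seed via fixed per-component derivation, and a repeated run is
  byte-identical.
* Distances below 0.01 m clamp (contact); relative angles fold to
  $[0, \pi/2]$.
* Degenerate inputs fail loudly: single-distance calibration designs,
  single receiver stations, empty pulse streams, out-of-order detection
  streams, overlapping same-pair logs from one logger, unknown listener
  ids, and arenas too small for their nest grid are all explicit errors;
  an empty common-uptime intersection warns and returns no records.
* Complete separation in the logistic fit is detected and reported; if
  glmnet is installed a ridge-penalized fit replaces the unstable
  estimates, with a warning either way.

## Problem sizes used by the checks

The package validates itself at desk scale, chosen once: reciprocity on a
sedentary colony of 17 tags over one compressed hour (away bouts and
visits off, 1.5 m home radius so even perpendicular nest-mate readings
stay above the decode floor — the conditions under which perfect
reciprocity is the correct expectation); calibration recovery over 50
trial sets at the 11-pair design size; direction-of-effect recovery over
20 colony deployments of 15 tags across 4 days of twice-daily 3 h
windows (roughly 28 duration-matched broken/unbroken pairs per run); and
oracle equivalence over exhaustively enumerated fragment sets of up to
four fragments per side.

## Known limitations

* The movement model is a stand-in; none of its parameters are calibrated
  to any species, and conclusions about real data must rest on the
  pipeline's correctness, not on the generator's realism.
* The radio model is two-dimensional and ignores terrain, obstacles and
  3-D posture beyond the flight-attenuation shorthand.
* The mean-RSSI of a log is the exact arithmetic mean of its pulses; real
  hardware may use a running integer approximation.
* Whether real firmware closes an encounter after exactly one missed
  pulse slot is unknown; one slot is assumed, which makes the 20 s merge
  rule the exact inverse of the split.
* Dyad calling requires interval overlap, so two complementary one-pulse
  logs a few seconds apart (phase offset) are called two singles. This is
  a property of any overlap rule at these pulse rates, and one reason
  brief encounters are systematically under-called as dyads.
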