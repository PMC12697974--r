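---
title: "The gemaflow engine: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gemaflow engine: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemaflow)
```

Geographic ecological momentary assessment (GEMA) pairs brief, repeated
in-situ surveys with continuous background location capture, so that survey
prompts — and the exposure measures analysed later — can be conditioned on
*place*: a prompt fires when a participant has dwelt in a park for ten
minutes, or when their device transmits a location during a morning window.
gemaflow implements the server-side logic of such a study as an open,
deterministic engine: accuracy filtering, geofence visit detection over
complex polygons, declarative prompt scheduling with expiry, reversible
coordinate masking, a synthetic cohort simulator, and the standard
adherence/latency/time-use analytics. This vignette records the models and
the reasoning behind every tunable parameter and design choice, in the
spirit of a methods appendix.

## 1. The fix stream and the accuracy filter

The unit of input is a GNSS fix: `(participant_id, lat, lon, t,
accuracy_m)` with `t` in Unix epoch seconds and `accuracy_m` the device's
reported radial accuracy in metres. Devices following the motion-gated
sampling policy transmit a fix every `interval_s = 120` s while in motion
and pause after `pause_after_motionless_s = 600` s of stillness — a battery
compromise that matters downstream, because silence is then *ambiguous*:
it can mean "stationary inside the park" just as well as "device off".

`filter_accuracy()` drops fixes whose reported radial accuracy *exceeds*
30 m. "Exceeds" is read strictly: a fix reporting exactly 30.0 m is
retained. The boundary convention is arbitrary but must be fixed and
documented; the strict reading is the literal one. The filter is idempotent
and commutes with partitioning the stream by participant, and both
properties are tested.

Calendar-day accounting (`unique_location_days()`) converts epoch seconds
to the participant's *local* calendar date and counts distinct dates;
consecutiveness is never required. The timezone comes from the protocol
configuration, not from the coordinates: inferring a zone from positions
would make day counts depend on the geometry of the data, which is neither
deterministic nor testable.

## 2. Geofence containment

Geofences are polygons in WGS84 degrees, possibly multi-part and possibly
holed. Containment (`fence_contains()`) is even-odd ray casting over all
rings: interior rings are excluded automatically by parity, a MultiPolygon
is the union of its parts, and points on any boundary segment or vertex
count as **inside**. The boundary convention is a behavioural choice, not a
numerical nicety: a participant walking the perimeter path of a park should
be prompted.

Containment is evaluated planar, directly on lon/lat. At park scale
(hundreds of metres) the Earth's curvature contributes relative errors
around 10^-6 of the polygon size, far below GNSS noise, and a planar
predicate needs no projection library and is bit-for-bit reproducible.
Distances, where the engine needs them, use the haversine formula.
Geometry is validated at load time (closed rings, at least four vertices,
no self-intersection), so a malformed fence fails the study configuration,
never a query mid-stream. The test suite checks the predicate against an
independent computational-geometry oracle (shapely's `covers`) on randomly
generated concave, holed and multi-part polygons; agreement is required on
at least 99.9% of dense grid points, with disagreements confined to within
one grid cell of a boundary.

## 3. Visits: from sparse fixes to entry, dwell, and exit

`detect_visits()` converts the fix stream into *visits* — maximal runs of
consecutive fixes inside one fence — and emits events at fix granularity:

* `ENTRY` at the first inside fix;
* `DWELL` at the first fix whose elapsed time since entry reaches the
  dwell threshold (600 s by default), so with 2-minute sampling the event
  fires within `[threshold, threshold + interval]`;
* `FOLLOWUP_DWELL` at the first fix reaching the follow-up threshold
  (2700 s), only in visits whose `DWELL` fired;
* `EXIT` when the visit closes.

The gap rule handles the sampling pause: a silent gap bounded by two
inside-fixes of at most `max_gap_s` (default 12 h) counts as continuous
presence, because sampling stops exactly when the device is motionless —
a participant sitting on a park bench for an hour produces two inside
fixes an hour apart, not an absence. A gap beyond `max_gap_s` is no longer
credibly a nap on a bench; the visit then closes conservatively at the
last observed inside fix. When the stream continues with an outside fix
within the gap bound, the visit closes at that fix's timestamp — the
event-driven reading: a server can only react when data arrives, so the
exit time is the time of the datum that revealed the exit, not an
interpolated midpoint. Overlapping fences are legal; a fix inside k fences
advances k concurrent visit states. A single-fix boundary clip still emits
`EXIT`; suppressing prompts for trivially short visits is the scheduler
configuration's business, not the detector's.

The implementation is vectorised run-splitting; the test suite replays the
same semantics through a deliberately naive per-fix state machine (the
interval-scan oracle) and requires identical visits and events on hundreds
of random streams.

## 4. The prompt scheduler

A protocol is a set of declarative rules, the in-package analogue of a
logic server's instruction sets (input connector → filters → processors →
output connector). Five kinds cover the study designs targeted here:

| kind | trigger | cap |
|------|---------|-----|
| `TIME_WINDOW` | first fix whose local wall-clock time falls in `[start, end)` | `max_per_day` per local date (default 1) |
| `DWELL` | the visit's DWELL event | one per visit |
| `FOLLOWUP_DWELL` | the visit's FOLLOWUP_DWELL event | one per visit |
| `EXIT` | the visit's EXIT event | one per visit |
| `RESPONSE_CONTINGENT` | an accepted response to a named source rule, optionally gated on an item comparison | one per triggering response |

Windows are half-open in the participant's configured IANA timezone, with
daylight-saving transitions resolved by local wall-clock time. A window
rule emits nothing on days without an in-window fix: prompting is
conditional on the device actually transmitting during the slot, which is
what couples adherence to device behaviour. Location rules bind to fence
*classes* (`class == "park"`), so one protocol generalises across fence
sets.

Every prompt expires `expiry_s = 3600` s after delivery. Delivery is
modelled as instantaneous (`delivery_t = trigger_t`) with an optional
fixed delay, since delivery failure is a transport concern outside this
engine's scope. `accept_response()` accepts a submission iff it arrives in
`[delivery_t, expiry_t]` against a pending prompt; late submissions expire
the prompt, duplicates are rejected, and a submission timestamped before
delivery is a clock inconsistency and errors. No accepted response can
ever have latency above the expiry — an invariant the acceptance suite
checks on whole simulated studies.

Two points the study description leaves open were decided as follows. A
window that expires unanswered is *not* re-prompted: the design says each
daily survey is requested once, and one emission per window is the literal
reading. The follow-up prompt requires only that the DWELL event fired,
not that its prompt was answered: the follow-up measures continued
exposure, not engagement with the earlier survey.

The evaluator is a fold over time-ordered records with explicit state
(`scheduler_state()` / `evaluate_rules()`), so feeding the stream in any
time-ordered chunking produces byte-identical prompt logs to batch
evaluation — tested, since a streaming server and an offline re-analysis
must agree. Prompt identifiers are UUID-format strings derived
deterministically (FNV-1a) from rule, participant and trigger time, which
makes whole runs reproducible at the byte level.

## 5. Reversible coordinate masking

Stored location data should not reveal true positions, yet offline
analysis must recover them exactly. GEMA platforms typically scramble
coordinates with a secret algorithm before storage and restore them only
for offline analysis, without committing to a particular construction, so
gemaflow chooses one with provable properties:

1. project fixes into a local equirectangular plane about the stream
   centroid (valid within 1000 km; farther points are a reported error);
2. rotate rigidly about a keyed fixed point placed 2000–3000 km away,
   with a keyed chord between 5×10^-3 and 5×10^-2 — every point is
   displaced at least `2 × floor_m` (default floor 1000 m) and at most
   ~150 km;
3. permute record order with a keyed seed;
4. store the projection origin in the file header *offset by a keyed
   shift* (the token is meaningless without the secret), together with a
   keyed checksum of the true coordinates.

All parameters derive deterministically from the secret, so masking is a
pure function of (stream, key). Unmasking inverts the permutation and the
rotation and verifies the checksum: a wrong key produces a reported
mismatch, never plausible-but-wrong coordinates. Round-trip error is below
10^-9 degrees (tested over 100 keys × 10^4 points).

The displacement ceiling is deliberate: a rigid transform preserves
within-stream distances, which is the analytic utility geomasking is
supposed to keep, but the equirectangular scale is only locally valid, so
the keyed displacement is kept small enough (≤ ~150 km, ≤ ~2° of
latitude) that pairwise haversine distances survive within a few percent.
The flip side is a known residual: preserved pairwise geometry is itself
re-identification information if an attacker holds matching true
trajectories. Formal differential-privacy guarantees are out of scope and
documented as such.

## 6. The synthetic cohort: a stated world

No participant data ships with the package; the simulator *is* the test
bed, and its defaults are the study conditions the engine assumes — they
are inputs, never reproductions of field results.

* **Cohort and duration**: 38 participants × 14 days, the compliant
  cohort size and app period of the motivating field deployment.
* **Sampling**: 120 s interval, 600 s motionless pause, replayed by
  `motion_gated_fixes()` over a continuous simulated trajectory.
  "Motionless" is simulated as sustained speed below 0.1 m/s — a simulator
  assumption, flagged as such; the engine itself never needs a motion
  threshold.
* **Daily behaviour**: home-anchored putter episodes that overlap the
  9:00–10:00 and 19:00–20:00 windows with probability 0.7 each per day
  (chosen so the expected number of morning prompts over 38×14 person-days
  lands near the printed field count of ~360); Poisson(0.9) park trips per
  day between 10:30 and 18:30, walking below 1.5 km, driving otherwise.
* **Dwell**: lognormal with median 5 min and sdlog 1.4, putting ~31% of
  visits past the 10-minute engagement threshold and ~6% past 45 minutes —
  matching the ordering and rough magnitudes of the printed prompt counts
  (exits ≫ engagements ≫ follow-ups). The field distribution of dwell
  times is unpublished; these values are an explicit assumption.
* **GNSS error**: Rayleigh positional noise with 5 m scale; reported
  accuracy drawn independently as lognormal(log 8, 0.7), putting ~3% of
  fixes beyond the 30 m filter so the filter is always exercised. The
  exact shapes are immaterial to engine correctness.
* **Response behaviour**: per-kind response probabilities
  (0.61, 0.68, 0.47, 0.50, 0.44) and latency medians (3, 4, 2, 9, 4) min
  for (morning, evening, engagement, follow-up, exit) — the replica preset,
  mirroring the field adherence table as *inputs*. Latency is lognormal
  about the configured median, truncated at expiry by an inverse-CDF draw,
  so the configured probability is exactly the propensity to answer before
  expiry. The sdlog of 0.9 is narrower than the field latency spreads;
  it was chosen once so that the configured medians are identifiable at
  simulated sample sizes and truncation removes under 2% of mass, and it
  is documented here rather than tuned.
* **Videos**: an answered engagement prompt attaches a video with
  probability 0.23.

Ground-truth visit intervals are recorded from the continuous trajectory
(exact segment–boundary crossing times), independent of anything the
engine computes, which is what makes parameter recovery a real test:
the acceptance suite requires the engine's visits to match truth within
one sampling interval plus noise ambiguity for clear stays, configured
response probabilities to be recovered within binomial 95% confidence
intervals, and latency medians within ±1 minute at pooled n ≥ 500.

What a green simulator-based test does **not** establish: the cohort is
behaviourally homogeneous (one profile), so across-participant adherence
SDs are far smaller than the 30–40 point spreads real cohorts show; there
is no urban road network, no multi-modal travel, no differential GNSS
degradation indoors or under canopy, and no missingness mechanism beyond
the motion gate and the accuracy tail. Conclusions about engine logic
transfer; conclusions about field adherence levels do not.

## 7. Analytics conventions

* Per-kind adherence is the *participant-level* mean of answered/sent,
  with the sample (n−1) SD across participants; a pooled proportion has no
  meaningful SD of this magnitude, so the participant-level reading is the
  only one consistent with adherence tables of the 30–40%-SD kind.
  Participants sent zero prompts of a kind stay out of that kind's row.
* Latency is delivery→submission in whole minutes (floor), matching
  integer-minute reporting; medians and SDs are computed across accepted
  responses (not across participant medians — the alternative reading is
  possible but undocumented, so the simpler one was chosen and flagged).
* Reported percentages round half away from zero, the presentation
  convention of the field literature (96/1379 → 7%, 38/96 → 40%).
* The video attachment rate is reported under both denominators
  (engagement only; engagement + follow-up) because the field definition
  is ambiguous.
* WHO-5 well-being scores are item sums in [0, 25] (higher = better
  well-being); PROMIS Sleep Disturbance raw scores are item sums in
  [8, 40] (lower = better sleep). Item counts and ranges are enforced;
  T-score conversion tables are out of scope.

## 8. Numerical and degenerate-input choices

Boundary tests in the containment predicate use an absolute tolerance of
10^-12 degree-units scaled by edge length — far below GNSS noise, present
only so that exactly-on-vertex queries behave. Empty streams flow through
every operation and produce empty, schema-valid outputs (tested end to
end with a zero-participant cohort). Open visits at end of stream carry
`NA` exit times and must be closed explicitly (`close_visits()`) before
time accounting; time-use shares for participants with no qualifying time
are `NA` and flagged rather than silently zero. All timestamps serialise
as integer epoch seconds; no locale-dependent formatting exists anywhere
in the IO layer.

Protocol files are JSON. YAML input was considered and dropped: this
build environment provides no R YAML parser, and JSON covers the
configuration shapes losslessly.

## 9. Known limitations

* Containment is planar on lon/lat; fences spanning many degrees or
  polar regions are out of scope (geometry validation does not forbid
  them, but accuracy degrades).
* The geomask preserves within-stream pairwise geometry by design — a
  privacy/utility trade-off, not an oversight; see §5.
* The scheduler's response-contingent predicates are conjunctions of
  (source rule, item comparison, delay); a general expression language is
  deliberately not built.
* The simulator's behavioural realism is limited as catalogued in §6.
* Masked files store coordinates that may leave the valid WGS84 ranges;
  they are ciphertext-like by intent and must be unmasked before any
  geographic use.
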