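---
title: "A sparse distributed coding memory for binary frame sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sparse distributed coding memory for binary frame sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcmem)
```

## The model

`sdcmem` implements a hierarchical content-addressable memory for
spatiotemporal sequences of binary frames, patterned on the macrocolumn /
minicolumn organization of cortex. The canonical module is the **mac**: a grid
of `Q` **competitive modules** (CMs, the minicolumn analog), each holding `K`
binary cells. At any frame an active mac expresses a **sparse distributed
code** (SDC): exactly one winner per CM, i.e. `Q` co-active cells out of
`Q*K`. Because codes physically overlap, the number of shared winners between
two codes carries their similarity, and activating one stored code partially
activates every other stored code in proportion to its intersection with it.

A mac receives three classes of afferent evidence:

* **U** (bottom-up): from the pixels of its aperture (level 1) or from the
  cells of the macs in its receptive field at the level below (level ≥ 2),
  sampled at the *current* frame;
* **H** (horizontal): from codes active in same-level neighborhood macs
  (including itself, recurrently) on the *previous* frame;
* **D** (top-down): from codes active in its superjacent parent macs on the
  previous frame.

U projections are all-to-all from every source unit in the aperture to every
cell of the mac — all cells of a mac share identical receptive fields, which
is what lets the mac act as a single coherent module. Recurrent H projections
connect every cell to every cell in *other* CMs of the same mac, never within
a CM. This exclusion is not arbitrary: it is the unique wiring under which
the single-mac synapse count obeys `P*Z + Z*(Z-K)` (with `P` input pixels and
`Z = Q*K`), reproducing the whole tabulated family of model sizes (6 336 at
`K = 4` up to 115 200 at `K = 32`), and it also reflects that a cell never
needs evidence from its own CM's previous winner to compete against its CM
siblings. A configuration switch (`h_include_own_cm`) restores the full
wiring for comparison. Macs tile each level without overlap.

### Code selection

Each frame, every eligible mac converts its inputs into a code by a two-phase
competition (the code selection algorithm, CSA):

1. **Gate.** A mac activates if the number of active features in its U
   receptive field lies within `[pi_u_lo, pi_u_hi]`, or if its current code is
   still within its persistence window (during learning, persistence trumps
   the bounds).
2. **Raw summations.** Each cell sums the weights from active pre-synaptic
   units; signals from a source mac with `zeta` tied hypotheses are scaled by
   the correction factor `F(zeta) = zeta^A` (for `zeta <= B`; 0 beyond — a
   "muddled" source is ignored entirely and excluded from the effective
   feature count).
3. **Normalization.** Summations are divided by the *lower* activation bound
   times `w_max` (times `Q` when features are macs) and clamped to `[0, 1]`,
   so inputs with different feature counts compete on an equal footing.
4. **Local support.** `V = H^λ_H * U^λ_U(t) * D^λ_D`, with only the sources
   that exist at this moment included (first frame: U alone; top level: no D).
5. **Familiarity.** The per-CM maximum supports `V̂` are averaged into
   `G ∈ [0, 1]`: 1 means the moment exactly matches a stored moment, 0 a
   wholly novel one.
6. **Familiarity-modulated softmax.** `G` sets the range
   `η = 1 + ((G − G⁻)/(1 − G⁻))₊^γ · χ·K` of a sigmoid applied to `V`,
   yielding relative win weights `ψ ∈ [1, η]`, normalized per CM to
   probabilities `ρ`, from which one winner per CM is drawn. As `G → 1` the
   map becomes maximally expansive and the best-matching stored code is
   reinstated almost surely; at `G = 0` (or below the floor `G⁻`) it collapses
   to the uniform draw, assigning a fresh quasi-random code. This soft
   interpolation is what maps similar inputs to similar codes (SISC).

The whole procedure runs in a fixed number of elementary operations set by
the wiring, never by the number of stored codes — storage and best-match
retrieval cost the same after one code or fifty (asserted by an instrumented
operation count in the tests).

### Learning, persistence, and critical periods

Learning is single-trial and Hebbian. A pre-post correlation sets a synapse's
age `σ` to 0, which drives its weight to `w_max = 127` in the age/permanence
weight table; ages advance once per global frame and the weight decays
passively along its permanence row. A repeat correlation within the
permanence-dependent window `T_σ(θ)` increments `θ`, lengthening the plateau,
until `θ_max` pins the weight at 127 permanently. The published description
of the weight table is qualitative, so the package's default schedule is a
concrete realization of its stated constraints: plateau `T_σ(θ) = 100·2^θ`
frames at 127, then linear decay to 0 over another `100·2^θ` frames, with
`θ_max = 2` (a synapse becomes permanent on its third within-window
correlation). Every element is configurable; within the ten-frame studies
shipped with the package no weight ever leaves its plateau, so the synapses
behave as strictly binary there.

Persistence `δ` doubles with level (1, 2, 4, …). A level-2 code that stays on
for two frames U-associates with both level-1 codes active beneath it and
D-associates forward, *chunking* the lower-level sequence — the mechanism by
which single higher-level codes come to stand for multi-frame events.

Once the potentiated fraction of **any one** afferent projection of a mac
reaches `freeze_threshold` (default 0.8), all its afferent projections freeze
permanently (a critical period); its efferent weights, which live in other
macs' afferent matrices, keep learning. Tests assert the freeze is bitwise:
no `σ`/`θ` in a frozen mac's afferent matrices changes over further training.

### Retrieval and time-warp tolerance

Two retrieval regimes are provided. **Probabilistic** retrieval is the
learning-mode competition augmented with the back-off policy below;
**simple** retrieval replaces the softmax with a per-CM hard max over `V`
(seeded uniform tie-break) and is the right choice when the caller knows no
learning is required — the max-`V` cell is the maximum-likelihood winner, so
simple mode strictly dominates when saturation is low. Simple mode must not
be used during learning: mapping every input through a hard max would funnel
all inputs onto a handful of codes and destroy the mac's capacity, which is
why the fitting function always runs the softmax CSA (there is deliberately
no option to train in simple mode).

In retrieval, a mac first evaluates `G` under the most stringent evidence
combination available (`G_HUD`), and only if it falls below that variant's
threshold (default 0.9 for the 3-way, 0.95 for 2-way variants) backs off to
`G_UD`, `G_HU`, `G_HD` and finally the terminal U-only variant (threshold 0).
Dropping the H (or D) factor asks: *could this moment be a time-warped
continuation of something I know?* A deleted frame leaves U and D agreeing on
the code the sequence should have reached one step later, so `G_UD = 1` and
the mac's state jumps forward, after which the rest of the hierarchy follows
without back-off — recognition keeps pace with nonlinearly sped-up or
slowed-down presentations at the cost of at most a fixed number of extra
variant evaluations. The precedence order is configurable; the default
follows decreasing evidence order, and thresholds are constant in time.

Two retrieval-mode design points deserve explicit statement:

* **Codes are re-selected every frame in retrieval.** Persistence still
  feeds the activation gate, but a persisting code is not *held*; this is
  required for the catch-up behavior above (the higher level must be free to
  advance early when its inputs say so) and reduces to an exact replay on
  undistorted input, which the tests assert frame by frame.
* **H normalization under the within-CM exclusion** divides by `Q − 1`
  reachable cells (per recurrent source mac) rather than `Q`, so a perfectly
  familiar moment yields `H = 1` exactly — without this, `G` could never
  reach 1 and familiar moments would be misjudged.

### Multiple competing hypotheses

When a prompt is ambiguous — e.g. an item that occurred in several stored
contexts is shown first — all of its context codes tie at maximal support,
and the drawn code is a blend of them. The mac detects this by tallying cells
with `V` strictly above `V_ζ = 0.95` per CM and averaging (rounded to nearest
integer) into `zeta`. Efferent signals are then boosted by `zeta^A`
(`A = 0.7`), restoring the next frame's h-summations toward their
single-hypothesis levels; past `B = 4` tied hypotheses the mac is muddled and
silenced instead. Two numerical notes: an *active* mac whose input is wholly
novel has every `V ≈ 0` and hence a raw tally of 0, but its code still
expresses exactly one (new) hypothesis, so the stored state clamps
`zeta = max(1, tally)`; and rounding uses half-up rather than banker's
rounding for determinism. Because `zeta^0.7 < zeta`, the boost restores `H`
only partially, and the 2-way back-off threshold (0.95) then discards H
during probabilistic retrieval of such prompts — the boost's measurable
benefit therefore appears in the learning-mode (autonomous) competition,
which is how the package's disambiguation benchmark exercises it; in simple
retrieval the following item settles the mac on the correct stored code with
certainty through U alone.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `Q`, `K` | study-dependent | CMs per mac, cells per CM; capacity grows with both |
| `pi_u = c(lo, hi)` | generator's active range | activation gate; `lo` is also the U normalizer |
| `delta` | `2^(level-1)` frames | persistence; chunking factor between levels |
| `V_zeta` | 0.95 | tie tolerance for the MCH tally (strict `>`) |
| `A`, `B` | 0.7, 4 | MCH boost exponent and muddle cutoff |
| `G_floor` (`G⁻`) | 0 | familiarity below which the draw is uniform |
| `gamma`, `chi` | 2, 100 | sigmoid range growth: `η(G=1) = 1 + 100·K` |
| `sigma1..4` | 1, 10, 0.5, 1 | plain logistic, inflection at `V = 0.5` |
| `sigma3_rate`, `sigma3_max` | 0.008/code, 0.9 | rightward inflection shift with stored codes |
| `theta_max`, `T_sigma` | 2, `100·2^θ` | permanence cap and decay plateau (frames) |
| `freeze_threshold` | 0.8 | afferent saturation closing the critical period |
| back-off thresholds | 0.9 / 0.95 / 0 | 3-way, 2-way, terminal variant acceptance |

The one default that required a judgment call is the **inflection schedule**.
With a static `sigma3` and no familiarity floor, the crosstalk of codes
stored in superposition inflates `G` for genuinely novel moments late in
training; the expansive sigmoid then *reuses* stored codes (pairwise code
intersections far above chance), and storage capacity falls with model size
instead of rising. Shifting the sigmoid's inflection right as codes
accumulate suppresses exactly those moderate-`V` crosstalk cells while
leaving true matches (`V ≈ 1`) on the expansive arm. The default rate,
+0.008 per stored code capped at 0.9, places the inflection at ~0.9 by the
time a mac holds 50 codes — past the largest crosstalk supports observed at
the loads the benchmarks reach. It was fixed from that reasoning and left
alone thereafter.

## What the synthetic generators emulate — and what they do not

The generators produce the studies' input statistics exactly: random frames
with a uniformly drawn number of active pixels (9–12 of 144 by default),
relocation noise (a "changed" pixel is switched off and another switched on,
so one change = two pixel-level differences and the active count is
preserved), deletion/repetition time-warp schedules, two-frame overlap
ladders whose first frames share a controlled pixel fraction, and
aperture-tiled frames in which a chosen number of apertures carry a
gate-eligible pixel count. They do **not** emulate natural video: no edge
structure, no spatial continuity between frames, no correlated motion.
Passing the benchmarks therefore demonstrates the storage/retrieval
mechanics — capacity, noise tolerance, warp tolerance, SISC — on inputs
matching the published statistics, but says nothing about feature bases
learned from natural imagery (letter-shaped figure items are likewise
replaced by random patterns with controlled overlap, which is the property
the studies actually exercise).

## Numerical and edge-case decisions

* The printed normalization formula reads `max(1, ·)`, which would floor all
  inputs at 1; the accompanying text demands hard-limiting *to* 1, so the
  package clamps with `min(1, ·)`.
* Hard-max ties keep **all** tied cells for `V̂` and `G`; simple retrieval
  breaks them by a seeded uniform draw (a blank mac thus returns a uniform
  random code).
* An inactive source mac contributes no signal (`F = 0`) — distinct from an
  active single-hypothesis source (`F(1) = 1`).
* Feature counts for normalization use active *non-muddled* sources; if every
  source is muddled the normalized input is defined as 0.
* No upper bounds are imposed on H- or D-RF feature counts.
* One integer seed governs a run; per-(sequence, frame, mac) substreams are
  derived by an integer hash, so evaluation order can never change results,
  and every substream seed stays below 2^31.
* Ages tick before the frame's correlations are applied; a correlated synapse
  ends the frame at age 0 either way, so the orders are equivalent up to a
  one-frame shift in the (hundred-frame) permanence window test.

## Benchmark problem sizes

The shipped benchmarks use the studies' own scales, which are modest: the
noisy-recall conditions run 25 replicates of (train `S`·10 frames, test
`S`·10 frames) in a single mac of at most 288 cells, and the SISC benchmark
runs 50 replicates of a 6-level overlap ladder in a `Q = 25, K = 9` mac.
These sizes give sub-minute runtimes while holding the Monte-Carlo standard
error of the reported means to a few tenths of a percentage point; they are
the package's chosen defaults, not limits.

## Known limitations

* The hierarchical benchmarks stop at three internal levels; deeper stacks
  run but are untested beyond structural invariants.
* Warp-aware *alignment* of accuracy scoring is out of scope: trace accuracy
  compares equal-length traces (exact-match protocol), while warped inputs
  are scored by final-frame state equality.
* The weight table's numeric decay profile is a constructed realization of
  qualitative constraints; only those constraints (plateau, monotone decay,
  window growth, permanence pinning) are load-bearing.
* `G`-modulated retrieval quality degrades gracefully but measurably once a
  mac's afferent saturation grows — the overload benchmark makes this
  visible rather than hiding it.
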