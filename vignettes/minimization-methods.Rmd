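---
title: "Minimization in minimizr: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimization in minimizr: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimizr)
```

## The allocation model

`minimizr` allocates participants between two arms by minimization over
the *marginal totals* of prognostic factors. Every factor level is one
*class*; a participant's class vector holds, for each factor, the
configured weight (default 1) at their true level and 0 elsewhere, plus
two outcome positions that record the assigned arm once allocation is
final. The running state of a trial is a pair of arm aggregates: the
elementwise sum of the class vectors of everyone allocated to that arm,
plus a participant count.

For a new participant the engine sums, separately per arm, the aggregate
totals at the classes where the participant's vector is nonzero. The arm
with the smaller score has seen fewer participants *like this one*, and
is the minimization-preferred arm. Three cases follow:

1. **Equal scores** — a fair coin decides. The first participant of every
   trial lands here, so the first allocation is always randomized.
2. **Experimental score greater** — control is preferred and selected
   with probability `r`, the randomization element.
3. **Control score greater** — experimental is preferred, again followed
   with probability `r`.

This is the sum-of-marginal-totals form of minimization: it considers
each factor's margins, not the joint distribution, which is exactly what
makes it workable in real time for small trials. Range- or
variance-based imbalance measures, multi-arm extensions, and stratified
or blocked hybrids are out of scope.

## Tunable parameters

* **Randomization element `r`** (unitless probability, default 1).
  Probability of following the preferred arm when scores differ. `r = 1`
  is deterministic minimization; `r = 0.5` makes every decision a fair
  coin, i.e. complete randomization within the same operational
  machinery. We accept only `r` in `[0.5, 1]`: as a probability of
  *following* the preference, any value below 0.5 would systematically
  fight the minimization objective, so it is rejected with an
  explanatory error rather than silently honored. Ties ignore `r` and
  always use 0.5.
* **Per-level weights** (default 1 everywhere). Applied at class-vector
  construction, so a true level contributes its weight to the arm
  aggregate and thence to future scores. Halving a factor's weights
  (e.g. ethnicity at 0.5) halves its pull on the decision relative to
  weight-1 factors.
* **Age threshold** (years, default 65). Ages at or above the threshold
  fall in the `old` class — the boundary belongs to `old`, matching the
  usual "under 65 / 65 and over" banding.
* **Delimiter** (default `"zz"`). Joins the fields of one state-file
  line. Any field whose text contains the delimiter is rejected at
  serialization time, naming the field, so the parser stays an exact
  inverse; trials whose identifiers might contain `zz` should configure
  a different delimiter up front.
* **Recipients and seed** — notification addresses and an optional RNG
  seed applied by the command-line entry points for auditable runs.

## The state file and its backups

The allocation history is an append-only plain-text file, one delimited
line per participant: four documentary fields (participant ID, ISO date,
weekday, submitter) followed by all class values including the two
outcome positions. The original line dialect this emulates did not fix a
printed field order, so this canonical order is the package's own
definition, documented here and held fixed per trial.

Every allocation appends the identical line to the state file and to a
mirror archive that is never read during operation; the two are
line-for-line identical after every successful allocation. The
administrator notification embeds the complete state file between marker
lines, so any single administrator message suffices to reconstruct the
trial byte-identically (`rebuild_from_backup()`), giving a distributed
off-site backup with zero infrastructure. Transactions (load history,
decide, append, notify) run under an advisory lock — an atomically
created lock directory beside the state file — so concurrent submitters
serialize. Encoding is UTF-8 with Unix newlines and no header.

Two deliberate operational rules: duplicate participant IDs are refused
by default (accidental double enrolment is far likelier than a true
re-allocation; an override flag exists), and a failed notification never
rolls back an allocation, because the state file, not the outbox, is the
single source of truth.

## Intake

The detailed ethnicity vocabulary maps 17 intake codes onto the four
aggregated categories used for allocation (`white`, `black`, `asian`,
`chinese`); configuration load enforces 17 codes, exactly 4 categories,
and codes A, B, C aggregating to `white`. Only those three example
assignments are normative; the remaining 14, shipped with NHS-style code
letters, are a synthetic stand-in and are expected to be overridden per
trial — the engine never hard-codes a contested mapping. "Not stated" is
an ordinary code in the vocabulary, never a silently dropped value.
Intake validation reports all problems in a submission at once, and the
two-step confirmation of interactive use is modeled as a library-level
token (`confirm_submission()`) shared by the CLI and any future front
end.

## The simulator

`population_model()` describes a participant stream as independent
per-factor level prevalences. The defaults mirror the marginals of a
152-participant renal-medicine study population: an even gender split,
71/152 under 65, 39/152 diabetic, and 142/5/4/1 of 152 across the four
ethnicity categories. Ages are drawn uniformly within the band implied
by the drawn age class, and a detailed code uniformly within the drawn
aggregated category.

What the generator deliberately does **not** emulate: correlation
between factors (real comorbidity structure), temporal drift in the
arrival stream, site effects, and missingness. Passing balance tests
therefore demonstrate the engine's behavior under a stationary
independent-margins population — they bound what minimization does to
marginal imbalance, not how a particular real trial would have unfolded.

`run_trial()` replays a stream against a running aggregate; this is
tested to be equivalent to re-aggregating the full record list at every
step, and to producing a state file the store can reload.
`compare_strategies()` replays the *same* generated streams under each
randomization element for a paired comparison, summarizing the maximum
per-class imbalance and the arm-size difference.

## Numerical and reproducibility choices

* One global R RNG drives every draw; entry points accept a seed, and
  every consumed uniform is kept in the decision object for the audit
  trail. When `r = 1` and scores differ the branch is deterministic and
  **no draw is consumed**, so deterministic trials have reproducible RNG
  streams regardless of history length.
* Class values are serialized as integers when integral and with 17
  significant digits otherwise, making `parse(format(record))` the exact
  identity, including fractional weights.
* Scores are plain sums over at most one position per factor; no
  floating-point rearrangement is involved beyond `sum()`, and equality
  of scores is exact equality, which is well-defined because totals are
  sums of identical weight constants.
* Degenerate inputs: an empty history yields all-zero aggregates and a
  tie; empty state-file lines are skipped with a warning; any other
  malformed line (wrong field count, non-numeric value, zero or two
  outcome flags, violated one-level-per-factor invariant) is a hard
  corrupt-history error naming the line.

## Problem sizes used by the test suite

The suite exercises the stochastic claims at sizes chosen to make the
binomial 3-sigma bands decisive while keeping a full run in tens of
seconds on one CPU: 100,000 decisions for the biased-coin rate at
`r = 0.8`, 20,000 first-participant ties, 1,000-record round-trip and
score-oracle sweeps, and 200 simulated trials of n = 152 per strategy
for the balance comparison. The acceptance script reuses the 100,000-
decision design and reports the percentage of decisions that went
against the preferred arm.

## Known limitations

Two arms only; a single global randomization element (no per-factor or
per-site values); marginal-total scores only; advisory locking assumes a
shared filesystem for concurrent writers; and the balance evidence is
simulation under the independence assumptions above, not a claim about
any specific recruited cohort.
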