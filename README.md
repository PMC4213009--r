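# minimizr

Covariate-adaptive minimization and randomization for two-arm clinical
trials.

## The problem

Simple randomization balances participant characteristics between the
control and experimental arms of a trial only in expectation. In small
studies the realized arms can differ badly in gender, age, diabetes
status or ethnicity, and those differences can masquerade as treatment
effects. **Minimization** (Taves 1974; Pocock & Simon 1975) fixes this by
looking at everyone already allocated: each new participant is steered to
the arm where their own characteristics are currently under-represented.

`minimizr` implements the whole operational loop a small multi-site trial
needs: intake validation, the allocation decision, an append-only
plain-text state file with a mirrored archive, notification messages
whose administrator copy embeds the complete history (a distributed
real-time backup), and a simulator for quantifying what minimization buys
over simple randomization.

## The algorithm

Each prognostic factor contributes one indicator *class* per level; the
default scheme has 10 allocation classes (gender 2, age class 2, diabetes
2, aggregated ethnicity 4) plus two outcome classes recording the
assigned arm. For a new participant with class-indicator vector
*x* and per-arm marginal totals *C* and *E* (elementwise sums of all
prior participants' vectors in each arm), the scores are

    S_C = sum_{j : x_j != 0} C_j        S_E = sum_{j : x_j != 0} E_j

The arm with the smaller score is *preferred* (the participant's
characteristics are rarer there). The **randomization element** `r` in
[0.5, 1] is the probability of following the preferred arm: `r = 1` is
deterministic minimization, `r = 0.8` sends one decision in five against
the preference, `r = 0.5` is pure randomization. Equal scores — always
the case for the first participant — are settled by a fair coin. Per-level
weights let one factor count more than another: a true level contributes
its configured weight instead of 1 to the vector and hence to the totals.

## Worked example

A new participant is male, under 65, non-diabetic and white. The
marginal totals already accumulated at those four classes are
(25, 26, 14, 30) in the control arm and (23, 22, 18, 35) in the
experimental arm:

```r
library(minimizr)
scheme <- default_scheme()
control <- arm_aggregate(scheme)
experimental <- arm_aggregate(scheme)
control$totals[]      <- c(25, 27, 26, 26, 14, 38, 30, 9, 8, 5)  # count 52
experimental$totals[] <- c(23, 28, 22, 29, 18, 33, 35, 7, 6, 3)  # count 51
sub <- confirm_submission(stamp_submission(
  list(participant_id = "NEW", submitter = "researcher@example.org",
       gender = "male", age_years = 40, diabetes = "no",
       ethnicity_code = "A"), engine_config()))
vec <- make_class_vector(sub, scheme)
decide_allocation(vec, control, experimental, r = 1)
#> allocation: option1 (scores control=95 experimental=98, mode=deterministic)
```

The control score is 95 (25+26+14+30), the experimental score 98
(23+22+18+35): this participant's profile is rarer in the control arm, so
with `r = 1` they are allocated to the control arm, deterministically.

How much balance does that buy? Simulating 200 trials of 152
participants under the default population model:

```r
set.seed(20)
compare_strategies(population_model(n = 152),
                   r_values = c(0.5, 0.8, 1), replicates = 200)
#>    r mean_max_imbalance q025_max_imbalance q975_max_imbalance mean_arm_diff
#>  0.5              13.23                  4                 27          9.53
#>  0.8               2.88                  1                  5          1.17
#>  1.0               1.62                  1                  3          0.37
```

`mean_max_imbalance` is the worst per-class between-arm difference,
averaged over trials: pure randomization (`r = 0.5`) leaves an average
worst-class gap of about 13 participants, deterministic minimization
under 2.

## Running a trial from the shell

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "minimizr", package = "minimizr"))')
Rscript $CLI init --dir mytrial
Rscript $CLI allocate --dir mytrial --id P001 --gender female --age 67 \
        --diabetes no --ethnicity-code A --submitter site@example.org --yes
#> P001 allocated to: Control Arm
#> totals: 1 allocated (1 control, 0 experimental)
Rscript $CLI status --dir mytrial
```

Every allocation appends one `zz`-delimited line to `mytrial/state.txt`
and its mirror `archive.txt`, and drops three notification messages in
`mytrial/outbox/`; the administrator message embeds the full state file,
and `rebuild` reconstructs the trial from it byte-identically.

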