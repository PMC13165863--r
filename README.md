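# dyadsense

Desk-scale analytics for two-person collaborative sessions recorded as
time-synchronized multimodal event logs (speech transcripts, eye-gaze
samples, controller and task events). The package targets researchers
studying dyadic teamwork in collaborative virtual environments — in
particular mixed autistic/neurotypical dyads, where breakdowns are
mutual mismatches rather than one-sided deficits and both partners may
need scaffolding — and provides the full chain from raw logs to
collaboration profiles and small-sample statistics.

## What it computes

**Behavior states.** Each participant is classified per 1 s window into
*Engaged*, *Struggling* or *Waiting* by an interpretable decision tree:
speech ⇒ Engaged; otherwise controller input is checked — object moving
away from its target ⇒ Struggling, toward ⇒ Engaged, stationary despite
input ⇒ Waiting; with neither speech nor input, gaze present ⇒ Waiting,
absent ⇒ Struggling.

**Feedback machine.** A deterministic five-state machine (*Observe,
Redirect, Assist, Intervene, Positive Feedback*) consumes the two
behavior timelines. A breakdown condition must persist 30 s before any
prompt fires (e.g. to a waiting participant: *"Please wait for your
partner to finish"*); after a further 30 s the machine escalates —
Redirect asks both participants to request help, Assist and Intervene
automatically complete the current task step.

**Speech.** Transcribed words are segmented into utterances by silence
(1 s) with a 15 s duration cap, labeled with one of eight dialogue acts
(Acks, Neg, Pos, Ques, Read, Inform, Conv, Out) by a transparent rule
cascade, and flagged as initiations when they open a topic or break
≥ 30 s of dyad-wide silence.

**Gaze.** Fixations are maximal same-ROI dwell runs of ≥ 200 ms,
categorized as task gaze (virtual objects), social gaze (the partner's
video window) or time gaze (the timer bar).

**Collaboration dimensions.** Features map onto five dimensions —
Dialogue Management, Information Pooling, Reciprocal Interaction, Task
Division & Coordination, Time Management — via a frozen incidence
matrix; each score is the mean of its normalized constituent features.

**Statistics.** Cohen's *d* (pooled or paired) with 0.2/0.5/0.8
interpretation bands, closed-form *t*-tests with 95% CIs on the mean
difference, Benjamini–Hochberg FDR adjustment, exact post hoc power
from the noncentral *t* (paired: ncp = d·√n, df = n−1; two-sample:
ncp = d·√(n/2), df = 2n−2), and dimension-level effect aggregation as
the mean |d| of constituent features.

**Simulator.** Scripted ground-truth behavior scenarios are rendered
into raw 15-parameter logs (the generative inverse of the classifier),
so the whole pipeline is testable end to end without human data.

## Worked example

Simulate a dyad in which P1 waits for 90 s while P2 keeps working, then
run the full pipeline:

```r
library(dyadsense)

presets <- preset_scenarios(seed = 7)
sim <- simulate_session(presets$redirect_case)
sim$log
#> <session_log> dyad sim (training): 10994 records, 2 players, 90.0 s

an <- analyze_session(sim$log, run_feedback = TRUE)
an$trace$prompts[, c("time", "recipient", "template_id")]
#>   time recipient       template_id
#> 1   30        P1  redirect_waiting
#> 2   30        P2  redirect_partner
#> 3   60      both redirect_escalate
```

The machine detects P1's sustained Waiting at its onset, holds back for
the 30 s grace period, then prompts both partners (the waiting one to
hold on, the busy one to update them), and escalates to a researcher
help request after 30 more seconds of no change. The per-player feature
vector shows the asymmetry the prompts react to:

```r
an$features[, c("player", "da_Inform", "piece_shared_count",
                "active_effort_total")]
#>   player da_Inform piece_shared_count active_effort_total
#> 1     P1         0                  0                   0
#> 2     P2         7                  2                  90
```

P2 spoke (7 informing utterances), shared 2 pieces and was active in
all 90 windows; P1 produced nothing, which is exactly what Waiting
renders. The statistics layer works on such features across sessions:

```r
posthoc_power(1.00, 6, design = "independent")
#> post hoc power = 0.347 (d = 1.00, n = 6, alpha = 0.050, independent two.sided)
```

i.e. a between-group contrast of six dyads per arm at d = 1 is an
underpowered pilot (35% power), while a within-group paired contrast at
d = 1.92 reaches 96%.

A shell entry point wrapping the same functions ships in
`inst/cli/dyadsense`:

```sh
Rscript inst/cli/dyadsense demo --scenario redirect_case --seed 7 --out out/
```

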