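---
title: "Methods: multimodal behavior analytics for dyadic collaboration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal behavior analytics for dyadic collaboration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsense)
```

## The problem and the data model

Two people collaborate on a shared construction task in a networked
virtual workspace while the system records a synchronized 15-parameter
event stream per participant: a timestamp, the player label,
transcribed speech, gaze coordinates and the focused on-screen object,
overall and individual completion scores, piece placement/sharing
events with a running shared count, a binary active-effort flag, the
task duration, and the manipulated object's distance to its target.
`dyadsense` ingests this stream (CSV or JSON-lines), classifies each
participant's moment-to-moment behavior, drives a rule-based feedback
machine, scores five dimensions of collaboration, and provides the
small-sample statistics appropriate to dyadic pilot studies.

Timestamps are clock strings (`HH:MM:SS`, optionally `.mmm`). The
whole-second dialect is accepted but cannot express the 200 ms fixation
threshold, so fixation resolution degrades with such inputs; loggers
should emit milliseconds. At equal timestamps, P1 sorts before P2 and
file order breaks remaining ties — an arbitrary but frozen rule that
makes every downstream artifact byte-reproducible.

Invalid rows (unparseable timestamp, unknown player, out-of-range score
or flag) are dropped and counted, never imputed; a file in which more
than half the rows fail validation is rejected outright as a
wrong-schema signal. This conservative policy trades completeness for
integrity, which is the right trade at pilot-study sample sizes.

## Behavior classification

Sessions are discretized into half-open windows `[k·tick, (k+1)·tick)`;
`tick` defaults to 1 s, a compromise between responsiveness and speech
burst length (nothing in the method depends on the exact value, and it
is configurable). Each window exposes four channels — speech present,
controller active, gaze present, and the signed change in the object's
distance-to-target — and the decision tree assigns one of three states:

1. speech ⇒ **Engaged**;
2. else, with controller input: moving away ⇒ **Struggling**, moving
   toward ⇒ **Engaged**, stationary ⇒ **Waiting**;
3. else: gaze present ⇒ **Waiting**, gaze absent ⇒ **Struggling**.

Movement direction uses a dead-band of `movement_epsilon` (default
0.05 scene units) on the distance delta so sensor jitter does not
register as motion. Gaze is deliberately not consulted when controller
input is present, and any valid gaze sample counts as "gaze present"
regardless of ROI: the tree tests presence, not target. Two windowing
subtleties are worth noting. A record exactly on a boundary belongs to
the later window. And the window containing the first distance
observation uses that observation as its own movement baseline —
otherwise the first active window of every session is unclassifiable
and all feedback timers would start one tick late.

No smoothing is applied by default; an optional width-3 majority filter
exists but is off, because hysteresis would blur the exact persistence
semantics of the feedback timers below. The tree is total and
deterministic; the test suite checks all 24 input combinations against
an independently transcribed oracle table.

## The feedback machine

Five states — Observe, Redirect, Assist, Intervene, Positive
Feedback — react to the pair of behavior states per window: both
Engaged ⇒ Observe; exactly one Struggling ⇒ Assist; both Struggling ⇒
Intervene; otherwise any Waiting ⇒ Redirect. Where one participant
waits while the other struggles, Struggling dominates (Assist): the
machine addresses the greater breakdown first. Both participants idle
but not struggling is treated as the Redirect row's "both idle" branch.

Prompts are governed by one persistence parameter, `wait` (default
30 s — long enough for the dyad to resolve a hiccup on its own, short
enough to catch real breakdowns): the *triggering condition* — the
target state together with the identity of the participant(s) driving
it — must hold continuously for `wait` seconds before the first
prompts fire, and for another `wait` seconds before escalation
(Redirect: a help request to both; Assist/Intervene: automatic
completion of the current step, after which the machine returns to
Observe and all timers clear). Any change of the condition, including a
swap of *which* participant is waiting, resets the timer. Positive
feedback on step/task completion is instantaneous: one tick in the
Positive Feedback state, then back to Observe with timers cleared.
Timers run on the timeline clock, so with a 1 s tick a condition
starting at window *k* prompts exactly at `k + 30` seconds.

Prompt texts live in an editable catalogue (`default_prompt_catalogue()`,
YAML round-trippable), including role-adapted variants (nudging one
partner to initiate, the other to check in), so deployments can adapt
wording without touching code.

## Speech analysis

Segmentation emulates a streaming transcription service: a new
utterance opens at a ≥ 1 s inter-word silence or when the current
utterance would exceed 15 s. The 1 s silence default reflects typical
continuous-recognition segmentation behavior; the 15 s cap is the
platform constant and is what the acceptance script measures as
emergent behavior.

An utterance is an **initiation** if it is the session's first, opens a
new annotated topic, or follows ≥ 30 s of silence *from either
participant* — the dyad-wide reading of "silence", chosen because a
partner's reply, verbal or not, is what the grace period is for. When
no topic annotations exist, only the silence rule applies: topic
novelty was a human judgment in the source coding scheme, and a lexical
heuristic would silently diverge from it, so none is attempted.

Dialogue acts are assigned by a deterministic rule cascade standing in
for a trained classifier (documented in `?classify_dialogue_act`):
pleasantries (Conv), praise (Pos), questions (Ques), instruction
quoting (Read), early negation (Neg), short acknowledgements (Acks),
uninterpretable fragments (Out), and the residual informing/directive
class (Inform), which is also empirically the dominant class in task
talk. One refinement earned its place: an instruction-quoting cue
("mine says …", "it said …") yields Read only when the quoted remainder
carries interpretable content (a known task verb or a digit); a
contentless quote is transcription noise and labeled Out. The full set
of coded example phrases for all eight classes is a frozen regression
fixture at 100% agreement. The cascade order (Conv and Pos before Ques;
Neg before Acks) is itself a documented choice: mixed utterances like
"Okay but no" have no coded ground truth, and the order was fixed once
and pinned by tests.

## Gaze analysis

A fixation is a maximal run of consecutive samples on one ROI whose
first-to-last time span reaches `min_fixation` (default 0.200 s, the
conventional minimum dwell for an intentional fixation). Detection is
dwell-on-labeled-ROI, not a dispersion or velocity algorithm, because
the logs carry the tracker's own object-resolution rather than raw
gaze traces. Tracker dropout is ubiquitous, so a single null sample (or
a ≤ 25 ms gap, whichever is more permissive) inside a run is bridged; a
sample on a *different* ROI always ends the run. Fixations are then
categorized by an ROI map — task objects (the default for unmapped
names), the partner's video window (social gaze), the timer bar (time
gaze). The package reports *fixation counts* per category, one per
dwell run, and total dwell time; note that a continuous stare is one
fixation regardless of length.

## Dimensions of collaboration

The frozen incidence matrix (`dimension_feature_map()`):

| Dimension | Constituent features |
|---|---|
| Dialogue Management | initiations; Acks, Neg, Conv |
| Information Pooling | pieces shared; Ques, Read, Inform |
| Reciprocal Interaction | active-effort windows; Pos, Acks |
| Task Division & Coordination | task-object fixations; pieces shared; active effort; Inform |
| Time Management | timer-bar fixations |

Out-labeled utterances feed no dimension. A dimension score is the
unweighted mean of its normalized constituents. The source framework
never defines a numeric "score", so normalization is configuration:
per-minute rates by default (scale-free across session lengths), or
within-cohort z-scores for relative profiling. Both participant-level
and dyad-level (summed-feature) exports exist because the right unit of
analysis for group statistics is genuinely open. Dimension-level effect
sizes aggregate as the arithmetic mean of the *absolute* Cohen's d of
constituent features.

## Statistics

The bespoke layer is the effect-size battery: pooled-SD Cohen's d
(`(n−1)`-weighted pooling; paired: mean over SD of differences) with
0.2/0.5/0.8 bands; closed-form Student t-tests with 95% CIs (the pooled
two-sample form, consistent with pooled-SD d — and implemented from the
formulas precisely so the standard library routine can serve as an
independent oracle in the tests); Benjamini–Hochberg step-up adjustment
(delegated to `stats::p.adjust`, with a hand-rolled brute-force oracle
in the tests); and exact post hoc power from the noncentral t. Power
conventions default to two-sided α = 0.05, paired for within-group and
two-sample for between-group contrasts with n counted per group/pairs —
all exposed as parameters, because published power figures rarely state
their convention. At d = 1.00 with six dyads per arm the two-sample
two-sided power is 0.347; at d = 1.92 with six pairs the paired
two-sided power is 0.959, comfortably above the conventional 0.80
adequacy threshold though not equal to every rounding convention a
different tool might print. Nested model fitting (mixed models,
MANOVA, multiple regression) is out of scope: those are standard fits
for which standard tools exist, and `stat_battery` documents that
boundary.

## The simulator and what passing tests mean

`scenario()` scripts each participant as (state, duration) segments and
fixes the noise model: gaze dropout as independent sample deletion,
utterances at an exponential rate while Engaged, a linear
distance-to-target drift (0.5 units/s) with optional Gaussian jitter,
gaze at 60 Hz (the display rate). Rendering inverts the decision tree —
Engaged emits controller activity with the distance falling (plus
utterances), Waiting emits gaze-only samples or stationary controller
activity (both branches exercised via `waiting_mode`), Struggling emits
controller activity with the distance rising or total silence — and
the starting distance is set high enough that Engaged segments never
reach the target. Everything is deterministic given the seed.

Because simulated signals are *exactly* tree-consistent, zero-noise
recovery is 100% rather than the ≥ 95% the tests require; the slack
exists for state-transition boundary windows under non-integer
alignment. What passing recovery tests show is internal consistency of
the render–classify loop, not field validity: real gaze is noisier than
independent dropout, real speech does not arrive as Poisson bursts of
template phrases, and real struggling looks like many things besides
monotone distance growth. Claims about human dyads require human data.

Problem sizes used by the default test run: simulated sessions of
40–500 windows at 1 s ticks (the 500-window recovery case fixes the
seed), 25 randomized gaze streams of ≤ 200 samples against the
brute-force fixation oracle, 1,000 random p-vectors (m ≤ 20) against
the BH oracle, and 10⁴ replicates for the null-uniformity check of the
t statistic, chosen so the whole suite runs in well under a minute.

## Numerical and degenerate-input choices

Zero-variance samples make d and t undefined and raise errors rather
than returning infinities. Fixation spans are first-to-last sample
times, so an n-sample run at rate f spans (n−1)/f — thirteen 60 Hz
samples are the minimum for a 200 ms fixation. Boundary conventions
are half-open everywhere; `≥` thresholds (silence gap, dwell, 30 s
initiation silence) are inclusive, which the acceptance sweeps pin
exactly at 30 s, 200 ms and 15 s. Empty inputs return empty, typed
results rather than errors wherever a vacuous answer is meaningful.

## Known limitations

The dialogue-act cascade is a transparent approximation; utterances
outside its lexicons default to Inform, inflating that class on
off-task chatter. Topic-based initiations require annotations. The
behavior tree ignores gaze whenever the controller is active, by
design fidelity rather than by optimality. Dimension scores are
operational indices, not validated psychometric constructs, and the
package makes no claim that they measure real-world collaboration
quality.
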