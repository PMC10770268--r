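---
title: "Situation recognition over executable surgical process models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Situation recognition over executable surgical process models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgflow)
```

## The problem

Intraoperative situation recognition asks, at every moment of a surgical
intervention: *which step is the team performing now, and is that plausible
given the modeled course of the operation?* surgflow answers this with two
knowledge sources that are fused per observation:

* **Sensor knowledge** — simulated observations of the instruments in use,
  the positions of the actors, or (where nothing richer is available) the
  bare step name, interpreted through a table of situation rules.
* **Process knowledge** — a formal surgical process model that is not only
  *consulted* (which steps may come next, how long should the remainder
  take) but also *executed*: an engine instance tracks the intervention and
  is driven forward by the recognized situations.

Two modeling notations are supported because neither alone fits surgical
work. BPMN describes strictly ordered processes well but needs workarounds
for variability: steps in variable order become parallel (AND) gateway
blocks that are really executed one at a time ("semi-parallel"), and
optional steps become exclusive (XOR) gateways with a bypass branch. CMMN
turns this around: plan items inside a stage are unordered by default,
ordering is added via sentries (entry criteria firing on the completion of
referenced items), and optionality is expressed by rules — an optional step
carries no required rule but a manual activation rule. Combination models
use a BPMN root whose call activities reference CMMN cases, either for every
phase ("structured") or only for the variable ones ("mixed").

## Execution semantics

### Token engine (BPMN)

`start_process()` advances a token from the start event until it rests on
user tasks. AND gateways activate all branches; XOR gateways leave a pending
decision whose branch-first tasks are reported as activatable; completing a
task resolves the decision of its branch and bypasses the sibling branches.
Sub-processes complete automatically at their end event. Completing a task
that is downstream, already completed, or bypassed raises a classed refusal
(out-of-order, regression, late-optional) — skipping and regressing are
impossible by construction.

The engine assumes block-structured graphs (every split has a matching join
of the same kind reached by all branches). This is not a limitation in
practice — the generator only emits such graphs, and the optional-step
pattern prescribed for the supported subset is inherently block-structured —
and it keeps both the engine and the independent trace oracle simple enough
to check against each other.

One peculiarity of the workflow engine whose behavior this package
reproduces is kept behind the `camunda_compat` flag (default `TRUE`): inside
an AND block, an undecided optional task is bypassed as soon as a task in a
sibling branch completes, so the optional can no longer be done late. With
the flag off, the optional stays activatable until the join is passed. The
flag changes the accepted trace set, and the trace oracle implements both
variants independently.

### Lifecycle engine (CMMN)

Plan items move through `available → enabled → active → completed`, with
`disabled` for optional items whose stage closes without them. Items whose
entry criteria are satisfied activate automatically when required, or wait
in `enabled` for `manually_start()` when optional. Sentries support exactly
one standard event, `complete` — completion dependencies are all the case
models here use. Stages without optional children auto-complete with their
last required child; stages with optional children must be completed
explicitly (`complete_stage()`), which disables the un-run optionals. The
case itself never completes on its own: `complete_case()` and `close_case()`
are the system's job after the last task, and a closed case is immutable.

### Where the notations disagree — by design

The case models are deliberately looser than the process models, and the
package preserves rather than papers over this, because the divergence *is*
the finding the test matrix checks:

* **Delayed optionals.** On the token engine (compatibility mode), an
  optional variable-order step must come before any sibling completes. On
  the lifecycle engine it stays enabled until its stage closes.
* **Exclusive paths.** A case model renders "exactly one of these paths" as
  a set of optional siblings; nothing stops a session from executing
  several paths — or none. The trace-set tests therefore characterize the
  CMMN-only traces as: optional delayed past a sibling, or a number of
  exclusive branches taken different from one (including zero, the
  degenerate half of the same modeling gap).

For one stage of `k` required variable tasks and `m` optional ones the
lifecycle semantics accept `sum_j C(m, j) * (k + j)!` complete traces
(`variable_block_trace_count()`), which equals the token-engine count
without the compatibility rule; with it the optional must come first, giving
`(1 + m) * k!`. A block of five variable tasks with one optional yields
`4! + 5! = 144` paths — the desk-scale reason variable order is modeled with
AND gateways rather than enumerated XOR alternatives.

## Knowledge, recognition and control

`static_next_steps()` walks the sequence flows recursively from the current
step, fanning out over both gateway kinds, descending into sub-processes and
stopping each path at the first task; `dynamic_next_steps()` refines this by
replaying the trace on a fresh instance. Both default to depth one — the
lookahead horizon is a parameter of the recursion, and one task ahead is
what the fusion prior consumes. Process knowledge is always derived from the
BPMN variant of the intervention, even when a case or combination model is
being controlled: the structured model stands in for what a library of
similar executed cases would provide (a `knowledge_source` switch exists for
experiments).

`score_sensors()` turns one observation into a distribution over steps:
every firing rule (instrument subset and positions compatible) contributes
its base score, a step-label observation scores its named step 1.0, and the
result is normalized. `fuse()` is a convex combination

```
fused(c) = w_s * p_sensor(c) + (1 - w_s) * q(c)
```

where `q` is uniform over the next possible steps plus the current one and
zero elsewhere, and `w_s` defaults to 0.8 (process knowledge 0.2). The
formula itself is this package's definition — the impact weighting is
specified as a configurable split between the two knowledge sources, and a
convex combination with a uniform process prior is the simplest fusion that
honors it. Ties at the maximum break lexically by step id, so logs are
reproducible. Process knowledge down-weights implausible candidates but
never vetoes them numerically; the plausibility verdict travels separately
as the `reasonable` flag.

```{r fusion}
fuse(c(s1 = 0.6, s2 = 0.4),
     list(next_steps = "s2", reasonable = TRUE),
     impact_config(0.8))$candidates
```

The controller (`step_controller()`, looped by `run_session()`) treats an
observation as the *start* of a situation and tracks exactly one current
situation. Recognizing a new step completes the previously running task —
this is what activates the next tasks in the engine, and it is also what
makes the compatibility rule bite: recognizing one variable-order sibling
completes the previous one, which bypasses a still-undecided optional.
Housekeeping that the notations demand is inserted automatically: manual
start before an optional item's completion, explicit stage completion when
un-run optionals block it, case complete/close plus the call-activity hop in
combination models. Repetition of the current situation is a no-op; an
unreasonable or engine-refused candidate produces a refusal row and leaves
the runtime untouched (all control is applied transactionally and rolled
back on failure). At the end of the stream the session is finalized: the
last situation is completed and the remaining stage/case bookkeeping runs.

Candidates inside the first stage of a case bypass the reasonableness veto
in reporting (`first_stage_exception`, default on) — the plausibility check
is documented to behave differently there, without detail, so the exception
lives in the controller as an explicit, switchable interpretation.

The remaining-surgery-duration module uses process knowledge only:
`rsd` sums the expected durations of required steps not yet completed,
optional steps are excluded, an unresolved exclusive decision contributes
its maximum-duration branch (a conservative upper estimate) and a resolved
one the remainder of its chosen branch; `delay = clock − expected_elapsed`.
Models without durations yield an `available = FALSE` estimate rather than
an error.

## The synthetic data generator

`ramie_spec()` and `ci_spec()` define the two intervention families. The
esophagectomy family has the nine phases of its use case; the cochlea
implantation the five printed ones (preparation, access, operation under and
after the microscope, follow-up). Phase *names* for the esophagectomy and
all step-level content are plausible placeholders authored here — the
originals are hospital-derived and not public — so passing tests show that
the engines, knowledge and control behave as specified on models *shaped*
like the use cases, not that any clinical content is correct. Step counts
are deliberately desk-scale (12 and 20 steps): every acceptance-relevant
structure (variable-order group with an optional member, standalone
optional, exclusive decision with branches of unequal length, an exemplary
modeled event) occurs at least once per family, and full sessions stay
fast enough to run dozens of times in the test matrix. Each step defaults
to 10 minutes so duration arithmetic is legible in logs.

Sensing follows the use cases: instrument sets plus actor positions for the
esophagectomy, bare step names for the cochlea implantation (where no sensor
data were available to simulate). `build_rules()` draws instrument pairs and
positions from shuffled vocabularies cycled per step, which guarantees
adjacent steps distinguishable signatures; with label sensing it emits one
label rule per step. Streams are deterministic in `(spec, scenario seed)` —
byte-identical across runs — and each distortion kind injects exactly one
anomaly: dropping a required step (one that is required in *every*
notation, i.e. not an exclusive-path member), dropping an included optional,
regressing to a completed step, repeating the current one, adding a second
exclusive path, reordering a variable group, or delaying an optional past
its siblings. Observation timestamps follow the expected durations, so valid
streams run at zero delay.

What the generator does not emulate: sensor noise and ambiguous rule
signatures, missing or out-of-vocabulary observations, timing jitter,
concurrent true parallelism, and modeled event occurrences (the exemplary
boundary event and event listener parse and round-trip but never fire).
Results on this data say nothing about recognition robustness under real
sensor noise — only about the model-execution and fusion logic downstream
of it.

## Numerical and degenerate-input choices

* Fused distributions renormalize after combination; with no evidence at
  all the result is an explicit no-recognition value, not a uniform guess.
* Argmax ties break lexically; reported task sets are sorted; generated ids
  (`phase_03`, `step_03_02`) are deterministic, so traces diff cleanly.
* Trace enumeration caps at 10 000 traces (`limit`) and reports truncation
  instead of silently stopping; the closed form is used for pure
  variable-order blocks.
* A trace driven on a permissive model may not replay on the BPMN knowledge
  model; knowledge lookups then degrade (empty next-step set, unavailable
  duration estimate) rather than fail the session.
* Re-completion of the current step is tolerated by the controller as a
  repetition no-op; the engine itself treats it as a regression error —
  tolerance policy belongs to the controller, strictness to the engine.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full matrix — two
intervention families × four model variants × eight scenario kinds — plus
oracle/engine trace-set comparisons on fragments of up to five variable
tasks (144 traces) and property checks over dozens of random fusion inputs
and lifecycle walks. These sizes were chosen so that a complete run stays in
the order of a minute while still covering every behavior class; all of
them are generated in code, and nothing in the package depends on stored
binary fixtures.

## Known limitations

* Only the documented element subsets parse; signal boundary events, event
  listeners and their follow-up measures have no runtime semantics.
* Sentry conditions (if-parts), repetition rules, milestones, discretionary
  tasks and case file items are out of scope; optionality is rule-encoded.
* The BPMN engine requires block-structured models.
* Exclusive decisions carry no condition expressions; branch choice is
  implicit in the first completed task.
* The first-stage exception and the fusion formula are documented
  interpretations of behavior that is described only qualitatively; both
  are flagged as such above and kept switchable.
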