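# surgflow

Execution, control and situation recognition for surgical process models.

Operating-room assistance systems need to know which step of an intervention
is being performed *right now*. surgflow implements a complete,
vendor-free situation-recognition workflow for that problem: it parses
surgical process models written in restricted subsets of **BPMN 2.0** and
**CMMN 1.1** (plus hybrid combinations of both), executes them with its own
token engine (BPMN) and plan-item lifecycle engine (CMMN), and fuses
simulated sensor observations with model-derived process knowledge to
recognize the current situation and drive the executing model forward.

It is written for surgical data science / clinical workflow informatics
work: comparing how well a strictly ordered process notation and a
declarative case notation capture variable interventions, and what that
choice does to a recognition system built on top of them.

## The core machinery

* **Model IO** — read/write `.bpmn` and `.cmmn` files and combination
  bundles; strict subset validation with structured rejections; everything
  round-trips (`read(write(m)) == m`).
* **Two engines** — token semantics for BPMN (parallel blocks for
  variable-order steps, exclusive-gateway bypasses for optional steps,
  strict ordering otherwise) and the CMMN lifecycle
  (`available → enabled → active → completed/disabled`, sentries on
  completion events, manual activation for optional items, manual stage and
  case completion).
* **Process knowledge** — next possible steps by recursive model lookahead
  and by engine replay; completable running instances with a plausibility
  verdict; remaining surgery duration and delay,
  `rsd = Σ duration(required steps not yet done)` with exclusive decisions
  contributing their maximum branch.
* **Recognition** — situation rules score sensor observations (instruments,
  actor positions, or step labels); fusion is the convex combination
  `w·p_sensor + (1−w)·q_process` with a uniform prior over the next
  possible steps and a configurable impact weight (default 0.8 sensor /
  0.2 process).
* **Control** — a transactional controller completes the previously running
  task when a new situation is recognized, inserts manual starts, stage
  completions and case enter/close hops as the notation requires, and
  refuses implausible observations without touching the runtime.
* **Synthetic fixtures** — deterministic generators for a nine-phase
  robot-assisted esophagectomy (RAMIE) family and a five-phase cochlea
  implantation (CI) family in all four variants (BPMN, CMMN, structured and
  mixed combination), with rule tables and observation streams (valid, or
  carrying exactly one distortion: skipped required/optional step,
  regression, repetition, second exclusive path, reordered variable group,
  delayed optional).
* **Trace oracle** — independent brute-force enumeration of all accepted
  complete traces, used to verify both engines; a block of `k` required
  variable-order tasks and `m` optionals accepts `Σⱼ C(m,j)·(k+j)!` traces
  (five variable tasks with one optional → 144 paths).

## Worked example

```r
library(surgflow)

spec   <- ci_spec()                          # five-phase cochlea implantation
bundle <- build_models(spec)                 # BPMN, CMMN, structured, mixed
rules  <- build_rules(spec, seed = 1)
stream <- simulate_stream(spec, bundle, scenario("valid", seed = 1), rules)

report <- run_session(bundle, stream, rules, variant = "cmmn")
report
#> <session_report> variant=cmmn, 11 observations
#>   completed: TRUE, refusals: 0
#>   trace (11 steps): step_01_01 > step_01_02 > step_02_01 > step_02_02 > ...

head(report$rows[, c("obs", "recognized", "probability", "accepted", "rsd", "delay")], 5)
#>  obs recognized probability accepted rsd delay
#>    1 step_01_01        1.00     TRUE 100     0
#>    2 step_01_02        0.90     TRUE  90     0
#>    3 step_02_01        0.90     TRUE  80     0
#>    4 step_02_02        0.90     TRUE  70     0
#>    5 step_03_01        0.85     TRUE  60     0
```

Each row is one observation: the fused best candidate and its probability,
whether the controller accepted it, and the remaining-duration estimate in
minutes (here 10 min per step, on schedule at every observation). Row 5 also
shows the controller's housekeeping when a phase border is crossed:
`complete_task(step_02_02); complete_stage(phase_02); manual_start(step_03_01)` —
the finished stage must be completed explicitly because an optional step was
never run, and the first task of the exclusive decision is started manually
because case models encode alternative paths as optional items.

The same stream completes identically on every variant; the distortion
streams separate them. A delayed optional is refused by the token engine but
tolerated by the case engine — the divergence the test matrix pins down:

```r
late <- simulate_stream(spec, bundle, scenario("delayed_optional", 1), rules)
run_session(bundle, late, rules, variant = "bpmn")
#> <session_report> variant=bpmn, 10 observations
#>   completed: TRUE, refusals: 1
run_session(bundle, late, rules, variant = "cmmn")$refusals
#> [1] 0
```

## Command line

```sh
Rscript inst/cli/surgflow.R generate --spec ci --out models/ci --seed 1
Rscript inst/cli/surgflow.R validate models/ci/ci.bpmn models/ci/structured
Rscript inst/cli/surgflow.R run --models models/ci \
    --stream models/ci/streams/valid.jsonl --variant cmmn
Rscript inst/cli/surgflow.R enumerate --model models/ci/ci.bpmn --limit 1000
```

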