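---
title: "Matrix-approach GMO screening: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-approach GMO screening: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GMOscreen)
```

## The screening problem

Routine enforcement laboratories must establish which genetically modified
events a feed or food sample contains, and whether anything in it points to
a GMO that no event-specific method would find. Testing every known event
directly is impractical, so samples are first screened with PCR assays for
the genetic *elements* (promoters, terminators, coding sequences) and
*constructs* (joined element pairs) that transformation events share — the
matrix approach. GMOscreen implements the interpretation layer of an
extended version of this strategy built on 32 TaqMan assays: seven
endogenous taxon genes (soy Lec, maize HMG, canola FatA, rice SPS, sugar
beet GS, wheat Wx-1 and an all-plants actin control), 24 element/construct
assays and a CaMV assay that guards against virus-derived P-35S signals.

The central data object is the **specificity matrix**: for each of 60
events and each of the 25 screening targets it records what the assay does
on reference material of that event, in six states:

| symbol | meaning | detectable? | explains a signal? |
|---|---|---|---|
| `+`  | verified positive | yes | yes |
| `-`  | verified negative | no | no |
| `X`  | element present but missed (sequence divergence) | no | no |
| `+*` | fires through sequence similarity | yes | yes, annotated |
| `(+)`| expected positive, unverified | no (non-binding) | only as "unverified" |
| empty | expected negative, unverified | no | no |

The treatment of the borderline states is a deliberate design choice.
`X` never contributes to candidacy or explanation — the element is there,
but the assay cannot see it, so no signal can be attributed to it. `+*`
counts as fully detectable (the signal is real, whatever its sequence
origin) but carries an annotation. `(+)` is non-binding in both directions:
a negative call on an `(+)` assay never rules an event out, and an `(+)`
link explains a detected element only with the `explained_unverified`
status. Empty cells behave as negatives but are flagged as unverified in
the shipped provenance notes.

Because the published table is easy to mis-transcribe, the bundled file is
cross-validated on load against statements the accompanying text makes
directly: seven zero-coverage events; the seven-element set
{P-35S, P-FMV, T-nos, Cry1A(b), Cry1A.105, Cry2Ab2, I-rAct1} jointly
produced by MON89034 and MON810 maize and fully covered by MON89034 alone;
Bt11's `+*` on T-35S; MON87460's diverged rice-actin promoter with four
remaining detectable elements; DP356043's diverged P-35S. `gmoMatrix()`
refuses to return a matrix that fails an anchor; `validateBundledData()`
exposes the same checks as a report.

Authorisation statuses (`authorised`, `low_level_619_2011`, `expired`,
`unauthorised`, `unknown`) are *configuration*, carried in the editable
matrix file. Only statuses the method description states in text are
pre-set (the unauthorised DAS59132 (E32) maize and the unauthorised rice
cases); everything else defaults to `unknown` rather than guessing a legal
situation that changes over time.

## Plate design and copy arithmetic

`buildLayout()` produces the fixed eight-plate design: four assays per
96-well plate, each in a 24-well block of three columns filled column-major
with samples 1-1, 1-2, …, 11-2, then the positive sensitivity control,
then the water control. The published figure fixes this *content* but not
machine coordinates, so the block-filling order above is normative for this
package and byte-identical across runs. Runs with fewer than 11 samples
keep their unused wells in the map with role `empty`, so well bookkeeping
never depends on the sample count.

Every reaction holds 25 µL: 20 µL mix and 5 µL template at 10 ng/µL, i.e.
50 ng DNA. Sensitivity controls run at 0.1% GMO or 25 haploid genome
equivalent copies. The conversion is

```
copies = floor(dna_mass_ng * 1000 * gmo_fraction / genome_1C_pg)
```

Floor rounding is used because it reproduces all three documented control
values exactly — 44 copies soy (1C = 1.13 pg), 18 copies maize
(2.725 pg), 43 copies canola (1.15 pg) — and because a fractional genome
is not an amplifiable template. The arithmetic deliberately ignores
zygosity: true copy numbers in certified reference material depend on it,
and the package records this caveat rather than modelling it. 1C values
for soy, maize and canola are the documented ones; cotton (2.33 pg), rice
(0.43), sugar beet (0.757), potato (0.87) and wheat (16.93) use standard
plant-genome values adopted once for the simulator.

## Calling rules

The thermocycler software computes Cq values upstream; this package never
re-derives them from fluorescence. Duplicate isolations collapse to one
call per sample and assay:

* both replicates amplified at Cq ≤ `detect_cq_max` → **D**;
* neither amplified → **ND**;
* discordant replicates → **S**;
* both amplified but only inside the late window
  (`suspect_cq_min`, `detect_cq_max`] → **S** with a late-Cq note.

The published module displays D/ND/S but defines no numeric rule, so these
thresholds are explicit choices of this implementation, kept in
`screeningConfig()`: `detect_cq_max = 45` equals the run's cycle count
(any amplification within the programme is signal), and
`suspect_cq_min = 34` reflects the observed onset of trace-contamination
signals (Cq 34–40) in reference-material runs. A missing replicate is
called from the remaining well and flagged `single replicate`. An assay
whose sensitivity control fails or whose water control amplifies yields
calls annotated `invalid-run`; inference refuses such calls unless
explicitly overridden, and never drops them silently.

## Inference

**Crop gating.** A crop counts as present when its taxon assay is D or S.
Cotton and potato have no taxon assay among the 32 and are therefore
*ungated*: their events are always considered. The actin assay confirms
amplifiable plant DNA; a fully silent endogenous lane raises a DNA-quality
warning rather than a clean negative.

**Candidacy.** In strict mode (the default) an event is "possibly
present" when its crop gate passes and *every* assay it is detectable by
was called D or S; lenient mode (≥ 1 such call) exists for degraded
samples. Whether the original interactive module required all or any
element is not documented; strict is the default here because the purpose
of a complete 32-assay screen is to rule events in or out, and a
detectable element that stayed negative is positive evidence of absence.
S counts as detected throughout — conservative with respect to missing an
unauthorised GMO. Zero-coverage events can never be predicted from
screening and are returned separately (`alwaysTest`) for every present or
ungated crop.

**Explanation and the unknown-GMO flag.** After event-specific testing,
each detected screening target is checked against the *confirmed* events:
explained if a confirmed event is detectable by it, `explained_unverified`
if only an `(+)` cell links them, otherwise unexplained. Detected targets
on the donor-organism caveat list (nptII, T-g7, T-E9, P-Rice actin,
I-rAct1, CaMV) receive the `donor_caveat` status with a softened
annotation — the signal may come from naturally occurring donor organisms
— but still count toward the unknown-GMO indication: a donor origin is a
possibility, not an explanation. The indication itself raises only when
unexplained targets remain *and* every candidate has an entered event
result; while candidates are untested the engine asks for those tests
instead. A CaMV-positive sample additionally annotates P-35S detections as
possibly virus-derived.

`requiredNextTests` deliberately contains candidates only. Zero-coverage
events stay in `alwaysTest` as a standing recommendation: for a
GMO-labelled sample the workflow is *complete* once all elements are
explained, and conflating the two lists would make that stopping rule
unreachable.

**Masking.** An unconfirmed event whose non-empty detectable set is
contained in the union of elements of the confirmed events would change no
screening call; `maskingCheck()` lists such events (MON810 behind
MON89034 is the canonical case). The report is advisory — screening alone
cannot decide it either way.

**Workflow.** GMO-labelled samples stop when everything is explained,
list untested candidates otherwise, and escalate to "unknown unauthorised
GMO indicated; orthogonal identification required" when nothing remains to
test. Non-GMO-labelled samples must test every candidate and quantify
every detected event against the 0.9% labelling threshold; quantification
itself is outside this package's scope. Candidate and test listings are
ordered by authorisation severity (unauthorised, unknown, expired,
low-level, authorised), then support, then name — a reporting convenience,
not a documented property of the original module.

**Stacked events** produce the union pattern of their components and are
not resolvable by screening. The engine never claims stack identification;
`stackCqHint()` can annotate similar Cq values across detected elements as
a hint, nothing more.

## The simulator

`simulateRun()` exists so the whole pipeline is testable end to end
without instrument data. Its model is intentionally minimal and
analysable:

* the template count of a well is Poisson with mean equal to the summed
  `copiesPerReaction()` contributions of every composition component whose
  matrix state is `+` or `+*` (`X` components contribute nothing);
* amplification is all-or-nothing at ≥ 1 copy — justified by the methods'
  verified limits of detection below 20 copies — so the no-amplification
  rate at mean λ is exactly exp(−λ);
* an amplified well reports Cq = 40 − 3.32·log10(copies) + N(0, σ), i.e.
  a single-copy intercept of 40 cycles at perfect doubling efficiency,
  with σ = 0.2 cycles of replicate noise by default;
* positive-control wells contain their assay's target at the
  sensitivity-control level: 0.1% of 50 ng for GMO reference material of
  known crop (44/18/43 copies for soy/maize/canola), undiluted material
  for taxon-assay controls, 25 copies otherwise. Control template presence
  is modelled directly because control materials are selected to contain
  the target; water controls never amplify unless a contamination mean is
  injected.

What the simulator does *not* model — PCR efficiency and inhibition,
extraction yield, zygosity, fluorescence baselines, cross-contamination
between wells — bounds what passing tests show: they verify the
interpretation logic against the matrix semantics and the copy-number
arithmetic, not instrument behaviour on real extracts.

Free `elements` contributions (a screening target present at a mass
fraction without any catalogued event) make the unknown-GMO scenario
constructible; `makeFixture()` registers four scenarios used throughout
the test suite, including a 0.01% MON531 trace in MON1445 cotton that
reproduces late-Cq (> 34) contamination signals.

## Numerical and testing choices

Tolerances and sizes used by the test suite are part of the package's own
verification design: the statistical properties run on 1000 random
profiles (explanation monotonicity), an exhaustive single-event sweep of
all 60 bundled events against a brute-force subset oracle (masking), 200
noise-free simulated samples carrying 1–3 events at fractions chosen so
every event contributes at least 25 copies (parameter recovery), and 1000
wells at λ = 1 with a 3-standard-error band (Poisson dropout). Degenerate
inputs are pinned by construction: empty event sets explain nothing and
mask nothing, empty summaries keep their full header, and sub-single-copy
loads floor to zero copies.

## Known limitations

* The specificity matrix is a transcription; cells that could not be read
  unambiguously from the published table are encoded as unverified states
  and listed in the shipped provenance notes. The anchor checks bound, but
  cannot eliminate, transcription risk for cells the prose never mentions.
* Event authorisation statuses are configuration and mostly `unknown` as
  shipped; reports that count by status are only as good as that file.
* The D/ND/S thresholds are implementation defaults, not documented
  properties of the original interactive module.
* No in-silico PCR: specificity comes from the matrix, never from primer
  sequences. No quantification, no stacked-event resolution, no retrieval
  from external GMO databases.
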