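# GMOscreen

Matrix-approach qPCR screening of genetically modified organisms (GMOs)
with unknown-event flagging, for enforcement and routine feed/food
laboratories.

Series of up to 11 samples are screened in duplicate with 32 TaqMan PCR
methods — seven endogenous taxon genes, 24 element/construct assays and a
CaMV virus control — pipetted as four 24-well blocks on each of eight
96-well plates, every assay carrying a positive sensitivity control
(0.1% GMO or 25 genome copies) and a water control. The package
interprets such screens against a verified **specificity matrix**
`S[event, assay] ∈ {+, -, X, +*, (+), ∅}` over 60 GMO events in seven
crops:

* **candidacy** — an event *e* is possibly present when its crop's taxon
  assay fired and every assay in `det(e) = {a : S[e,a] ∈ {+, +*}}` was
  called D or S (strict mode);
* **explanation** — after event-specific testing, a detected element *a*
  is explained iff some confirmed event *e* has `S[e,a] ∈ {+, +*}`;
* **unknown-GMO indication** — raised when detected elements remain
  unexplained after all candidates have been tested: the signature of an
  unknown unauthorised GMO;
* **masking** — an unconfirmed event with
  `∅ ≠ det(e) ⊆ ⋃ det(confirmed)` would change no screening call and is
  reported as maskable;
* **copy arithmetic** —
  `copies = ⌊ mass_ng · 1000 · fraction / 1C_pg ⌋` converts DNA mass to
  haploid genome equivalents (44/18/43 copies for 0.1% soy/maize/canola
  at 50 ng).

Duplicate wells collapse to D / ND / S calls (both ≤ 45 cycles → D;
neither → ND; discordant, or both in the late window above Cq 34 → S),
and a Poisson single-copy simulator makes the whole pipeline testable
without instrument data.

## Worked example

A maize sample carrying 5% MON89034 and 5% MON810 is simulated, called
and interpreted; the analyst then enters the MON89034 event-test result:

```r
library(GMOscreen)
m      <- gmoMatrix()
layout <- buildLayout(11)
comp   <- sampleComposition(1, "maize",
            events = c("MON89034 maize" = 0.05, "MON810 maize" = 0.05))
cq     <- simulateRun(comp, layout, m, seed = 11)
f <- tempfile(); writeCqTable(cq, f)
calls  <- callSampleProfile(parseCqTable(f, layout))
interp <- interpretSample(calls, m, sample_id = 1,
            eventResults = c("MON89034 maize" = "detected"))
interp
#> ScreenInterpretation: sample 1 (gmo_labelled)
#> CandidateReport
#>   crops present: maize
#>   candidates: MON89034 maize, MON810 maize, 5307 maize, MIR604 maize
#>   always test: DAS40278 maize, DP98140 maize, GHB614 cotton
#> ExplanationReport: 7 detected screening target(s)
#>   explained: Cry1A.105, Cry1A(b), Cry2Ab2, I-rAct1, P-35S, P-FMV, T-nos
#>   unknown GMO indicated: FALSE
#>   workflow: complete
```

The stack fires seven elements (P-35S, P-FMV, T-nos, Cry1A(b), Cry1A.105,
Cry2Ab2, I-rAct1). MON89034 alone is detectable by all seven, so after
confirming it the workflow is `complete`: every element is explained, no
further event tests are required for a GMO-labelled sample — and MON810,
whose detectable set {P-35S, Cry1A(b)} is contained in MON89034's, will
consequently not be identified. That blind spot is exactly what the
masking report surfaces:

```r
maskingCheck(m, "MON89034 maize")
#>          event  crop  status
#> 1   5307 maize maize unknown
#> 2 MIR604 maize maize unknown
#> 3 MON810 maize maize unknown
```

The per-assay sheet carries the colour semantics of the interactive
analysis module as explicit tokens:

```r
head(renderSampleSheet(interp, m, "text"), 10)
#> Sample 1 (gmo_labelled)
#> Crops present: maize
#>
#> assay                 Cq1    Cq2     expectation   explanation
#> bar                     -      -  ND EXPECTED_NEG
#> Barstar                 -      -  ND EXPECTED_NEG
#> CaMV                    -      -  ND EXPECTED_NEG
#> Canola FatA             -      -  ND
#> CP4-epsps               -      -  ND EXPECTED_NEG
#> Cry1A.105            30.4   30.0  D  EXPECTED_POS  EXPLAINED
```

`buildSummary()` flattens any number of interpreted samples into the
tab-separated table handed to a LIMS. The bundled data (specificity
matrix, assay catalogue with primer/probe sequences and concentrations,
plate distribution, positive-control assignments, 1C genome sizes) live
under `inst/extdata/` with provenance notes, and
`validateBundledData()` / the `validate-data` subcommand re-verify them,
including the prose anchors that pin the matrix transcription.

See the vignette (`vignettes/screening-methods.Rmd`) for the models,
calling rules, inference semantics and the simulator's assumptions.

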