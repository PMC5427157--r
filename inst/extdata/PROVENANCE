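Provenance notes for the bundled screening data
===============================================

specificity_matrix.tsv
  Assay-by-event specificity of the 25 screening targets (elements,
  constructs and the CaMV virus assay) against 60 GMO events covering
  seven crops. Cell symbols:
    +    element detected in the reference material
    -    element verified not detected
    X    element present in the event but not detected (sequence
         divergence from the assay's primers/probe)
    +*   detected, but attributed to sequence similarity rather than a
         bona fide element copy (Bt11 / T-35S)
    (+)  expected positive, not verified experimentally (no reference
         material available)
    (empty) expected negative, not verified experimentally
  The published table typesets several rows ambiguously; cells that could
  not be read with confidence were encoded with the unverified symbols
  rather than guessed.  The Bt63 rice construct row is largely unverified
  (no certified reference material exists); its expected-negative cells
  are left empty.  The transcription is cross-checked at load time against
  the publication's prose statements (seven zero-coverage events; the
  MON89034 / MON810 element sets; Bt11 T-35S "+*"; MON87460 P-Rice actin
  "X" with four remaining detectable elements; DP356043 P-35S "X";
  T-35S positive in T45 canola and DAS59122 maize) via
  validateBundledData().

  Authorisation statuses are configuration, not certified fact: only
  statuses stated in the method description's text are set (DAS59132 (E32)
  maize, LL601 rice and the Bt63 rice construct as unauthorised); all
  other events carry "unknown" and should be edited to the current legal
  situation before routine use.

assays.tsv
  Primer/probe sequences and final concentrations (nM) of the 32 TaqMan
  screening methods, with literature reference keys.  Seven endogenous
  (taxon) assays carry a crop scope; "Plant actin" covers all plants.

plate_methods.tsv
  Distribution of the 32 methods over eight 96-well plates, four mixes
  per plate.

positive_controls.tsv
  Per-assay positive sensitivity control material (0.1% GMO CRM at 50 ng
  per reaction, or 25 haploid genome equivalent copies in non-GMO
  background).  Transcribed as published, including the assignment of
  MON810 maize to the CP4-epsps and ctp4/CP4-epsps methods.

genome_sizes_1C.tsv
  Haploid (1C) genome masses in picograms used for copy-number
  arithmetic.  Soy, maize and canola values are those used in the method
  description; the remaining crops use standard plant-genome values
  chosen for the simulator.
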