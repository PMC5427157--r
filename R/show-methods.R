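setMethod("show", "SpecificityMatrix", function(object) {
  st <- object@states
  cat("SpecificityMatrix:", nrow(st), "events x", ncol(st),
      "screening targets\n")
  cat("  crops:", paste(sort(unique(object@events$crop)), collapse = ", "),
      "\n")
  cat("  zero-coverage events:", length(zeroCoverageEvents(object)), "\n")
  cat("  donor-caveat assays:",
      paste(object@donorCaveatAssays, collapse = ", "), "\n")
})

setMethod("show", "PlateLayout", function(object) {
  a <- object@assignments
  cat("PlateLayout:", length(unique(a$plate)), "plates,", nrow(a),
      "wells,", object@nSamples, "samples in duplicate\n")
  cat("  roles:", paste(names(table(a$role)), table(a$role), sep = "=",
                        collapse = ", "), "\n")
})

setMethod("show", "CqModel", function(object) {
  cat(sprintf("CqModel: Cq = %.2f - %.2f * log10(copies), sigma = %.2f\n",
              object@intercept, object@slope, object@sigma))
})

setMethod("show", "CandidateReport", function(object) {
  cat("CandidateReport\n")
  cat("  crops present:", paste(object@cropsPresent, collapse = ", "), "\n")
  cat("  candidates:", if (nrow(object@candidates))
    paste(object@candidates$event, collapse = ", ") else "none", "\n")
  if (length(object@alwaysTest))
    cat("  always test:", paste(object@alwaysTest, collapse = ", "), "\n")
  if (object@dnaQualityWarning)
    cat("  WARNING: no endogenous signal - check DNA quality\n")
})

setMethod("show", "ExplanationReport", function(object) {
  el <- object@elements
  cat("ExplanationReport:", nrow(el), "detected screening target(s)\n")
  if (nrow(el))
    for (s in unique(el$status))
      cat(sprintf("  %s: %s\n", s,
                  paste(el$assay[el$status == s], collapse = ", ")))
  if (length(object@requiredNextTests))
    cat("  required next tests:",
        paste(object@requiredNextTests, collapse = ", "), "\n")
  cat("  unknown GMO indicated:", object@unknownGmoIndicated, "\n")
})

setMethod("show", "ScreenInterpretation", function(object) {
  cat(sprintf("ScreenInterpretation: sample %d (%s)\n", object@sampleId,
              object@labelMode))
  show(object@candidates)
  show(object@explanation)
  cat("  workflow:", object@workflow$status, "\n")
})
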