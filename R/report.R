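## Per-sample sheets and the cross-sample summary (LIMS export).
## Colour semantics of the interactive module map to explicit status
## tokens so delimited-text exports carry the same information.

.expectation_tokens <- function(interp, matrix) {
  targets <- screeningTargets(matrix)
  cand <- candidates(interp@candidates)$event
  expected_pos <- expectedElements(matrix, cand)
  ifelse(targets %in% expected_pos, "EXPECTED_POS", "EXPECTED_NEG")
}

#' Hint at a possible stacked event
#'
#' Screening cannot identify stacked events (a stack produces the union
#' element pattern of its components); similar Cq values across detected
#' elements can merely hint at one.  Returns an annotation string, or `""`.
#'
#' @param calls one-sample calls data.frame with `call`, `cq1`, `cq2`.
#' @param tol Cq window regarded as "similar" (cycles).
#' @return character annotation (never an identification)
#' @export
stackCqHint <- function(calls, tol = 1) {
  d <- calls[calls$call == "D" & !is.na(calls$cq1), ]
  if (nrow(d) < 2L) return("")
  mcq <- rowMeans(d[, c("cq1", "cq2")], na.rm = TRUE)
  if (max(mcq) - min(mcq) <= tol)
    "similar Cq values across detected elements may indicate a stacked event (screening cannot identify stacks)"
  else ""
}

#' Render a per-sample analysis sheet
#'
#' `format = "data"` returns the machine-readable lanes (a data.frame per
#' assay row: Cq pair, call, expectation and explanation tokens) plus the
#' candidate and event-result lanes; `format = "text"` returns printable
#' lines; `format = "tsv"` returns the assay lane as tab-separated lines
#' (with `#`-prefixed header lines) that [parseSampleSheet()] reads back.
#'
#' @param interp a [ScreenInterpretation-class].
#' @param matrix the [SpecificityMatrix-class] used for the
#'   interpretation.
#' @param format `"data"`, `"text"` or `"tsv"`.
#' @return see above
#' @export
renderSampleSheet <- function(interp, matrix,
                              format = c("data", "text", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(interp, "ScreenInterpretation"))
  calls <- interp@calls
  expl <- explanationStatus(interp@explanation)
  lane <- data.frame(assay = calls$assay, call = calls$call,
                     cq1 = calls$cq1, cq2 = calls$cq2,
                     notes = calls$notes, stringsAsFactors = FALSE)
  targets <- screeningTargets(matrix)
  tok <- .expectation_tokens(interp, matrix)
  lane$expectation <- ifelse(lane$assay %in% targets,
                             tok[match(lane$assay, targets)], "")
  st <- expl$status[match(lane$assay, expl$assay)]
  lane$explanation <- ifelse(is.na(st), "",
                             c(explained = "EXPLAINED",
                               explained_unverified = "EXPLAINED_UNVERIFIED",
                               unexplained = "UNEXPLAINED",
                               donor_caveat = "DONOR_CAVEAT")[st])
  lane$explanation[is.na(lane$explanation)] <- ""
  cand <- candidates(interp@candidates)
  evres <- interp@explanation@eventResults
  if (format == "data") {
    return(list(sample_id = interp@sampleId, calls = lane,
                candidates = cand,
                always_test = alwaysTest(interp@candidates),
                event_results = evres,
                workflow = interp@workflow,
                stack_hint = stackCqHint(calls)))
  }
  if (format == "tsv") {
    hdr <- c(sprintf("# sample\t%d", interp@sampleId),
             sprintf("# label_mode\t%s", interp@labelMode),
             sprintf("# workflow\t%s", interp@workflow$status),
             sprintf("# unknown_gmo\t%s",
                     unknownGmoIndicated(interp@explanation)))
    body <- c(paste(names(lane), collapse = "\t"),
              vapply(seq_len(nrow(lane)), function(i)
                paste(vapply(lane[i, ], function(v)
                  ifelse(is.na(v), "", as.character(v)), character(1L)),
                  collapse = "\t"), character(1L)))
    return(c(hdr, body))
  }
  fmt_cq <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  lines <- c(
    sprintf("Sample %d (%s)", interp@sampleId, interp@labelMode),
    sprintf("Crops present: %s%s",
            paste(interp@candidates@cropsPresent, collapse = ", "),
            if (interp@candidates@dnaQualityWarning)
              "  [WARNING: no endogenous signal - check DNA quality]" else ""),
    "",
    sprintf("%-18s %6s %6s  %-2s %-13s %s", "assay", "Cq1", "Cq2", "",
            "expectation", "explanation"),
    sprintf("%-18s %6s %6s  %-2s %-13s %s", lane$assay, fmt_cq(lane$cq1),
            fmt_cq(lane$cq2), lane$call, lane$expectation,
            lane$explanation),
    "",
    sprintf("Possibly present GMO events: %s",
            if (nrow(cand)) paste(cand$event, collapse = ", ") else "none"),
    if (length(alwaysTest(interp@candidates)))
      sprintf("Test directly (no screening coverage): %s",
              paste(alwaysTest(interp@candidates), collapse = ", ")),
    if (length(evres))
      sprintf("Event results entered: %s",
              paste(names(evres), evres, sep = "=", collapse = ", ")),
    sprintf("Workflow: %s", interp@workflow$status),
    if (length(interp@workflow$tests))
      sprintf("Required event tests: %s",
              paste(interp@workflow$tests, collapse = ", ")),
    if (length(interp@workflow$quantify))
      sprintf("Quantify vs 0.9%% threshold: %s",
              paste(interp@workflow$quantify, collapse = ", ")),
    if (unknownGmoIndicated(interp@explanation))
      "INDICATION OF UNKNOWN UNAUTHORISED GMO",
    if (nzchar(stackCqHint(calls))) stackCqHint(calls))
  unlist(lines)
}

#' Parse the call lane of a rendered sheet
#'
#' Reads back the `tsv` rendering of [renderSampleSheet()].
#'
#' @param lines character vector (or path to a file of) tsv sheet lines.
#' @return named character vector assay -> call
#' @export
parseSampleSheet <- function(lines) {
  if (length(lines) == 1L && file.exists(lines))
    lines <- readLines(lines)
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$call, tab$assay)
}

#' Build the cross-sample summary table
#'
#' One row per sample: the 32 assay calls, the tested events with their
#' results, detected-event counts per authorisation category, the workflow
#' directive and the unknown-GMO flag - the flat table handed to a LIMS.
#' Column order is fixed.
#'
#' @param interps list of [ScreenInterpretation-class] objects built
#'   against the same design (identical assay sets).
#' @param matrix the [SpecificityMatrix-class] used.
#' @return data.frame, one row per sample
#' @export
buildSummary <- function(interps, matrix) {
  stopifnot(is.list(interps))
  if (!length(interps)) {
    assays <- gmoAssays()$name
    out <- as.data.frame(matrix(character(), nrow = 0L,
                                ncol = 6L + length(assays)))
    names(out) <- c("sample_id", "label_mode", assays, "tested_events",
                    "detected_event_statuses", "workflow", "unknown_gmo")
    return(out)
  }
  assay_sets <- lapply(interps, function(x) sort(x@calls$assay))
  if (!all(vapply(assay_sets, identical, logical(1L), assay_sets[[1L]])))
    stop("mixed designs: interpretations cover different assay sets")
  ev <- eventCatalogue(matrix)
  rows <- lapply(interps, function(x) {
    calls <- stats::setNames(x@calls$call, x@calls$assay)
    evres <- x@explanation@eventResults
    confirmed <- names(evres)[evres == "detected"]
    statuses <- ev$status[match(confirmed, ev$name)]
    status_counts <- paste(
      vapply(.AUTH_STATUSES, function(s)
        sprintf("%s=%d", s, sum(statuses == s)), character(1L)),
      collapse = ";")
    row <- data.frame(sample_id = x@sampleId, label_mode = x@labelMode,
                      stringsAsFactors = FALSE)
    for (as in sort(names(calls))) row[[as]] <- calls[[as]]
    row$tested_events <- paste(names(evres), evres, sep = ":",
                               collapse = ";")
    row$detected_event_statuses <- status_counts
    row$workflow <- x@workflow$status
    row$unknown_gmo <- unknownGmoIndicated(x@explanation)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the summary table
#'
#' Tab-separated, lossless round-trip of [buildSummary()] output.
#'
#' @param summary summary data.frame.
#' @param path file path.
#' @return `writeSummary`: path invisibly; `readSummary`: the data.frame.
#' @export
writeSummary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeSummary
#' @export
readSummary <- function(path) {
  s <- .read_tsv(path, colClasses = "character")
  s$sample_id <- as.integer(s$sample_id)
  s$unknown_gmo <- as.logical(s$unknown_gmo)
  s
}
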