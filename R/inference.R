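## Screening inference: crops present, candidate events, element
## explanation, masking, workflow directives.

.profile_vector <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(all(c("assay", "call") %in% names(profile)))
    profile <- stats::setNames(profile$call, profile$assay)
  }
  stopifnot(is.character(profile), !is.null(names(profile)),
            all(profile %in% .CALLS))
  profile
}

#' Crops present in a sample
#'
#' A crop counts as present when its endogenous taxon assay was called `D`
#' or `S`.  Crops without a dedicated taxon assay in the design (cotton and
#' potato) cannot be gated and are returned as `ungated`: their events are
#' always considered possible.  The all-plants actin assay confirms
#' amplifiable plant DNA; if no endogenous assay fired at all, a DNA
#' quality warning is raised.
#'
#' @param profile named character vector assay -> call (`D`/`ND`/`S`), or a
#'   calls data.frame for one sample.
#' @param assays assay catalogue ([gmoAssays()]).
#' @return list with `crops`, `ungated`, `plant_material`,
#'   `dna_quality_warning`.
#' @export
cropsPresent <- function(profile, assays = gmoAssays()) {
  profile <- .profile_vector(profile)
  endo <- assays[assays$category == "endogenous", ]
  det <- function(nm) nm %in% names(profile) && profile[[nm]] %in% c("D", "S")
  taxon <- endo[endo$crop_scope != "all plants", ]
  crops <- taxon$crop_scope[vapply(taxon$name, det, logical(1L))]
  actin <- endo$name[endo$crop_scope == "all plants"]
  plant <- length(actin) == 1L && det(actin)
  list(crops = crops,
       ungated = c("cotton", "potato"),
       plant_material = plant,
       dna_quality_warning = !plant && length(crops) == 0L)
}

.severity_rank <- function(status) {
  r <- .AUTH_SEVERITY[status]
  r[is.na(r)] <- max(.AUTH_SEVERITY) + 1L
  unname(r)
}

#' Predict candidate GMO events from a screening profile
#'
#' An event passes the crop gate when its crop's taxon assay fired (or the
#' crop has no taxon assay).  In strict mode (default) it becomes a
#' candidate when additionally *every* assay it is detectable by was called
#' `D` or `S`; in lenient mode one such call suffices (for degraded
#' samples).  Suspect calls count as detected, conservatively.  Events with
#' no detectable screening element (zero coverage) cannot be predicted and
#' are returned under `alwaysTest` for every present or ungated crop.
#'
#' Candidates are ordered by authorisation severity (unauthorised first,
#' then unknown, expired, low-level, authorised), then by number of
#' supporting detections, then name - a reporting convenience.
#'
#' @param profile named call vector or one-sample calls data.frame.
#' @param matrix a [SpecificityMatrix-class].
#' @param config a [screeningConfig()]; `candidate_mode` selects
#'   strict/lenient.
#' @return a [CandidateReport-class]
#' @export
candidateEvents <- function(profile, matrix, config = screeningConfig()) {
  config <- .as_config(config)
  profile <- .profile_vector(profile)
  crops <- cropsPresent(profile, assayCatalogue(matrix))
  detected <- names(profile)[profile %in% c("D", "S")]
  ev <- eventCatalogue(matrix)
  cand <- list(); excl <- list(); always <- character()
  for (i in seq_len(nrow(ev))) {
    name <- ev$name[i]
    gate <- ev$crop[i] %in% crops$crops || ev$crop[i] %in% crops$ungated
    det <- expectedDetectable(matrix, name)$detectable
    if (!gate) {
      excl[[name]] <- sprintf("crop gate: %s not detected", ev$crop[i])
      next
    }
    if (length(det) == 0L) {
      always <- c(always, name)
      next
    }
    support <- intersect(det, detected)
    ok <- if (config$candidate_mode == "strict")
      length(support) == length(det) else length(support) >= 1L
    if (ok) {
      cand[[name]] <- data.frame(
        event = name, crop = ev$crop[i], status = ev$status[i],
        basis = paste(support, collapse = ";"),
        n_support = length(support),
        notes = if (length(expectedDetectable(matrix, name)$cross_react))
          "includes cross-reacting assay" else "",
        stringsAsFactors = FALSE)
    } else {
      first_fail <- setdiff(det, detected)[1L]
      excl[[name]] <- sprintf("assay %s not detected", first_fail)
    }
  }
  cdf <- if (length(cand)) do.call(rbind, cand)
         else data.frame(event = character(), crop = character(),
                         status = character(), basis = character(),
                         n_support = integer(), notes = character())
  if (nrow(cdf)) {
    ord <- order(.severity_rank(cdf$status), -cdf$n_support, cdf$event)
    cdf <- cdf[ord, ]
    rownames(cdf) <- NULL
  }
  edf <- if (length(excl))
    data.frame(event = names(excl), reason = unlist(excl),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(event = character(), reason = character())
  new("CandidateReport", cropsPresent = crops$crops,
      ungatedCrops = crops$ungated, plantMaterial = crops$plant_material,
      dnaQualityWarning = crops$dna_quality_warning,
      candidates = cdf, alwaysTest = sort(always), excluded = edf)
}

#' Accessors for candidate reports
#' @param x a [CandidateReport-class]
#' @return `candidates()`: data.frame of candidate events; `alwaysTest()`:
#'   character vector of zero-coverage events to test directly.
#' @export
candidates <- function(x) { stopifnot(is(x, "CandidateReport")); x@candidates }

#' @rdname candidates
#' @export
alwaysTest <- function(x) { stopifnot(is(x, "CandidateReport")); x@alwaysTest }

.event_results_vector <- function(eventResults) {
  if (is.null(eventResults)) return(character())
  if (is.data.frame(eventResults)) {
    stopifnot(all(c("event", "result") %in% names(eventResults)))
    eventResults <- stats::setNames(eventResults$result, eventResults$event)
  }
  stopifnot(all(eventResults %in% c("detected", "not_detected")))
  eventResults
}

#' Explain detected elements by confirmed events
#'
#' After event-specific testing, each detected screening target is checked
#' against the events confirmed in the sample.  A target is `explained`
#' when a confirmed event is detectable by it (`+` or `+*` in the matrix),
#' `explained_unverified` when only an unverified `(+)` expectation links
#' them, and otherwise `unexplained` - or `donor_caveat` when the signal
#' may originate from a naturally occurring donor organism.  Unexplained
#' and donor-caveat targets both raise the unknown-GMO indication once
#' every candidate has an event-test result; donor-caveat ones carry a
#' softened annotation.  A CaMV-positive sample additionally annotates
#' P-35S detections as possibly virus-derived.
#'
#' @param profile named call vector or one-sample calls data.frame.
#' @param matrix a [SpecificityMatrix-class].
#' @param eventResults named character vector event -> `"detected"` /
#'   `"not_detected"`, or a data.frame with `event`, `result`.
#' @param config a [screeningConfig()]; `label_mode` governs which further
#'   tests are required.
#' @return an [ExplanationReport-class]
#' @export
explainElements <- function(profile, matrix, eventResults = NULL,
                            config = screeningConfig()) {
  config <- .as_config(config)
  profile <- .profile_vector(profile)
  eventResults <- .event_results_vector(eventResults)
  unknown_ev <- setdiff(names(eventResults), eventNames(matrix))
  if (length(unknown_ev))
    stop("event result for event absent from matrix: ", unknown_ev[1L])
  confirmed <- names(eventResults)[eventResults == "detected"]

  targets <- screeningTargets(matrix)
  det_assays <- intersect(names(profile)[profile %in% c("D", "S")], targets)
  st <- x_states <- matrix@states
  notes_sample <- character()
  camv_pos <- "CaMV" %in% det_assays

  rows <- lapply(det_assays, function(as) {
    states <- st[confirmed, as]
    firing <- confirmed[states %in% c("+", "+*")]
    unver <- confirmed[states == "(+)"]
    if (length(firing)) {
      status <- "explained"
      expl <- firing
      note <- if (any(st[firing, as] == "+*"))
        "explained via cross-reacting signal" else ""
    } else if (length(unver)) {
      status <- "explained_unverified"
      expl <- unver
      note <- "explanation rests on unverified expected-positive cell"
    } else if (as %in% matrix@donorCaveatAssays) {
      status <- "donor_caveat"
      expl <- character()
      note <- "may originate from donor organism; confirm GMO origin"
    } else {
      status <- "unexplained"
      expl <- character()
      note <- ""
    }
    if (as == "P-35S" && camv_pos)
      note <- paste0(note, if (nzchar(note)) "; ",
                     "CaMV positive: P-35S signal possibly virus-derived")
    data.frame(assay = as, call = profile[[as]], status = status,
               explaining_events = paste(expl, collapse = ";"),
               notes = note, stringsAsFactors = FALSE)
  })
  el <- if (length(rows)) do.call(rbind, rows)
        else data.frame(assay = character(), call = character(),
                        status = character(),
                        explaining_events = character(),
                        notes = character())
  cand <- candidateEvents(profile, matrix, config)
  untested <- setdiff(candidates(cand)$event, names(eventResults))
  open <- any(el$status %in% c("unexplained", "donor_caveat"))
  unknown_flag <- open && length(untested) == 0L
  required <- if (config$label_mode == "gmo_labelled") {
    if (open) untested else character()
  } else untested
  if (length(required)) {
    ev <- eventCatalogue(matrix)
    required <- required[order(
      .severity_rank(ev$status[match(required, ev$name)]), required)]
  }
  if (unknown_flag)
    notes_sample <- c(notes_sample,
      "detected element(s) unexplained by any confirmed event: indication of an unknown unauthorised GMO")
  new("ExplanationReport", elements = el,
      unknownGmoIndicated = unknown_flag,
      requiredNextTests = required,
      eventResults = eventResults,
      notes = notes_sample)
}

#' Accessors for explanation reports
#' @param x an [ExplanationReport-class]
#' @return `explanationStatus()`: the per-element data.frame;
#'   `unknownGmoIndicated()`: logical flag; `requiredNextTests()`:
#'   character vector of events still to test.
#' @export
explanationStatus <- function(x) {
  stopifnot(is(x, "ExplanationReport")); x@elements
}

#' @rdname explanationStatus
#' @export
unknownGmoIndicated <- function(x) {
  stopifnot(is(x, "ExplanationReport")); x@unknownGmoIndicated
}

#' @rdname explanationStatus
#' @export
requiredNextTests <- function(x) {
  stopifnot(is(x, "ExplanationReport")); x@requiredNextTests
}

#' Events maskable by a set of confirmed events
#'
#' An unconfirmed event with a non-empty detectable element set entirely
#' contained in the union of elements of the confirmed events would change
#' no screening call: its presence cannot be noticed by screening.  Such
#' masked events (e.g. MON810 behind MON89034) are reported so the
#' laboratory can decide to test them regardless.
#'
#' @param x a [SpecificityMatrix-class]
#' @param confirmed character vector of confirmed event names.
#' @return data.frame with `event`, `crop`, `status`, sorted by event name
#' @examples
#' m <- gmoMatrix()
#' maskingCheck(m, "MON89034 maize")$event  # includes "MON810 maize"
#' @export
setMethod("maskingCheck", "SpecificityMatrix", function(x, confirmed) {
  stopifnot(all(confirmed %in% eventNames(x)))
  pool <- expectedElements(x, confirmed)
  ev <- eventCatalogue(x)
  masked <- vapply(ev$name, function(e) {
    if (e %in% confirmed) return(FALSE)
    det <- expectedDetectable(x, e)$detectable
    length(det) > 0L && all(det %in% pool)
  }, logical(1L))
  out <- ev[masked, c("name", "crop", "status")]
  names(out)[1L] <- "event"
  out <- out[order(out$event), ]
  rownames(out) <- NULL
  out
})

#' Decide the per-sample workflow
#'
#' For a GMO-labelled sample the screen is complete once every detected
#' element is explained by a confirmed event; otherwise the untested
#' candidates are listed, and when none remain while elements stay
#' unexplained, the unknown-unauthorised-GMO indication is raised and
#' orthogonal identification (e.g. sequencing) is required.  For a
#' non-GMO-labelled sample every candidate must be tested and every
#' detected event must be quantified against the 0.9% labelling threshold
#' (quantification is outside this package).
#'
#' @param candidateReport a [CandidateReport-class].
#' @param explanationReport an [ExplanationReport-class] for the same
#'   sample.
#' @param config a [screeningConfig()].
#' @return list with `status` (`"complete"`, `"tests_required"` or
#'   `"unknown_gmo_indicated"`), `tests`, `quantify`, `notes`.
#' @export
decideWorkflow <- function(candidateReport, explanationReport,
                           config = screeningConfig()) {
  config <- .as_config(config)
  stopifnot(is(candidateReport, "CandidateReport"),
            is(explanationReport, "ExplanationReport"))
  el <- explanationStatus(explanationReport)
  open <- any(el$status %in% c("unexplained", "donor_caveat"))
  confirmed <- names(explanationReport@eventResults)[
    explanationReport@eventResults == "detected"]
  notes <- character()
  if (length(alwaysTest(candidateReport)))
    notes <- c(notes, paste0(
      "zero-coverage event(s) of crops present require direct event-specific testing: ",
      paste(alwaysTest(candidateReport), collapse = ", ")))
  if (config$label_mode == "gmo_labelled") {
    if (!open) {
      list(status = "complete", tests = character(),
           quantify = character(), notes = notes)
    } else if (length(requiredNextTests(explanationReport))) {
      list(status = "tests_required",
           tests = requiredNextTests(explanationReport),
           quantify = character(), notes = notes)
    } else {
      list(status = "unknown_gmo_indicated", tests = character(),
           quantify = character(),
           notes = c(notes,
             "unknown unauthorised GMO indicated; orthogonal identification (e.g. sequencing) required"))
    }
  } else {
    tests <- requiredNextTests(explanationReport)
    status <- if (explanationReport@unknownGmoIndicated)
      "unknown_gmo_indicated"
    else if (length(tests)) "tests_required" else "complete"
    list(status = status, tests = tests,
         quantify = confirmed,
         notes = c(notes, if (length(confirmed))
           "quantify detected event(s) against the 0.9% labelling threshold (event-specific quantification, external)"))
  }
}

#' Interpret one sample end to end
#'
#' Composes [cropsPresent()], [candidateEvents()], [explainElements()] and
#' [decideWorkflow()] into a [ScreenInterpretation-class].
#'
#' @param calls calls data.frame ([callSampleProfile()]) or named call
#'   vector for one sample.
#' @param matrix a [SpecificityMatrix-class].
#' @param sample_id sample number (required when `calls` covers several
#'   samples).
#' @param eventResults optional event-test results (see
#'   [explainElements()]).
#' @param config a [screeningConfig()].
#' @return a [ScreenInterpretation-class]
#' @export
interpretSample <- function(calls, matrix, sample_id = NA_integer_,
                            eventResults = NULL,
                            config = screeningConfig()) {
  config <- .as_config(config)
  if (is.data.frame(calls) && "sample_id" %in% names(calls)) {
    if (is.na(sample_id)) {
      ids <- unique(calls$sample_id)
      if (length(ids) != 1L)
        stop("calls cover several samples; give sample_id")
      sample_id <- ids
    }
    cdf <- calls[calls$sample_id == sample_id, ]
  } else {
    prof <- .profile_vector(calls)
    cdf <- data.frame(sample_id = sample_id, assay = names(prof),
                      call = unname(prof), cq1 = NA_real_, cq2 = NA_real_,
                      notes = "", stringsAsFactors = FALSE)
  }
  if (!config$allow_invalid_controls &&
      any(grepl("invalid-run", cdf$notes)))
    stop("assay(s) with failed run controls present; rerun or set allow_invalid_controls = TRUE")
  profile <- stats::setNames(cdf$call, cdf$assay)
  cand <- candidateEvents(profile, matrix, config)
  expl <- explainElements(profile, matrix, eventResults, config)
  wf <- decideWorkflow(cand, expl, config)
  new("ScreenInterpretation", sampleId = as.integer(sample_id),
      labelMode = config$label_mode, calls = cdf, candidates = cand,
      explanation = expl, workflow = wf)
}
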