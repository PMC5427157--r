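## The specificity matrix: load/serialize, queries, validation.

#' Load a specificity matrix from delimited text
#'
#' The file is UTF-8 tab-separated: header row names the screening targets,
#' first three columns are `event`, `crop` and authorisation `status`, and
#' every remaining cell holds one of the six specificity symbols `+`, `-`,
#' `X`, `+*`, `(+)` or the empty string.
#'
#' @param path path to the matrix file.
#' @param assays assay catalogue data.frame (see [gmoAssays()]); used to
#'   cross-check that matrix columns are known non-endogenous assays.  May
#'   be a zero-row data.frame for free-standing matrices.
#' @param donorCaveatAssays screening targets carrying the donor-organism
#'   annotation; defaults to the shipped set (intersected with the file's
#'   columns).
#' @return a validated [SpecificityMatrix-class]
#' @seealso [writeMatrix()], [validateMatrix()]
#' @export
loadMatrix <- function(path, assays = gmoAssays(),
                       donorCaveatAssays = .DONOR_CAVEAT_ASSAYS) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tab <- .read_tsv(path, colClasses = "character")
  if (ncol(tab) < 4L || !identical(names(tab)[1:3],
                                   c("event", "crop", "status")))
    stop("matrix file must start with columns event, crop, status")
  ev <- tab[, 1:3]
  names(ev) <- c("name", "crop", "status")
  if (anyDuplicated(ev$name))
    stop("duplicate event name in matrix file: ",
         ev$name[duplicated(ev$name)][1L])
  st <- as.matrix(tab[, -(1:3), drop = FALSE])
  rownames(st) <- ev$name
  if (anyDuplicated(colnames(st)))
    stop("duplicate assay column in matrix file: ",
         colnames(st)[duplicated(colnames(st))][1L])
  bad <- !(st %in% .SPEC_STATES)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(st)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid specificity symbol %s at event '%s', assay '%s'",
                 dQuote(st[idx[1L], idx[2L]]), rownames(st)[idx[1L]],
                 colnames(st)[idx[2L]]))
  }
  new("SpecificityMatrix", states = st, events = ev, assays = assays,
      donorCaveatAssays = intersect(donorCaveatAssays, colnames(st)))
}

#' @describeIn writeMatrix write the matrix back to tab-separated text; a
#'   written file reloads to an identical object.
#' @export
setMethod("writeMatrix", "SpecificityMatrix", function(x, path) {
  header <- paste(c("event", "crop", "status", colnames(x@states)),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(x@states)), function(i)
    paste(c(x@events$name[i], x@events$crop[i], x@events$status[i],
            x@states[i, ]), collapse = "\t"), character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
})

#' Serialize a specificity matrix
#' @param x a [SpecificityMatrix-class]
#' @param path output file
#' @return the path, invisibly
#' @name writeMatrix
NULL

setMethod("eventNames", "SpecificityMatrix", function(x) x@events$name)
setMethod("screeningTargets", "SpecificityMatrix",
          function(x) colnames(x@states))
setMethod("assayCatalogue", "SpecificityMatrix", function(x) x@assays)
setMethod("eventCatalogue", "SpecificityMatrix", function(x) x@events)

.event_states <- function(x, event) {
  if (!event %in% rownames(x@states))
    stop("unknown event: ", event)
  x@states[event, ]
}

#' Screening targets expected to fire on an event
#'
#' An assay is counted as detectable for an event when its matrix state is
#' `+` (verified positive) or `+*` (fires through sequence similarity).
#' `(+)` cells (expected positive, never verified) are reported separately
#' and are non-binding for inference; `X` cells (element present but missed
#' by the assay) are annotations only.
#'
#' @param x a [SpecificityMatrix-class]
#' @param event event name
#' @return list with character vectors `detectable`, `unverified`
#'   (the `(+)` cells), `cross_react` (the `+*` subset of `detectable`) and
#'   `divergent` (the `X` cells)
#' @examples
#' m <- gmoMatrix()
#' expectedDetectable(m, "MON810 maize")$detectable
#' @export
setMethod("expectedDetectable", "SpecificityMatrix", function(x, event) {
  st <- .event_states(x, event)
  list(detectable = names(st)[st %in% c("+", "+*")],
       unverified = names(st)[st == "(+)"],
       cross_react = names(st)[st == "+*"],
       divergent = names(st)[st == "X"])
})

#' Union of detectable targets over a set of events
#'
#' @param x a [SpecificityMatrix-class]
#' @param events character vector of event names (may be empty)
#' @return character vector in matrix column order
#' @examples
#' m <- gmoMatrix()
#' expectedElements(m, c("MON89034 maize", "MON810 maize"))
#' @export
setMethod("expectedElements", "SpecificityMatrix", function(x, events) {
  if (length(events) == 0L) return(character())
  hit <- Reduce(`|`, lapply(events, function(e)
    .event_states(x, e) %in% c("+", "+*")))
  colnames(x@states)[hit]
})

#' Events invisible to the screening set
#'
#' Events none of whose elements is detectable by any screening assay; these
#' must always be tested directly with their event-specific method.
#'
#' @param x a [SpecificityMatrix-class]
#' @return character vector of event names, sorted
#' @export
setMethod("zeroCoverageEvents", "SpecificityMatrix", function(x) {
  zero <- rowSums(matrix(x@states %in% c("+", "+*"), nrow(x@states))) == 0L
  sort(rownames(x@states)[zero])
})

#' Validate a specificity matrix
#'
#' Collects invariant violations and advisory warnings without throwing.
#' Warnings include every event with at most one detectable screening
#' element (little redundancy if that element diverges in a new variety).
#'
#' @param x a [SpecificityMatrix-class]
#' @return data.frame with columns `severity` (`"violation"` or
#'   `"warning"`), `item`, `message`; zero rows with no warnings on a fully
#'   valid, well-covered matrix.
#' @export
setMethod("validateMatrix", "SpecificityMatrix", function(x) {
  rep <- data.frame(severity = character(), item = character(),
                    message = character(), stringsAsFactors = FALSE)
  v <- validObject(x, test = TRUE)
  if (is.character(v))
    rep <- rbind(rep, data.frame(severity = "violation", item = "class",
                                 message = v))
  ndet <- rowSums(matrix(x@states %in% c("+", "+*"), nrow(x@states)))
  thin <- rownames(x@states)[ndet <= 1L]
  if (length(thin))
    rep <- rbind(rep, data.frame(
      severity = "warning", item = thin,
      message = sprintf("event '%s' has %d detectable screening element(s); event-specific testing recommended",
                        thin, ndet[match(thin, rownames(x@states))])))
  rep
})

#' Transcription anchors for the bundled matrix
#'
#' The published table is easy to mis-transcribe, so the shipped file is
#' checked against statements made in the accompanying prose: the number of
#' zero-coverage events, the MON89034/MON810 element sets and their masking
#' relation, and individually discussed cells.  Returns violations as a
#' report (empty when all anchors hold); intended for the bundled matrix,
#' not for user-supplied matrices.
#'
#' @param x a [SpecificityMatrix-class]
#' @return data.frame with columns `anchor`, `message` (zero rows = pass)
#' @export
checkMatrixAnchors <- function(x) {
  stopifnot(is(x, "SpecificityMatrix"))
  fail <- list()
  add <- function(anchor, message)
    fail[[length(fail) + 1L]] <<- data.frame(anchor = anchor,
                                             message = message)
  if (length(screeningTargets(x)) != 25L)
    add("columns", sprintf("expected 25 screening-target columns, found %d",
                           length(screeningTargets(x))))
  zc <- zeroCoverageEvents(x)
  if (length(zc) != 7L)
    add("zero_coverage", sprintf("expected exactly 7 zero-coverage events, found %d",
                                 length(zc)))
  seven <- c("P-35S", "P-FMV", "T-nos", "Cry1A(b)", "Cry1A.105", "Cry2Ab2",
             "I-rAct1")
  both <- c("MON89034 maize", "MON810 maize")
  if (all(both %in% eventNames(x))) {
    if (!setequal(expectedElements(x, both), seven))
      add("mon89034_mon810_union",
          "MON89034+MON810 union differs from the documented 7-element set")
    d34 <- expectedDetectable(x, "MON89034 maize")$detectable
    d10 <- expectedDetectable(x, "MON810 maize")$detectable
    if (!all(seven %in% d34))
      add("mon89034_set", "MON89034 must cover all seven listed elements")
    if (!all(d10 %in% d34))
      add("masking_premise",
          "MON810 detectable set must be a subset of MON89034's")
  } else add("events", "MON89034/MON810 rows missing")
  cell <- function(ev, as) if (ev %in% rownames(x@states) &&
                               as %in% colnames(x@states))
    x@states[ev, as] else NA_character_
  if (!identical(cell("Bt11 maize", "T-35S"), "+*"))
    add("bt11_t35s", "Bt11 maize / T-35S must be '+*'")
  if (!identical(cell("MON87460 maize", "P-Rice actin"), "X"))
    add("mon87460_ract", "MON87460 maize / P-Rice actin must be 'X'")
  if ("MON87460 maize" %in% eventNames(x) &&
      length(expectedDetectable(x, "MON87460 maize")$detectable) != 4L)
    add("mon87460_coverage",
        "MON87460 maize must retain four detectable screening elements")
  if (!identical(cell("DP356043 soy", "P-35S"), "X"))
    add("dp356043_p35s", "DP356043 soy / P-35S must be 'X'")
  if (!identical(cell("DP98140 maize", "P-35S"), "-"))
    add("dp98140_p35s", "DP98140 maize / P-35S must be '-'")
  if (!identical(cell("T45 canola", "T-35S"), "+"))
    add("t45_t35s", "T45 canola / T-35S must be '+'")
  if (!identical(cell("DAS59122 maize", "T-35S"), "+"))
    add("das59122_t35s", "DAS59122 maize / T-35S must be '+'")
  if (length(fail)) do.call(rbind, fail)
  else data.frame(anchor = character(), message = character())
}

#' Validate all bundled data files
#'
#' Loads every shipped data file, revalidates the matrix invariants, the
#' transcription anchors, the plate distribution and the positive-control
#' assignments, and reports problems without throwing.
#'
#' @param matrix optionally, a [SpecificityMatrix-class] to validate in
#'   place of the shipped one (the plate/control tables are always the
#'   bundled ones).
#' @return data.frame with columns `severity`, `item`, `message`; the
#'   bundled data yields no `"violation"` rows.
#' @export
validateBundledData <- function(matrix = NULL) {
  rep <- data.frame(severity = character(), item = character(),
                    message = character(), stringsAsFactors = FALSE)
  add <- function(severity, item, message)
    rep <<- rbind(rep, data.frame(severity = severity, item = item,
                                  message = message))
  m <- tryCatch(if (is.null(matrix)) gmoMatrix(checkAnchors = FALSE)
                else matrix,
                error = function(e) {
                  add("violation", "matrix", conditionMessage(e))
                  NULL
                })
  if (!is.null(m)) {
    vm <- validateMatrix(m)
    if (nrow(vm)) rep <- rbind(rep, vm)
    an <- checkMatrixAnchors(m)
    if (nrow(an))
      rep <- rbind(rep, data.frame(severity = "violation",
                                   item = an$anchor, message = an$message))
  }
  assays <- tryCatch(gmoAssays(), error = function(e) {
    add("violation", "assays", conditionMessage(e)); NULL
  })
  pm <- gmoPlateMethods()
  if (!is.null(assays)) {
    if (nrow(assays) != 32L)
      add("violation", "assays", "assay catalogue must have 32 methods")
    if (!setequal(pm$assay, assays$name))
      add("violation", "plate_methods",
          "plate distribution does not cover the 32 assays exactly")
  }
  if (any(table(pm$plate) != 4L))
    add("violation", "plate_methods", "every plate must carry 4 methods")
  pc <- gmoPositiveControls()
  if (!is.null(assays) && !setequal(pc$assay, assays$name))
    add("violation", "positive_controls",
        "positive-control table must assign a material to every assay")
  gs <- gmoGenomeSizes()
  if (!is.null(m) && !all(unique(eventCatalogue(m)$crop) %in% names(gs)))
    add("violation", "genome_sizes", "crop missing a 1C genome size")
  rep
}
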