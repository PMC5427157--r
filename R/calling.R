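## Cq ingestion, run-control validation and duplicate-well D/ND/S calling.

#' Screening run configuration
#'
#' The published module does not fix numeric D/ND/S rules; these defaults
#' are explicit choices of this implementation.  `detect_cq_max` equals the
#' cycle count of the PCR programme (45 cycles): any amplification within
#' the run counts as signal.  `suspect_cq_min = 34` reflects the observed
#' onset of trace-contamination signals (Cq 34-40 in reference-material
#' runs): duplicates that both sit in the late window `(34, 45]` are called
#' suspect rather than detected.
#'
#' @param detect_cq_max Cq at or below which a well counts as amplified.
#' @param suspect_cq_min start of the late-Cq (suspect) window.
#' @param max_cycles cycle count of the run; numeric Cq values must lie in
#'   `(0, max_cycles]`.
#' @param no_amp_tokens tokens in Cq tables meaning "no amplification".
#' @param candidate_mode `"strict"` (an event is a candidate only when all
#'   its detectable elements were called) or `"lenient"` (at least one).
#' @param label_mode `"gmo_labelled"` or `"non_gmo_labelled"`.
#' @param allow_invalid_controls proceed to inference although an assay's
#'   run controls failed (calls keep their `invalid-run` note).
#' @return a list of class `screening_config`
#' @export
screeningConfig <- function(detect_cq_max = 45, suspect_cq_min = 34,
                            max_cycles = 45,
                            no_amp_tokens = c("", "N/A", "NA", "Undetermined",
                                              "NO_AMP"),
                            candidate_mode = c("strict", "lenient"),
                            label_mode = c("gmo_labelled",
                                           "non_gmo_labelled"),
                            allow_invalid_controls = FALSE) {
  stopifnot(detect_cq_max > 0, suspect_cq_min > 0,
            suspect_cq_min <= detect_cq_max)
  structure(list(detect_cq_max = detect_cq_max,
                 suspect_cq_min = suspect_cq_min,
                 max_cycles = max_cycles,
                 no_amp_tokens = no_amp_tokens,
                 candidate_mode = match.arg(candidate_mode),
                 label_mode = match.arg(label_mode),
                 allow_invalid_controls = allow_invalid_controls),
            class = "screening_config")
}

.as_config <- function(config) {
  if (is.null(config)) screeningConfig()
  else { stopifnot(inherits(config, "screening_config")); config }
}

#' Parse a per-well Cq table against a plate layout
#'
#' Reads a long-format delimited file with header columns `plate`, `well`
#' and `cq` (tab- or comma-separated, auto-detected) and joins every row to
#' its well assignment.  Cq cells must be numeric within `(0, max_cycles]`
#' or one of the configured no-amplification tokens.
#'
#' @param path Cq table file.
#' @param layout the [PlateLayout-class] the run was pipetted from.
#' @param config a [screeningConfig()].
#' @return data.frame: one row per well present in the file, with `plate`,
#'   `well`, `cq` (numeric, `NA` = no amplification) and the joined
#'   assignment columns (`assay`, `role`, `sample_id`, `isolation`).
#' @export
parseCqTable <- function(path, layout, config = screeningConfig()) {
  config <- .as_config(config)
  if (!file.exists(path)) stop("Cq table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = character(),
                           colClasses = "character")
  need <- c("plate", "well", "cq")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Cq table missing column(s): ", paste(miss, collapse = ", "))
  tab$plate <- as.integer(tab$plate)
  dup <- duplicated(tab[c("plate", "well")])
  if (any(dup))
    stop(sprintf("duplicate Cq row for plate %d well %s",
                 tab$plate[dup][1L], tab$well[dup][1L]))
  token <- trimws(tab$cq)
  cq <- rep(NA_real_, nrow(tab))
  numeric_mask <- !(token %in% config$no_amp_tokens)
  cq[numeric_mask] <- suppressWarnings(as.numeric(token[numeric_mask]))
  bad <- numeric_mask & is.na(cq)
  if (any(bad))
    stop(sprintf("non-numeric Cq token '%s' at plate %d well %s",
                 token[bad][1L], tab$plate[bad][1L], tab$well[bad][1L]))
  out_of_range <- !is.na(cq) & (cq <= 0 | cq > config$max_cycles)
  if (any(out_of_range))
    stop(sprintf("Cq %.2f out of (0, %g] at plate %d well %s",
                 cq[out_of_range][1L], config$max_cycles,
                 tab$plate[out_of_range][1L], tab$well[out_of_range][1L]))
  a <- layoutAssignments(layout)
  key <- paste(tab$plate, tab$well)
  idx <- match(key, paste(a$plate, a$well))
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1L]
    stop(sprintf("well %s on plate %d is not part of the layout",
                 tab$well[k], tab$plate[k]))
  }
  cbind(data.frame(plate = tab$plate, well = tab$well, cq = cq,
                   stringsAsFactors = FALSE),
        a[idx, c("assay", "role", "sample_id", "isolation",
                 "control_material")])
}

#' Validate run controls
#'
#' Per assay the positive sensitivity control must amplify within the
#' detection window and the no-template control must stay negative.  An
#' assay failing either is marked invalid; its sample calls are annotated
#' (never silently dropped).
#'
#' @param results parsed well results from [parseCqTable()].
#' @param config a [screeningConfig()].
#' @return data.frame: `assay`, `positive_control_ok`, `ntc_ok`,
#'   `positive_control_cq`, `ntc_cq`, `valid`, `note`.
#' @export
validateControls <- function(results, config = screeningConfig()) {
  config <- .as_config(config)
  assays <- unique(results$assay)
  out <- lapply(assays, function(as) {
    r <- results[results$assay == as, ]
    pcq <- r$cq[r$role == "positive_control"]
    ncq <- r$cq[r$role == "no_template_control"]
    if (length(pcq) == 0L || length(ncq) == 0L)
      stop("missing control well for assay ", as)
    pos_ok <- !is.na(pcq[1L]) && pcq[1L] <= config$detect_cq_max
    ntc_ok <- is.na(ncq[1L]) || ncq[1L] > config$detect_cq_max
    note <- character()
    if (!pos_ok) note <- c(note, "sensitivity control failed")
    if (!ntc_ok) note <- c(note, sprintf(
      "no-template control amplified (Cq %.1f): contamination suspected",
      ncq[1L]))
    data.frame(assay = as, positive_control_ok = pos_ok, ntc_ok = ntc_ok,
               positive_control_cq = pcq[1L], ntc_cq = ncq[1L],
               valid = pos_ok && ntc_ok,
               note = paste(note, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.call_one <- function(cq1, cq2, config) {
  amp1 <- !is.na(cq1) && cq1 <= config$detect_cq_max
  amp2 <- !is.na(cq2) && cq2 <= config$detect_cq_max
  late <- function(cq) cq > config$suspect_cq_min
  if (amp1 && amp2) {
    if (late(cq1) && late(cq2))
      list(call = "S", notes = "late-Cq")
    else list(call = "D", notes = "")
  } else if (!amp1 && !amp2) {
    list(call = "ND", notes = "")
  } else {
    notes <- "discordant replicates"
    if ((amp1 && late(cq1)) || (amp2 && late(cq2)))
      notes <- paste(notes, "late-Cq", sep = "; ")
    list(call = "S", notes = notes)
  }
}

#' Call a duplicate pair of Cq values
#'
#' Both replicates amplified within the detection window gives `D`; neither
#' gives `ND`; a discordant pair gives `S`, and a pair that amplified only
#' in the late window `(suspect_cq_min, detect_cq_max]` gives `S` with a
#' late-Cq note (trace-level signal).  Symmetric in its two arguments.
#'
#' @param cq1,cq2 numeric Cq values; `NA` = no amplification.
#' @param config a [screeningConfig()].
#' @return list with `call` (`"D"`, `"ND"` or `"S"`) and `notes`.
#' @examples
#' callDuplicates(25.1, 25.3)$call   # "D"
#' callDuplicates(32.0, NA)$call     # "S"
#' @export
callDuplicates <- function(cq1, cq2, config = screeningConfig()) {
  .call_one(cq1, cq2, .as_config(config))
}

.call_single <- function(cq, config) {
  amp <- !is.na(cq) && cq <= config$detect_cq_max
  if (!amp) list(call = "ND", notes = "single replicate")
  else if (cq > config$suspect_cq_min)
    list(call = "S", notes = "single replicate; late-Cq")
  else list(call = "D", notes = "single replicate")
}

#' Collapse well results into per-sample assay calls
#'
#' Pairs the two isolations of every sample for every assay and calls them
#' with [callDuplicates()].  A sample missing one replicate well is called
#' from the remaining one and flagged; assays whose run controls failed
#' contribute calls annotated `invalid-run`.
#'
#' @param results parsed well results from [parseCqTable()].
#' @param config a [screeningConfig()].
#' @param controls optional control outcomes from [validateControls()]
#'   (computed from `results` when omitted and control wells are present).
#' @return data.frame: `sample_id`, `assay`, `call`, `cq1`, `cq2`, `notes`;
#'   one row per (sample, assay) pair present in the run.
#' @export
callSampleProfile <- function(results, config = screeningConfig(),
                              controls = NULL) {
  config <- .as_config(config)
  if (is.null(controls) &&
      any(results$role %in% c("positive_control", "no_template_control")))
    controls <- validateControls(results, config)
  invalid <- if (is.null(controls)) character()
             else controls$assay[!controls$valid]
  smp <- results[results$role == "sample", ]
  if (!nrow(smp)) stop("no sample wells in results")
  grp <- split(smp, list(smp$sample_id, smp$assay), drop = TRUE)
  out <- lapply(grp, function(g) {
    cq1 <- g$cq[g$isolation == 1L]
    cq2 <- g$cq[g$isolation == 2L]
    if (nrow(g) > 2L)
      stop("more than two replicate wells for sample ", g$sample_id[1L],
           " assay ", g$assay[1L])
    res <- if (length(cq1) == 1L && length(cq2) == 1L)
      .call_one(cq1, cq2, config)
    else .call_single(c(cq1, cq2)[1L], config)
    notes <- res$notes
    if (g$assay[1L] %in% invalid)
      notes <- paste0(notes, if (nzchar(notes)) "; ", "invalid-run")
    data.frame(sample_id = g$sample_id[1L], assay = g$assay[1L],
               call = res$call,
               cq1 = if (length(cq1)) cq1 else NA_real_,
               cq2 = if (length(cq2)) cq2 else NA_real_,
               notes = notes, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$sample_id, calls$assay), ]
  rownames(calls) <- NULL
  calls
}

#' Extract one sample's call profile as a named vector
#'
#' @param calls output of [callSampleProfile()].
#' @param sample_id sample number.
#' @return named character vector assay -> call
#' @export
sampleProfile <- function(calls, sample_id) {
  c1 <- calls[calls$sample_id == sample_id, ]
  if (!nrow(c1)) stop("no calls for sample ", sample_id)
  stats::setNames(c1$call, c1$assay)
}
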