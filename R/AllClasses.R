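#' @import methods
NULL

## Symbols a specificity-matrix cell may hold.  "+" and "+*" fire the assay;
## "X" marks an element present but missed through sequence divergence; "(+)"
## and "" are expectations never verified against reference material.
.SPEC_STATES <- c("+", "-", "X", "+*", "(+)", "")

.CROPS <- c("soy", "maize", "canola", "potato", "cotton", "rice", "sugar beet")

.AUTH_STATUSES <- c("authorised", "low_level_619_2011", "expired",
                    "unauthorised", "unknown")

## Ranking used to order candidate/required-test listings: the severest legal
## consequence first.  "unknown" sits directly after "unauthorised" because an
## event of unknown status must be treated conservatively.
.AUTH_SEVERITY <- c(unauthorised = 1L, unknown = 2L, expired = 3L,
                    low_level_619_2011 = 4L, authorised = 5L)

## Elements that also occur in naturally present donor organisms (nptII in
## E. coli, T-g7 from A. tumefaciens, T-E9 from pea, the rice actin promoter
## and intron from rice, and the cauliflower mosaic virus itself), so a
## positive signal is not necessarily GMO-derived.
.DONOR_CAVEAT_ASSAYS <- c("nptII", "T-g7", "T-E9", "P-Rice actin",
                          "I-rAct1", "CaMV")

.WELL_ROLES <- c("sample", "positive_control", "no_template_control", "empty")

.CALLS <- c("D", "ND", "S")

#' Specificity matrix of screening assays against GMO events
#'
#' Holds the assay-by-event specificity grid together with the event
#' catalogue (crop, authorisation status) and the full assay catalogue
#' (including the endogenous taxon assays, which are not matrix columns).
#'
#' @slot states character matrix; rows are events, columns are the screening
#'   targets (elements, constructs, CaMV); each cell one of `"+"`, `"-"`,
#'   `"X"`, `"+*"`, `"(+)"` or `""`.
#' @slot events data.frame with columns `name`, `crop`, `status`.
#' @slot assays data.frame assay catalogue (columns `name`, `category`,
#'   `crop_scope`, primers/probe and concentrations).
#' @slot donorCaveatAssays character; screening targets whose positive
#'   signal may originate from a donor organism rather than a GMO.
#'
#' @export
setClass("SpecificityMatrix",
         representation(states = "matrix",
                        events = "data.frame",
                        assays = "data.frame",
                        donorCaveatAssays = "character"))

setValidity("SpecificityMatrix", function(object) {
  msg <- character()
  st <- object@states
  if (!is.character(st))
    msg <- c(msg, "states must be a character matrix")
  bad <- !(st %in% .SPEC_STATES)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("invalid state symbol %s at event '%s', assay '%s'",
                          dQuote(st[bad][1L]), rownames(st)[idx[1L]],
                          colnames(st)[idx[2L]]))
  }
  ev <- object@events
  if (!identical(rownames(st), ev$name))
    msg <- c(msg, "event rows and event catalogue out of step")
  if (anyDuplicated(ev$name))
    msg <- c(msg, sprintf("duplicate event name: %s",
                          ev$name[duplicated(ev$name)][1L]))
  if (anyDuplicated(colnames(st)))
    msg <- c(msg, "duplicate assay column")
  if (!all(ev$crop %in% .CROPS))
    msg <- c(msg, sprintf("unknown crop: %s",
                          setdiff(ev$crop, .CROPS)[1L]))
  if (!all(ev$status %in% .AUTH_STATUSES))
    msg <- c(msg, sprintf("unknown authorisation status: %s",
                          setdiff(ev$status, .AUTH_STATUSES)[1L]))
  as <- object@assays
  if (nrow(as)) {
    if (anyDuplicated(as$name))
      msg <- c(msg, "duplicate assay name in catalogue")
    if (!all(colnames(st) %in% as$name))
      msg <- c(msg, "matrix column missing from assay catalogue")
    if (any(colnames(st) %in% as$name[as$category == "endogenous"]))
      msg <- c(msg, "endogenous assay used as a matrix column")
    ## crops lacking a dedicated taxon assay must at least be covered by the
    ## all-plants actin assay (cotton and potato in the shipped design)
    scoped <- as$crop_scope[as$category == "endogenous"]
    if (length(scoped) && !any(scoped == "all plants") &&
        !all(unique(ev$crop) %in% scoped))
      msg <- c(msg, "crop without taxon assay and no all-plants assay present")
  }
  if (length(object@donorCaveatAssays) &&
      !all(object@donorCaveatAssays %in% c(colnames(st))))
    msg <- c(msg, "donor-caveat assay not a matrix column")
  if (length(msg)) msg else TRUE
})

#' Plate layout for the eight-plate screening design
#'
#' @slot assignments data.frame with one row per used well: `plate`, `well`,
#'   `assay`, `role`, `sample_id`, `isolation`, `control_material`.
#' @slot methodsPerPlate named list mapping plate index to its four assays
#'   in mix order.
#' @slot nSamples integer; number of samples placed (at most 11).
#'
#' @export
setClass("PlateLayout",
         representation(assignments = "data.frame",
                        methodsPerPlate = "list",
                        nSamples = "integer"))

setValidity("PlateLayout", function(object) {
  a <- object@assignments
  msg <- character()
  need <- c("plate", "well", "assay", "role", "sample_id", "isolation",
            "control_material")
  if (!all(need %in% names(a)))
    return(sprintf("assignments must have columns: %s",
                   paste(need, collapse = ", ")))
  if (!all(a$role %in% .WELL_ROLES))
    msg <- c(msg, "unknown well role")
  if (anyDuplicated(a[c("plate", "well")]))
    msg <- c(msg, "duplicated well coordinate within a plate")
  for (p in unique(a$plate)) {
    ap <- a[a$plate == p, ]
    if (length(unique(ap$assay)) != 4L)
      msg <- c(msg, sprintf("plate %d does not carry exactly 4 assays", p))
    cnt <- table(ap$assay)
    if (any(cnt != 24L))
      msg <- c(msg, sprintf("plate %d has an assay block != 24 wells", p))
  }
  by_assay <- split(a, a$assay)
  for (blk in by_assay) {
    if (sum(blk$role == "positive_control") != 1L ||
        sum(blk$role == "no_template_control") != 1L)
      msg <- c(msg, sprintf("assay '%s' must have exactly one positive and one no-template control",
                            blk$assay[1L]))
    if (sum(blk$role %in% c("sample", "empty")) != 22L)
      msg <- c(msg, sprintf("assay '%s' must have 22 sample wells", blk$assay[1L]))
    if (any(blk$role == "positive_control" & is.na(blk$control_material)))
      msg <- c(msg, sprintf("assay '%s' positive control lacks a material",
                            blk$assay[1L]))
  }
  smp <- a$role == "sample"
  if (any(smp & (is.na(a$sample_id) | is.na(a$isolation))))
    msg <- c(msg, "sample well without sample_id/isolation")
  if (any(!smp & !is.na(a$sample_id)))
    msg <- c(msg, "non-sample well carries a sample_id")
  if (length(msg)) msg else TRUE
})

#' Cq response model for the simulator
#'
#' Single-hit amplification model: a well holding `k` template copies
#' amplifies at `Cq = intercept - slope * log10(k)` plus Gaussian replicate
#' noise; a well holding zero copies never amplifies.
#'
#' @slot intercept numeric, Cq at one template copy.
#' @slot slope numeric, Cq decrease per tenfold template increase
#'   (3.32 at perfect doubling efficiency).
#' @slot sigma numeric, replicate noise SD in cycles.
#'
#' @export
setClass("CqModel",
         representation(intercept = "numeric", slope = "numeric",
                        sigma = "numeric"))

setValidity("CqModel", function(object) {
  if (object@slope <= 0) return("slope must be > 0")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' Candidate report for one sample
#'
#' @slot cropsPresent character, crops whose taxon assay was detected.
#' @slot ungatedCrops character, crops without a taxon assay (always
#'   considered possible).
#' @slot plantMaterial logical, plant actin detected.
#' @slot dnaQualityWarning logical, no endogenous signal at all.
#' @slot candidates data.frame (`event`, `crop`, `status`, `basis`,
#'   `n_support`, `notes`), ordered by authorisation severity.
#' @slot alwaysTest character, zero-coverage events of present/ungated crops
#'   that must go straight to event-specific testing.
#' @slot excluded data.frame (`event`, `reason`).
#'
#' @export
setClass("CandidateReport",
         representation(cropsPresent = "character",
                        ungatedCrops = "character",
                        plantMaterial = "logical",
                        dnaQualityWarning = "logical",
                        candidates = "data.frame",
                        alwaysTest = "character",
                        excluded = "data.frame"))

#' Element explanation report for one sample
#'
#' @slot elements data.frame, one row per detected screening target:
#'   `assay`, `call`, `status` (explained / explained_unverified /
#'   unexplained / donor_caveat), `explaining_events`, `notes`.
#' @slot unknownGmoIndicated logical; some detected element remains
#'   unexplained after all candidates carry an event-test result.
#' @slot requiredNextTests character, untested candidate events still needed.
#' @slot eventResults named character vector of entered event results.
#' @slot notes character, sample-level annotations.
#'
#' @export
setClass("ExplanationReport",
         representation(elements = "data.frame",
                        unknownGmoIndicated = "logical",
                        requiredNextTests = "character",
                        eventResults = "character",
                        notes = "character"))

#' Full interpretation of one screened sample
#'
#' @slot sampleId integer sample number.
#' @slot labelMode `"gmo_labelled"` or `"non_gmo_labelled"`.
#' @slot calls data.frame of per-assay calls (`assay`, `call`, `cq1`,
#'   `cq2`, `notes`).
#' @slot candidates [CandidateReport-class].
#' @slot explanation [ExplanationReport-class].
#' @slot workflow list with `status`, `tests`, `quantify`, `notes`.
#'
#' @export
setClass("ScreenInterpretation",
         representation(sampleId = "integer",
                        labelMode = "character",
                        calls = "data.frame",
                        candidates = "CandidateReport",
                        explanation = "ExplanationReport",
                        workflow = "list"))
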