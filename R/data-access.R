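## Loaders for the machine-readable screening data shipped under extdata/.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "GMOscreen")
  if (!nzchar(path))
    stop("bundled data file not found: ", file)
  path
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = character(), ...)
}

#' Bundled assay catalogue
#'
#' The 32 TaqMan screening methods: seven endogenous taxon assays, the
#' element and construct assays and the CaMV virus assay, with primer and
#' probe sequences (IUPAC alphabet) and final concentrations in nM.
#'
#' @return data.frame with columns `name`, `category`, `crop_scope`, `fwd`,
#'   `rev`, `probe`, `primer_nM`, `probe_nM`, `reference`.
#' @examples
#' nrow(gmoAssays())  # 32
#' @export
gmoAssays <- function() {
  a <- .read_tsv(.extdata("assays.tsv"))
  a$crop_scope[a$crop_scope == ""] <- NA_character_
  a$primer_nM <- as.numeric(a$primer_nM)
  a$probe_nM <- as.numeric(a$probe_nM)
  .check_assays(a)
  a
}

.IUPAC <- strsplit("ACGTRYSWKMBDHVN", "")[[1L]]

.check_assays <- function(a) {
  if (anyDuplicated(a$name))
    stop("duplicate assay name: ", a$name[duplicated(a$name)][1L])
  if (!all(a$category %in% c("endogenous", "element", "construct", "virus")))
    stop("unknown assay category")
  for (col in c("fwd", "rev", "probe")) {
    seqs <- a[[col]]
    if (any(!nzchar(seqs)))
      stop("empty ", col, " sequence for assay ",
           a$name[!nzchar(seqs)][1L])
    ok <- vapply(strsplit(seqs, ""), function(s) all(s %in% .IUPAC),
                 logical(1L))
    if (!all(ok))
      stop("non-IUPAC character in ", col, " of assay ", a$name[!ok][1L])
  }
  if (any(a$primer_nM <= 0) || any(a$probe_nM <= 0))
    stop("non-positive primer/probe concentration")
  if (sum(a$category == "endogenous") != 7L)
    stop("assay catalogue must contain exactly 7 endogenous assays")
  if (sum(a$category == "virus") != 1L)
    stop("assay catalogue must contain exactly 1 virus assay")
  invisible(a)
}

#' Bundled plate-to-method distribution
#'
#' @return data.frame with columns `plate`, `mix`, `assay`: the 32 methods
#'   spread over eight 96-well plates, four mixes per plate.
#' @export
gmoPlateMethods <- function() {
  m <- .read_tsv(.extdata("plate_methods.tsv"))
  m$plate <- as.integer(m$plate)
  m$mix <- as.integer(m$mix)
  m
}

#' Bundled positive sensitivity control assignments
#'
#' One control material per assay, run at 0.1% GMO (50 ng per reaction) or
#' 25 haploid genome equivalent copies.
#'
#' @return data.frame with columns `assay`, `control_material`,
#'   `material_crop` (NA for the CaMV positive sample).
#' @export
gmoPositiveControls <- function() {
  pc <- .read_tsv(.extdata("positive_controls.tsv"))
  pc$material_crop[pc$material_crop == ""] <- NA_character_
  pc
}

#' Bundled haploid (1C) genome sizes
#'
#' @return named numeric vector of 1C genome masses in picograms per crop.
#' @examples
#' gmoGenomeSizes()[["maize"]]  # 2.725 pg
#' @export
gmoGenomeSizes <- function() {
  g <- .read_tsv(.extdata("genome_sizes_1C.tsv"))
  stats::setNames(as.numeric(g$pg_1C), g$crop)
}

#' Bundled specificity matrix
#'
#' Loads the shipped assay-by-event specificity matrix and cross-validates
#' the transcription against the publication's prose statements (the seven
#' zero-coverage events, the MON89034/MON810 element sets, and the
#' individually discussed cells).  A failing anchor is a packaging error,
#' so the check runs on every load unless disabled.
#'
#' @param checkAnchors logical; verify the transcription anchors.
#' @return a [SpecificityMatrix-class]
#' @examples
#' m <- gmoMatrix()
#' length(screeningTargets(m))  # 25
#' @export
gmoMatrix <- function(checkAnchors = TRUE) {
  m <- loadMatrix(.extdata("specificity_matrix.tsv"), assays = gmoAssays())
  if (checkAnchors) {
    rep <- checkMatrixAnchors(m)
    if (nrow(rep))
      stop("bundled specificity matrix fails transcription anchors:\n  ",
           paste(rep$message, collapse = "\n  "))
  }
  m
}
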