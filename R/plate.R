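## Eight-plate, 96-well layout: four 24-well assay blocks per plate, each
## holding 11 samples in duplicate plus a positive sensitivity control and a
## water control.

#' Build the screening plate layout
#'
#' Produces the deterministic eight-plate design: each plate carries four
#' assays in 24-well blocks (three columns of eight wells).  Within a block
#' wells are filled column-major in the order sample 1 isolation 1, sample 1
#' isolation 2, ..., sample 11 isolation 2, then the positive sensitivity
#' control, then the no-template (water) control.  The block structure is
#' fixed by the design; the machine coordinates follow this normative
#' ordering.
#'
#' @param nSamples number of samples, at most 11; with fewer than 11 the
#'   unused sample wells are kept in the layout with role `"empty"`.
#' @param methods data.frame `plate`/`mix`/`assay` (default: bundled
#'   distribution, [gmoPlateMethods()]).
#' @param controls data.frame `assay`/`control_material` assigning a
#'   positive-control material to every assay ([gmoPositiveControls()]).
#' @return a [PlateLayout-class]
#' @examples
#' layout <- buildLayout(11)
#' nrow(layoutAssignments(layout))  # 768
#' @export
buildLayout <- function(nSamples = 11L, methods = gmoPlateMethods(),
                        controls = gmoPositiveControls()) {
  nSamples <- as.integer(nSamples)
  if (is.na(nSamples) || nSamples < 1L || nSamples > 11L)
    stop("nSamples must be between 1 and 11 (the design holds 11 duplicate samples)")
  bad <- names(which(table(methods$plate) != 4L))
  if (length(bad))
    stop("plate(s) without exactly 4 assays: ", paste(bad, collapse = ", "))
  missing_pc <- setdiff(methods$assay, controls$assay)
  if (length(missing_pc))
    stop("assay(s) missing a positive-control material: ",
         paste(missing_pc, collapse = ", "))
  methods <- methods[order(methods$plate, methods$mix), ]
  pc <- stats::setNames(controls$control_material, controls$assay)

  rows <- vector("list", nrow(methods))
  for (k in seq_len(nrow(methods))) {
    plate <- methods$plate[k]
    mix <- methods$mix[k]
    assay <- methods$assay[k]
    i <- 1:24
    col <- 3L * (mix - 1L) + ceiling(i / 8)
    well <- paste0(LETTERS[(i - 1L) %% 8L + 1L], col)
    sample_id <- ifelse(i <= 22L, ceiling(i / 2), NA_integer_)
    isolation <- ifelse(i <= 22L, 2L - i %% 2L, NA_integer_)
    role <- rep("sample", 24L)
    role[i == 23L] <- "positive_control"
    role[i == 24L] <- "no_template_control"
    role[i <= 22L & sample_id > nSamples] <- "empty"
    sample_id[role != "sample"] <- NA_integer_
    isolation[role != "sample"] <- NA_integer_
    rows[[k]] <- data.frame(
      plate = plate, well = well, assay = assay, role = role,
      sample_id = as.integer(sample_id), isolation = as.integer(isolation),
      control_material = ifelse(role == "positive_control",
                                pc[[assay]], NA_character_),
      stringsAsFactors = FALSE)
  }
  mpp <- split(methods$assay, methods$plate)
  new("PlateLayout", assignments = do.call(rbind, rows),
      methodsPerPlate = mpp, nSamples = nSamples)
}

#' Well assignments of a layout
#' @param layout a [PlateLayout-class]
#' @return the assignments data.frame
#' @export
layoutAssignments <- function(layout) {
  stopifnot(is(layout, "PlateLayout"))
  layout@assignments
}

#' Look up a single well
#'
#' @param layout a [PlateLayout-class]
#' @param plate plate index
#' @param well well coordinate, e.g. `"A1"`
#' @return one-row data.frame for that well (role `"empty"` marks an unused
#'   sample position)
#' @export
wellLookup <- function(layout, plate, well) {
  a <- layoutAssignments(layout)
  if (!plate %in% a$plate)
    stop("plate out of range: ", plate)
  if (!grepl("^[A-H](1[0-2]|[1-9])$", well))
    stop("not a 96-well coordinate: ", well)
  hit <- a[a$plate == plate & a$well == well, ]
  if (nrow(hit) != 1L)
    stop(sprintf("well %s on plate %d is not part of the layout", well, plate))
  hit
}

#' Haploid genome equivalent copies per PCR reaction
#'
#' `floor(dna_mass_ng * 1000 * gmo_fraction / genome_1C_pg)`: the number of
#' haploid GMO genome copies in a reaction loading `dna_mass_ng` nanograms
#' of total DNA at mass fraction `gmo_fraction` of a crop with haploid
#' genome mass `genome_1C_pg` picograms.  Floor rounding is used (a partial
#' genome copy is not an amplifiable template).  The true copy number in
#' certified reference material additionally depends on the zygosity of the
#' GMO material, which this arithmetic ignores.
#'
#' @param dna_mass_ng total DNA mass per reaction (ng), positive.
#' @param gmo_fraction GMO mass fraction in (0, 1].
#' @param genome_1C_pg haploid genome mass (pg), positive.
#' @return integer copy count (vectorized)
#' @examples
#' copiesPerReaction(50, 0.001, 1.13)   # 44 copies, 0.1% soy
#' copiesPerReaction(50, 0.001, 2.725)  # 18 copies, 0.1% maize
#' copiesPerReaction(50, 0.001, 1.15)   # 43 copies, 0.1% canola
#' @export
copiesPerReaction <- function(dna_mass_ng, gmo_fraction, genome_1C_pg) {
  if (any(dna_mass_ng <= 0) || any(gmo_fraction <= 0) ||
      any(genome_1C_pg <= 0))
    stop("all arguments must be positive")
  if (any(gmo_fraction > 1))
    stop("gmo_fraction must not exceed 1")
  as.integer(floor(dna_mass_ng * 1000 * gmo_fraction / genome_1C_pg))
}

#' Per-well mix recipe for an assay
#'
#' Every well receives 25 uL: 20 uL of PCR mix (mastermix, water, primers
#' and probe at the assay's final concentrations) plus 5 uL of template DNA
#' at 10 ng/uL, i.e. 50 ng DNA per reaction.
#'
#' @param assay assay name
#' @param assays assay catalogue ([gmoAssays()])
#' @return list with the volumes, DNA mass and component concentrations
#' @export
mixRecipe <- function(assay, assays = gmoAssays()) {
  row <- assays[assays$name == assay, ]
  if (nrow(row) != 1L) stop("unknown assay: ", assay)
  list(assay = assay, mix_volume_uL = 20, dna_volume_uL = 5, total_uL = 25,
       dna_concentration_ng_per_uL = 10, dna_mass_ng = 50,
       primer_conc_nM = row$primer_nM, probe_conc_nM = row$probe_nM)
}

#' Export / import a plate map
#'
#' Tab-separated round-trip of the layout (`plate`, `well`, `assay`, `role`,
#' `sample_id`, `isolation`, `control_material`).  Import revalidates the
#' count invariants; well positions themselves are free, so a hand-edited
#' map that swaps two sample wells reloads without complaint.
#'
#' @param layout a [PlateLayout-class]
#' @param path file path
#' @return `exportPlateMap`: the path invisibly; `importPlateMap`: a
#'   [PlateLayout-class]
#' @export
exportPlateMap <- function(layout, path) {
  utils::write.table(layoutAssignments(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname exportPlateMap
#' @export
importPlateMap <- function(path) {
  if (!file.exists(path)) stop("plate map not found: ", path)
  a <- .read_tsv(path)
  need <- c("plate", "well", "assay", "role", "sample_id", "isolation",
            "control_material")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("plate map missing column(s): ", paste(miss, collapse = ", "))
  a$plate <- as.integer(a$plate)
  a$sample_id <- suppressWarnings(as.integer(a$sample_id))
  a$isolation <- suppressWarnings(as.integer(a$isolation))
  a$control_material[a$control_material == ""] <- NA_character_
  bad <- which(!a$role %in% .WELL_ROLES)
  if (length(bad))
    stop(sprintf("line %d: unknown well role '%s'", bad[1L] + 1L,
                 a$role[bad[1L]]))
  mpp <- lapply(split(a, a$plate), function(p) unique(p$assay))
  ns <- if (any(a$role == "sample")) max(a$sample_id[a$role == "sample"])
        else 0L
  layout <- new("PlateLayout", assignments = a, methodsPerPlate = mpp,
                nSamples = as.integer(ns))
  validObject(layout)
  layout
}
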