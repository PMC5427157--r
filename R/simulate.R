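## Synthetic Cq data: Poisson template sampling with a log-linear Cq
## response, over the full plate design.

#' Construct a Cq response model
#'
#' @param intercept Cq at a single template copy (default 40).
#' @param slope Cq per tenfold template change; 3.32 corresponds to perfect
#'   doubling efficiency.
#' @param sigma replicate noise SD in cycles (default 0.2, a typical
#'   within-run TaqMan replicate scatter).
#' @return a [CqModel-class]
#' @export
cqModel <- function(intercept = 40, slope = 3.32, sigma = 0.2) {
  new("CqModel", intercept = intercept, slope = slope, sigma = sigma)
}

#' Describe a sample's composition
#'
#' Mass fractions of a crop background, GMO events and optional trace
#' contaminations, plus free `elements` contributions (screening targets
#' present without a catalogued event - the unknown-GMO scenario).
#'
#' @param sample_id sample number (1-based plate position).
#' @param background_crop crop of the non-GMO background material.
#' @param background_fraction its mass fraction; defaults to the remainder
#'   to 1.
#' @param events named numeric vector, event name -> mass fraction.
#' @param contamination named numeric vector of trace event fractions.
#' @param elements named numeric vector, screening target -> mass fraction
#'   carried by an uncatalogued source in the background crop.
#' @return a list of class `sample_composition`
#' @export
sampleComposition <- function(sample_id, background_crop,
                              background_fraction = NULL,
                              events = numeric(), contamination = numeric(),
                              elements = numeric()) {
  used <- sum(events) + sum(contamination) + sum(elements)
  if (is.null(background_fraction)) background_fraction <- 1 - used
  stopifnot(background_fraction >= 0, all(events >= 0),
            all(contamination >= 0), all(elements >= 0),
            background_fraction + used <= 1 + 1e-9)
  structure(list(sample_id = as.integer(sample_id),
                 background_crop = background_crop,
                 background_fraction = background_fraction,
                 events = events, contamination = contamination,
                 elements = elements),
            class = "sample_composition")
}

#' Expected template copies per well
#'
#' For a screening assay, every event of the composition whose matrix state
#' is `+` or `+*` contributes `copiesPerReaction(dna_mass_ng, fraction,
#' 1C of its crop)` copies; `X` events contribute nothing (element present
#' but invisible to the assay).  For an endogenous assay, all material of
#' the scoped crop contributes (the all-plants actin assay sees every
#' fraction).  Free `elements` contributions are converted with the
#' background crop's genome size.
#'
#' @param composition a [sampleComposition()].
#' @param assay assay name.
#' @param matrix a [SpecificityMatrix-class].
#' @param genomeSizes named 1C vector in pg ([gmoGenomeSizes()]).
#' @param dna_mass_ng DNA mass per reaction (50 ng in the standard design).
#' @return named numeric vector of per-source expected copies (possibly
#'   empty); sum it for the well's Poisson mean.
#' @examples
#' m <- gmoMatrix()
#' comp <- sampleComposition(1, "soy", events = c("GTS 40-3-2 soy" = 0.001))
#' sum(expectedCopies(comp, "ctp4/CP4-epsps", m))  # 44
#' @export
expectedCopies <- function(composition, assay, matrix,
                           genomeSizes = gmoGenomeSizes(),
                           dna_mass_ng = 50) {
  stopifnot(inherits(composition, "sample_composition"))
  assays <- assayCatalogue(matrix)
  arow <- assays[assays$name == assay, ]
  if (nrow(arow) != 1L) stop("unknown assay: ", assay)
  ev <- eventCatalogue(matrix)
  pg <- function(crop) {
    if (!crop %in% names(genomeSizes))
      stop("no 1C genome size for crop: ", crop)
    genomeSizes[[crop]]
  }
  contrib <- numeric()
  if (arow$category == "endogenous") {
    scope <- arow$crop_scope
    fracs <- numeric(); crops <- character()
    if (composition$background_fraction > 0 &&
        (scope == "all plants" || composition$background_crop == scope)) {
      fracs["background"] <- composition$background_fraction
      crops["background"] <- composition$background_crop
    }
    evs <- c(composition$events, composition$contamination)
    for (nm in names(evs)) {
      if (!nm %in% ev$name) stop("unknown event in composition: ", nm)
      crop <- ev$crop[match(nm, ev$name)]
      if ((scope == "all plants" || crop == scope) && evs[[nm]] > 0) {
        fracs[nm] <- sum(fracs[nm], evs[[nm]], na.rm = TRUE)
        crops[nm] <- crop
      }
    }
    if (length(fracs))
      contrib <- stats::setNames(
        mapply(function(f, cr) copiesPerReaction(dna_mass_ng, f, pg(cr)),
               fracs, crops), names(fracs))
  } else {
    all_events <- c(composition$events, composition$contamination)
    for (nm in names(all_events)) {
      if (!nm %in% ev$name) stop("unknown event in composition: ", nm)
      state <- matrix@states[nm, assay]
      if (state %in% c("+", "+*") && all_events[[nm]] > 0)
        contrib[nm] <- copiesPerReaction(dna_mass_ng, all_events[[nm]],
                                         pg(ev$crop[match(nm, ev$name)]))
    }
    if (assay %in% names(composition$elements) &&
        composition$elements[[assay]] > 0)
      contrib["element"] <- copiesPerReaction(
        dna_mass_ng, composition$elements[[assay]],
        pg(composition$background_crop))
  }
  contrib
}

.sim_cq <- function(lambda, model) {
  copies <- stats::rpois(length(lambda), lambda)
  cq <- rep(NA_real_, length(lambda))
  amp <- copies > 0L
  cq[amp] <- model@intercept - model@slope * log10(copies[amp]) +
    stats::rnorm(sum(amp), 0, model@sigma)
  pmax(cq, 1e-3)
}

#' Simulate a full screening run
#'
#' Every sample well draws its template copy number from a Poisson
#' distribution with the composition-implied mean (zero copies = no
#' amplification; the single-hit model amplifies any non-zero template),
#' and its Cq from the [CqModel-class].  Positive-control wells contain the
#' target template at the sensitivity-control level: 0.1% of 50 ng of the
#' control material's crop where the crop is known (44/18/43 copies for
#' soy/maize/canola), 25 copies otherwise.  No-template controls never
#' amplify unless `ntc_contamination` injects a trace mean.  Fully
#' reproducible from `seed`.
#'
#' @param compositions list of [sampleComposition()]s; sample ids must fit
#'   the layout.
#' @param layout a [PlateLayout-class].
#' @param matrix a [SpecificityMatrix-class].
#' @param model a [cqModel()].
#' @param genomeSizes named 1C vector in pg.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param ntc_contamination Poisson mean of trace copies in NTC wells
#'   (default 0).
#' @return data.frame `plate`, `well`, `cq` (numeric, `NA` = no
#'   amplification), in layout order, covering every non-empty well.
#' @export
simulateRun <- function(compositions, layout, matrix, model = cqModel(),
                        genomeSizes = gmoGenomeSizes(), seed = NULL,
                        ntc_contamination = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(compositions, "sample_composition"))
    compositions <- list(compositions)
  ids <- vapply(compositions, `[[`, integer(1L), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id in compositions")
  if (any(ids < 1L | ids > layout@nSamples))
    stop("sample_id outside layout capacity")
  a <- layoutAssignments(layout)
  a <- a[a$role != "empty", ]
  pcs <- gmoPositiveControls()
  acat <- assayCatalogue(matrix)
  assays_cat <- stats::setNames(acat$category, acat$name)

  lambda <- numeric(nrow(a))
  keep <- logical(nrow(a))
  ## cache per (sample, assay) expected copies
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(a))) {
    role <- a$role[r]
    if (role == "sample") {
      k <- match(a$sample_id[r], ids)
      if (is.na(k)) next
      key <- paste(a$sample_id[r], a$assay[r], sep = "\r")
      if (is.null(cache[[key]]))
        cache[[key]] <- sum(expectedCopies(compositions[[k]], a$assay[r],
                                           matrix, genomeSizes))
      lambda[r] <- cache[[key]]
      keep[r] <- TRUE
    } else if (role == "positive_control") {
      crop <- pcs$material_crop[match(a$assay[r], pcs$assay)]
      cat_ <- assays_cat[match(a$assay[r], names(assays_cat))]
      lambda[r] <- if (is.na(crop) || !crop %in% names(genomeSizes)) {
        25                      # e.g. the CaMV positive sample
      } else if (identical(unname(cat_), "endogenous")) {
        ## taxon controls are undiluted material of the scoped crop
        copiesPerReaction(50, 1, genomeSizes[[crop]])
      } else {
        ## 0.1% GMO CRM at 50 ng (44/18/43 copies for soy/maize/canola)
        copiesPerReaction(50, 0.001, genomeSizes[[crop]])
      }
      keep[r] <- TRUE
    } else if (role == "no_template_control") {
      lambda[r] <- ntc_contamination
      keep[r] <- TRUE
    }
  }
  a <- a[keep, ]
  cq <- .sim_cq(lambda[keep], model)
  data.frame(plate = a$plate, well = a$well, cq = cq,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a simulated Cq table
#'
#' The on-disk format is the long tab-separated `plate`/`well`/`cq` layout
#' [parseCqTable()] consumes; non-amplified wells carry the `NO_AMP` token.
#'
#' @param cq data.frame from [simulateRun()].
#' @param path output file.
#' @return the path, invisibly
#' @export
writeCqTable <- function(cq, path) {
  out <- cq
  out$cq <- ifelse(is.na(out$cq), "NO_AMP", formatC(out$cq, digits = 4,
                                                    format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled simulation scenarios
#'
#' Named scenarios with their expected downstream truths, used by the test
#' suite and as worked examples:
#' \describe{
#'   \item{`non_gmo_soy`}{pure soy: endogenous soy/actin calls only, zero
#'     candidates.}
#'   \item{`mon89034_mon810_masking`}{maize carrying MON89034 and MON810:
#'     seven detected elements, both events candidates; confirming MON89034
#'     alone explains everything and MON810 is reported as maskable.}
#'   \item{`unknown_gmo`}{soy carrying P-35S and bar from no catalogued
#'     event: no candidate explains the pattern, the unknown-GMO indication
#'     must raise.}
#'   \item{`trace_contamination`}{MON1445 cotton with a 0.01% MON531
#'     trace: late Cq (>34) signals on the Cry1A assays.}
#' }
#'
#' @param name scenario name.
#' @return list with `name`, `compositions` (list of
#'   [sampleComposition()]), and `expected` truths for test oracles.
#' @export
makeFixture <- function(name) {
  seven <- c("P-35S", "P-FMV", "T-nos", "Cry1A(b)", "Cry1A.105",
             "Cry2Ab2", "I-rAct1")
  fixtures <- list(
    non_gmo_soy = list(
      compositions = list(sampleComposition(1L, "soy")),
      expected = list(detected = character(), crops = "soy",
                      candidates = character(), unknown = FALSE)),
    mon89034_mon810_masking = list(
      compositions = list(sampleComposition(
        1L, "maize", events = c("MON89034 maize" = 0.05,
                                "MON810 maize" = 0.05))),
      expected = list(detected = seven, crops = "maize",
                      candidates = c("MON810 maize", "MON89034 maize"),
                      confirm = c("MON89034 maize" = "detected"),
                      masked = "MON810 maize", unknown = FALSE)),
    unknown_gmo = list(
      compositions = list(sampleComposition(
        1L, "soy", elements = c("P-35S" = 0.01, "bar" = 0.01))),
      expected = list(detected = c("P-35S", "bar"), crops = "soy",
                      candidates = character(), unknown = TRUE)),
    trace_contamination = list(
      compositions = list(sampleComposition(
        1L, "cotton", events = c("MON1445 cotton" = 0.1),
        contamination = c("MON531 cotton" = 1e-4))),
      expected = list(late_assays = c("Cry1A(b)", "Cry1Ab/Ac"),
                      unknown = FALSE))
  )
  if (!name %in% names(fixtures))
    stop("unknown fixture: ", name, " (available: ",
         paste(names(fixtures), collapse = ", "), ")")
  c(list(name = name), fixtures[[name]])
}
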