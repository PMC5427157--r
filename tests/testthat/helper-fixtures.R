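# Shared fixtures: the bundled matrix/layout are loaded once per run, and
# small constructors keep the tests free of boilerplate.

`%||%` <- function(a, b) if (is.null(a)) b else a

the_matrix <- gmoMatrix()
the_layout <- buildLayout(11)
the_assays <- gmoAssays()

SEVEN_ELEMENTS <- c("P-35S", "P-FMV", "T-nos", "Cry1A(b)", "Cry1A.105",
                    "Cry2Ab2", "I-rAct1")

# Full 32-assay call profile: everything ND except the given sets.
make_profile <- function(detected = character(), suspect = character(),
                         assays = the_assays$name) {
  prof <- stats::setNames(rep("ND", length(assays)), assays)
  prof[detected] <- "D"
  prof[suspect] <- "S"
  prof
}

# A detected-call profile for a crop background plus a set of true events,
# as the matrix implies it (endogenous + union of detectable elements).
profile_for_events <- function(events, background_crop = "soy",
                               matrix = the_matrix) {
  endo <- the_assays[the_assays$category == "endogenous", ]
  crops <- unique(c(background_crop,
                    eventCatalogue(matrix)$crop[
                      match(events, eventCatalogue(matrix)$name)]))
  endo_hit <- endo$name[endo$crop_scope %in% c(crops, "all plants")]
  make_profile(detected = c(endo_hit, expectedElements(matrix, events)))
}

# Minimal free-standing matrix written to a temp file, for parser tests.
write_tiny_matrix <- function(path,
                              cells = c("+\t-\t-", "-\t+\t+", "-\t-\t-")) {
  writeLines(c("event\tcrop\tstatus\tA1\tA2\tA3",
               paste0("ev1 maize\tmaize\tunknown\t", cells[1]),
               paste0("ev2 soy\tsoy\tauthorised\t", cells[2]),
               paste0("ev3 soy\tsoy\tunauthorised\t", cells[3])),
             path)
  path
}

tiny_matrix <- function() {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  write_tiny_matrix(f)
  loadMatrix(f, assays = the_assays[0, ])
}

# Independent oracle: detectable set read straight off the state grid.
oracle_detectable <- function(matrix, event) {
  st <- matrix@states[event, ]
  names(st)[st %in% c("+", "+*")]
}
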