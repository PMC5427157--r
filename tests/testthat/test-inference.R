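cfg <- screeningConfig()
endo_names <- the_assays$name[the_assays$category == "endogenous"]

test_that("crops present follow the endogenous calls", {
  prof <- make_profile(detected = c("Soy Lec", "Plant actin"))
  cp <- cropsPresent(prof)
  expect_identical(cp$crops, "soy")
  expect_true(cp$plant_material)
  expect_false(cp$dna_quality_warning)
  expect_setequal(cp$ungated, c("cotton", "potato"))
  # actin only: plant material confirmed, no gated crop
  cp2 <- cropsPresent(make_profile(detected = "Plant actin"))
  expect_length(cp2$crops, 0L)
  expect_true(cp2$plant_material)
  # nothing endogenous at all: DNA quality warning
  cp3 <- cropsPresent(make_profile())
  expect_true(cp3$dna_quality_warning)
})

test_that("the MON89034/MON810 worked example predicts both events", {
  prof <- make_profile(detected = c(SEVEN_ELEMENTS, "Maize HMG",
                                    "Plant actin"))
  rep <- candidateEvents(prof, the_matrix, cfg)
  expect_true(all(c("MON89034 maize", "MON810 maize") %in%
                  candidates(rep)$event))
  # MON89034 leads the listing within equal status (most support)
  cand <- candidates(rep)
  expect_lt(which(cand$event == "MON89034 maize"),
            which(cand$event == "MON810 maize"))
  # crop-gated exclusions carry their reason
  expect_true("GTS 40-3-2 soy" %in% rep@excluded$event)
  expect_match(rep@excluded$reason[
    rep@excluded$event == "GTS 40-3-2 soy"], "crop gate")
  # a maize event with an undetected element names its first failing assay
  expect_match(rep@excluded$reason[
    rep@excluded$event == "TC1507 maize"], "not detected")
  # zero-coverage events of present/ungated crops are always-test
  expect_true(all(c("DAS40278 maize", "DP98140 maize", "GHB614 cotton")
                  %in% alwaysTest(rep)))
  expect_false("CV127 soy" %in% alwaysTest(rep))  # soy not present
})

test_that("an all-negative screen yields no candidates", {
  prof <- make_profile(detected = c("Soy Lec", "Plant actin"))
  rep <- candidateEvents(prof, the_matrix, cfg)
  expect_equal(nrow(candidates(rep)), 0L)
  expect_setequal(alwaysTest(rep),
                  c("CV127 soy", "DP305423 soy", "DP356043 soy",
                    "GHB614 cotton"))
})

test_that("strict candidates are a subset of lenient candidates", {
  set.seed(23)
  targets <- screeningTargets(the_matrix)
  lenient <- screeningConfig(candidate_mode = "lenient")
  for (i in 1:40) {
    prof <- make_profile(
      detected = c(sample(endo_names, 3),
                   sample(targets, rpois(1, 4) + 1)))
    s <- candidates(candidateEvents(prof, the_matrix, cfg))$event
    l <- candidates(candidateEvents(prof, the_matrix, lenient))$event
    expect_true(all(s %in% l))
  }
})

test_that("confirming MON89034 explains the whole seven-element pattern", {
  prof <- make_profile(detected = c(SEVEN_ELEMENTS, "Maize HMG",
                                    "Plant actin"))
  expl <- explainElements(prof, the_matrix,
                          c("MON89034 maize" = "detected"), cfg)
  st <- explanationStatus(expl)
  expect_setequal(st$assay, SEVEN_ELEMENTS)
  expect_true(all(st$status == "explained"))
  expect_false(unknownGmoIndicated(expl))
  expect_length(requiredNextTests(expl), 0L)
  # the same pattern with MON89034 ruled out leaves five orphans
  others <- stats::setNames(
    rep("not_detected", 3),
    c("MON89034 maize", "5307 maize", "MIR604 maize"))
  expl2 <- explainElements(prof, the_matrix,
                           c(others, "MON810 maize" = "detected"), cfg)
  st2 <- explanationStatus(expl2)
  unexplained <- st2$assay[st2$status %in% c("unexplained", "donor_caveat")]
  expect_setequal(unexplained,
                  setdiff(SEVEN_ELEMENTS, c("P-35S", "Cry1A(b)")))
  expect_true(unknownGmoIndicated(expl2))
})

test_that("donor-caveat and unverified explanations are annotated", {
  prof <- make_profile(detected = c("Maize HMG", "Plant actin", "nptII"))
  expl <- explainElements(prof, the_matrix, NULL, cfg)
  st <- explanationStatus(expl)
  expect_equal(st$status[st$assay == "nptII"], "donor_caveat")
  expect_match(st$notes[st$assay == "nptII"], "donor organism")
  # CaMV positivity annotates P-35S as possibly virus-derived
  prof2 <- make_profile(detected = c("Maize HMG", "Plant actin",
                                     "P-35S", "CaMV"))
  st2 <- explanationStatus(explainElements(prof2, the_matrix, NULL, cfg))
  expect_match(st2$notes[st2$assay == "P-35S"], "virus")
  # an (+) cell explains only with the unverified status
  prof3 <- make_profile(detected = c("Rice SPS", "Plant actin",
                                     "P-Rice actin", "P-35S", "T-35S",
                                     "bar"))
  expl3 <- explainElements(prof3, the_matrix,
                           c("LL601 rice" = "detected"), cfg)
  st3 <- explanationStatus(expl3)
  expect_equal(st3$status[st3$assay == "P-Rice actin"],
               "explained_unverified")
  expect_equal(st3$status[st3$assay == "P-35S"], "explained")
  expect_error(explainElements(prof, the_matrix,
                               c("no such event" = "detected"), cfg),
               "absent from matrix")
})

test_that("no detected screening target is vacuously explained", {
  prof <- make_profile(detected = c("Soy Lec", "Plant actin"))
  expl <- explainElements(prof, the_matrix, NULL, cfg)
  expect_equal(nrow(explanationStatus(expl)), 0L)
  expect_false(unknownGmoIndicated(expl))
})

test_that("explanation is monotone under added confirmed events", {
  set.seed(31)
  targets <- screeningTargets(the_matrix)
  evs <- eventNames(the_matrix)
  rank <- c(explained = 1, explained_unverified = 2, donor_caveat = 3,
            unexplained = 4)
  for (i in 1:30) {
    prof <- make_profile(detected = c(sample(endo_names, 2),
                                      sample(targets, 5)))
    e1 <- sample(evs, 2)
    e2 <- c(e1, sample(setdiff(evs, e1), 2))
    r1 <- explanationStatus(explainElements(
      prof, the_matrix, stats::setNames(rep("detected", 2), e1), cfg))
    r2 <- explanationStatus(explainElements(
      prof, the_matrix, stats::setNames(rep("detected", 4), e2), cfg))
    expect_true(all(rank[r2$status[match(r1$assay, r2$assay)]] <=
                    rank[r1$status]))
  }
})

test_that("masking agrees with the exhaustive subset oracle", {
  # independent oracle straight off the state grid
  oracle <- function(confirmed) {
    pool <- unique(unlist(lapply(confirmed, oracle_detectable,
                                 matrix = the_matrix)))
    sort(Filter(function(e) {
      d <- oracle_detectable(the_matrix, e)
      !(e %in% confirmed) && length(d) > 0 && all(d %in% pool)
    }, eventNames(the_matrix)))
  }
  expect_true("MON810 maize" %in%
              maskingCheck(the_matrix, "MON89034 maize")$event)
  expect_equal(nrow(maskingCheck(the_matrix, character())), 0L)
  set.seed(41)
  sets <- c(as.list(sample(eventNames(the_matrix), 10)),
            lapply(1:10, function(i) sample(eventNames(the_matrix), 3)))
  for (conf in sets)
    expect_identical(maskingCheck(the_matrix, conf)$event, oracle(conf))
})

test_that("workflow directives follow the label mode", {
  prof <- make_profile(detected = c(SEVEN_ELEMENTS, "Maize HMG",
                                    "Plant actin"))
  cand <- candidateEvents(prof, the_matrix, cfg)
  # GMO-labelled, everything explained: stop
  done <- decideWorkflow(cand, explainElements(
    prof, the_matrix, c("MON89034 maize" = "detected"), cfg), cfg)
  expect_equal(done$status, "complete")
  expect_length(done$tests, 0L)
  # GMO-labelled, unexplained elements, candidates untested: list them
  open <- decideWorkflow(cand, explainElements(prof, the_matrix, NULL, cfg),
                         cfg)
  expect_equal(open$status, "tests_required")
  expect_true("MON89034 maize" %in% open$tests)
  # GMO-labelled, all candidates negative: unknown GMO indicated
  allneg <- stats::setNames(rep("not_detected",
                                nrow(candidates(cand))),
                            candidates(cand)$event)
  stuck <- decideWorkflow(cand, explainElements(prof, the_matrix, allneg,
                                                cfg), cfg)
  expect_equal(stuck$status, "unknown_gmo_indicated")
  expect_true(any(grepl("orthogonal identification", stuck$notes)))
  # non-GMO-labelled: all candidates must be tested, detections quantified
  ng <- screeningConfig(label_mode = "non_gmo_labelled")
  todo <- decideWorkflow(cand, explainElements(
    prof, the_matrix, c("MON89034 maize" = "detected"), ng), ng)
  expect_equal(todo$status, "tests_required")
  expect_true("MON810 maize" %in% todo$tests)
  expect_equal(todo$quantify, "MON89034 maize")
  expect_true(any(grepl("0.9%", todo$notes)))
})

test_that("stacked events produce the union pattern and are never identified as stacks", {
  prof <- profile_for_events(c("MON89034 maize", "MON810 maize"),
                             background_crop = "maize")
  interp <- interpretSample(prof, the_matrix, sample_id = 1,
                            eventResults = c("MON89034 maize" = "detected",
                                             "MON810 maize" = "detected"))
  # both components appear individually; no output field claims a stack
  expect_true(all(c("MON89034 maize", "MON810 maize") %in%
                  candidates(interp@candidates)$event))
  sheet <- renderSampleSheet(interp, the_matrix, "data")
  expect_false(any(grepl("stack identified",
                         unlist(lapply(sheet, as.character)),
                         ignore.case = TRUE)))
  # the Cq-similarity hint is an annotation only
  expect_type(sheet$stack_hint, "character")
})
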