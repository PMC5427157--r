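test_that("expected copies reproduce the sensitivity-control arithmetic", {
  comp <- sampleComposition(1, "soy",
                            events = c("GTS 40-3-2 soy" = 0.001))
  expect_equal(sum(expectedCopies(comp, "ctp4/CP4-epsps", the_matrix)),
               44)
  # an X cell contributes nothing although the element is present
  comp2 <- sampleComposition(1, "maize",
                             events = c("MON87460 maize" = 0.001))
  expect_equal(sum(expectedCopies(comp2, "P-Rice actin", the_matrix)), 0)
  expect_gt(sum(expectedCopies(comp2, "P-35S", the_matrix)), 0)
  # absent event contributes nothing
  comp3 <- sampleComposition(1, "soy")
  expect_equal(sum(expectedCopies(comp3, "P-35S", the_matrix)), 0)
  # endogenous assays see all material of their crop
  expect_equal(sum(expectedCopies(comp, "Soy Lec", the_matrix)),
               copiesPerReaction(50, 0.999, 1.13) +
                 copiesPerReaction(50, 0.001, 1.13))
  expect_equal(sum(expectedCopies(comp2, "Soy Lec", the_matrix)), 0)
  expect_gt(sum(expectedCopies(comp2, "Plant actin", the_matrix)), 0)
  expect_error(expectedCopies(comp, "no such assay", the_matrix),
               "unknown assay")
})

test_that("simulation is reproducible from the seed", {
  fx <- makeFixture("mon89034_mon810_masking")
  l1 <- buildLayout(1)
  a <- simulateRun(fx$compositions, l1, the_matrix, seed = 99)
  b <- simulateRun(fx$compositions, l1, the_matrix, seed = 99)
  expect_identical(a, b)
  c <- simulateRun(fx$compositions, l1, the_matrix, seed = 100)
  expect_false(identical(a, c))
})

test_that("a 10% event sample yields D calls on its whole detectable set", {
  comp <- sampleComposition(1, "maize",
                            events = c("MON89034 maize" = 0.1))
  l1 <- buildLayout(1)
  cq <- simulateRun(comp, l1, the_matrix, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCqTable(cq, f)
  calls <- callSampleProfile(parseCqTable(f, l1))
  prof <- sampleProfile(calls, 1)
  expect_true(all(prof[SEVEN_ELEMENTS] == "D"))
  others <- setdiff(screeningTargets(the_matrix), SEVEN_ELEMENTS)
  expect_true(all(prof[others] == "ND"))
})

test_that("noise-free detection at control copy numbers is deterministic", {
  model0 <- cqModel(sigma = 0)
  comp <- sampleComposition(1, "soy",
                            events = c("GTS 40-3-2 soy" = 0.001))  # 44 cp
  l1 <- buildLayout(1)
  for (seed in c(1, 2, 3)) {
    cq <- simulateRun(comp, l1, the_matrix, model = model0, seed = seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCqTable(cq, f)
    prof <- sampleProfile(callSampleProfile(parseCqTable(f, l1)), 1)
    det <- expectedDetectable(the_matrix, "GTS 40-3-2 soy")$detectable
    expect_true(all(prof[det] %in% c("D", "S")))
    expect_true(all(prof[setdiff(screeningTargets(the_matrix), det)]
                    == "ND"))
  }
})

test_that("single-copy dropout follows the Poisson zero class", {
  lam <- 1
  n <- 2000L
  set.seed(17)
  cq <- GMOscreen:::.sim_cq(rep(lam, n), cqModel())
  p_hat <- mean(is.na(cq))
  p <- exp(-lam)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("raising an event fraction never lowers detection probability", {
  comp_at <- function(f) sampleComposition(
    1, "maize", events = c("MON810 maize" = f))
  lams <- vapply(c(1e-4, 1e-3, 1e-2, 0.1), function(f)
    sum(expectedCopies(comp_at(f), "Cry1A(b)", the_matrix)), numeric(1))
  expect_true(!is.unsorted(lams))  # P(detect) = 1 - exp(-lambda), monotone
})

test_that("trace contamination surfaces as late-Cq suspect signals", {
  fx <- makeFixture("trace_contamination")
  l1 <- buildLayout(1)
  hits <- 0L
  for (seed in 1:6) {
    cq <- simulateRun(fx$compositions, l1, the_matrix, seed = seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCqTable(cq, f)
    parsed <- parseCqTable(f, l1)
    tr <- parsed[parsed$role == "sample" &
                 parsed$assay %in% fx$expected$late_assays, ]
    amp <- tr$cq[!is.na(tr$cq)]
    expect_true(all(amp > 34))  # 2-copy template cannot give early Cq
    hits <- hits + length(amp)
  }
  expect_gt(hits, 0L)  # the trace is seen at least once over six runs
})

test_that("fixtures carry their registered truths", {
  expect_error(makeFixture("nonexistent"), "unknown fixture")
  run_fixture <- function(name, eventResults = NULL) {
    fx <- makeFixture(name)
    l <- buildLayout(length(fx$compositions))
    cq <- simulateRun(fx$compositions, l, the_matrix, seed = 77)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCqTable(cq, f)
    calls <- callSampleProfile(parseCqTable(f, l))
    interpretSample(calls, the_matrix, sample_id = 1,
                    eventResults = eventResults)
  }
  # non-GMO soy: zero candidates
  i1 <- run_fixture("non_gmo_soy")
  expect_equal(nrow(candidates(i1@candidates)), 0L)
  expect_false(unknownGmoIndicated(i1@explanation))
  # unknown GMO: element pattern from no catalogued event
  i2 <- run_fixture("unknown_gmo")
  expect_true(unknownGmoIndicated(i2@explanation))
  expect_equal(i2@workflow$status, "unknown_gmo_indicated")
  # masking: MON89034 explains everything, MON810 reported maskable
  fx <- makeFixture("mon89034_mon810_masking")
  i3 <- run_fixture("mon89034_mon810_masking",
                    eventResults = fx$expected$confirm)
  expect_true(all(fx$expected$candidates %in%
                  candidates(i3@candidates)$event))
  expect_false(unknownGmoIndicated(i3@explanation))
  expect_equal(i3@workflow$status, "complete")
  confirmed <- names(fx$expected$confirm)
  expect_true(fx$expected$masked %in%
              maskingCheck(the_matrix, confirmed)$event)
})
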