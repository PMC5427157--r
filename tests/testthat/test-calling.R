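cfg <- screeningConfig()

test_that("duplicate calling follows the D/ND/S rules", {
  expect_equal(callDuplicates(25.1, 25.3)$call, "D")
  expect_equal(callDuplicates(NA, NA)$call, "ND")
  s <- callDuplicates(32.0, NA)
  expect_equal(s$call, "S")
  expect_match(s$notes, "discordant")
  late <- callDuplicates(38.5, 39.2)
  expect_equal(late$call, "S")
  expect_match(late$notes, "late-Cq")
  # boundary: exactly at the suspect threshold is still a clean detection
  expect_equal(callDuplicates(34.0, 33.0)$call, "D")
  # beyond the detection window counts as no amplification
  expect_equal(callDuplicates(45.5, 45.9, screeningConfig(
    detect_cq_max = 45, max_cycles = 50))$call, "ND")
})

test_that("duplicate calling is symmetric and monotone in the threshold", {
  set.seed(7)
  for (i in 1:50) {
    cq <- ifelse(runif(2) < 0.3, NA_real_, runif(2, 15, 45))
    expect_identical(callDuplicates(cq[1], cq[2])$call,
                     callDuplicates(cq[2], cq[1])$call)
    lo <- callDuplicates(cq[1], cq[2], screeningConfig(detect_cq_max = 35))
    hi <- callDuplicates(cq[1], cq[2], screeningConfig(detect_cq_max = 45))
    # raising the detection threshold never turns D into ND
    if (lo$call == "D") expect_false(hi$call == "ND")
  }
})

sim_parsed <- local({
  comps <- c(list(sampleComposition(1, "soy"),
                  sampleComposition(2, "soy",
                                    events = c("GTS 40-3-2 soy" = 0.1))),
             lapply(3:11, function(i) sampleComposition(i, "soy")))
  cq <- simulateRun(comps, the_layout, the_matrix, seed = 101)
  f <- tempfile(fileext = ".tsv")
  writeCqTable(cq, f)
  parseCqTable(f, the_layout)
})

test_that("a full simulated export parses to 704 sample and 64 control wells", {
  expect_equal(nrow(sim_parsed), 768L)
  expect_equal(sum(sim_parsed$role == "sample"), 704L)
  expect_equal(sum(sim_parsed$role != "sample"), 64L)
})

test_that("Cq table parsing rejects malformed input with coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plate\twell\tcq", "1\tA1\t25.0", "1\tA1\t26.0"), f)
  expect_error(parseCqTable(f, the_layout), "duplicate")
  writeLines(c("plate\twell\tcq", "1\tZ99\t25.0"), f)
  expect_error(parseCqTable(f, the_layout), "Z99")
  writeLines(c("plate\twell\tcq", "1\tA1\tabc"), f)
  expect_error(parseCqTable(f, the_layout), "abc")
  writeLines(c("plate\twell\tcq", "1\tA1\t99"), f)
  expect_error(parseCqTable(f, the_layout), "out of")
  # comma-separated input and configured no-amp tokens are accepted
  writeLines(c("plate,well,cq", "1,A1,Undetermined", "1,B1,31.2"), f)
  p <- parseCqTable(f, the_layout)
  expect_true(is.na(p$cq[1]))
  expect_equal(p$cq[2], 31.2)
})

test_that("control validation flags failing assays", {
  ctrl <- validateControls(sim_parsed, cfg)
  expect_equal(nrow(ctrl), 32L)
  expect_true(all(ctrl$valid))
  # sabotage: positive control of bar fails, NTC of pat contaminates
  bad <- sim_parsed
  bad$cq[bad$assay == "bar" & bad$role == "positive_control"] <- NA
  bad$cq[bad$assay == "pat" & bad$role == "no_template_control"] <- 38
  ctrl2 <- validateControls(bad, cfg)
  expect_false(ctrl2$valid[ctrl2$assay == "bar"])
  expect_false(ctrl2$positive_control_ok[ctrl2$assay == "bar"])
  expect_false(ctrl2$ntc_ok[ctrl2$assay == "pat"])
  expect_match(ctrl2$note[ctrl2$assay == "pat"], "contamination")
  # a removed control well is an error, not a silent pass
  expect_error(validateControls(
    bad[!(bad$assay == "bar" & bad$role == "positive_control"), ], cfg),
    "missing control")
})

test_that("per-sample calling yields one call per sample and assay", {
  calls <- callSampleProfile(sim_parsed, cfg)
  expect_equal(nrow(calls), 11L * 32L)
  p1 <- sampleProfile(calls, 1)
  expect_equal(unname(p1[["Soy Lec"]]), "D")
  expect_equal(unname(p1[["Plant actin"]]), "D")
  screening <- setdiff(names(p1),
                       the_assays$name[the_assays$category == "endogenous"])
  expect_true(all(p1[screening] == "ND"))
  # the Roundup Ready soy sample fires exactly its detectable set
  p2 <- sampleProfile(calls, 2)
  det <- expectedDetectable(the_matrix, "GTS 40-3-2 soy")$detectable
  expect_true(all(p2[det] %in% c("D", "S")))
  expect_true(all(p2[setdiff(screening, det)] == "ND"))
})

test_that("missing replicates are called from the remaining well and flagged", {
  half <- sim_parsed[!(sim_parsed$sample_id %in% 1 &
                       sim_parsed$isolation %in% 2), ]
  calls <- callSampleProfile(half, cfg)
  c1 <- calls[calls$sample_id == 1, ]
  expect_true(all(grepl("single replicate", c1$notes)))
  expect_equal(unname(c1$call[c1$assay == "Soy Lec"]), "D")
})

test_that("failed controls annotate sample calls instead of dropping them", {
  bad <- sim_parsed
  bad$cq[bad$assay == "bar" & bad$role == "positive_control"] <- NA
  calls <- callSampleProfile(bad, cfg)
  expect_true(all(grepl("invalid-run",
                        calls$notes[calls$assay == "bar"])))
  expect_false(any(grepl("invalid-run",
                         calls$notes[calls$assay == "pat"])))
  # inference refuses invalid runs unless overridden
  expect_error(interpretSample(calls, the_matrix, sample_id = 1),
               "invalid")
  cfg_ov <- screeningConfig(allow_invalid_controls = TRUE)
  expect_s4_class(interpretSample(calls, the_matrix, sample_id = 1,
                                  config = cfg_ov),
                  "ScreenInterpretation")
})
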