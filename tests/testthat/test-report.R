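test_that("tolerance evaluation applies the documented defaults", {
  mkj <- function(v) new("JunctionResult", values = c(vertical = v),
    intensities = list(), worst = v, tolerance = 0.3, pass = NA)
  expect_true(isPass(evaluateTolerances(mkj(0.29))))
  expect_false(isPass(evaluateTolerances(mkj(0.31))))
  mkb <- function(maxpd) new("VMATBandResult", R = 1, ROpen = 1,
    corrected = 1, percentDiff = c(0.2, maxpd), diffAbs = mean(abs(c(0.2, maxpd))),
    tolerance = 1.5, pass = NA)
  expect_true(isPass(evaluateTolerances(mkb(1.4))))
  expect_false(isPass(evaluateTolerances(mkb(1.6))))
  ## all leaves within 1 mm -> pass
  pf <- new("PicketFenceResult",
    measured = matrix(0, 2, 2), expected = c(0, 15),
    deviation = matrix(c(0.3, -0.8, 0.1, 0.9), 2, 2),
    detected = matrix(TRUE, 2, 2), perGapSpacing = 15,
    maxSingleLeafDeviation = 0.9, percentPassing = 100,
    leafTolerance = 1, pairs = 1:2, pass = NA)
  rep <- evaluateTolerances(pf)
  expect_true(isPass(rep))
  ## custom tolerance overrides flip the verdict
  expect_false(isPass(evaluateTolerances(pf,
    tolerances = list(picket_leaf_mm = 0.5))))
})

test_that("QA reports round-trip losslessly and re-evaluate idempotently", {
  plan <- buildJunctionPlan()
  img <- renderJunctionImage(plan, fastConfig(), noiseless(junctionError = -4))
  rep <- evaluateTolerances(analyzeJunction(img, plan), machine = "TB1",
                            date = "2026-01-01")
  f <- withr::local_tempfile(fileext = ".json")
  writeQAReport(rep, f)
  back <- readQAReport(f)
  expect_equal(back@payload, rep@payload, tolerance = 1e-12)
  expect_equal(back@pass, rep@pass)
  expect_equal(back@testType, rep@testType)
  ## idempotent re-evaluation of the deserialized report
  again <- evaluateTolerances(back)
  expect_equal(again@pass, rep@pass)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeQAReport(again, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("contingency tables count fail as the positive class", {
  same <- contingencyTable(c(TRUE, FALSE, FALSE, TRUE),
                           c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(same@counts[c("fn", "fp")]), c(0, 0))
  expect_equal(same@sensitivity, 100)
  ## truth has 5 fails, measurement catches 4
  truth <- c(rep(FALSE, 5), rep(TRUE, 5))
  meas <- c(rep(FALSE, 4), TRUE, rep(TRUE, 5))
  ct <- contingencyTable(truth, meas)
  expect_equal(ct@sensitivity, 80)
  expect_equal(unname(ct@counts), c(4, 1, 0, 5))
  expect_error(contingencyTable(logical(0), logical(0)), "empty")
  expect_error(contingencyTable(c(TRUE), c(TRUE, FALSE)), "paired")
})

test_that("the noiseless error-injection study detects every failure", {
  res <- runSensitivityStudy(config = fastConfig(), noiseSigma = 0, seed = 2)
  expect_equal(res$overall@sensitivity, 100)
  expect_equal(unname(res$overall@counts[c("fn", "fp")]), c(0, 0))
  jd <- res$details[res$details$test == "junction", ]
  expect_equal(jd$truth_pass, abs(jd$injected) < 4)  # +/-4 mm out of tolerance
  expect_true(all(res$details$truth_pass == res$details$measured_pass))
})
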