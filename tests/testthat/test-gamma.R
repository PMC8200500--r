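test_that("gamma is zero for identical images and bounded for pure dose scaling", {
  plan <- buildOpenFieldPlan(c(120, 120))
  cfg <- RenderConfig(gridShape = c(64L, 64L), pixelSpacing = 4.5)
  img <- renderOpenField(plan, cfg, noiseless())
  r <- gamma2d(img, img)
  expect_equal(r@passRate, 100)
  expect_equal(max(r@gammaMap, na.rm = TRUE), 0)
  expect_true(isPass(r))
  ## uniform scaling by exactly (1 + dd): gamma <= 1 in the flat interior
  ev <- EPIDImage(pixelData(img) * 1.03, pixelSpacing(img),
                  sid = img@sid, sad = img@sad)
  r2 <- gamma2d(img, ev, ddPct = 3, dtaMm = 3)
  co <- isoCoords(img)
  interior <- outer(abs(co$y) < 45, abs(co$x) < 45, "&")
  expect_true(all(r2@gammaMap[interior] <= 1 + 1e-9))
})

test_that("gamma equals the exhaustive brute-force oracle on small grids", {
  set.seed(7)
  mk_smooth <- function(n) {
    z <- outer(seq(0, 1, length.out = n), seq(0, 1, length.out = n),
               function(a, b) 1 + 0.3 * sin(3 * a) * cos(2 * b))
    z + matrix(rnorm(n * n, 0, 0.01), n)
  }
  for (n in c(5, 16, 32)) {
    ref <- mk_smooth(n)
    ev <- mk_smooth(n)
    r <- gamma2d(ref, ev, ddPct = 3, dtaMm = 2, lowDoseCutoffPct = 0,
                 spacingMm = c(1, 1), searchStepMm = 0.5,
                 searchRadiusFactor = 2)
    oracle <- bruteForceGamma(ref, ev, c(1, 1), dd_pct = 3, dta = 2,
                              step = 0.5, radius = 4)
    expect_all_near(r@gammaMap, oracle, 1e-6)
  }
})

test_that("low-dose pixels are excluded from the gamma pass rate", {
  ref <- matrix(0.05, 32, 32)
  ref[8:24, 8:24] <- 1
  ev <- ref * 1.5  # 50% off everywhere
  r <- gamma2d(ref, ev, ddPct = 3, dtaMm = 1, lowDoseCutoffPct = 10,
               spacingMm = c(1, 1))
  expect_true(all(is.na(r@gammaMap[ref < 0.1])))
  expect_lt(r@passRate, 50)
})
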