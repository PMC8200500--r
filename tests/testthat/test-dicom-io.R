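test_that("RT-Plan write/read is the identity on every builder plan", {
  plans <- list(
    open = buildOpenFieldPlan(),
    junction = buildJunctionPlan(junctionError = 2),
    lightrad = buildLightRadPlan(),
    picketfence = buildPicketFencePlan(leafOffsets = 0.5),
    winston_lutz = buildWinstonLutzPlan(),
    vmat_t2 = buildVmatPlan("t2_doserate_gantry"),
    vmat_t1 = buildVmatPlan("t1_rotating_picket", injectMlcErrors = TRUE),
    dlg = buildDlgPlan(gapWidths = c(2, 10)))
  for (nm in names(plans)) {
    f <- withr::local_tempfile(fileext = ".dcm")
    writeRTPlan(plans[[nm]], f)
    back <- readRTPlan(f)
    expect_equal(back, plans[[nm]], tolerance = 1e-6, label = nm)
  }
})

test_that("RT-Plan writing is deterministic and validates its input", {
  p <- buildPicketFencePlan()
  f1 <- withr::local_tempfile(fileext = ".dcm")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(p, f1, seed = 9)
  writeRTPlan(p, f2, seed = 9)
  expect_identical(readBin(f1, raw(), file.size(f1)),
                   readBin(f2, raw(), file.size(f2)))
  bad <- p
  bad@beams[[1]]$control_points[[3]]$meterset_weight <- 0  # non-monotonic
  expect_error(writeRTPlan(bad, f1), "beam 1.*non-decreasing")
})

test_that("large resampled arcs preserve their control-point count", {
  p <- buildOpenFieldPlan()
  p@beams[[1]]$control_points[[2]]$gantry_deg <- 180
  arc <- resampleControlPoints(p, maxGantryDeg = 180 / 176)
  expect_length(beams(arc)[[1]]$control_points, 177)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(arc, f)
  expect_length(beams(readRTPlan(f))[[1]]$control_points, 177)
})

test_that("written DICOM parses identically under an independent reader", {
  ## pydicom (python, same environment) as the independent DICOM oracle
  pf <- buildPicketFencePlan()
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(pf, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", f, "'); ",
    "b = d.BeamSequence[0]; ",
    "print(len(d.BeamSequence), len(b.ControlPointSequence), ",
    "int(b.BeamLimitingDeviceSequence[2].NumberOfLeafJawPairs), ",
    "float(d.FractionGroupSequence[0].ReferencedBeamSequence[0].BeamMeterset))"
  ))), stdout = TRUE)
  expect_equal(strsplit(out, " ")[[1]], c("1", "18", "60", "100.0"))
})

test_that("malformed plan files raise format errors", {
  img <- renderOpenField(buildOpenFieldPlan(), fastConfig())
  f <- withr::local_tempfile(fileext = ".dcm")
  writeEPIDImage(img, f)
  expect_error(readRTPlan(f), "no BeamSequence")
  txt <- withr::local_tempfile(fileext = ".dcm")
  writeLines("not dicom at all", txt)
  expect_error(readRTPlan(txt), "DICM|truncated")
})

test_that("EPID images round-trip through DICOM and the text sidecar", {
  img <- renderOpenField(buildOpenFieldPlan(), fastConfig(),
                         ErrorModel(noiseSigma = 0.01, seed = 4))
  fd <- withr::local_tempfile(fileext = ".dcm")
  writeEPIDImage(img, fd)
  b1 <- readEPIDImage(fd)
  expect_all_near(pixelData(b1), pixelData(img), 1e-4)  # 16-bit quantization
  expect_equal(pixelSpacing(b1), pixelSpacing(img))
  expect_equal(caxPixel(b1), caxPixel(img))
  expect_equal(b1@sid, img@sid)
  expect_equal(b1@sad, img@sad)

  fs <- withr::local_tempfile(fileext = ".json")
  writeEPIDImage(img, fs, format = "sidecar")
  b2 <- readEPIDImage(fs)
  expect_all_near(pixelData(b2), pixelData(img), 1e-8)
  expect_equal(isoSpacing(b2), isoSpacing(img))
})

test_that("isocenter-plane scaling follows SID/SAD magnification", {
  px <- matrix(1, 64, 64)
  img <- EPIDImage(px, pixelSpacing = 0.336, sid = 1500, sad = 1000)
  expect_equal(isoSpacing(img), c(0.224, 0.224))
  ## doubling SID halves the effective isocenter-plane pixel size
  img2 <- EPIDImage(px, pixelSpacing = 0.336, sid = 3000, sad = 1000)
  expect_equal(isoSpacing(img2), isoSpacing(img) / 2)
})

test_that("missing geometry metadata is flagged or fatal", {
  img <- renderOpenField(buildOpenFieldPlan(), fastConfig())
  fs <- withr::local_tempfile(fileext = ".json")
  writeEPIDImage(img, fs, format = "sidecar")
  hdr <- jsonlite::fromJSON(fs, simplifyVector = TRUE)
  hdr$pixel_spacing_mm <- NULL
  jsonlite::write_json(hdr, fs, auto_unbox = TRUE, digits = NA)
  expect_error(readEPIDImage(fs), "metadata error")
  ## missing SID falls back to the default and is flagged
  hdr2 <- jsonlite::fromJSON(fs, simplifyVector = TRUE)
  hdr2$pixel_spacing_mm <- c(0.75, 0.75)
  hdr2$sid_mm <- NULL
  jsonlite::write_json(hdr2, fs, auto_unbox = TRUE, digits = NA)
  back <- readEPIDImage(fs)
  expect_equal(back@sid, 1500)
  expect_true("sid_mm" %in% imageMeta(back)$defaults_applied)
})
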