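#' @import methods
#' @importFrom stats pnorm rnorm quantile sd
NULL

## Central data containers. All positions are millimetres in the
## isocenter plane, IEC 61217: x = crossplane (image columns),
## y = inplane (image rows). Angles are degrees in [0, 360).

#' Multileaf collimator geometry model
#'
#' An \code{MLCModel} records the transverse (inplane, y) boundaries of
#' every leaf pair at the isocenter plane.  Leaf pair \code{i} covers the
#' band \code{[boundaries[i], boundaries[i+1]]}.  The default model,
#' \code{\link{millennium120}}, is a 60-pair Millennium-120 layout:
#' 10 outer pairs of 10 mm, 40 central pairs of 5 mm, 10 outer pairs of
#' 10 mm, spanning -200 to +200 mm.
#'
#' @slot name character model label.
#' @slot boundaries numeric vector of n_pairs + 1 strictly increasing
#'   leaf-edge positions (mm at isocenter).
#' @aliases MLCModel
#' @exportClass MLCModel
setClass("MLCModel",
  representation(name = "character", boundaries = "numeric"))

setValidity("MLCModel", function(object) {
  b <- object@boundaries
  if (length(b) < 3) return("need at least 2 leaf pairs (3 boundaries)")
  if (any(!is.finite(b))) return("boundaries must be finite")
  if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
  TRUE
})

#' Construct an MLC model
#'
#' @param boundaries numeric leaf-pair boundaries (mm, isocenter plane),
#'   strictly increasing, length n_pairs + 1.
#' @param name model label.
#' @return An \code{\linkS4class{MLCModel}}.
#' @examples
#' mlc <- MLCModel(seq(-100, 100, by = 5), name = "toy40")
#' nPairs(mlc)
#' @export
MLCModel <- function(boundaries, name = "custom") {
  new("MLCModel", name = name, boundaries = as.numeric(boundaries))
}

#' Millennium-120 MLC model
#'
#' @return The default 60-pair \code{\linkS4class{MLCModel}}.
#' @examples
#' nPairs(millennium120())
#' @export
millennium120 <- function() {
  b <- c(seq(-200, -100, by = 10), seq(-95, 95, by = 5), seq(100, 200, by = 10))
  new("MLCModel", name = "Millennium-120", boundaries = b)
}

#' QA plan: ordered beams of machine control points
#'
#' A \code{QAPlan} holds one QA test as an ordered list of beams.  Each
#' beam is a plain list with elements \code{name}, \code{mu} (beam
#' meterset) and \code{control_points}, a list of control points as
#' produced by \code{\link{controlPoint}}.  The \code{meta} slot carries
#' test-specific geometry the analyzers need (nominal junction lines,
#' expected picket centers, band ROIs, BB phantom layout); it is
#' serialized into the RT-Plan so plans round-trip through DICOM.
#'
#' @slot testType one of \code{"open"}, \code{"junction"},
#'   \code{"lightrad"}, \code{"picketfence"}, \code{"dlg"},
#'   \code{"winston_lutz"}, \code{"vmat_t1"}, \code{"vmat_t2"},
#'   \code{"vmat_t3"}.
#' @slot machineName treatment machine label.
#' @slot energy beam energy label, e.g. \code{"6X"}.
#' @slot beams list of beams (see Details).
#' @slot mlc the \code{\linkS4class{MLCModel}} the leaf positions refer to.
#' @slot meta named list of analyzer metadata.
#' @aliases QAPlan
#' @exportClass QAPlan
setClass("QAPlan",
  representation(testType = "character", machineName = "character",
    energy = "character", beams = "list", mlc = "MLCModel", meta = "list"))

.qa_test_types <- c("open", "junction", "lightrad", "picketfence", "dlg",
  "winston_lutz", "vmat_t1", "vmat_t2", "vmat_t3")

.validate_cp <- function(cp, npairs) {
  if (!all(c("meterset_weight", "gantry_deg", "collimator_deg", "couch_deg",
             "jaws", "mlc_a", "mlc_b") %in% names(cp)))
    return("control point missing required fields")
  j <- cp$jaws
  if (length(j) != 4 || any(!is.finite(j)))
    return("jaws must be 4 finite values (X1, X2, Y1, Y2)")
  if (j[["X1"]] > j[["X2"]] || j[["Y1"]] > j[["Y2"]])
    return("jaws must satisfy X1 <= X2 and Y1 <= Y2")
  for (a in c("gantry_deg", "collimator_deg", "couch_deg")) {
    v <- cp[[a]]
    if (v < 0 || v >= 360) return(sprintf("%s must lie in [0, 360)", a))
  }
  if (length(cp$mlc_a) != npairs || length(cp$mlc_b) != npairs)
    return("leaf bank length does not match MLC model pair count")
  if (any(cp$mlc_a > cp$mlc_b + 1e-9))
    return("bank A leaf positions must not exceed bank B")
  TRUE
}

setValidity("QAPlan", function(object) {
  if (!object@testType %in% .qa_test_types)
    return(sprintf("unknown test type '%s'", object@testType))
  np <- length(object@mlc@boundaries) - 1L
  if (length(object@beams) < 1) return("plan must contain at least one beam")
  for (bi in seq_along(object@beams)) {
    b <- object@beams[[bi]]
    cps <- b$control_points
    if (length(cps) < 2)
      return(sprintf("beam %d needs at least 2 control points", bi))
    w <- vapply(cps, function(cp) cp$meterset_weight, numeric(1))
    if (abs(w[1]) > 1e-9 || abs(w[length(w)] - 1) > 1e-9)
      return(sprintf("beam %d cumulative meterset must start at 0 and end at 1", bi))
    if (any(diff(w) < -1e-9))
      return(sprintf("beam %d cumulative meterset weights must be non-decreasing", bi))
    for (ci in seq_along(cps)) {
      ok <- .validate_cp(cps[[ci]], np)
      if (!isTRUE(ok)) return(sprintf("beam %d, control point %d: %s", bi, ci, ok))
    }
  }
  TRUE
})

#' Construct a machine control point
#'
#' @param meterset_weight cumulative meterset weight in [0, 1].
#' @param jaws named numeric \code{c(X1, X2, Y1, Y2)}, mm at isocenter.
#' @param mlc_a,mlc_b per-leaf bank positions (mm, crossplane); bank A is
#'   the -x bank and must not exceed bank B for any pair.  Defaults park
#'   the carriages fully retracted for a 60-pair MLC.
#' @param gantry_deg,collimator_deg,couch_deg IEC angles in [0, 360).
#' @return A list with class \code{"ControlPoint"}.
#' @examples
#' cp <- controlPoint(0, jaws = c(X1 = -50, X2 = 50, Y1 = -50, Y2 = 50))
#' @export
controlPoint <- function(meterset_weight, jaws,
                         mlc_a = rep(-200, 60), mlc_b = rep(200, 60),
                         gantry_deg = 0, collimator_deg = 0, couch_deg = 0) {
  jaws <- as.numeric(jaws)
  names(jaws) <- c("X1", "X2", "Y1", "Y2")
  structure(list(
    meterset_weight = as.numeric(meterset_weight),
    gantry_deg = as.numeric(gantry_deg),
    collimator_deg = as.numeric(collimator_deg),
    couch_deg = as.numeric(couch_deg),
    jaws = jaws, mlc_a = as.numeric(mlc_a), mlc_b = as.numeric(mlc_b)),
    class = "ControlPoint")
}

#' Construct a QA plan
#'
#' Usually called by the \code{build*Plan()} family rather than directly.
#'
#' @param testType QA test identifier (see \code{\linkS4class{QAPlan}}).
#' @param beams list of beams; each a list \code{(name, mu, control_points)}.
#' @param mlc \code{\linkS4class{MLCModel}}; default Millennium-120.
#' @param machineName,energy machine and energy labels.
#' @param meta analyzer metadata list.
#' @return A validated \code{\linkS4class{QAPlan}}.
#' @export
QAPlan <- function(testType, beams, mlc = millennium120(),
                   machineName = "LINAC1", energy = "6X", meta = list()) {
  new("QAPlan", testType = testType, machineName = machineName,
      energy = energy, beams = beams, mlc = mlc, meta = meta)
}

#' EPID portal image with detector geometry
#'
#' Pixel \code{(r, c)} maps to isocenter-plane millimetres as
#' \code{x = (c - cax[2]) * spacing[2] * sad/sid},
#' \code{y = (r - cax[1]) * spacing[1] * sad/sid}.
#'
#' @slot pixels non-negative numeric matrix (rows = inplane y,
#'   columns = crossplane x), at least 32 x 32.
#' @slot pixelSpacing detector-plane pixel spacing (row, col), mm.
#' @slot sid source-to-imager distance, mm.
#' @slot sad source-to-axis distance, mm (1000 for conventional linacs).
#' @slot cax fractional (row, col) pixel index of the beam central axis.
#' @slot meta acquisition metadata list (gantry_deg, machine, test_type, ...).
#' @aliases EPIDImage
#' @exportClass EPIDImage
setClass("EPIDImage",
  representation(pixels = "matrix", pixelSpacing = "numeric",
    sid = "numeric", sad = "numeric", cax = "numeric", meta = "list"))

setValidity("EPIDImage", function(object) {
  p <- object@pixels
  if (nrow(p) < 32 || ncol(p) < 32) return("image must be at least 32 x 32")
  if (any(!is.finite(p)) || any(p < -1e-9)) return("pixels must be finite and non-negative")
  if (length(object@pixelSpacing) != 2 || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values")
  if (object@sid <= 0 || object@sad <= 0) return("sid and sad must be positive")
  if (length(object@cax) != 2) return("cax must be (row, col)")
  TRUE
})

#' Construct an EPID image
#'
#' @param pixels numeric matrix of intensities (arbitrary units, >= 0).
#' @param pixelSpacing detector-plane spacing (row, col) in mm; a scalar
#'   is recycled.
#' @param sid source-to-imager distance (mm).
#' @param sad source-to-axis distance (mm).
#' @param cax central-axis (row, col) pixel, fractional allowed; default
#'   the geometric grid center.
#' @param meta metadata list.
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
EPIDImage <- function(pixels, pixelSpacing, sid = 1500, sad = 1000,
                      cax = NULL, meta = list()) {
  pixelSpacing <- rep(as.numeric(pixelSpacing), length.out = 2)
  if (is.null(cax)) cax <- (dim(pixels) + 1) / 2
  new("EPIDImage", pixels = pixels, pixelSpacing = pixelSpacing,
      sid = as.numeric(sid), sad = as.numeric(sad),
      cax = as.numeric(cax), meta = meta)
}

#' Injectable delivery-error model for the synthetic renderer
#'
#' @slot leafOffset mm added to every delivered leaf-bank position
#'   (scalar) or per active leaf pair (vector).
#' @slot junctionError signed mm; positive opens a gap between abutting
#'   jaw-defined fields, negative overlaps them.
#' @slot phantomShift (x, y) mm in-plane shift of the BB phantom.
#' @slot ssd phantom source-to-surface distance, mm (nominal 1000).
#' @slot bandPerturbation per-band intensity multipliers (> 0).
#' @slot noiseSigma relative Gaussian noise (fraction of the plateau).
#' @slot seed RNG seed used by the renderer.
#' @aliases ErrorModel
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(leafOffset = "numeric", junctionError = "numeric",
    phantomShift = "numeric", ssd = "numeric", bandPerturbation = "numeric",
    noiseSigma = "numeric", seed = "numeric"))

setValidity("ErrorModel", function(object) {
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (any(object@bandPerturbation <= 0)) return("band multipliers must be > 0")
  if (object@ssd <= 0) return("ssd must be positive")
  if (length(object@phantomShift) != 2) return("phantomShift must be (x, y)")
  TRUE
})

#' Construct an error model
#'
#' @param leafOffset scalar or per-pair leaf offset (mm).
#' @param junctionError signed junction gap(+)/overlap(-) (mm).
#' @param phantomShift phantom in-plane shift \code{c(x, y)} (mm).
#' @param ssd phantom SSD (mm).
#' @param bandPerturbation per-band multipliers, recycled to the band count.
#' @param noiseSigma relative Gaussian noise level.
#' @param seed renderer RNG seed.
#' @return An \code{\linkS4class{ErrorModel}}.  The default is an
#'   error-free, noiseless delivery.
#' @export
ErrorModel <- function(leafOffset = 0, junctionError = 0,
                       phantomShift = c(0, 0), ssd = 1000,
                       bandPerturbation = 1, noiseSigma = 0, seed = 1) {
  new("ErrorModel", leafOffset = as.numeric(leafOffset),
      junctionError = as.numeric(junctionError),
      phantomShift = as.numeric(phantomShift), ssd = as.numeric(ssd),
      bandPerturbation = as.numeric(bandPerturbation),
      noiseSigma = as.numeric(noiseSigma), seed = as.numeric(seed))
}

#' Renderer configuration
#'
#' @slot gridShape detector grid (rows, cols).
#' @slot pixelSpacing detector-plane pixel spacing (row, col), mm.
#' @slot sid source-to-imager distance, mm.
#' @slot sad source-to-axis distance, mm.
#' @slot penumbraSigma Gaussian penumbra width at isocenter, mm.
#' @slot backgroundLevel out-of-field intensity as a fraction of the
#'   open-field plateau.
#' @slot bbContrast relative attenuation of a ball bearing (0..1).
#' @slot bbDiameter BB diameter, mm.
#' @slot offAxisBow quadratic off-axis intensity roll-off coefficient
#'   (0 disables; positive values dim the field corners).
#' @aliases RenderConfig
#' @exportClass RenderConfig
setClass("RenderConfig",
  representation(gridShape = "integer", pixelSpacing = "numeric",
    sid = "numeric", sad = "numeric", penumbraSigma = "numeric",
    backgroundLevel = "numeric", bbContrast = "numeric",
    bbDiameter = "numeric", offAxisBow = "numeric"))

setValidity("RenderConfig", function(object) {
  if (object@penumbraSigma <= 0) return("penumbraSigma must be > 0")
  if (any(object@gridShape < 32)) return("grid must be at least 32 x 32")
  if (any(object@pixelSpacing <= 0)) return("pixelSpacing must be > 0")
  TRUE
})

#' Construct a renderer configuration
#'
#' The default is a 512 x 512 panel with 0.75 mm detector pixels at
#' 1500 mm SID (0.5 mm isocenter-plane sampling over a +/-128 mm field
#' of view).
#'
#' @param gridShape detector grid \code{c(rows, cols)}.
#' @param pixelSpacing detector pixel spacing (mm); scalar recycled.
#' @param sid,sad imaging geometry (mm).
#' @param penumbraSigma penumbra sigma at isocenter (mm).
#' @param backgroundLevel out-of-field fraction of the plateau.
#' @param bbContrast,bbDiameter BB attenuation depth and diameter (mm).
#' @param offAxisBow quadratic off-axis roll-off coefficient.
#' @return A \code{\linkS4class{RenderConfig}}.
#' @export
RenderConfig <- function(gridShape = c(512L, 512L), pixelSpacing = 0.75,
                         sid = 1500, sad = 1000, penumbraSigma = 1.5,
                         backgroundLevel = 0.02, bbContrast = 0.25,
                         bbDiameter = 4, offAxisBow = 0) {
  new("RenderConfig", gridShape = as.integer(rep(gridShape, length.out = 2)),
      pixelSpacing = rep(as.numeric(pixelSpacing), length.out = 2),
      sid = as.numeric(sid), sad = as.numeric(sad),
      penumbraSigma = as.numeric(penumbraSigma),
      backgroundLevel = as.numeric(backgroundLevel),
      bbContrast = as.numeric(bbContrast), bbDiameter = as.numeric(bbDiameter),
      offAxisBow = as.numeric(offAxisBow))
}

#' Picket fence test specification
#'
#' @slot nPickets number of pickets (stripe dwell positions).
#' @slot spacing center-to-center picket spacing, mm.
#' @slot gap leaf-gap (slit) width, mm.
#' @slot activePairs integer range \code{c(first, last)} of leaf pairs
#'   driven by the test; \code{integer(0)} selects every pair inside the
#'   Y jaw aperture.
#' @aliases PicketFenceSpec
#' @exportClass PicketFenceSpec
setClass("PicketFenceSpec",
  representation(nPickets = "integer", spacing = "numeric",
    gap = "numeric", activePairs = "integer"))

setValidity("PicketFenceSpec", function(object) {
  if (object@nPickets < 1) return("need at least one picket")
  if (object@gap <= 0) return("gap must be > 0")
  if (object@spacing <= 0) return("spacing must be > 0")
  TRUE
})

#' Construct a picket fence specification
#'
#' Defaults follow the conventional 9-picket, 15 mm spacing layout.
#'
#' @param nPickets number of pickets.
#' @param spacing center-to-center spacing (mm).
#' @param gap slit width (mm).
#' @param activePairs optional \code{c(first, last)} leaf-pair range.
#' @return A \code{\linkS4class{PicketFenceSpec}}.
#' @export
PicketFenceSpec <- function(nPickets = 9, spacing = 15, gap = 2,
                            activePairs = integer(0)) {
  new("PicketFenceSpec", nPickets = as.integer(nPickets),
      spacing = as.numeric(spacing), gap = as.numeric(gap),
      activePairs = as.integer(activePairs))
}

## ---- test result containers -------------------------------------------

#' Virtual parent of all per-test result objects
#' @aliases QATestResult
#' @exportClass QATestResult
setClass("QATestResult", representation("VIRTUAL", pass = "logical"))

#' Junction test result
#' @slot values per-junction dimensionless junction statistics.
#' @slot intensities per-junction list of \code{c(I_junc, I_BG, I_rad)}.
#' @slot worst the junction statistic of largest magnitude.
#' @slot tolerance tolerance applied for \code{pass}.
#' @slot pass TRUE when all junction values are within tolerance.
#' @aliases JunctionResult
#' @exportClass JunctionResult
setClass("JunctionResult", contains = "QATestResult",
  representation(values = "numeric", intensities = "list",
    worst = "numeric", tolerance = "numeric"))

#' Light-radiation coincidence result
#' @slot bbCenters data.frame of detected BB centroids (x, y, radius,
#'   roundness, index, inner).
#' @slot innerDistances per-inner-BB distance to the nearest 50\%
#'   radiation field edge, mm.
#' @slot deviations \code{innerDistances - 5} mm.
#' @slot detectedCount number of BBs found.
#' @slot tolerance mm tolerance applied.
#' @slot pass TRUE when every inner deviation is within tolerance.
#' @aliases LightRadResult
#' @exportClass LightRadResult
setClass("LightRadResult", contains = "QATestResult",
  representation(bbCenters = "data.frame", innerDistances = "numeric",
    deviations = "numeric", detectedCount = "integer", tolerance = "numeric"))

#' Picket fence result
#' @slot measured pairs x pickets matrix of detected stripe positions, mm.
#' @slot expected nominal picket centers, mm.
#' @slot deviation \code{expected - measured}, mm.
#' @slot detected logical matrix of successfully detected stripes.
#' @slot perGapSpacing mean measured picket-to-picket distance per gap, mm.
#' @slot maxSingleLeafDeviation largest absolute deviation, mm.
#' @slot percentPassing percent of detected leaves within the leaf
#'   tolerance (1 mm default).
#' @slot leafTolerance mm tolerance used for percentPassing.
#' @slot pairs leaf-pair indices analyzed.
#' @slot pass TRUE when percentPassing == 100.
#' @aliases PicketFenceResult
#' @exportClass PicketFenceResult
setClass("PicketFenceResult", contains = "QATestResult",
  representation(measured = "matrix", expected = "numeric",
    deviation = "matrix", detected = "matrix", perGapSpacing = "numeric",
    maxSingleLeafDeviation = "numeric", percentPassing = "numeric",
    leafTolerance = "numeric", pairs = "integer"))

#' VMAT band statistic result
#' @slot R per-band mean ROI reading of the test image.
#' @slot ROpen per-band mean ROI reading of the open-field image.
#' @slot corrected \code{R / ROpen} per band.
#' @slot percentDiff per-band percent difference from the mean corrected
#'   reading.
#' @slot diffAbs mean absolute percent difference.
#' @slot tolerance percent tolerance applied.
#' @slot pass TRUE when every band is within tolerance.
#' @aliases VMATBandResult
#' @exportClass VMATBandResult
setClass("VMATBandResult", contains = "QATestResult",
  representation(R = "numeric", ROpen = "numeric", corrected = "numeric",
    percentDiff = "numeric", diffAbs = "numeric", tolerance = "numeric"))

#' 2D gamma evaluation result
#' @slot gammaMap per-pixel gamma index (NA below the low-dose cutoff).
#' @slot passRate percent of evaluated pixels with gamma <= 1.
#' @slot ddPct,dtaMm,lowDoseCutoffPct criteria used.
#' @slot pass TRUE when passRate meets the configured threshold.
#' @aliases GammaResult
#' @exportClass GammaResult
setClass("GammaResult", contains = "QATestResult",
  representation(gammaMap = "matrix", passRate = "numeric",
    ddPct = "numeric", dtaMm = "numeric", lowDoseCutoffPct = "numeric"))

#' Winston-Lutz result
#' @slot bbCenter detected BB centroid (x, y), mm.
#' @slot fieldCenter radiation field center (x, y), mm.
#' @slot offset \code{bbCenter - fieldCenter}, mm.
#' @slot magnitude Euclidean norm of \code{offset}, mm.
#' @slot tolerance mm tolerance applied.
#' @slot pass TRUE when magnitude is within tolerance.
#' @aliases WinstonLutzResult
#' @exportClass WinstonLutzResult
setClass("WinstonLutzResult", contains = "QATestResult",
  representation(bbCenter = "numeric", fieldCenter = "numeric",
    offset = "numeric", magnitude = "numeric", tolerance = "numeric"))

#' Serializable QA report
#' @slot testType QA test identifier.
#' @slot machine machine label.
#' @slot date ISO date string.
#' @slot payload named list of measured quantities.
#' @slot tolerances named list of tolerances applied.
#' @slot pass overall pass flag.
#' @aliases QAReport
#' @exportClass QAReport
setClass("QAReport",
  representation(testType = "character", machine = "character",
    date = "character", payload = "list", tolerances = "list",
    pass = "logical"))

#' 2x2 pass/fail contingency table
#'
#' Failing a test is the positive class: sensitivity is the percentage
#' of true failures that the measured analysis also flags.
#'
#' @slot counts named counts \code{tp, fn, fp, tn} (tp = both fail).
#' @slot sensitivity percent of true failures detected.
#' @aliases ContingencyTable
#' @exportClass ContingencyTable
setClass("ContingencyTable",
  representation(counts = "numeric", sensitivity = "numeric"))
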