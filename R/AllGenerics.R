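## Accessor generics. Slot access from user code is discouraged; these
## are the supported surface.

#' @name epidqa-accessors
#' @title Accessors for epidqa objects
#' @description Small accessor functions for the S4 containers.
#' @param object an epidqa object.
#' @return The requested component.
NULL

#' @rdname epidqa-accessors
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))

#' @rdname epidqa-accessors
#' @export
setGeneric("leafBoundaries", function(object) standardGeneric("leafBoundaries"))

#' @rdname epidqa-accessors
#' @export
setGeneric("testType", function(object) standardGeneric("testType"))

#' @rdname epidqa-accessors
#' @export
setGeneric("beams", function(object) standardGeneric("beams"))

#' @rdname epidqa-accessors
#' @export
setGeneric("mlcModel", function(object) standardGeneric("mlcModel"))

#' @rdname epidqa-accessors
#' @export
setGeneric("planMeta", function(object) standardGeneric("planMeta"))

#' @rdname epidqa-accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname epidqa-accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname epidqa-accessors
#' @export
setGeneric("isoSpacing", function(object) standardGeneric("isoSpacing"))

#' @rdname epidqa-accessors
#' @export
setGeneric("caxPixel", function(object) standardGeneric("caxPixel"))

#' @rdname epidqa-accessors
#' @export
setGeneric("imageMeta", function(object) standardGeneric("imageMeta"))

#' @rdname epidqa-accessors
#' @export
setGeneric("isPass", function(object) standardGeneric("isPass"))

setMethod("nPairs", "MLCModel", function(object) length(object@boundaries) - 1L)
setMethod("leafBoundaries", "MLCModel", function(object) object@boundaries)

setMethod("testType", "QAPlan", function(object) object@testType)
setMethod("beams", "QAPlan", function(object) object@beams)
setMethod("mlcModel", "QAPlan", function(object) object@mlc)
setMethod("planMeta", "QAPlan", function(object) object@meta)

setMethod("pixelData", "EPIDImage", function(object) object@pixels)
setMethod("pixelSpacing", "EPIDImage", function(object) object@pixelSpacing)
setMethod("caxPixel", "EPIDImage", function(object) object@cax)
setMethod("imageMeta", "EPIDImage", function(object) object@meta)

## isocenter-plane sampling: detector spacing demagnified by sad/sid
setMethod("isoSpacing", "EPIDImage", function(object)
  object@pixelSpacing * object@sad / object@sid)

setMethod("isPass", "QATestResult", function(object) object@pass)
setMethod("isPass", "QAReport", function(object) object@pass)

#' Isocenter-plane coordinates of image pixels
#'
#' @param image an \code{\linkS4class{EPIDImage}}.
#' @return list with \code{x} (per-column crossplane mm) and \code{y}
#'   (per-row inplane mm) at the isocenter plane.
#' @export
isoCoords <- function(image) {
  sp <- isoSpacing(image)
  list(
    y = (seq_len(nrow(image@pixels)) - image@cax[1]) * sp[1],
    x = (seq_len(ncol(image@pixels)) - image@cax[2]) * sp[2])
}

setMethod("show", "MLCModel", function(object) {
  cat(sprintf("MLCModel '%s': %d leaf pairs spanning %g..%g mm\n",
    object@name, nPairs(object), min(object@boundaries), max(object@boundaries)))
})

setMethod("show", "QAPlan", function(object) {
  ncp <- vapply(object@beams, function(b) length(b$control_points), integer(1))
  cat(sprintf("QAPlan <%s> on %s (%s): %d beam(s), control points %s\n",
    object@testType, object@machineName, object@energy,
    length(object@beams), paste(ncp, collapse = "/")))
})

setMethod("show", "EPIDImage", function(object) {
  sp <- isoSpacing(object)
  cat(sprintf(
    "EPIDImage %dx%d px, %.3f x %.3f mm at isocenter (SID %g / SAD %g)\n",
    nrow(object@pixels), ncol(object@pixels), sp[1], sp[2],
    object@sid, object@sad))
})

.pf <- function(x) if (isTRUE(x)) "PASS" else "FAIL"

setMethod("show", "JunctionResult", function(object) {
  cat(sprintf("Junction test [%s]: worst %.4f (tolerance +/-%g)\n",
    .pf(object@pass), object@worst, object@tolerance))
  for (nm in names(object@values))
    cat(sprintf("  %s: %.4f\n", nm, object@values[[nm]]))
})

setMethod("show", "LightRadResult", function(object) {
  cat(sprintf(
    "Light-rad test [%s]: %d BBs detected; inner deviations %s mm (tol +/-%g)\n",
    .pf(object@pass), object@detectedCount,
    paste(sprintf("%+.2f", object@deviations), collapse = ", "),
    object@tolerance))
})

setMethod("show", "PicketFenceResult", function(object) {
  cat(sprintf(
    "Picket fence [%s]: %d pairs x %d pickets; mean spacing %.3f mm; max dev %.3f mm; %.1f%% leaves within %g mm\n",
    .pf(object@pass), nrow(object@measured), ncol(object@measured),
    mean(object@perGapSpacing), object@maxSingleLeafDeviation,
    object@percentPassing, object@leafTolerance))
})

setMethod("show", "VMATBandResult", function(object) {
  cat(sprintf(
    "VMAT bands [%s]: %d bands; percent diffs %s; Diff_ABS %.3f%% (tol +/-%g%%)\n",
    .pf(object@pass), length(object@R),
    paste(sprintf("%+.2f", object@percentDiff), collapse = ", "),
    object@diffAbs, object@tolerance))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("Gamma %g%%/%g mm (cutoff %g%%) [%s]: pass rate %.2f%%\n",
    object@ddPct, object@dtaMm, object@lowDoseCutoffPct,
    .pf(object@pass), object@passRate))
})

setMethod("show", "WinstonLutzResult", function(object) {
  cat(sprintf("Winston-Lutz [%s]: offset (%+.2f, %+.2f) mm, |offset| %.3f mm\n",
    .pf(object@pass), object@offset[1], object@offset[2], object@magnitude))
})

setMethod("show", "QAReport", function(object) {
  cat(sprintf("QAReport <%s> %s %s: %s\n", object@testType, object@machine,
    object@date, .pf(object@pass)))
})

setMethod("show", "ContingencyTable", function(object) {
  k <- object@counts
  cat(sprintf(
    "Contingency: fail/fail %d, fail/pass %d, pass/fail %d, pass/pass %d; sensitivity %.1f%%\n",
    k[["tp"]], k[["fn"]], k[["fp"]], k[["tn"]], object@sensitivity))
})
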