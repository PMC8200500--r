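## Portal-image analyzers.  Shared conventions: the radiation field edge
## is the 50% crossing of the background-subtracted plateau, located by
## linear sub-pixel interpolation; all positions are isocenter-plane mm.

.corner_background <- function(px, n = 16) {
  r <- nrow(px); c <- ncol(px)
  mean(c(px[1:n, 1:n], px[1:n, (c - n + 1):c],
         px[(r - n + 1):r, 1:n], px[(r - n + 1):r, (c - n + 1):c]))
}

.plateau_level <- function(px) {
  mx <- max(px)
  mean(px[px > 0.8 * mx])
}

## sub-pixel 50% crossings of a 1D profile; returns outermost rising and
## falling crossing positions (in the coordinate vector v)
.edge_crossings <- function(v, f, thr) {
  above <- f >= thr
  if (!any(above) || all(above)) return(NULL)
  idx <- which(above)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  lo <- if (i1 == 1) v[1] else {
    t <- (thr - f[i1 - 1]) / (f[i1] - f[i1 - 1])
    v[i1 - 1] + t * (v[i1] - v[i1 - 1])
  }
  hi <- if (i2 == length(f)) v[length(v)] else {
    t <- (thr - f[i2 + 1]) / (f[i2] - f[i2 + 1])
    v[i2 + 1] + t * (v[i2] - v[i2 + 1])
  }
  c(lo, hi)
}

#' Detect the four radiation field edges
#'
#' Mean profiles through the high-intensity region are thresholded at
#' 50\% of the background-subtracted plateau; crossings are located by
#' linear interpolation, giving sub-pixel edge positions.
#'
#' @param image an \code{\linkS4class{EPIDImage}} containing one
#'   rectangular field.
#' @param bandMm half-width of the averaging band around the field
#'   center, mm.
#' @return Named numeric \code{c(X1, X2, Y1, Y2)}, mm isocenter plane.
#' @export
detectFieldEdges <- function(image, bandMm = 5) {
  px <- image@pixels
  co <- isoCoords(image)
  bg <- .corner_background(px)
  pl <- .plateau_level(px)
  if (pl - bg < 10 * max(sd(as.vector(px)) / 100, 1e-6) || pl <= bg * 1.5)
    stop("detection error: no field found (flat image)", call. = FALSE)
  thr <- bg + 0.5 * (pl - bg)
  mask <- px >= thr
  cy <- sum(co$y * rowSums(mask)) / sum(mask)
  cx <- sum(co$x * colSums(mask)) / sum(mask)
  rows <- which(abs(co$y - cy) <= bandMm)
  cols <- which(abs(co$x - cx) <= bandMm)
  ex <- .edge_crossings(co$x, colMeans(px[rows, , drop = FALSE]), thr)
  ey <- .edge_crossings(co$y, rowMeans(px[, cols, drop = FALSE]), thr)
  if (is.null(ex) || is.null(ey))
    stop("detection error: could not locate 50% crossings", call. = FALSE)
  c(X1 = ex[1], X2 = ex[2], Y1 = ey[1], Y2 = ey[2])
}

#' Junction intensity statistic
#'
#' The dimensionless junction dose statistic
#' \deqn{J = (I_{junc} - I_{BG}) / (I_{rad} - I_{BG}) - 1,}
#' zero for a perfectly matched junction, +1 when the junction doubles
#' the in-field reading, -1 when it falls to background.
#'
#' @param iJunc intensity at the junction between the fields.
#' @param iBg background reading.
#' @param iRad reading inside the open field.
#' @return The junction statistic (dimensionless).
#' @examples
#' junctionStatistic(80, 10, 100)  # -0.2222...
#' @export
junctionStatistic <- function(iJunc, iBg, iRad) {
  if (iRad <= iBg)
    stop("degenerate input: I_rad must exceed I_BG", call. = FALSE)
  (iJunc - iBg) / (iRad - iBg) - 1
}

#' Analyze a junction-test image
#'
#' For every junction recorded in the plan metadata, a profile is
#' extracted perpendicular to the junction line (averaged over a band
#' sampled 10-30 mm away from any crossing junction), the junction
#' intensity is the extremum within +/-3 mm of the nominal line, the
#' in-field reading is the plateau sampled at least 10 mm from the
#' junction and the field edges, and the background comes from the image
#' corners.  The worst junction statistic decides pass/fail.
#'
#' @param image an \code{\linkS4class{EPIDImage}}.
#' @param plan the junction \code{\linkS4class{QAPlan}}.
#' @param tolerance pass tolerance on the junction statistic.
#' @param windowMm search half-window around the nominal line, mm.
#' @return A \code{\linkS4class{JunctionResult}}.
#' @export
analyzeJunction <- function(image, plan, tolerance = 0.3, windowMm = 3) {
  jm <- plan@meta$junctions
  if (is.null(jm) || !length(jm))
    stop("plan carries no junction metadata", call. = FALSE)
  px <- image@pixels
  co <- isoCoords(image)
  bg <- .corner_background(px)
  h <- (plan@meta$field_mm %||% 120) / 2
  values <- numeric(0)
  intens <- list()
  for (axis in names(jm)) {
    j <- jm[[axis]]
    line <- j$line_mm
    if (axis == "vertical") {
      band <- which(co$y >= 10 & co$y <= 30)
      prof <- colMeans(px[band, , drop = FALSE])
      u <- co$x
    } else {
      band <- which(co$x >= 10 & co$x <= 30)
      prof <- rowMeans(px[, band, drop = FALSE])
      u <- co$y
    }
    infield <- abs(u - line) >= 10 & u >= -h + 10 & u <= h - 10
    iRad <- mean(prof[infield])
    win <- which(abs(u - line) <= windowMm)
    iJunc <- prof[win][which.max(abs(prof[win] - iRad))]
    values[[axis]] <- junctionStatistic(iJunc, bg, iRad)
    intens[[axis]] <- c(I_junc = iJunc, I_BG = bg, I_rad = iRad)
  }
  worst <- values[which.max(abs(values))]
  new("JunctionResult", values = values, intensities = intens,
      worst = unname(worst), tolerance = tolerance,
      pass = all(abs(values) <= tolerance))
}

#' Detect ball bearings in an open-field image
#'
#' In-field attenuation blobs are segmented at half the maximum
#' in-field depression, labelled by connected components, and scored
#' for circularity as area / (pi * r_max^2) -- 1 for a disk, about 0.64
#' for a square.  Candidates failing the roundness or size filter are
#' dropped, as are blobs whose centroid lies within one BB radius plus
#' one penumbra width of a 50\% field edge (a BB merged with the edge
#' cannot be localized and is reported as undetected).
#'
#' @param image an \code{\linkS4class{EPIDImage}}.
#' @param expectedRadiusMm nominal BB radius; detections outside
#'   +/-50\% are rejected.
#' @param roundnessMin minimum circularity score.
#' @param penumbraMm assumed penumbra width for the edge-merge rule.
#' @return data.frame with columns \code{x}, \code{y} (intensity-weighted
#'   centroid, mm), \code{radius_mm}, \code{roundness}; zero rows when
#'   nothing is found.
#' @export
detectBBs <- function(image, expectedRadiusMm = 2, roundnessMin = 0.9,
                      penumbraMm = 1.5) {
  px <- image@pixels
  co <- isoCoords(image)
  sp <- isoSpacing(image)
  edges <- detectFieldEdges(image)
  bg <- .corner_background(px)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      radius_mm = numeric(0), roundness = numeric(0))
  ## interior of the field, clear of the penumbra
  m <- 1.5 * penumbraMm
  infield <- outer(co$y > edges[["Y1"]] + m & co$y < edges[["Y2"]] - m,
                   co$x > edges[["X1"]] + m & co$x < edges[["X2"]] - m, "&")
  if (!any(infield)) return(empty)
  pl <- mean(px[infield & px > 0.8 * max(px[infield])])
  ## flat-field correction: divide out the expected open-field shape so
  ## the edge roll-off does not smear blobs near the field border; the
  ## segmentation region extends into the penumbra (where the division
  ## is still stable), so near-edge BBs keep their circular footprint
  base <- bg + (pl - bg) *
    outer(.edge_profile(co$y, edges[["Y1"]], edges[["Y2"]], penumbraMm),
          .edge_profile(co$x, edges[["X1"]], edges[["X2"]], penumbraMm))
  ratio <- px / pmax(base, 1e-6)
  ## light smoothing stabilizes the blob boundary under pixel noise
  ratio <- EBImage::gblur(ratio, sigma = 1)
  seg <- base > bg + 0.35 * (pl - bg)
  depth <- 1 - min(ratio[infield])
  if (depth < 0.08) return(empty)
  mask <- seg & (ratio < 1 - 0.5 * depth)
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(px)))
  feats <- EBImage::computeFeatures.shape(lab)
  if (is.null(feats) || nrow(feats) == 0) return(empty)
  pxmm <- sqrt(prod(sp))
  out <- empty
  for (k in seq_len(nrow(feats))) {
    idx <- which(lab == k, arr.ind = TRUE)
    w <- 1 - ratio[lab == k]
    w <- pmax(w, 0)
    if (sum(w) <= 0) next
    cy <- sum(co$y[idx[, 1]] * w) / sum(w)
    cx <- sum(co$x[idx[, 2]] * w) / sum(w)
    area_mm2 <- feats[k, "s.area"] * prod(sp)
    r_eq <- sqrt(area_mm2 / pi)
    rmax <- feats[k, "s.radius.max"] * pxmm
    roundness <- area_mm2 / (pi * rmax^2)
    if (roundness < roundnessMin) next
    if (r_eq < 0.5 * expectedRadiusMm || r_eq > 1.5 * expectedRadiusMm) next
    edge_dist <- min(cx - edges[["X1"]], edges[["X2"]] - cx,
                     cy - edges[["Y1"]], edges[["Y2"]] - cy)
    if (edge_dist < 1.5 * penumbraMm + 0.5) next  # merged with the edge
    out <- rbind(out, data.frame(x = cx, y = cy, radius_mm = r_eq,
                                 roundness = roundness))
  }
  out
}

#' Analyze a light-radiation coincidence image
#'
#' Detects the BBs and the 50\% radiation field edges, classifies inner
#' vs outer BBs by their edge distance, and reports each inner BB's
#' distance to its nearest field edge and the deviation from the
#' expected 5 mm inset.  BB indices run clockwise starting from the
#' patient-right (+x) side, inner ring first.
#'
#' @param image an \code{\linkS4class{EPIDImage}}.
#' @param plan the lightrad \code{\linkS4class{QAPlan}}.
#' @param toleranceMm pass tolerance on the inner-BB deviation.
#' @return A \code{\linkS4class{LightRadResult}}.
#' @export
analyzeLightRad <- function(image, plan, toleranceMm = 2) {
  lr <- plan@meta$lightrad
  if (is.null(lr)) stop("plan carries no lightrad metadata", call. = FALSE)
  edges <- detectFieldEdges(image)
  bbs <- detectBBs(image, expectedRadiusMm = 2)
  if (nrow(bbs) == 0)
    stop("detection error: no ball bearings found", call. = FALSE)
  inner_inset <- lr$inner_inset_mm %||% 5
  outer_inset <- lr$outer_inset_mm %||% 25
  edist <- pmin(bbs$x - edges[["X1"]], edges[["X2"]] - bbs$x,
                bbs$y - edges[["Y1"]], edges[["Y2"]] - bbs$y)
  bbs$edge_distance_mm <- edist
  bbs$inner <- edist < (inner_inset + outer_inset) / 2
  ## clockwise ordering from +x within each ring (image y up the rows)
  ang <- (-atan2(bbs$y, bbs$x)) %% (2 * pi)
  ord <- order(!bbs$inner, ang)
  bbs <- bbs[ord, , drop = FALSE]
  bbs$index <- seq_len(nrow(bbs))
  rownames(bbs) <- NULL
  inner_d <- bbs$edge_distance_mm[bbs$inner]
  dev <- inner_d - inner_inset
  new("LightRadResult", bbCenters = bbs, innerDistances = inner_d,
      deviations = dev, detectedCount = nrow(bbs),
      tolerance = toleranceMm,
      pass = length(dev) > 0 && all(abs(dev) <= toleranceMm))
}

.parabolic_peak <- function(v, f, i) {
  if (i <= 1 || i >= length(f)) return(v[i])
  d2 <- f[i - 1] - 2 * f[i] + f[i + 1]
  if (d2 >= 0) return(v[i])
  v[i] + 0.5 * (f[i - 1] - f[i + 1]) / d2 * (v[i] - v[i - 1])
}

#' Analyze a picket-fence image
#'
#' For every active leaf pair, the crossplane intensity profile is
#' averaged over the central 60\% of the pair's row band; within
#' +/- half the picket spacing of each expected picket center, the
#' stripe position is the parabolically interpolated location of the
#' profile maximum.  Deviations are reported as expected minus measured
#' (an injected +2 mm leaf offset therefore appears as a -2 mm mean
#' deviation).  Stripes with no maximum above half the stripe plateau
#' are flagged undetected and excluded from the passing percentage.
#'
#' @param image an \code{\linkS4class{EPIDImage}}.
#' @param plan the picket-fence \code{\linkS4class{QAPlan}} (carries the
#'   expected picket centers).
#' @param mlc MLC model; defaults to the plan's.
#' @param leafToleranceMm leaf-passing tolerance, mm.
#' @return A \code{\linkS4class{PicketFenceResult}}.
#' @export
analyzePicketFence <- function(image, plan, mlc = NULL,
                               leafToleranceMm = 1) {
  pk <- plan@meta$picket
  if (is.null(pk)) stop("plan carries no picket metadata", call. = FALSE)
  if (is.null(mlc)) mlc <- plan@mlc
  px <- image@pixels
  co <- isoCoords(image)
  centers <- pk$centers_mm
  spacing <- pk$spacing_mm
  act <- seq.int(pk$active_pairs[1], pk$active_pairs[2])
  bd <- leafBoundaries(mlc)
  yap <- pk$y_aperture_mm %||% c(-Inf, Inf)
  measured <- matrix(NA_real_, length(act), length(centers))
  detected <- matrix(FALSE, length(act), length(centers))
  plateau <- .plateau_level(px)
  bg <- .corner_background(px)
  for (ai in seq_along(act)) {
    p <- act[ai]
    lo <- max(bd[p], yap[1]); hi <- min(bd[p + 1], yap[2])
    mid <- (lo + hi) / 2; hw <- 0.3 * (hi - lo)  # central 60%
    rows <- which(co$y >= mid - hw & co$y <= mid + hw)
    if (length(rows) < 1) next
    prof <- colMeans(px[rows, , drop = FALSE])
    for (k in seq_along(centers)) {
      win <- which(abs(co$x - centers[k]) <= spacing / 2 - 0.5)
      if (!length(win)) next
      i <- win[which.max(prof[win])]
      if (prof[i] < bg + 0.5 * (plateau - bg)) next
      measured[ai, k] <- .parabolic_peak(co$x, prof, i)
      detected[ai, k] <- TRUE
    }
  }
  if (!any(detected))
    stop("detection error: no picket stripes found", call. = FALSE)
  if (any(!detected))
    warning(sum(!detected), " stripe(s) undetected; excluded from the ",
            "passing percentage")
  deviation <- -sweep(measured, 2, centers)  # expected - measured
  per_gap <- colMeans(t(apply(measured, 1, diff)), na.rm = TRUE)
  if (length(centers) == 2) per_gap <- mean(per_gap, na.rm = TRUE)
  devs <- deviation[detected]
  new("PicketFenceResult", measured = measured, expected = centers,
      deviation = deviation, detected = detected,
      perGapSpacing = as.numeric(per_gap),
      maxSingleLeafDeviation = max(abs(devs)),
      percentPassing = 100 * mean(abs(devs) <= leafToleranceMm),
      leafTolerance = leafToleranceMm,
      pairs = as.integer(act),
      pass = all(abs(devs) <= leafToleranceMm))
}

.roi_mean <- function(image, roi) {
  co <- isoCoords(image)
  rows <- which(co$y >= roi[["y1"]] & co$y <= roi[["y2"]])
  cols <- which(co$x >= roi[["x1"]] & co$x <= roi[["x2"]])
  mean(image@pixels[rows, cols])
}

#' VMAT band statistic
#'
#' Per band: the corrected reading is the mean test-image ROI value
#' normalized to the open-field delivery, \eqn{R / R_{Open}}; the
#' per-band percent difference is taken from the mean corrected reading
#' across bands, and the summary statistic is the mean of the absolute
#' percent differences.  A band set passes when every percent
#' difference is within the tolerance (1.5\% default).
#'
#' @param testImage banded delivery \code{\linkS4class{EPIDImage}}.
#' @param openImage open-field reference with identical geometry.
#' @param bandRois list of ROI rectangles \code{c(x1, x2, y1, y2)} (mm),
#'   or a \code{\linkS4class{QAPlan}} carrying band metadata.
#' @param tolerancePct pass tolerance, percent.
#' @return A \code{\linkS4class{VMATBandResult}}.
#' @export
analyzeVmatBands <- function(testImage, openImage, bandRois,
                             tolerancePct = 1.5) {
  if (is(bandRois, "QAPlan")) {
    if (is.null(bandRois@meta$bands))
      stop("plan carries no band metadata", call. = FALSE)
    bandRois <- bandRois@meta$bands$rois
  }
  if (!identical(dim(testImage@pixels), dim(openImage@pixels)))
    stop("test and open images must share geometry", call. = FALSE)
  R <- vapply(bandRois, .roi_mean, numeric(1), image = testImage)
  ROpen <- vapply(bandRois, .roi_mean, numeric(1), image = openImage)
  corrected <- R / ROpen
  pd <- 100 * (corrected / mean(corrected) - 1)
  new("VMATBandResult", R = R, ROpen = ROpen, corrected = corrected,
      percentDiff = pd, diffAbs = mean(abs(pd)), tolerance = tolerancePct,
      pass = all(abs(pd) <= tolerancePct))
}

#' Analyze a Winston-Lutz image
#'
#' Field center from the midpoints of the 50\% edges; BB center from
#' \code{\link{detectBBs}}; offset vector and magnitude in mm.
#'
#' @param image an \code{\linkS4class{EPIDImage}} of a small field
#'   containing one BB.
#' @param toleranceMm pass tolerance on the offset magnitude.
#' @param expectedRadiusMm nominal BB radius.
#' @return A \code{\linkS4class{WinstonLutzResult}}.
#' @export
analyzeWinstonLutz <- function(image, toleranceMm = 1,
                               expectedRadiusMm = 2) {
  edges <- detectFieldEdges(image)
  fc <- c((edges[["X1"]] + edges[["X2"]]) / 2,
          (edges[["Y1"]] + edges[["Y2"]]) / 2)
  bbs <- detectBBs(image, expectedRadiusMm = expectedRadiusMm)
  if (nrow(bbs) == 0)
    stop("detection error: no ball bearing found", call. = FALSE)
  d2 <- (bbs$x - fc[1])^2 + (bbs$y - fc[2])^2
  bb <- bbs[which.min(d2), ]
  off <- c(bb$x, bb$y) - fc
  new("WinstonLutzResult", bbCenter = c(bb$x, bb$y), fieldCenter = fc,
      offset = off, magnitude = sqrt(sum(off^2)), tolerance = toleranceMm,
      pass = sqrt(sum(off^2)) <= toleranceMm)
}
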