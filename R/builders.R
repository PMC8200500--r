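## QA plan builders: each returns a validated QAPlan whose meta slot
## carries the nominal geometry the analyzers compare against.

.mlc_park <- 200  # crossplane carriage limit, mm

.retracted <- function(np) list(a = rep(-.mlc_park, np), b = rep(.mlc_park, np))

.check_angles <- function(...) {
  a <- c(...)
  if (any(a < 0 | a >= 360))
    stop("angles must be normalized to [0, 360)", call. = FALSE)
  invisible(a)
}

#' Build an open (static jaw) field plan
#'
#' @param fieldSize \code{c(X, Y)} field extent in mm at isocenter
#'   (symmetric about the CAX).
#' @param energy,machineName labels copied into the plan.
#' @param gantryDeg gantry angle in [0, 360).
#' @param mlc \code{\linkS4class{MLCModel}}.
#' @return A \code{\linkS4class{QAPlan}} with two control points, static
#'   jaws and fully retracted MLC.
#' @examples
#' plan <- buildOpenFieldPlan(c(100, 100))
#' beams(plan)[[1]]$control_points[[1]]$jaws
#' @export
buildOpenFieldPlan <- function(fieldSize = c(100, 100), energy = "6X",
                               gantryDeg = 0, machineName = "LINAC1",
                               mlc = millennium120()) {
  fieldSize <- rep(as.numeric(fieldSize), length.out = 2)
  if (any(fieldSize <= 0)) stop("field extents must be positive", call. = FALSE)
  if (any(fieldSize / 2 > .mlc_park))
    stop("field extents must lie within +/-200 mm", call. = FALSE)
  .check_angles(gantryDeg)
  np <- nPairs(mlc)
  park <- .retracted(np)
  jaws <- c(X1 = -fieldSize[1] / 2, X2 = fieldSize[1] / 2,
            Y1 = -fieldSize[2] / 2, Y2 = fieldSize[2] / 2)
  cps <- lapply(c(0, 1), function(w)
    controlPoint(w, jaws, park$a, park$b, gantry_deg = gantryDeg))
  QAPlan("open",
    beams = list(list(name = "OPEN", mu = 100, control_points = cps)),
    mlc = mlc, machineName = machineName, energy = energy,
    meta = list(field_mm = fieldSize))
}

#' Build a jaw-junction plan of abutting half fields
#'
#' Each requested axis contributes two jaw-delimited half fields whose
#' shared edge lies on the junction line (x = 0 for a vertical junction,
#' y = 0 for a horizontal one).  A positive \code{junctionError} opens an
#' unirradiated gap of that many mm between the nominal edges; a negative
#' value double-exposes an overlap.
#'
#' @param axes subset of \code{c("vertical", "horizontal")}.
#' @param junctionError signed gap(+)/overlap(-) in mm, |error| <= 10.
#' @param fieldSize full extent of the composite field, mm.
#' @param energy,machineName,gantryDeg,mlc as in
#'   \code{\link{buildOpenFieldPlan}}.
#' @return A \code{\linkS4class{QAPlan}}; \code{planMeta(plan)$junction}
#'   records the nominal junction lines for the analyzer.
#' @export
buildJunctionPlan <- function(axes = c("vertical", "horizontal"),
                              junctionError = 0, fieldSize = 120,
                              energy = "6X", gantryDeg = 0,
                              machineName = "LINAC1", mlc = millennium120()) {
  axes <- match.arg(axes, c("vertical", "horizontal"), several.ok = TRUE)
  if (abs(junctionError) > 10)
    stop("|junctionError| must be <= 10 mm", call. = FALSE)
  .check_angles(gantryDeg)
  h <- fieldSize / 2
  e <- junctionError / 2
  np <- nPairs(mlc)
  park <- .retracted(np)
  mkbeam <- function(name, jaws) {
    cps <- lapply(c(0, 1), function(w)
      controlPoint(w, jaws, park$a, park$b, gantry_deg = gantryDeg))
    list(name = name, mu = 50, control_points = cps)
  }
  bms <- list()
  jmeta <- list()
  if ("vertical" %in% axes) {
    bms <- c(bms, list(
      mkbeam("JUNC-V-LEFT",  c(X1 = -h, X2 = -e, Y1 = -h, Y2 = h)),
      mkbeam("JUNC-V-RIGHT", c(X1 = e, X2 = h, Y1 = -h, Y2 = h))))
    jmeta$vertical <- list(line_mm = 0, beams = c(length(bms) - 1L, length(bms)),
                           shared_edges = c("X2", "X1"))
  }
  if ("horizontal" %in% axes) {
    bms <- c(bms, list(
      mkbeam("JUNC-H-LOW",  c(X1 = -h, X2 = h, Y1 = -h, Y2 = -e)),
      mkbeam("JUNC-H-HIGH", c(X1 = -h, X2 = h, Y1 = e, Y2 = h))))
    jmeta$horizontal <- list(line_mm = 0, beams = c(length(bms) - 1L, length(bms)),
                             shared_edges = c("Y2", "Y1"))
  }
  QAPlan("junction", beams = bms, mlc = mlc, machineName = machineName,
    energy = energy,
    meta = list(field_mm = fieldSize, junction_error_mm = junctionError,
                junctions = jmeta))
}

#' Build a light-radiation coincidence plan
#'
#' An open field plus the nominal ball-bearing phantom layout: eight BBs,
#' two per field side on the field axes -- one inner BB 5 mm inside the
#' 50\% field edge and one outer BB further in (default 25 mm).  BBs are
#' indexed 1-8 clockwise starting from the +x (patient right) side,
#' inner ring first.
#'
#' @param fieldSize square field extent, mm.
#' @param innerInset,outerInset BB distances from the field edge, mm.
#' @inheritParams buildOpenFieldPlan
#' @return A \code{\linkS4class{QAPlan}} with \code{testType "lightrad"}.
#' @export
buildLightRadPlan <- function(fieldSize = 100, innerInset = 5,
                              outerInset = 25, energy = "6X", gantryDeg = 0,
                              machineName = "LINAC1", mlc = millennium120()) {
  plan <- buildOpenFieldPlan(c(fieldSize, fieldSize), energy, gantryDeg,
                             machineName, mlc)
  h <- fieldSize / 2
  ri <- h - innerInset
  ro <- h - outerInset
  bb <- data.frame(
    index = 1:8,
    x = c(ri, 0, -ri, 0, ro, 0, -ro, 0),
    y = c(0, -ri, 0, ri, 0, -ro, 0, ro),
    inner = rep(c(TRUE, FALSE), each = 4))
  plan@testType <- "lightrad"
  plan@meta <- list(field_mm = c(fieldSize, fieldSize),
    lightrad = list(inner_inset_mm = innerInset, outer_inset_mm = outerInset,
                    bb = bb))
  validObject(plan)
  plan
}

#' Build a picket fence (DMLC) plan
#'
#' The beam sweeps a \code{gap}-wide slit that dwells at each picket
#' center; dwell segments carry equal meterset, moves carry none.  The
#' nominal picket centers are stored in the plan metadata as the
#' analyzer's expected positions.  \code{leafOffsets} shift the
#' \emph{delivered} bank positions only, so injected leaf errors appear
#' as measured-vs-expected deviations.
#'
#' @param spec a \code{\link{PicketFenceSpec}}.
#' @param leafOffsets scalar, or one value per active leaf pair, mm.
#' @param yAperture Y jaw aperture \code{c(Y1, Y2)}, mm.
#' @inheritParams buildOpenFieldPlan
#' @return A \code{\linkS4class{QAPlan}} with \code{testType
#'   "picketfence"}.
#' @examples
#' plan <- buildPicketFencePlan()
#' planMeta(plan)$picket$centers_mm
#' @export
buildPicketFencePlan <- function(spec = PicketFenceSpec(), leafOffsets = 0,
                                 yAperture = c(-100, 100), energy = "6X",
                                 gantryDeg = 0, machineName = "LINAC1",
                                 mlc = millennium120()) {
  validObject(spec)
  .check_angles(gantryDeg)
  n <- spec@nPickets
  centers <- spec@spacing * (seq_len(n) - (n + 1) / 2)
  xj <- c(min(centers) - spec@gap / 2 - 10, max(centers) + spec@gap / 2 + 10)
  if (any(abs(xj) > .mlc_park))
    stop("pickets do not fit inside the jaw aperture", call. = FALSE)
  b <- leafBoundaries(mlc)
  np <- nPairs(mlc)
  if (length(spec@activePairs)) {
    act <- seq.int(spec@activePairs[1], spec@activePairs[2])
    if (any(act < 1 | act > np))
      stop("active leaf pairs outside the MLC model", call. = FALSE)
  } else {
    act <- which(b[-length(b)] >= yAperture[1] - 1e-9 &
                 b[-1] <= yAperture[2] + 1e-9)
  }
  offs <- as.numeric(leafOffsets)
  if (length(offs) == 1) offs <- rep(offs, length(act))
  if (length(offs) != length(act))
    stop(sprintf("leafOffsets must be scalar or length %d (active pairs)",
                 length(act)), call. = FALSE)
  jaws <- c(X1 = xj[1], X2 = xj[2], Y1 = yAperture[1], Y2 = yAperture[2])
  closed <- xj[1] - 20  # parked behind the X1 jaw
  slit_cp <- function(center, w) {
    a <- rep(closed, np); bb <- rep(closed, np)
    a[act] <- center - spec@gap / 2 + offs
    bb[act] <- center + spec@gap / 2 + offs
    controlPoint(w, jaws, a, bb, gantry_deg = gantryDeg)
  }
  cps <- vector("list", 2L * n)
  for (k in seq_len(n)) {
    cps[[2 * k - 1]] <- slit_cp(centers[k], (k - 1) / n)
    cps[[2 * k]] <- slit_cp(centers[k], k / n)
  }
  QAPlan("picketfence",
    beams = list(list(name = "PF", mu = 100, control_points = cps)),
    mlc = mlc, machineName = machineName, energy = energy,
    meta = list(picket = list(
      centers_mm = centers, spacing_mm = spec@spacing, gap_mm = spec@gap,
      active_pairs = c(min(act), max(act)), y_aperture_mm = yAperture)))
}

#' Build a Winston-Lutz plan
#'
#' One small square field per gantry/collimator/couch combination.
#'
#' @param combos data.frame with columns \code{gantry}, \code{collimator},
#'   \code{couch} (degrees, [0, 360)); default the four cardinal gantry
#'   angles.
#' @param fieldSize square field side, mm.
#' @inheritParams buildOpenFieldPlan
#' @return A \code{\linkS4class{QAPlan}} with one beam per combo.
#' @export
buildWinstonLutzPlan <- function(combos = data.frame(
                                   gantry = c(0, 90, 180, 270),
                                   collimator = 0, couch = 0),
                                 fieldSize = 20, energy = "6X",
                                 machineName = "LINAC1",
                                 mlc = millennium120()) {
  if (nrow(combos) < 1) stop("need at least one angle combination", call. = FALSE)
  .check_angles(combos$gantry, combos$collimator, combos$couch)
  h <- fieldSize / 2
  bd <- leafBoundaries(mlc)
  np <- nPairs(mlc)
  open_pairs <- which(bd[-length(bd)] < h & bd[-1] > -h)
  bms <- lapply(seq_len(nrow(combos)), function(i) {
    a <- rep(-100, np); bb <- rep(-100, np)  # closed behind X1 jaw
    a[open_pairs] <- -h; bb[open_pairs] <- h
    jaws <- c(X1 = -h, X2 = h, Y1 = -h, Y2 = h)
    cps <- lapply(c(0, 1), function(w)
      controlPoint(w, jaws, a, bb, gantry_deg = combos$gantry[i],
        collimator_deg = combos$collimator[i], couch_deg = combos$couch[i]))
    list(name = sprintf("WL-G%03d-C%03d-T%03d", round(combos$gantry[i]),
           round(combos$collimator[i]), round(combos$couch[i])),
         mu = 10, control_points = cps)
  })
  QAPlan("winston_lutz", beams = bms, mlc = mlc, machineName = machineName,
    energy = energy, meta = list(field_mm = fieldSize, combos = combos))
}

#' Build VMAT constancy QA plans
#'
#' Four test families following the usual vendor arc-QA layout:
#' \describe{
#'   \item{t1_static_dmlc}{sliding-window delivery repeated at the four
#'     cardinal gantry angles (gamma comparison against the 0-degree
#'     image).}
#'   \item{t1_rotating_picket}{picket pattern at cardinal angles plus a
#'     rotating-gantry delivery; with \code{injectMlcErrors} a second
#'     rotating beam shifts a documented subset of leaf pairs by
#'     +1.0 mm.}
#'   \item{t2_doserate_gantry}{dose-rate / gantry-speed modulation over
#'     \code{bandCount} (default 7) disjoint intensity bands.}
#'   \item{t3_mlc_speed}{MLC-speed modulation over \code{bandCount}
#'     (default 4) bands.}
#' }
#' For t2/t3 the band ROI rectangles are stored in the plan metadata.
#'
#' @param which test family.
#' @param bandCount number of bands (t2/t3); >= 2.
#' @param injectMlcErrors add the error-injected rotating picket beam.
#' @inheritParams buildOpenFieldPlan
#' @return A \code{\linkS4class{QAPlan}}.
#' @export
buildVmatPlan <- function(which = c("t1_static_dmlc", "t1_rotating_picket",
                                    "t2_doserate_gantry", "t3_mlc_speed"),
                          bandCount = NULL, injectMlcErrors = FALSE,
                          energy = "6X", machineName = "LINAC1",
                          mlc = millennium120()) {
  which <- match.arg(which)
  np <- nPairs(mlc)
  bd <- leafBoundaries(mlc)
  half_x <- 60; half_y <- 80
  jaws <- c(X1 = -half_x - 5, X2 = half_x + 5, Y1 = -half_y, Y2 = half_y)
  act <- which(bd[-length(bd)] >= -half_y & bd[-1] <= half_y)
  sliding_cps <- function(gantry_seq) {
    pos <- seq(-half_x, half_x, by = 10)
    nw <- length(pos)
    g <- if (length(gantry_seq) == 1) rep(gantry_seq, nw) else
      seq(gantry_seq[1], gantry_seq[2], length.out = nw)
    lapply(seq_len(nw), function(i) {
      a <- rep(jaws[["X1"]] - 20, np); b2 <- rep(jaws[["X1"]] - 20, np)
      a[act] <- pmax(pos[i] - 10, -half_x); b2[act] <- pmin(pos[i] + 10, half_x)
      controlPoint((i - 1) / (nw - 1), jaws, a, b2, gantry_deg = g[i])
    })
  }
  picket_cps <- function(gantry_seq, offset_pairs = integer(0), offset_mm = 0) {
    centers <- 15 * (seq_len(7) - 4)
    nw <- 2 * length(centers)
    g <- if (length(gantry_seq) == 1) rep(gantry_seq, nw) else
      seq(gantry_seq[1], gantry_seq[2], length.out = nw)
    cps <- vector("list", nw)
    for (k in seq_along(centers)) {
      for (j in 1:2) {
        i <- 2 * (k - 1) + j
        a <- rep(jaws[["X1"]] - 20, np); b2 <- rep(jaws[["X1"]] - 20, np)
        a[act] <- centers[k] - 1; b2[act] <- centers[k] + 1
        a[intersect(act, offset_pairs)] <- centers[k] - 1 + offset_mm
        b2[intersect(act, offset_pairs)] <- centers[k] + 1 + offset_mm
        w <- if (j == 1) (k - 1) / length(centers) else k / length(centers)
        cps[[i]] <- controlPoint(w, jaws, a, b2, gantry_deg = g[i])
      }
    }
    cps
  }
  if (which == "t1_static_dmlc") {
    bms <- lapply(c(0, 90, 180, 270), function(g)
      list(name = sprintf("T1-G%03d", g), mu = 100,
           control_points = sliding_cps(g)))
    return(QAPlan("vmat_t1", beams = bms, mlc = mlc,
      machineName = machineName, energy = energy,
      meta = list(vmat = list(family = "t1_static_dmlc"))))
  }
  if (which == "t1_rotating_picket") {
    err_pairs <- c(15L, 25L, 35L, 45L); err_mm <- 1.0
    bms <- lapply(c(0, 90, 180, 270), function(g)
      list(name = sprintf("T1P-G%03d", g), mu = 100,
           control_points = picket_cps(g)))
    bms <- c(bms, list(list(name = "T1P-ARC", mu = 100,
      control_points = picket_cps(c(180, 0)))))
    meta <- list(vmat = list(family = "t1_rotating_picket"))
    if (injectMlcErrors) {
      bms <- c(bms, list(list(name = "T1P-ARC-ERR", mu = 100,
        control_points = picket_cps(c(180, 0), err_pairs, err_mm))))
      meta$mlc_error <- list(pairs = err_pairs, offset_mm = err_mm,
                             beam = length(bms))
    }
    return(QAPlan("vmat_t1", beams = bms, mlc = mlc,
      machineName = machineName, energy = energy, meta = meta))
  }
  ## t2 / t3: banded modulation
  if (is.null(bandCount))
    bandCount <- if (which == "t2_doserate_gantry") 7L else 4L
  if (bandCount < 2) stop("bandCount must be >= 2", call. = FALSE)
  w <- 2 * half_x / bandCount
  rois <- lapply(seq_len(bandCount), function(b) {
    x1 <- -half_x + (b - 1) * w
    c(x1 = x1 + 5, x2 = x1 + w - 5, y1 = -half_y + 10, y2 = half_y - 10)
  })
  bounds <- lapply(seq_len(bandCount), function(b) {
    x1 <- -half_x + (b - 1) * w
    c(x1 = x1, x2 = x1 + w, y1 = -half_y, y2 = half_y)
  })
  bms <- list(list(name = toupper(sub("_.*", "", which)), mu = 100,
                   control_points = sliding_cps(c(180, 0))))
  QAPlan(if (which == "t2_doserate_gantry") "vmat_t2" else "vmat_t3",
    beams = bms, mlc = mlc, machineName = machineName, energy = energy,
    meta = list(bands = list(count = bandCount, rois = rois, bounds = bounds),
                field_mm = c(2 * (half_x + 5), 2 * half_y)))
}

#' Build a dosimetric-leaf-gap sweeping-slit plan
#'
#' One uniformly sweeping slit beam per requested gap width.
#'
#' @param gapWidths slit widths, mm.
#' @inheritParams buildOpenFieldPlan
#' @return A \code{\linkS4class{QAPlan}} with \code{testType "dlg"}.
#' @export
buildDlgPlan <- function(gapWidths = c(2, 4, 6, 10, 14, 16, 20),
                         energy = "6X", machineName = "LINAC1",
                         mlc = millennium120()) {
  if (any(gapWidths <= 0)) stop("gap widths must be positive", call. = FALSE)
  np <- nPairs(mlc)
  bd <- leafBoundaries(mlc)
  jaws <- c(X1 = -60, X2 = 60, Y1 = -100, Y2 = 100)
  act <- which(bd[-length(bd)] >= -100 & bd[-1] <= 100)
  bms <- lapply(gapWidths, function(g) {
    pos <- seq(-60 + g / 2, 60 - g / 2, length.out = 13)
    cps <- lapply(seq_along(pos), function(i) {
      a <- rep(-80, np); b2 <- rep(-80, np)
      a[act] <- pos[i] - g / 2; b2[act] <- pos[i] + g / 2
      controlPoint((i - 1) / (length(pos) - 1), jaws, a, b2)
    })
    list(name = sprintf("DLG-%gMM", g), mu = 100, control_points = cps)
  })
  QAPlan("dlg", beams = bms, mlc = mlc, machineName = machineName,
    energy = energy, meta = list(dlg = list(gap_widths_mm = gapWidths)))
}

#' Resample control points to a finer spacing
#'
#' Linearly interpolates every numeric machine axis (jaws, leaf banks,
#' gantry, collimator, couch, cumulative meterset) between neighbouring
#' control points until no consecutive pair exceeds the requested gantry
#' and/or meterset-weight spacing.  Endpoints are preserved exactly and
#' the operation is idempotent once the bound is met.
#'
#' @param plan a \code{\linkS4class{QAPlan}}.
#' @param maxGantryDeg maximum gantry spacing between consecutive control
#'   points, degrees (NULL to ignore).
#' @param maxWeight maximum cumulative meterset-weight spacing (NULL to
#'   ignore).
#' @return The resampled \code{\linkS4class{QAPlan}}.
#' @examples
#' p <- buildOpenFieldPlan()
#' p@beams[[1]]$control_points[[2]]$gantry_deg <- 180
#' length(resampleControlPoints(p, maxGantryDeg = 2)@beams[[1]]$control_points)
#' @export
resampleControlPoints <- function(plan, maxGantryDeg = NULL, maxWeight = NULL) {
  if (is.null(maxGantryDeg) && is.null(maxWeight))
    stop("give at least one of maxGantryDeg, maxWeight", call. = FALSE)
  validObject(plan)
  lerp_cp <- function(c1, c2, t) {
    mix <- function(a, b) a + t * (b - a)
    controlPoint(mix(c1$meterset_weight, c2$meterset_weight),
      mix(c1$jaws, c2$jaws), mix(c1$mlc_a, c2$mlc_a), mix(c1$mlc_b, c2$mlc_b),
      gantry_deg = mix(c1$gantry_deg, c2$gantry_deg),
      collimator_deg = mix(c1$collimator_deg, c2$collimator_deg),
      couch_deg = mix(c1$couch_deg, c2$couch_deg))
  }
  plan@beams <- lapply(plan@beams, function(bm) {
    cps <- bm$control_points
    out <- list(cps[[1]])
    for (i in seq_len(length(cps) - 1)) {
      c1 <- cps[[i]]; c2 <- cps[[i + 1]]
      nseg <- 1L
      if (!is.null(maxGantryDeg))
        nseg <- max(nseg, ceiling(abs(c2$gantry_deg - c1$gantry_deg) /
                                  maxGantryDeg - 1e-9))
      if (!is.null(maxWeight))
        nseg <- max(nseg, ceiling((c2$meterset_weight - c1$meterset_weight) /
                                  maxWeight - 1e-9))
      for (k in seq_len(nseg - 1)) out <- c(out, list(lerp_cp(c1, c2, k / nseg)))
      out <- c(out, list(c2))
    }
    bm$control_points <- out
    bm
  })
  validObject(plan)
  plan
}
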