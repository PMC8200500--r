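## Synthetic EPID renderer.  Images are computed directly in
## isocenter-plane mm on the detector pixel grid (one magnification
## bookkeeping, none of it duplicated).  Field edges are error-function
## profiles of width penumbraSigma; ball bearings are multiplicative
## attenuation disks blurred by the same sigma; noise is additive
## Gaussian with sd = noiseSigma x plateau, seeded explicitly.

.render_grid <- function(config) {
  iso <- config@pixelSpacing * config@sad / config@sid
  cax <- (config@gridShape + 1) / 2
  list(
    y = (seq_len(config@gridShape[1]) - cax[1]) * iso[1],
    x = (seq_len(config@gridShape[2]) - cax[2]) * iso[2],
    cax = cax)
}

## box [lo, hi] convolved with a Gaussian of width sigma
.edge_profile <- function(v, lo, hi, sigma)
  pnorm((v - lo) / sigma) - pnorm((v - hi) / sigma)

.jaw_fluence <- function(g, jaws, sigma)
  outer(.edge_profile(g$y, jaws[["Y1"]], jaws[["Y2"]], sigma),
        .edge_profile(g$x, jaws[["X1"]], jaws[["X2"]], sigma))

.bow_map <- function(g, config) {
  if (config@offAxisBow == 0) return(1)
  r2 <- outer(g$y^2, g$x^2, "+")
  1 - config@offAxisBow * r2 / max(r2)
}

.finish_image <- function(shape, config, error, meta) {
  img <- config@backgroundLevel + (1 - config@backgroundLevel) * shape
  if (error@noiseSigma > 0)
    img <- withr::with_seed(as.integer(error@seed),
      img + matrix(rnorm(length(img), 0, error@noiseSigma),
                   nrow = nrow(img)))
  img <- pmax(img, 0)
  EPIDImage(img, config@pixelSpacing, sid = config@sid, sad = config@sad,
            meta = meta)
}

.beam_jaws <- function(plan, beam) plan@beams[[beam]]$control_points[[1]]$jaws

.img_meta <- function(plan, beam = 1) {
  list(test_type = plan@testType, machine = plan@machineName,
       gantry_deg = plan@beams[[beam]]$control_points[[1]]$gantry_deg)
}

#' Render an open static-jaw field
#'
#' @param plan a \code{\linkS4class{QAPlan}} whose beam has static jaws.
#' @param config a \code{\link{RenderConfig}}.
#' @param error an \code{\link{ErrorModel}} (noise/seed used here).
#' @param beam beam index to render.
#' @return An \code{\linkS4class{EPIDImage}} with plateau 1.0 at the CAX
#'   and background \code{backgroundLevel}.
#' @export
renderOpenField <- function(plan, config = RenderConfig(),
                            error = ErrorModel(), beam = 1) {
  g <- .render_grid(config)
  shape <- .jaw_fluence(g, .beam_jaws(plan, beam), config@penumbraSigma) *
    .bow_map(g, config)
  .finish_image(shape, config, error, .img_meta(plan, beam))
}

#' Render an integrated junction-test image
#'
#' Sums the renders of every abutting half field in the plan.  A nonzero
#' \code{junctionError} in the error model shifts each pair's shared
#' edges apart (positive: gap) or together (negative: overlap) at
#' delivery time, on top of any error already built into the plan.
#'
#' @inheritParams renderOpenField
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
renderJunctionImage <- function(plan, config = RenderConfig(),
                                error = ErrorModel()) {
  if (is.null(plan@meta$junctions))
    stop("plan carries no junction metadata", call. = FALSE)
  g <- .render_grid(config)
  jaw_list <- lapply(plan@beams, function(b) b$control_points[[1]]$jaws)
  if (error@junctionError != 0) {
    e2 <- error@junctionError / 2
    for (j in plan@meta$junctions) {
      b1 <- j$beams[1]; b2 <- j$beams[2]
      ## shared_edges give the abutting jaw of each beam; the first beam
      ## is on the negative side of the junction line
      jaw_list[[b1]][j$shared_edges[1]] <- jaw_list[[b1]][j$shared_edges[1]] - e2
      jaw_list[[b2]][j$shared_edges[2]] <- jaw_list[[b2]][j$shared_edges[2]] + e2
    }
  }
  shape <- Reduce(`+`, lapply(jaw_list, .jaw_fluence, g = g,
                              sigma = config@penumbraSigma))
  shape <- shape * .bow_map(g, config)
  .finish_image(shape, config, error, .img_meta(plan))
}

.bb_attenuation <- function(g, centers, radius, contrast, sigma) {
  att <- matrix(1, length(g$y), length(g$x))
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((g$y - centers$y[i])^2, (g$x - centers$x[i])^2, "+"))
    att <- att * (1 - contrast * pnorm((radius - d) / sigma))
  }
  att
}

#' Render a light-radiation coincidence phantom image
#'
#' Open field with eight BB attenuation disks.  The phantom sits at
#' \code{error@ssd}: BB positions (and the projected BB radius) are
#' magnified by \code{sad/ssd} relative to nominal, and
#' \code{error@phantomShift} translates the whole BB pattern; the
#' radiation field edges are unaffected by either.
#'
#' @inheritParams renderOpenField
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
renderLightRadImage <- function(plan, config = RenderConfig(),
                                error = ErrorModel()) {
  lr <- plan@meta$lightrad
  if (is.null(lr)) stop("plan carries no lightrad metadata", call. = FALSE)
  g <- .render_grid(config)
  shape <- .jaw_fluence(g, .beam_jaws(plan, 1), config@penumbraSigma) *
    .bow_map(g, config)
  s <- config@sad / error@ssd
  bb <- as.data.frame(lr$bb)
  centers <- data.frame(x = (bb$x + error@phantomShift[1]) * s,
                        y = (bb$y + error@phantomShift[2]) * s)
  att <- .bb_attenuation(g, centers, radius = config@bbDiameter / 2 * s,
                         contrast = config@bbContrast,
                         sigma = config@penumbraSigma)
  .finish_image(shape * att, config, error, .img_meta(plan))
}

#' Render an integrated picket-fence delivery
#'
#' Accumulates the DMLC fluence of the plan's dwell segments: each leaf
#' pair contributes a stripe at its delivered slit position (nominal
#' control-point position plus \code{error@leafOffset}), confined to the
#' pair's transverse row band.  The image is normalized so the tallest
#' stripe has plateau 1.
#'
#' @inheritParams renderOpenField
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
renderPicketFenceImage <- function(plan, config = RenderConfig(),
                                   error = ErrorModel(), beam = 1) {
  g <- .render_grid(config)
  sg <- config@penumbraSigma
  bd <- leafBoundaries(plan@mlc)
  np <- nPairs(plan@mlc)
  cps <- plan@beams[[beam]]$control_points
  jaws <- cps[[1]]$jaws
  lo <- error@leafOffset
  offs <- rep(0, np)
  if (length(lo) == 1) {
    offs[] <- lo
  } else if (length(lo) == np) {
    offs <- lo
  } else if (!is.null(plan@meta$picket$active_pairs)) {
    act <- seq.int(plan@meta$picket$active_pairs[1],
                   plan@meta$picket$active_pairs[2])
    if (length(lo) != length(act))
      stop("leafOffset must be scalar, per-pair, or one per active pair",
           call. = FALSE)
    offs[act] <- lo
  } else {
    stop("leafOffset length does not match the MLC model", call. = FALSE)
  }
  shape <- matrix(0, length(g$y), length(g$x))
  wy_cache <- vector("list", np)
  for (i in seq_len(length(cps) - 1)) {
    c1 <- cps[[i]]; c2 <- cps[[i + 1]]
    dw <- c2$meterset_weight - c1$meterset_weight
    if (dw <= 0) next
    for (p in seq_len(np)) {
      a <- c1$mlc_a[p]; b <- c1$mlc_b[p]
      if (b - a < 0.05) next  # closed pair
      if (is.null(wy_cache[[p]]))
        wy_cache[[p]] <- .edge_profile(g$y, max(bd[p], jaws[["Y1"]]),
                                       min(bd[p + 1], jaws[["Y2"]]), sg)
      px <- .edge_profile(g$x, max(a + offs[p], jaws[["X1"]]),
                          min(b + offs[p], jaws[["X2"]]), sg)
      shape <- shape + dw * outer(wy_cache[[p]], px)
    }
  }
  mx <- max(shape)
  if (mx <= 0) stop("plan delivered no fluence", call. = FALSE)
  .finish_image(shape / mx, config, error, .img_meta(plan, beam))
}

#' Render a VMAT band-test image
#'
#' The composite aperture filled at nominal intensity, with each band
#' ROI multiplied by its \code{error@bandPerturbation} entry (recycled
#' to the band count).  Render the matching open-field reference with
#' \code{\link{renderOpenField}} using the same config so the off-axis
#' shape cancels in the band ratio.
#'
#' @inheritParams renderOpenField
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
renderBandImage <- function(plan, config = RenderConfig(),
                            error = ErrorModel()) {
  bands <- plan@meta$bands
  if (is.null(bands)) stop("plan carries no band metadata", call. = FALSE)
  g <- .render_grid(config)
  sg <- config@penumbraSigma
  shape <- .jaw_fluence(g, .beam_jaws(plan, 1), sg) * .bow_map(g, config)
  pert <- rep(error@bandPerturbation, length.out = bands$count)
  strips <- bands$bounds %||% bands$rois
  mult <- matrix(1, length(g$y), length(g$x))
  for (b in seq_len(bands$count)) {
    roi <- strips[[b]]
    box <- outer(.edge_profile(g$y, roi[["y1"]], roi[["y2"]], sg),
                 .edge_profile(g$x, roi[["x1"]], roi[["x2"]], sg))
    mult <- mult + (pert[b] - 1) * box
  }
  .finish_image(shape * mult, config, error, .img_meta(plan))
}

#' Render a Winston-Lutz image
#'
#' Small square field with a single BB at the isocenter (displaced by
#' \code{error@phantomShift}).
#'
#' @inheritParams renderOpenField
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
renderWinstonLutzImage <- function(plan, config = RenderConfig(),
                                   error = ErrorModel(), beam = 1) {
  g <- .render_grid(config)
  shape <- .jaw_fluence(g, .beam_jaws(plan, beam), config@penumbraSigma)
  s <- config@sad / error@ssd
  centers <- data.frame(x = error@phantomShift[1] * s,
                        y = error@phantomShift[2] * s)
  att <- .bb_attenuation(g, centers, radius = config@bbDiameter / 2 * s,
                         contrast = config@bbContrast,
                         sigma = config@penumbraSigma)
  .finish_image(shape * att, config, error, .img_meta(plan, beam))
}

#' Render the image a QA plan's analyzer expects
#'
#' Dispatches to the per-test renderer by \code{testType(plan)}.
#'
#' @inheritParams renderOpenField
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
renderPlanImage <- function(plan, config = RenderConfig(),
                            error = ErrorModel(), beam = 1) {
  switch(plan@testType,
    junction = renderJunctionImage(plan, config, error),
    lightrad = renderLightRadImage(plan, config, error),
    picketfence = renderPicketFenceImage(plan, config, error, beam),
    winston_lutz = renderWinstonLutzImage(plan, config, error, beam),
    vmat_t2 = ,
    vmat_t3 = renderBandImage(plan, config, error),
    renderOpenField(plan, config, error, beam))
}
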