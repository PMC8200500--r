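## 2D gamma evaluation (Low-style, global normalization).  The search
## minimizes over a disk of candidate spatial offsets with sub-pixel
## bilinear interpolation of the evaluated image; offsets are taken on a
## regular grid of step `searchStepMm` out to `searchRadiusFactor x dta`.

## shift a matrix by a (possibly fractional) number of pixels with
## bilinear interpolation; cells sampling outside the grid become NA
.shift_bilinear <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(dr); fr <- dr - r0
  c0 <- floor(dc); fc <- dc - c0
  pick <- function(ri, ci) {
    rows <- seq_len(nr) + ri
    cols <- seq_len(nc) + ci
    ok_r <- rows >= 1 & rows <= nr
    ok_c <- cols >= 1 & cols <= nc
    out <- matrix(NA_real_, nr, nc)
    out[ok_r, ok_c] <- m[rows[ok_r], cols[ok_c]]
    out
  }
  ## zero-weight neighbors must not poison the sum with off-grid NAs
  acc <- function(total, w, ri, ci)
    if (w == 0) total else total + w * pick(ri, ci)
  out <- matrix(0, nr, nc)
  out <- acc(out, (1 - fr) * (1 - fc), r0, c0)
  out <- acc(out, (1 - fr) * fc, r0, c0 + 1)
  out <- acc(out, fr * (1 - fc), r0 + 1, c0)
  acc(out, fr * fc, r0 + 1, c0 + 1)
}

#' 2D gamma index between two dose images
#'
#' Global-normalization gamma: the dose-difference criterion is
#' \code{ddPct} percent of the reference maximum; the spatial search
#' runs over a disk of radius \code{searchRadiusFactor * dtaMm} sampled
#' every \code{searchStepMm} with bilinear sub-pixel interpolation.
#' Reference pixels below \code{lowDoseCutoffPct} percent of the
#' maximum are excluded from the map and the pass rate.
#'
#' @param reference,evaluated \code{\linkS4class{EPIDImage}}s (or plain
#'   matrices with \code{spacingMm} given), co-registered and equally
#'   sampled.
#' @param ddPct dose-difference criterion, percent of the reference max.
#' @param dtaMm distance-to-agreement criterion, mm.
#' @param lowDoseCutoffPct low-dose exclusion threshold, percent.
#' @param spacingMm isocenter-plane pixel spacing (row, col) when plain
#'   matrices are supplied.
#' @param searchStepMm offset-grid step; default one third of the pixel
#'   spacing (capped at dta/3).
#' @param searchRadiusFactor search radius in units of dta.
#' @param passThresholdPct pass-rate percentage required for the overall
#'   pass flag.
#' @return A \code{\linkS4class{GammaResult}}.
#' @export
gamma2d <- function(reference, evaluated, ddPct = 3, dtaMm = 3,
                    lowDoseCutoffPct = 10, spacingMm = NULL,
                    searchStepMm = NULL, searchRadiusFactor = 3,
                    passThresholdPct = 95) {
  if (is(reference, "EPIDImage")) {
    spacingMm <- isoSpacing(reference)
    ref <- reference@pixels
  } else ref <- reference
  ev <- if (is(evaluated, "EPIDImage")) evaluated@pixels else evaluated
  if (is.null(spacingMm))
    stop("spacingMm required with matrix input", call. = FALSE)
  spacingMm <- rep(spacingMm, length.out = 2)
  if (!identical(dim(ref), dim(ev)))
    stop("images must be co-registered with equal sampling", call. = FALSE)
  if (is.null(searchStepMm))
    searchStepMm <- min(min(spacingMm) / 3, dtaMm / 3)
  dmax <- max(ref)
  dd_abs <- ddPct / 100 * dmax
  radius <- searchRadiusFactor * dtaMm
  k <- ceiling(radius / searchStepMm)
  offs <- expand.grid(dy = (-k:k) * searchStepMm, dx = (-k:k) * searchStepMm)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2 + 1e-12, ]
  ## ascending distance so the running minimum converges fast
  offs <- offs[order(offs$dy^2 + offs$dx^2), ]
  g2 <- matrix(Inf, nrow(ref), ncol(ref))
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    dist2 <- (dy^2 + dx^2) / dtaMm^2
    if (all(g2 <= dist2)) next  # no offset farther out can improve
    sh <- .shift_bilinear(ev, dy / spacingMm[1], dx / spacingMm[2])
    cand <- (sh - ref)^2 / dd_abs^2 + dist2
    g2 <- pmin(g2, cand, na.rm = TRUE)
  }
  gmap <- sqrt(g2)
  gmap[ref < lowDoseCutoffPct / 100 * dmax] <- NA_real_
  rate <- 100 * mean(gmap[!is.na(gmap)] <= 1)
  new("GammaResult", gammaMap = gmap, passRate = rate, ddPct = ddPct,
      dtaMm = dtaMm, lowDoseCutoffPct = lowDoseCutoffPct,
      pass = rate >= passThresholdPct)
}
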