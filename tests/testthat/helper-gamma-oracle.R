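## independent oracle: plain nested-loop exhaustive gamma search with
## its own bilinear interpolation (edge rows duplicate only at exact
## zero fraction, matching the NA convention of the implementation)
bruteForceGamma <- function(ref, ev, spacing, dd_pct, dta, step, radius) {
  dd <- dd_pct / 100 * max(ref)
  k <- ceiling(radius / step)
  out <- matrix(NA_real_, nrow(ref), ncol(ref))
  interp <- function(m, r, c) {
    if (r < 1 || c < 1 || r > nrow(m) || c > ncol(m)) return(NA_real_)
    r0 <- floor(r); c0 <- floor(c)
    r1 <- min(r0 + 1, nrow(m)); c1 <- min(c0 + 1, ncol(m))
    fr <- r - r0; fc <- c - c0
    m[r0, c0] * (1 - fr) * (1 - fc) + m[r0, c1] * (1 - fr) * fc +
      m[r1, c0] * fr * (1 - fc) + m[r1, c1] * fr * fc
  }
  for (i in seq_len(nrow(ref))) for (j in seq_len(ncol(ref))) {
    best <- Inf
    for (a in -k:k) for (b in -k:k) {
      dy <- a * step; dx <- b * step
      if (dy^2 + dx^2 > radius^2 + 1e-12) next
      d <- interp(ev, i + dy / spacing[1], j + dx / spacing[2])
      if (is.na(d)) next
      g2 <- (d - ref[i, j])^2 / dd^2 + (dy^2 + dx^2) / dta^2
      if (g2 < best) best <- g2
    }
    out[i, j] <- sqrt(best)
  }
  out
}
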