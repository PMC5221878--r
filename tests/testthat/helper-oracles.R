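# Independent oracles and small fixture builders used across the suite.

# Exhaustive flood fill by relaxation: repeatedly dilate the current set by one
# 8-neighbour ring (whole-image shifts) and intersect with the in-range set,
# until a fixpoint. Independent of the frontier-queue implementation under test.
flood_fill_oracle <- function(inrange, seed) {
  nr <- nrow(inrange); nc <- ncol(inrange)
  cur <- matrix(FALSE, nr, nc)
  cur[seed[1], seed[2]] <- TRUE
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr
    cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr
    ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift(cur, dr, dc)
    }
    grown <- grown & inrange
    grown <- grown | cur
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# Brute-force Feret diameter: all pairs over every mask pixel center.
brute_feret <- function(mask, sr, sc) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  xy <- cbind((pts[, 2] - 1) * sc, (pts[, 1] - 1) * sr)
  max(dist(xy))
}

# AUC as the fraction of concordant case-control pairs (ties count half).
auc_pair_fraction <- function(scores, outcome) {
  s1 <- scores[outcome == 1]
  s0 <- scores[outcome == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Pixel-center rasterized disk of radius r (pixels) in an n x n grid.
raster_disk <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  g_r <- matrix(seq_len(n), n, n)
  g_c <- matrix(seq_len(n), n, n, byrow = TRUE)
  (g_r - center[1])^2 + (g_c - center[2])^2 <= r^2
}

# 90-degree clockwise rotation of a matrix.
rot90cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# Uniform background slice around a mask, isotropic spacing.
flat_slice <- function(n, hu = -800, spacing = 1) {
  ct_slice(matrix(hu, n, n), spacing)
}

# Slice whose pixels are `inside_hu` on the mask and `bg_hu` elsewhere.
mask_slice <- function(mask, inside_hu = 40, bg_hu = -800, spacing = 1) {
  px <- matrix(bg_hu, nrow(mask), ncol(mask))
  px[mask] <- inside_hu
  ct_slice(px, spacing)
}
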