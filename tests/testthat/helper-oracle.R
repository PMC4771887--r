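# Independent oracles, deliberately written with none of the package's
# machinery: a dense-sampling line integrator for the projector and a
# direct double-loop spatial convolution.

# Line integral of a voxel phantom by brute-force dense sampling along
# the ray from `src` to `dst` (nearest-voxel lookup at each sample).
dense_line_integral <- function(mu, voxel_mm, src, dst, step_frac = 0.05) {
  d <- dim(mu)
  len <- sqrt(sum((dst - src)^2))
  step <- voxel_mm * step_frac
  n <- max(2L, ceiling(len / step))
  tt <- (seq_len(n) - 0.5) / n
  acc <- 0
  px <- src[1] + tt * (dst[1] - src[1])
  py <- src[2] + tt * (dst[2] - src[2])
  pz <- src[3] + tt * (dst[3] - src[3])
  ix <- floor((px + 0.5 * d[1] * voxel_mm) / voxel_mm) + 1L
  iy <- floor((py + 0.5 * d[2] * voxel_mm) / voxel_mm) + 1L
  iz <- floor((pz + 0.5 * d[3] * voxel_mm) / voxel_mm) + 1L
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  if (any(ok)) acc <- sum(mu[cbind(ix[ok], iy[ok], iz[ok])]) * (len / n)
  acc
}

# Detector pixel position for the package's geometry convention.
detector_pixel_position <- function(geom, angle_deg, row, col) {
  a <- angle_deg * pi / 180
  es <- c(cos(a), sin(a), 0)
  eu <- c(-sin(a), cos(a), 0)
  u <- (col - (geom$det_cols + 1) / 2) * geom$pitch
  v <- (row - (geom$det_rows + 1) / 2) * geom$pitch
  (geom$dso - geom$dsd) * es + u * eu + c(0, 0, v)
}

source_position <- function(geom, angle_deg) {
  a <- angle_deg * pi / 180
  c(geom$dso * cos(a), geom$dso * sin(a), 0)
}

# Direct "same"-size spatial convolution by explicit double loops.
direct_convolve_same <- function(img, kernel) {
  n1 <- nrow(img); n2 <- ncol(img)
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  h1 <- (k1 - 1) / 2; h2 <- (k2 - 1) / 2
  out <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    acc <- 0
    for (a in 1:k1) for (b in 1:k2) {
      ii <- i - (a - h1 - 1)
      jj <- j - (b - h2 - 1)
      if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2)
        acc <- acc + img[ii, jj] * kernel[a, b]
    }
    out[i, j] <- acc
  }
  out
}

# Radial second moment of a centred kernel grid (pixel units).
radial_second_moment <- function(psf) {
  h1 <- (nrow(psf) - 1) / 2; h2 <- (ncol(psf) - 1) / 2
  r2 <- outer((-h1:h1)^2, (-h2:h2)^2, "+")
  sum(psf * r2) / sum(psf)
}
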