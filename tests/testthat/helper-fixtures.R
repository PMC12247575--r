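# Shared fixtures: a coarse (48^3 at 4 mm) phantom with the same physical
# geometry as the default study phantom, memoized per test run, plus
# brute-force oracles for morphology, convolution and binning.

.fixtures <- new.env(parent = emptyenv())

test_spec <- function() phantom_spec(shape = c(48, 48, 48),
                                     voxel_size = c(4, 4, 4))

test_phantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- build_phantom(test_spec())
  .fixtures$phantom
}

test_masks <- function() {
  if (is.null(.fixtures$masks))
    .fixtures$masks <- phantom_masks(test_phantom())
  .fixtures$masks
}

test_scanner <- function() scanner_model(grid = test_phantom()$grid)

# study-scale (96^3 at 2 mm) fixtures for the acceptance checks
study_phantom <- function() {
  if (is.null(.fixtures$phantom96))
    .fixtures$phantom96 <- build_phantom(phantom_spec())
  .fixtures$phantom96
}

study_masks <- function() {
  if (is.null(.fixtures$masks96))
    .fixtures$masks96 <- phantom_masks(study_phantom())
  .fixtures$masks96
}

study_calibration <- function(name) {
  key <- paste0("cal96_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- calibrate_ecb_activities(ecb_profile(name),
                                                 study_phantom())
  .fixtures[[key]]
}

test_calibration <- function(name) {
  key <- paste0("cal_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- calibrate_ecb_activities(ecb_profile(name),
                                                 test_phantom())
  .fixtures[[key]]
}

# voxel-pair brute-force dilation: v in result iff some mask voxel within r mm
brute_dilate <- function(mask, radius_mm, voxel_size) {
  d <- dim(mask)
  on <- which(mask)
  oni <- arrayInd(on, d)
  out <- array(FALSE, d)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(prod(d))) {
    dv <- sweep(oni, 2, all_idx[v, ])
    dist2 <- (dv[, 1] * voxel_size[1])^2 + (dv[, 2] * voxel_size[2])^2 +
      (dv[, 3] * voxel_size[3])^2
    out[v] <- any(dist2 <= radius_mm^2 + 1e-9)
  }
  out
}

# brute-force erosion: keep voxel iff every ball offset stays inside mask
brute_erode <- function(mask, radius_mm, voxel_size) {
  d <- dim(mask)
  m <- floor(radius_mm / voxel_size)
  offs <- expand.grid(x = -m[1]:m[1], y = -m[2]:m[2], z = -m[3]:m[3])
  dist2 <- (offs$x * voxel_size[1])^2 + (offs$y * voxel_size[2])^2 +
    (offs$z * voxel_size[3])^2
  offs <- offs[dist2 <= radius_mm^2 + 1e-9, ]
  out <- array(FALSE, d)
  for (v in which(mask)) {
    i <- arrayInd(v, d)
    px <- i[1] + offs$x; py <- i[2] + offs$y; pz <- i[3] + offs$z
    inside <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] &
      pz >= 1 & pz <= d[3]
    out[v] <- all(inside) && all(mask[cbind(px, py, pz)])
  }
  out
}

# direct shift-and-add convolution with the same truncated kernel the
# package builds; independent of the FFT path
brute_convolve <- function(x, kernel) {
  d <- dim(x); dk <- dim(kernel)
  half <- (dk - 1) / 2
  out <- array(0, d)
  for (ox in -half[1]:half[1]) for (oy in -half[2]:half[2])
    for (oz in -half[3]:half[3]) {
      w <- kernel[ox + half[1] + 1, oy + half[2] + 1, oz + half[3] + 1]
      if (w == 0) next
      # build shifted copy with zero padding
      shifted <- array(0, d)
      xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
      vx <- xs[xs - ox >= 1 & xs - ox <= d[1]]
      vy <- ys[ys - oy >= 1 & ys - oy <= d[2]]
      vz <- zs[zs - oz >= 1 & zs - oz <= d[3]]
      shifted[vx, vy, vz] <- x[vx - ox, vy - oy, vz - oz]
      out <- out + w * shifted
    }
  out
}

# exhaustive Youden-index threshold search over all midpoint cuts
brute_youden <- function(values, labels, direction = "geq") {
  u <- sort(unique(values))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (t in cuts) {
    pred <- if (direction == "geq") values >= t else values <= t
    J <- sum(pred & labels) / sum(labels) +
      sum(!pred & !labels) / sum(!labels) - 1
    if (is.null(best) || J > best$J + 1e-12) best <- list(threshold = t, J = J)
  }
  best
}

# brute-force equal-width binning over (0, max], bin 0 for values <= 0
brute_bin <- function(values, n_bins = 11L) {
  pos <- values > 0
  k <- n_bins - 1L
  edges <- seq(0, max(values[pos]), length.out = k + 1L)
  bin <- integer(length(values))
  for (i in which(pos)) {
    for (b in seq_len(k)) {
      if (values[i] > edges[b] && values[i] <= edges[b + 1] + 1e-12) {
        bin[i] <- b
        break
      }
    }
    if (bin[i] == 0L) bin[i] <- k  # top-edge rounding guard
  }
  bin
}
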