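#' Scanner model for the resolution-matched forward simulation
#'
#' Describes the imaging chain as a Gaussian point-spread function plus
#' Poisson counting statistics. Because the regional input concentrations
#' are derived from smoothed clinical images, the kernel actually applied
#' by the forward model is the quadrature sum of the scanner PSF and the
#' processing smoothing kernel, so simulated and participant-equivalent
#' images share one effective resolution (about 7.3 mm in plane by default).
#'
#' @param psf_fwhm_inplane scanner in-plane FWHM in mm (default 4.1).
#' @param psf_fwhm_axial scanner axial FWHM in mm (default 4.3).
#' @param processing_smooth_fwhm processing smoothing FWHM in mm
#'   (default 6.0); combined in quadrature with the scanner PSF.
#' @param grid reconstruction [voxel_grid()]; the default is the clinical
#'   128 x 128 x 63 matrix at 2.574 x 2.574 x 2.425 mm.
#' @param sensitivity expected detected counts per kBq.s in one voxel-mL;
#'   the single free noise-calibration constant of the model.
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(psf_fwhm_inplane = 4.1,
                          psf_fwhm_axial = 4.3,
                          processing_smooth_fwhm = 6.0,
                          grid = voxel_grid(c(128, 128, 63),
                                            c(2.574, 2.574, 2.425)),
                          sensitivity = 0.01) {
  stopifnot(psf_fwhm_inplane >= 0, psf_fwhm_axial >= 0,
            processing_smooth_fwhm >= 0, sensitivity > 0,
            inherits(grid, "voxel_grid"))
  structure(list(psf_fwhm_inplane = psf_fwhm_inplane,
                 psf_fwhm_axial = psf_fwhm_axial,
                 processing_smooth_fwhm = processing_smooth_fwhm,
                 grid = grid, sensitivity = sensitivity),
            class = "scanner_model")
}

#' Effective simulation PSF of a scanner model
#'
#' @param scanner a [scanner_model()].
#' @return FWHM per axis in mm (length 3), the quadrature sum of scanner
#'   and processing kernels.
#' @export
effective_psf <- function(scanner) {
  stopifnot(inherits(scanner, "scanner_model"))
  sqrt(c(scanner$psf_fwhm_inplane, scanner$psf_fwhm_inplane,
         scanner$psf_fwhm_axial)^2 + scanner$processing_smooth_fwhm^2)
}

#' Frame schedule
#'
#' Non-overlapping acquisition frames, by default four 5-minute frames
#' starting 70 minutes post-injection, with the F-18 half-life.
#'
#' @param starts frame start times in seconds post-injection.
#' @param durations frame durations in seconds (> 0).
#' @param half_life isotope half-life in seconds (default 6586.2, F-18).
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(starts = 4200 + 300 * (0:3),
                           durations = rep(300, length(starts)),
                           half_life = 6586.2) {
  stopifnot(length(starts) == length(durations), all(durations > 0),
            half_life > 0)
  o <- order(starts)
  starts <- starts[o]; durations <- durations[o]
  if (length(starts) > 1 &&
      any(starts[-1] < (starts + durations)[-length(starts)] - 1e-9))
    stop("frame_schedule: frames overlap")
  structure(list(starts = starts, durations = durations,
                 half_life = half_life),
            class = "frame_schedule")
}

#' Mean physical decay factor over a frame
#'
#' The average of `2^(-t / half_life)` over the frame, in closed form.
#'
#' @param start frame start in seconds post-injection.
#' @param duration frame duration in seconds.
#' @param half_life isotope half-life in seconds.
#' @return Dimensionless decay factor in (0, 1].
#' @export
decay_factor <- function(start, duration, half_life) {
  lambda <- log(2) / half_life
  (exp(-lambda * start) - exp(-lambda * (start + duration))) /
    (lambda * duration)
}

# blurred concentration volume on the scanner grid (the noiseless image)
noiseless_volume <- function(emission, scanner) {
  conc <- conc_image(emission)
  if (any(conc < 0)) stop("simulate_frame: negative concentrations")
  conc <- resample_volume(conc, emission$grid, scanner$grid, "trilinear")
  psf_blur(conc, effective_psf(scanner), scanner$grid$voxel_size)
}

#' Simulate one PET frame
#'
#' Forward model: the emission concentrations are resampled to the scanner
#' grid, blurred with the effective PSF, converted to expected counts
#' (concentration x voxel volume x sensitivity x duration x mean decay
#' factor), Poisson noise is drawn, and the counts are scaled back to
#' decay-corrected concentration units. With `noiseless = TRUE` (the
#' sensitivity to infinity limit) the blurred concentration volume is
#' returned exactly.
#'
#' @param emission an emission map.
#' @param scanner a [scanner_model()].
#' @param schedule a [frame_schedule()].
#' @param frame frame index into the schedule.
#' @param seed optional integer seed for the Poisson draw (when `NULL`, the
#'   current RNG stream is used).
#' @param noiseless logical; skip the counting noise.
#' @return A [pet_image()] in kBq/mL.
#' @export
simulate_frame <- function(emission, scanner, schedule = frame_schedule(),
                           frame = 1L, seed = NULL, noiseless = FALSE) {
  stopifnot(inherits(scanner, "scanner_model"),
            inherits(schedule, "frame_schedule"),
            frame >= 1, frame <= length(schedule$starts))
  blurred <- noiseless_volume(emission, scanner)
  prov <- list(frame = frame, start = schedule$starts[frame],
               duration = schedule$durations[frame],
               seed = seed, noiseless = noiseless,
               scanner = scanner[c("psf_fwhm_inplane", "psf_fwhm_axial",
                                   "processing_smooth_fwhm", "sensitivity")])
  if (noiseless)
    return(pet_image(blurred, scanner$grid, "kBq/mL", prov))
  dcf <- decay_factor(schedule$starts[frame], schedule$durations[frame],
                      schedule$half_life)
  scale <- prod(scanner$grid$voxel_size) / 1000 * scanner$sensitivity *
    schedule$durations[frame] * dcf
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(blurred), pmax(blurred, 0) * scale)
  pet_image(array(counts / scale, dim = scanner$grid$shape),
            scanner$grid, "kBq/mL", prov)
}

#' Sum frames into a reconstructed scan
#'
#' Duration-weighted mean of the decay-corrected frames, mirroring the
#' clinical align-and-sum step (no motion in the simulation, so no
#' alignment). Post-reconstruction smoothing is off by default because the
#' effective PSF is already applied in the forward model.
#'
#' @param frames list of [pet_image()] frames on a common grid.
#' @param processing_smooth logical; apply the scanner's processing
#'   smoothing kernel to the summed image.
#' @param scanner a [scanner_model()], required when `processing_smooth`.
#' @return A [pet_image()] in kBq/mL.
#' @export
reconstruct_scan <- function(frames, processing_smooth = FALSE,
                             scanner = NULL) {
  stopifnot(length(frames) >= 1)
  grid <- frames[[1]]$grid
  for (f in frames)
    if (!same_grid(f$grid, grid)) stop("reconstruct_scan: grid mismatch")
  w <- vapply(frames, function(f) f$provenance$duration %||% 1, numeric(1))
  w <- w / sum(w)
  acc <- array(0, grid$shape)
  for (i in seq_along(frames)) acc <- acc + w[i] * frames[[i]]$values
  if (processing_smooth) {
    stopifnot(inherits(scanner, "scanner_model"))
    acc <- psf_blur(acc, rep(scanner$processing_smooth_fwhm, 3),
                    grid$voxel_size)
  }
  pet_image(acc, grid, "kBq/mL",
            list(n_frames = length(frames),
                 frames = lapply(frames, function(f)
                   f$provenance[c("frame", "start", "duration", "seed")]),
                 processing_smooth = processing_smooth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run seeded scan realizations
#'
#' Simulates `n` independent, reproducible realizations of the full frame
#' schedule; realization `i` uses seed `base_seed + i`. A manifest of the
#' seeds is attached to the result.
#'
#' @param emission an emission map.
#' @param scanner a [scanner_model()].
#' @param schedule a [frame_schedule()].
#' @param n number of realizations (>= 1).
#' @param base_seed integer base seed.
#' @param noiseless logical; noiseless realizations are all identical.
#' @return List of reconstructed [pet_image()]s with a `seeds` attribute.
#' @export
run_realizations <- function(emission, scanner, schedule = frame_schedule(),
                             n = 10L, base_seed = 1L, noiseless = FALSE) {
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n)
  blurred <- noiseless_volume(emission, scanner)
  out <- lapply(seeds, function(s) {
    set.seed(s)
    img <- realize_scan(blurred, scanner, schedule, noiseless)
    img$provenance$seed <- s
    img
  })
  attr(out, "seeds") <- seeds
  out
}

# one full-schedule realization from a precomputed blurred volume,
# using the current RNG stream
realize_scan <- function(blurred, scanner, schedule, noiseless = FALSE) {
  grid <- scanner$grid
  if (noiseless) {
    return(pet_image(blurred, grid, "kBq/mL",
                     list(noiseless = TRUE,
                          n_frames = length(schedule$starts))))
  }
  w <- schedule$durations / sum(schedule$durations)
  acc <- array(0, grid$shape)
  for (k in seq_along(schedule$starts)) {
    dcf <- decay_factor(schedule$starts[k], schedule$durations[k],
                        schedule$half_life)
    scale <- prod(grid$voxel_size) / 1000 * scanner$sensitivity *
      schedule$durations[k] * dcf
    counts <- stats::rpois(length(blurred), pmax(blurred, 0) * scale)
    acc <- acc + w[k] * counts / scale
  }
  pet_image(array(acc, grid$shape), grid, "kBq/mL",
            list(noiseless = FALSE, n_frames = length(schedule$starts)))
}

#' Noiseless reconstructed scan
#'
#' Convenience wrapper: the noiseless forward model of the whole scan (the
#' blurred concentration volume, identical for every frame).
#'
#' @inheritParams run_realizations
#' @return A [pet_image()] in kBq/mL.
#' @export
simulate_noiseless <- function(emission, scanner, schedule = frame_schedule()) {
  realize_scan(noiseless_volume(emission, scanner), scanner, schedule,
               noiseless = TRUE)
}
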