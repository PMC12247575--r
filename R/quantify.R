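#' Convert a concentration image to SUV
#'
#' SUV = concentration / (injected dose / body weight), with the dose in
#' kBq and the weight in grams, assuming unit tissue density. At the
#' nominal 370 MBq and 60 kg the divisor is 370,000 kBq / 60,000 g.
#'
#' @param image a [pet_image()] in kBq/mL.
#' @param injected_dose_MBq injected dose in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @return A [pet_image()] in SUV.
#' @export
to_suv <- function(image, injected_dose_MBq = 370, weight_kg = 60) {
  stopifnot(inherits(image, "pet_image"),
            injected_dose_MBq > 0, weight_kg > 0)
  if (image$unit != "kBq/mL")
    stop("to_suv: expected a kBq/mL image, got ", image$unit)
  divisor <- (injected_dose_MBq * 1000) / (weight_kg * 1000)
  prov <- image$provenance
  prov$injected_dose_MBq <- injected_dose_MBq
  prov$weight_kg <- weight_kg
  pet_image(image$values / divisor, image$grid, "SUV", prov)
}

#' ROI mean and standard deviation
#'
#' Mean, sample standard deviation (n - 1) and voxel count over a mask.
#' A mask on a different grid is resampled to the image grid by
#' nearest-neighbour lookup; this is recorded in the result.
#'
#' @param image a [pet_image()].
#' @param mask logical array, or a list with `mask` and `grid`.
#' @param region optional region name for the record.
#' @return An object of class `roi_stats` with fields `region`, `mean`,
#'   `sd`, `n`, `unit`, `resampled`.
#' @export
roi_mean <- function(image, mask, region = NA_character_) {
  stopifnot(inherits(image, "pet_image"))
  resampled <- FALSE
  if (is.list(mask) && !is.null(mask$grid)) {
    if (!same_grid(mask$grid, image$grid)) {
      mask <- resample_volume(mask$mask * 1, mask$grid, image$grid,
                              "nearest") > 0.5
      resampled <- TRUE
    } else mask <- mask$mask
  }
  if (!identical(dim(mask), image$grid$shape))
    stop("roi_mean: mask is not on the image grid")
  v <- image$values[mask]
  if (!length(v)) stop("roi_mean: empty mask")
  structure(list(region = region, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v), unit = image$unit, resampled = resampled),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s: %.4g (%.3g), n = %d [%s]\n",
              if (is.na(x$region)) "ROI" else x$region,
              x$mean, x$sd, x$n, x$unit))
  invisible(x)
}

#' Convert an image to SUVR against a reference region
#'
#' Divides the image voxelwise by the reference-ROI mean; the reference
#' region's own SUVR is 1 by construction and any global scaling of the
#' input leaves the SUVR unchanged.
#'
#' @param image a [pet_image()] (kBq/mL or SUV).
#' @param reference_mask logical array on the image grid.
#' @param masks optional named list of masks; when given, a data.frame of
#'   per-region SUVR statistics is attached as attribute `"roi_table"`.
#' @param reference_name name recorded in provenance.
#' @return A [pet_image()] in SUVR.
#' @export
compute_suvr <- function(image, reference_mask, masks = NULL,
                         reference_name = "inferior_cerebellum") {
  ref <- roi_mean(image, reference_mask, reference_name)
  if (ref$mean <= 0)
    stop("compute_suvr: reference ROI mean is not positive")
  prov <- image$provenance
  prov$reference_region <- reference_name
  prov$reference_mean <- ref$mean
  out <- pet_image(image$values / ref$mean, image$grid, "SUVR", prov)
  if (!is.null(masks)) {
    tab <- roi_table(out, masks)
    attr(out, "roi_table") <- tab
  }
  out
}

#' Tabulate ROI statistics over a set of masks
#'
#' @param image a [pet_image()].
#' @param masks named list of logical arrays.
#' @return data.frame with columns `region`, `mean`, `sd`, `n`, `unit`.
#' @export
roi_table <- function(image, masks) {
  rows <- lapply(names(masks), function(nm) {
    s <- roi_mean(image, masks[[nm]], nm)
    data.frame(region = nm, mean = s$mean, sd = s$sd, n = s$n,
               unit = s$unit, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Absolute and signed percent difference from a baseline
#'
#' The absolute convention is `100 * |value - baseline| / baseline`; set
#' `signed = TRUE` for the directional variant.
#'
#' @param value,baseline numeric (baseline > 0); vectorized.
#' @param signed logical.
#' @return Percent difference(s).
#' @export
percent_delta <- function(value, baseline, signed = FALSE) {
  if (any(baseline <= 0)) stop("percent_delta: baseline must be > 0")
  d <- 100 * (value - baseline) / baseline
  if (signed) d else abs(d)
}

#' Longitudinal percent-change summary for paired scans
#'
#' Per-pair signed percent change `100 * (v2 - v1) / v1`, summarized as the
#' cohort signed mean (SD), the absolute mean (SD) — the mean distance from
#' zero change — and the fraction of pairs beyond +/-10%.
#'
#' @param scan1,scan2 positive ROI values of the first and second scans.
#' @return An object of class `cohort_change`.
#' @export
longitudinal_change <- function(scan1, scan2) {
  stopifnot(length(scan1) == length(scan2), length(scan1) >= 1)
  if (any(scan1 <= 0) || any(scan2 <= 0))
    stop("longitudinal_change: values must be positive")
  signed <- 100 * (scan2 - scan1) / scan1
  structure(list(signed = signed,
                 signed_mean = mean(signed),
                 signed_sd = if (length(signed) > 1) stats::sd(signed) else 0,
                 abs_mean = mean(abs(signed)),
                 abs_sd = if (length(signed) > 1) stats::sd(abs(signed)) else 0,
                 frac_beyond_10 = mean(abs(signed) > 10)),
            class = "cohort_change")
}

#' @export
print.cohort_change <- function(x, ...) {
  cat(sprintf(paste0("<cohort_change> signed %.1f(%.1f)%%, absolute ",
                     "%.1f(%.1f)%%, %.0f%% beyond +/-10%%\n"),
              x$signed_mean, x$signed_sd, x$abs_mean, x$abs_sd,
              100 * x$frac_beyond_10))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (>= 3 points, nonzero variance).
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson_r: need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("pearson_r: zero variance")
  stats::cor(x, y)
}

#' Ordinary least-squares line
#'
#' @param x,y numeric vectors with at least two distinct x.
#' @return List with `slope`, `intercept`, `r`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("linear_fit: degenerate x")
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r = if (stats::var(y) > 0) stats::cor(x, y) else NA_real_)
}
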