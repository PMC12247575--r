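#' Simulation-based spill-in correction factor (SCF)
#'
#' A linear estimate of the ECB spill-in contribution to a target region,
#' subtracted from the measured SUV:
#' `corrected = target - (slope * source + intercept)`.
#' The two built-in models are the published ECAT HR+ factors:
#' ERC corrected by the sinus, `SUV - (0.22 * SUV_sinus - 0.75)`, and
#' inferior cerebellum corrected by the meninges,
#' `SUV - (0.14 * SUV_meninges - 0.55)`.
#'
#' @param slope spill coefficient (SUV per SUV).
#' @param intercept intercept of the correction term (SUV).
#' @param target,source region names; the built-in pair uses
#'   sinus -> ERC and meninges -> cerebellum.
#' @param provenance named list (fit inputs, scanner configuration, ...).
#' @return An object of class `scf_model`.
#' @export
scf_model <- function(slope, intercept, target = "erc", source = "sinus",
                      provenance = list()) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept,
                 target = target, source = source, provenance = provenance),
            class = "scf_model")
}

#' @export
print.scf_model <- function(x, ...) {
  cat(sprintf("<scf_model> %s' = %s - (%.4g * %s %+.4g)\n",
              x$target, x$target, x$slope, x$source, x$intercept))
  invisible(x)
}

#' @rdname scf_model
#' @export
scf_erc <- function() {
  scf_model(0.22, -0.75, "erc", "sinus",
            provenance = list(origin = "published ECAT HR+ factors"))
}

#' @rdname scf_model
#' @export
scf_cerebellum <- function() {
  scf_model(0.14, -0.55, "cerebellum", "meninges",
            provenance = list(origin = "published ECAT HR+ factors"))
}

#' Apply an SCF to target SUVs
#'
#' The correction term is subtracted as-is; values below the no-ECB
#' baseline are returned unclipped.
#'
#' @param target_suv,source_suv finite SUVs (vectorized).
#' @param model an [scf_model()].
#' @return Corrected SUV(s).
#' @export
apply_scf <- function(target_suv, source_suv, model) {
  stopifnot(inherits(model, "scf_model"),
            all(is.finite(target_suv)), all(is.finite(source_suv)))
  target_suv - (model$slope * source_suv + model$intercept)
}

#' Derive an SCF from a series of profiles
#'
#' Fits the target SUV on the source SUV by ordinary least squares across
#' ECB profiles; the slope is the spill coefficient. Because the OLS
#' intercept on group means does not pin down the correction offset, the
#' intercept term is anchored so that the baseline profile corrects exactly
#' to the known no-spill truth:
#' `intercept = target[baseline] - slope * source[baseline] - baseline_true_suv`.
#'
#' @param source_suv,target_suv SUVs across profiles (>= 3 distinct source
#'   values).
#' @param baseline_true_suv the true, spill-free target SUV.
#' @param baseline index of the baseline (no-ECB) profile in the series.
#' @param target,source region names for the model.
#' @return An [scf_model()] with the fit correlation in `provenance$r`.
#' @export
derive_scf <- function(source_suv, target_suv, baseline_true_suv,
                       baseline = 1L, target = "erc", source = "sinus") {
  stopifnot(length(source_suv) == length(target_suv))
  if (length(unique(source_suv)) < 3)
    stop("derive_scf: need at least 3 profiles with distinct source SUVs")
  fit <- linear_fit(source_suv, target_suv)
  intercept <- target_suv[baseline] - fit$slope * source_suv[baseline] -
    baseline_true_suv
  scf_model(fit$slope, intercept, target, source,
            provenance = list(r = fit$r, ols_intercept = fit$intercept,
                              baseline_true_suv = baseline_true_suv,
                              n = length(source_suv)))
}

#' Evaluate corrections across ECB groups
#'
#' For each group and each of the two target regions, computes the absolute
#' percent difference from the baseline group (`|value - baseline| /
#' baseline`) of the uncorrected, SCF-corrected and (optionally)
#' PVC-corrected SUVs. The SCF is applied to every group including the
#' baseline before the percent differences are taken.
#'
#' @param groups data.frame with columns `group`, `erc`, `sinus`,
#'   `cerebellum`, `meninges`, and optionally `pvc_erc`, `pvc_cerebellum`.
#' @param scf_erc_model,scf_cer_model [scf_model()]s for the two regions.
#' @param baseline baseline group name (default `"BKG"`).
#' @return A `correction_report` data.frame with the corrected SUVs and the
#'   percent-difference columns.
#' @export
evaluate_corrections <- function(groups,
                                 scf_erc_model = scf_erc(),
                                 scf_cer_model = scf_cerebellum(),
                                 baseline = "BKG") {
  need <- c("group", "erc", "sinus", "cerebellum", "meninges")
  missing <- setdiff(need, names(groups))
  if (length(missing))
    stop("evaluate_corrections: missing region column(s): ",
         paste(missing, collapse = ", "))
  if (!baseline %in% groups$group)
    stop("evaluate_corrections: baseline group '", baseline, "' not present")
  g <- groups
  g$erc_scf <- apply_scf(g$erc, g$sinus, scf_erc_model)
  g$cerebellum_scf <- apply_scf(g$cerebellum, g$meninges, scf_cer_model)
  b <- g[g$group == baseline, ]
  out <- data.frame(
    group = g$group,
    erc_pct_uncorrected = percent_delta(g$erc, b$erc),
    erc_pct_scf = percent_delta(g$erc_scf, b$erc_scf),
    cerebellum_pct_uncorrected = percent_delta(g$cerebellum, b$cerebellum),
    cerebellum_pct_scf = percent_delta(g$cerebellum_scf, b$cerebellum_scf),
    stringsAsFactors = FALSE
  )
  if (all(c("pvc_erc", "pvc_cerebellum") %in% names(groups))) {
    out$erc_pct_pvc <- percent_delta(g$pvc_erc, b$pvc_erc)
    out$cerebellum_pct_pvc <- percent_delta(g$pvc_cerebellum, b$pvc_cerebellum)
  }
  out <- cbind(out, g[, c("erc", "erc_scf", "cerebellum", "cerebellum_scf")])
  class(out) <- c("correction_report", "data.frame")
  out
}
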