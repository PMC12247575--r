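#' Tau-positivity classification
#'
#' A scan is tau positive when its ERC SUVR is at least the threshold
#' (boundary inclusive); the conventional uncorrected threshold is 1.27.
#'
#' @param erc_suvr finite SUVR value(s).
#' @param threshold positivity threshold (default 1.27).
#' @return Character vector `"positive"` / `"negative"`.
#' @export
classify_tau <- function(erc_suvr, threshold = 1.27) {
  stopifnot(all(is.finite(erc_suvr)), threshold > 0)
  ifelse(erc_suvr >= threshold, "positive", "negative")
}

#' Detection-threshold search configuration
#'
#' @param suvr_threshold tau-positivity SUVR threshold (default 1.27).
#' @param n_realizations realizations per probe (>= 2 so the SD exists).
#' @param sd_multiplier the stopping rule requires
#'   `mean - sd_multiplier * SD >= suvr_threshold` (default 2, so about
#'   97.7% of realizations exceed the threshold).
#' @param search_min,search_max bounds on the probed percent-above-reference.
#' @param rel_tol relative bisection tolerance on the returned threshold.
#' @param coarse_factor geometric growth factor of the coarse scan.
#' @param scan_step step (percent) of the linear-scan strategy.
#' @param strategy `"bisect"` (coarse geometric scan then bisection) or
#'   `"scan"` (linear scan at `scan_step`).
#' @param seed base seed; each probe derives its own seed from it and the
#'   probed percentage, so strategies see identical noise at equal probes.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(suvr_threshold = 1.27, n_realizations = 10L,
                             sd_multiplier = 2, search_min = 0,
                             search_max = 3200, rel_tol = 0.01,
                             coarse_factor = 2, scan_step = 25,
                             strategy = c("bisect", "scan"), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(suvr_threshold > 0, n_realizations >= 2, sd_multiplier >= 0,
            search_max > search_min, rel_tol > 0, coarse_factor > 1,
            scan_step > 0)
  structure(list(suvr_threshold = suvr_threshold,
                 n_realizations = as.integer(n_realizations),
                 sd_multiplier = sd_multiplier,
                 search_min = search_min, search_max = search_max,
                 rel_tol = rel_tol, coarse_factor = coarse_factor,
                 scan_step = scan_step, strategy = strategy,
                 seed = as.integer(seed)),
            class = "detection_config")
}

# Precomputed linear response of the forward model in the Braak I input:
# image(p) = base + (1 + p/100) * erc_component, both already blurred.
# Exploits linearity of the noiseless model so each probe costs only a
# Poisson draw, not a convolution.
detection_engine <- function(emission, phantom, scanner,
                             schedule = frame_schedule()) {
  masks <- phantom_masks(phantom)
  em0 <- emission
  em0$conc["3"] <- 0
  base <- noiseless_volume(em0, scanner)
  erc_ind <- emission
  erc_ind$conc[] <- 0
  erc_ind$conc["3"] <- emission$reference_concentration
  erc_unit <- noiseless_volume(erc_ind, scanner)
  if (!same_grid(phantom$grid, scanner$grid))
    stop("detection_engine: phantom and scanner grids must agree")
  list(base = base, erc_unit = erc_unit, scanner = scanner,
       schedule = schedule,
       erc_mask = masks$erc, ref_mask = masks$inferior_cerebellum)
}

# ERC SUVR of n realizations at percent-above-reference p. The Poisson
# draws are restricted to the two ROIs involved (voxel noise is
# independent, so the restriction is exact and much cheaper than a
# full-volume realization).
probe_erc_suvr <- function(engine, p, n, seed, noiseless = FALSE) {
  blurred <- engine$base + (1 + p / 100) * engine$erc_unit
  erc_v <- blurred[engine$erc_mask]
  ref_v <- blurred[engine$ref_mask]
  if (noiseless) return(mean(erc_v) / mean(ref_v))
  sch <- engine$schedule
  scanner <- engine$scanner
  w <- sch$durations / sum(sch$durations)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    erc_acc <- 0; ref_acc <- 0
    for (k in seq_along(sch$starts)) {
      dcf <- decay_factor(sch$starts[k], sch$durations[k], sch$half_life)
      scale <- prod(scanner$grid$voxel_size) / 1000 * scanner$sensitivity *
        sch$durations[k] * dcf
      erc_acc <- erc_acc +
        w[k] * mean(stats::rpois(length(erc_v), pmax(erc_v, 0) * scale)) / scale
      ref_acc <- ref_acc +
        w[k] * mean(stats::rpois(length(ref_v), pmax(ref_v, 0) * scale)) / scale
    }
    erc_acc / ref_acc
  }, numeric(1))
}

probe_seed <- function(base_seed, p) {
  as.integer((as.numeric(base_seed) * 131071 + round(p * 10)) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Search the tau-detection threshold on Braak I input activity
#'
#' Finds the smallest percent-above-reference Braak I concentration at
#' which the mean ERC SUVR over `n_realizations` simulated scans exceeds
#' the positivity threshold by `sd_multiplier` standard deviations
#' (`mean - k * SD >= threshold`), so nearly all scans at that input would
#' be classified tau positive. If the rule already holds with no specific
#' binding (p = 0) the result is 0 with a `positive_at_baseline` flag.
#'
#' @param calibration an [calibrate_ecb_activities()] result for the ECB
#'   profile under study.
#' @param phantom the phantom the calibration was built on.
#' @param scanner a [scanner_model()] whose grid matches the phantom.
#' @param schedule a [frame_schedule()].
#' @param config a [detection_config()].
#' @param region_ratios cerebral concentrations for the emission map.
#' @param noiseless logical; with `TRUE` the SD is zero and the rule
#'   reduces to `mean >= threshold`.
#' @return An object of class `detection_result` with the threshold
#'   `p_star`, the ERC SUVR mean and SD at threshold, the probe log and
#'   the realization manifest.
#' @export
find_detection_threshold <- function(calibration, phantom, scanner,
                                     schedule = frame_schedule(),
                                     config = detection_config(),
                                     region_ratios = default_region_ratios(),
                                     noiseless = FALSE) {
  emission <- build_emission_map(phantom, calibration, region_ratios)
  emission <- set_braak1_concentration(emission, 0)
  engine <- detection_engine(emission, phantom, scanner, schedule)
  probes <- list()
  rule <- function(p) {
    s <- probe_erc_suvr(engine, p, config$n_realizations,
                        probe_seed(config$seed, p), noiseless)
    m <- mean(s)
    sd <- if (length(s) > 1) stats::sd(s) else 0
    probes[[length(probes) + 1L]] <<-
      data.frame(p = p, mean = m, sd = sd,
                 ok = (m - config$sd_multiplier * sd >= config$suvr_threshold))
    list(ok = m - config$sd_multiplier * sd >= config$suvr_threshold,
         mean = m, sd = sd, suvr = s)
  }
  finish <- function(p, at) {
    structure(list(profile = calibration$profile$name, p_star = p,
                   mean = at$mean, sd = at$sd, suvr = at$suvr,
                   positive_at_baseline = (p == config$search_min),
                   probes = do.call(rbind, probes),
                   config = config, noiseless = noiseless),
              class = "detection_result")
  }
  at0 <- rule(config$search_min)
  if (at0$ok) return(finish(config$search_min, at0))

  if (config$strategy == "scan") {
    p <- config$search_min
    repeat {
      p <- p + config$scan_step
      if (p > config$search_max)
        stop(errorCondition(
          paste0("find_detection_threshold: rule unreachable within bounds ",
                 "(max achieved mean ", signif(max(vapply(probes, `[[`,
                 numeric(1), "mean")), 4), ")"),
          probes = do.call(rbind, probes), class = c("detection_error", "error")))
      at <- rule(p)
      if (at$ok) return(finish(p, at))
    }
  }
  # coarse geometric bracket then bisection
  lo <- config$search_min
  hi <- min(max(config$scan_step, 50), config$search_max)
  at_hi <- rule(hi)
  while (!at_hi$ok) {
    if (hi >= config$search_max)
      stop(errorCondition(
        paste0("find_detection_threshold: rule unreachable within bounds ",
               "(max achieved mean ", signif(max(vapply(probes, `[[`,
               numeric(1), "mean")), 4), ")"),
        probes = do.call(rbind, probes), class = c("detection_error", "error")))
    lo <- hi
    hi <- min(hi * config$coarse_factor, config$search_max)
    at_hi <- rule(hi)
  }
  while ((hi - lo) / hi > config$rel_tol) {
    mid <- (hi + lo) / 2
    at <- rule(mid)
    if (at$ok) { hi <- mid; at_hi <- at } else lo <- mid
  }
  finish(hi, at_hi)
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(paste0("<detection_result> %s: p* = %.1f%% above reference ",
                     "(ERC SUVR %.3f(%.3f))%s\n"),
              x$profile, x$p_star, x$mean, x$sd,
              if (x$positive_at_baseline) " [positive at baseline]" else ""))
  invisible(x)
}

#' Compare detection thresholds across profiles
#'
#' Signed percent difference of each profile's input-activity threshold
#' relative to the baseline profile (the population-average profile by
#' convention, since the positivity threshold was established on the
#' population average).
#'
#' @param results list of [find_detection_threshold()] results.
#' @param baseline baseline profile name (default `"AVG"`).
#' @return data.frame with columns `profile`, `p_star`,
#'   `pct_vs_baseline`, `positive_at_baseline`.
#' @export
compare_thresholds <- function(results, baseline = "AVG") {
  profs <- vapply(results, `[[`, character(1), "profile")
  if (!baseline %in% profs)
    stop("compare_thresholds: baseline profile '", baseline, "' not present")
  p <- vapply(results, `[[`, numeric(1), "p_star")
  pb <- p[match(baseline, profs)]
  if (pb == 0)
    stop("compare_thresholds: baseline threshold is 0; percent difference undefined")
  data.frame(profile = profs, p_star = p,
             pct_vs_baseline = 100 * (p - pb) / pb,
             positive_at_baseline = vapply(results, `[[`, logical(1),
                                           "positive_at_baseline"),
             stringsAsFactors = FALSE)
}
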