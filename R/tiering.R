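#' ROC threshold by Youden's index
#'
#' Scans every candidate cut (the midpoints between consecutive sorted
#' unique values) with the decision rule "positive when value >= cut" (or
#' `<=` with `direction = "leq"`), and returns the cut maximizing
#' `J = sensitivity + specificity - 1`; ties are broken toward the lowest
#' threshold.
#'
#' @param values numeric marker values.
#' @param labels logical (or 0/1) true class; both classes must be present.
#' @param direction `"geq"` (default) or `"leq"`.
#' @return List with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
roc_youden_threshold <- function(values, labels, direction = c("geq", "leq")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels))
  if (all(labels) || !any(labels))
    stop("roc_youden_threshold: both classes must be present")
  u <- sort(unique(values))
  if (length(u) < 2)
    stop("roc_youden_threshold: all values identical")
  cuts <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(labels); nneg <- sum(!labels)
  stats <- vapply(cuts, function(t) {
    pred <- if (direction == "geq") values >= t else values <= t
    sens <- sum(pred & labels) / npos
    spec <- sum(!pred & !labels) / nneg
    c(sens, spec, sens + spec - 1)
  }, numeric(3))
  best <- which(stats[3, ] >= max(stats[3, ]) - 1e-12)[1]
  list(threshold = cuts[best], J = stats[3, best],
       sensitivity = stats[1, best], specificity = stats[2, best])
}

#' ECB tier thresholds
#'
#' @param moderate_cut,high_cut meningeal SUVR cutpoints
#'   (`moderate_cut < high_cut`).
#' @param youden_moderate,youden_high the Youden J values of the two cuts.
#' @return An object of class `tier_thresholds`.
#' @export
tier_thresholds <- function(moderate_cut, high_cut,
                            youden_moderate = NA_real_,
                            youden_high = NA_real_) {
  if (!(moderate_cut < high_cut))
    stop("tier_thresholds: moderate_cut must be below high_cut")
  structure(list(moderate_cut = moderate_cut, high_cut = high_cut,
                 youden_moderate = youden_moderate,
                 youden_high = youden_high),
            class = "tier_thresholds")
}

#' Classify a scan into an ECB tier
#'
#' Low below the moderate cut, Moderate from the moderate cut up to (not
#' including) the high cut, High at or above the high cut; a value equal to
#' a cut goes to the higher tier (intervals closed on the left).
#'
#' @param meningeal_suvr numeric SUVR value(s).
#' @param thresholds a [tier_thresholds()].
#' @return Factor with levels Low, Moderate, High.
#' @export
classify_tier <- function(meningeal_suvr, thresholds) {
  stopifnot(inherits(thresholds, "tier_thresholds"))
  out <- ifelse(meningeal_suvr < thresholds$moderate_cut, "Low",
                ifelse(meningeal_suvr < thresholds$high_cut, "Moderate",
                       "High"))
  factor(out, levels = c("Low", "Moderate", "High"))
}

#' Synthetic visually-rated cohort
#'
#' Draws meningeal SUVRs from a truncated lognormal spanning the observed
#' clinical range (right-skewed, as meningeal uptake is, so the default
#' parameters put roughly 65/27/9 percent of the cohort below, between and
#' above the clinical tier cutpoints) and assigns 0-5 visual ratings
#' through a monotone noisy link: a latent value `SUVR + noise` is cut at
#' the generating tier cutpoints (scores 0-1 below the moderate cut, 2-3
#' between the cuts, 4-5 above, each tier split at its midpoint). With
#' `noise_sd = 0` the rating is a deterministic step function of the SUVR.
#'
#' @param n cohort size (>= 20).
#' @param seed integer seed.
#' @param cuts generating (moderate, high) cutpoints.
#' @param noise_sd SD of the latent rating noise (SUVR units).
#' @param suvr_range truncation range of the SUVR distribution.
#' @param suvr_median,suvr_sdlog median and log-scale SD of the lognormal
#'   SUVR distribution.
#' @return data.frame with columns `id`, `meninges_suvr`, `rating`.
#' @export
generate_synthetic_ratings <- function(n, seed = 1L, cuts = c(1.07, 1.34),
                                       noise_sd = 0.1,
                                       suvr_range = c(0.57, 2.10),
                                       suvr_median = 0.98,
                                       suvr_sdlog = 0.23) {
  stopifnot(n >= 20, length(cuts) == 2, cuts[1] < cuts[2], noise_sd >= 0)
  with_seed(seed, {
    suvr <- numeric(0)
    while (length(suvr) < n) {
      draw <- stats::rlnorm(2 * n, log(suvr_median), suvr_sdlog)
      suvr <- c(suvr, draw[draw >= suvr_range[1] & draw <= suvr_range[2]])
    }
    suvr <- suvr[seq_len(n)]
    latent <- suvr + stats::rnorm(n, 0, noise_sd)
    sub <- c(mean(c(suvr_range[1], cuts[1])), mean(cuts),
             mean(c(cuts[2], suvr_range[2])))
    rating <- findInterval(latent, sort(c(sub[1], cuts[1], sub[2],
                                          cuts[2], sub[3])))
    data.frame(id = seq_len(n), meninges_suvr = suvr,
               rating = as.integer(rating))
  })
}

#' Recover tier thresholds from a rated cohort
#'
#' Dichotomizes the ratings the way the tiers are defined (Moderate cut:
#' rating >= 2 vs <= 1; High cut: rating >= 4 vs <= 3) and fits each cut
#' by [roc_youden_threshold()].
#'
#' @param cohort data.frame with `meninges_suvr` and `rating` columns.
#' @return A [tier_thresholds()] carrying the Youden J values.
#' @export
recover_tier_thresholds <- function(cohort) {
  stopifnot(all(c("meninges_suvr", "rating") %in% names(cohort)))
  mod <- roc_youden_threshold(cohort$meninges_suvr, cohort$rating >= 2)
  hig <- roc_youden_threshold(cohort$meninges_suvr, cohort$rating >= 4)
  tier_thresholds(mod$threshold, hig$threshold, mod$J, hig$J)
}

#' Quartile comparison of ERC SUVR by sinus SUVR, before and after SCF
#'
#' Splits a cohort into sinus-SUVR quartiles (rank-based, so the quartiles
#' are balanced), fits the ERC-on-sinus slope, corrects the ERC values with
#' the SUVR-rescaled SCF, refits, and runs two-tailed Welch t-tests of the
#' first quartile against each of the others before and after correction.
#' The SUV-scale SCF intercept is rescaled to SUVR units by the reference
#' SUV (`intercept / reference_suv`); the slope is scale free because
#' target and source share the reference.
#'
#' @param sinus_suvr,erc_suvr paired cohort values (>= 8 scans).
#' @param scf an [scf_model()] in SUV units (default the built-in
#'   sinus-to-ERC factor).
#' @param reference_suv reference-region SUV used to rescale the intercept
#'   (default 8.36).
#' @return List with `quartiles` (per-quartile means), `slope_before`,
#'   `slope_after`, `tests` (Q1 vs Q2..Q4 p-values before/after) and the
#'   corrected values.
#' @export
quartile_group_test <- function(sinus_suvr, erc_suvr, scf = scf_erc(),
                                reference_suv = 8.36) {
  stopifnot(length(sinus_suvr) == length(erc_suvr))
  n <- length(sinus_suvr)
  if (n < 8) stop("quartile_group_test: need at least 8 scans")
  corrected <- erc_suvr - (scf$slope * sinus_suvr +
                             scf$intercept / reference_suv)
  q <- ceiling(4 * rank(sinus_suvr, ties.method = "first") / n)
  if (any(table(factor(q, levels = 1:4)) < 2))
    stop("quartile_group_test: fewer than 2 scans in a quartile")
  quart <- data.frame(
    quartile = paste0("Q", 1:4),
    n = as.vector(table(factor(q, levels = 1:4))),
    sinus_mean = tapply(sinus_suvr, q, mean),
    erc_mean = tapply(erc_suvr, q, mean),
    erc_corrected_mean = tapply(corrected, q, mean)
  )
  welch_p <- function(a, b) {
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  }
  tests <- do.call(rbind, lapply(2:4, function(k) {
    data.frame(comparison = paste0("Q1 vs Q", k),
               p_before = welch_p(erc_suvr[q == 1], erc_suvr[q == k]),
               p_after = welch_p(corrected[q == 1], corrected[q == k]))
  }))
  list(quartiles = quart,
       slope_before = linear_fit(sinus_suvr, erc_suvr)$slope,
       slope_after = linear_fit(sinus_suvr, corrected)$slope,
       tests = tests,
       corrected = corrected,
       quartile_assignment = q)
}
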