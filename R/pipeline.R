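#' Pipeline configuration
#'
#' Bundles every stage's configuration with explicit seeds. The default is
#' the desk-scale study: a 96^3 phantom at 2 mm, the six built-in ECB
#' profiles, ten noisy realizations per profile and the standard frame
#' schedule.
#'
#' @param spec a [phantom_spec()].
#' @param profiles character vector of profile names.
#' @param scanner a [scanner_model()]; by default the scanner grid is the
#'   phantom grid so no resampling is involved.
#' @param schedule a [frame_schedule()].
#' @param n_realizations noisy realizations per profile.
#' @param base_seed integer master seed; stage seeds derive from it.
#' @param run_detection logical; the detection-threshold search is the
#'   expensive stage and is off by default.
#' @param detection a [detection_config()].
#' @param rating_n synthetic rated-cohort size.
#' @param out_dir optional output directory for CSV reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = phantom_spec(),
                            profiles = c("BKG", "LOW", "AVG", "HIGH",
                                         "H_MENINGES", "H_SINUS"),
                            scanner = NULL,
                            schedule = frame_schedule(),
                            n_realizations = 10L,
                            base_seed = 1L,
                            run_detection = FALSE,
                            detection = detection_config(seed = base_seed),
                            rating_n = 433L,
                            out_dir = NULL) {
  if (is.null(scanner)) scanner <- scanner_model(grid = spec$grid)
  structure(list(spec = spec, profiles = profiles, scanner = scanner,
                 schedule = schedule,
                 n_realizations = as.integer(n_realizations),
                 base_seed = as.integer(base_seed),
                 run_detection = run_detection, detection = detection,
                 rating_n = as.integer(rating_n), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full ECB spill-in pipeline
#'
#' Orchestrates phantom construction, profile calibration, simulation,
#' SUV/SUVR tabulation, spill-in regression, correction derivation and
#' evaluation (SCF and Mueller-Gartner PVC), optional detection-threshold
#' search, and the tier-classification demonstration on a synthetic rated
#' cohort. Any stage failure is rethrown with the stage name. All outputs
#' are reproducible from the config seeds; when `out_dir` is set the
#' tables are written as CSV together with the serialized configuration.
#'
#' @param config a [pipeline_config()].
#' @return Named list of result tables and fitted models.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(config = config)

  phantom <- stage("phantom", build_phantom(config$spec))
  masks <- phantom_masks(phantom)
  roi_set <- masks[c("meninges_shell", "sinus", "inferior_cerebellum",
                     "erc", "insula")]
  names(roi_set) <- c("meninges", "sinus", "cerebellum", "erc", "ic")
  res$phantom <- phantom

  calibs <- stage("calibration", {
    cl <- lapply(config$profiles, function(nm)
      calibrate_ecb_activities(ecb_profile(nm, seed = config$base_seed + 100L),
                               phantom))
    names(cl) <- config$profiles
    cl
  })
  res$calibration <- data.frame(
    group = config$profiles,
    target_sinus = vapply(calibs, function(c) c$profile$target_sinus_suvr,
                          numeric(1)),
    achieved_sinus = vapply(calibs, function(c) c$achieved$sinus, numeric(1)),
    target_meninges = vapply(calibs, function(c) c$profile$target_meninges_suvr,
                             numeric(1)),
    achieved_meninges = vapply(calibs, function(c) c$achieved$meninges,
                               numeric(1)),
    iterations = vapply(calibs, `[[`, integer(1), "iterations")
  )

  sims <- stage("simulation", {
    lapply(seq_along(calibs), function(i) {
      emission <- build_emission_map(phantom, calibs[[i]])
      noiseless <- simulate_noiseless(emission, config$scanner,
                                      config$schedule)
      reals <- run_realizations(emission, config$scanner, config$schedule,
                                n = config$n_realizations,
                                base_seed = config$base_seed + 1000L * i)
      list(emission = emission, noiseless = noiseless, realizations = reals)
    })
  })
  names(sims) <- config$profiles

  res$suv_table <- stage("quantification", {
    rows <- lapply(config$profiles, function(nm) {
      per <- vapply(sims[[nm]]$realizations, function(img) {
        suv <- to_suv(img)
        vapply(roi_set, function(msk) roi_mean(suv, msk)$mean, numeric(1))
      }, numeric(length(roi_set)))
      means <- rowMeans(per)
      sds <- apply(per, 1, stats::sd)
      data.frame(group = nm, region = names(roi_set), suv_mean = means,
                 suv_sd = sds, n = config$n_realizations,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  res$spill <- stage("spill_fits", {
    wide <- stats::reshape(res$suv_table[, c("group", "region", "suv_mean")],
                           idvar = "group", timevar = "region",
                           direction = "wide")
    names(wide) <- sub("^suv_mean\\.", "", names(wide))
    wide <- wide[match(config$profiles, wide$group), ]
    b <- wide[wide$group == "BKG", ]
    list(groups = wide,
         r_meninges_cerebellum = pearson_r(
           wide$meninges, percent_delta(wide$cerebellum, b$cerebellum)),
         r_sinus_erc = pearson_r(
           wide$sinus, percent_delta(wide$erc, b$erc)),
         fit_erc = linear_fit(wide$sinus, wide$erc),
         fit_cerebellum = linear_fit(wide$meninges, wide$cerebellum))
  })

  res$scf <- stage("scf_derivation", {
    wide <- res$spill$groups
    bl <- match("BKG", wide$group)
    noiseless_bkg <- to_suv(pet_image(sims[["BKG"]]$noiseless$values,
                                      phantom$grid, "kBq/mL"))
    true_erc <- roi_mean(noiseless_bkg, roi_set$erc)$mean
    true_cer <- roi_mean(noiseless_bkg, roi_set$cerebellum)$mean
    list(erc = derive_scf(wide$sinus, wide$erc, true_erc, baseline = bl,
                          target = "erc", source = "sinus"),
         cerebellum = derive_scf(wide$meninges, wide$cerebellum, true_cer,
                                 baseline = bl, target = "cerebellum",
                                 source = "meninges"))
  })

  res$correction_report <- stage("correction_evaluation", {
    tissues <- tissue_probability_maps(phantom)
    cfg <- pvc_config(tissues$gm, tissues$wm, tissues$csf)
    wide <- res$spill$groups
    pvc <- t(vapply(config$profiles, function(nm) {
      mean_img <- Reduce(`+`, lapply(sims[[nm]]$realizations, `[[`, "values")) /
        config$n_realizations
      corr <- mg_pvc(to_suv(pet_image(mean_img, phantom$grid, "kBq/mL")), cfg)
      c(pvc_erc = roi_mean(corr, roi_set$erc)$mean,
        pvc_cerebellum = roi_mean(corr, roi_set$cerebellum)$mean)
    }, numeric(2)))
    groups <- cbind(wide, as.data.frame(pvc))
    evaluate_corrections(groups, res$scf$erc, res$scf$cerebellum)
  })

  if (config$run_detection) {
    res$detection <- stage("detection", {
      results <- lapply(config$profiles, function(nm)
        find_detection_threshold(calibs[[nm]], phantom, config$scanner,
                                 config$schedule, config$detection))
      names(results) <- config$profiles
      list(results = results,
           comparison = compare_thresholds(results, baseline = "AVG"))
    })
  }

  res$tiering <- stage("tiering", {
    cohort <- generate_synthetic_ratings(config$rating_n,
                                         seed = config$base_seed + 7L)
    thr <- recover_tier_thresholds(cohort)
    tiers <- classify_tier(cohort$meninges_suvr, thr)
    list(thresholds = thr, cohort = cohort,
         fractions = as.data.frame(prop.table(table(tiers))))
  })

  res$reference_tables <- stage("reference_tables",
                                reproduce_reference_tables())

  if (!is.null(config$out_dir)) stage("write_outputs", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(
      df, file.path(config$out_dir, paste0(nm, ".csv")), row.names = FALSE)
    wr(res$calibration, "calibration")
    wr(res$suv_table, "suv_table")
    wr(res$correction_report, "correction_report")
    wr(res$reference_tables, "reference_tables")
    if (!is.null(res$detection)) wr(res$detection$comparison, "detection")
    cfg <- config
    cfg$spec$grid <- NULL
    jsonlite::write_json(
      list(profiles = cfg$profiles, n_realizations = cfg$n_realizations,
           base_seed = cfg$base_seed,
           shape = cfg$spec$shape, voxel_size = cfg$spec$voxel_size,
           sensitivity = cfg$scanner$sensitivity),
      file.path(config$out_dir, "config.json"), auto_unbox = TRUE)
  })
  res
}
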