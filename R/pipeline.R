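# End-to-end synthetic study: simulation, analysis, and report assembly.

#' Default synthetic-study configuration
#'
#' The generator defaults define the simulated study conditions: perfusate
#' tracer concentration 50 ug/mL over 30-120 s, a baseline R123 transfer
#' constant of 0.12 uL/s/g over a 0.015 mL/g vascular space, transporter
#' inhibition raising K_in to 2.4 (cyclosporin A) and 2.2 (verapamil)
#' uL/s/g, n = 4 animals per group, per-vessel transporter intensities of
#' 22.6 (BBB) and 22.9 (BTB) a.u. with SD 10, and lesions amplifying the
#' passive tracer 4.9-fold but the efflux substrate only 0.98-fold over
#' brain distant to tumor. Override any element via the `config` argument
#' of [simulate_study()] / [run_pipeline()].
#'
#' @return named list of configuration values.
#' @export
default_study_config <- function() {
  list(
    standards = list(concentrations = c(0, 0.25, 0.5, 1, 2, 5),
                     slope = 100, intercept = 50, noise_sd = 5,
                     n_replicates = 3),
    kinetics = list(
      true_kin = 0.12, v0 = 0.015, cstar = 50,
      times = c(30, 60, 90, 120), noise_cv = 0.1, n_per_time = 4,
      n_per_group = 4, single_time = 120,
      inhibitors = c(cyclosporinA = 2.4, verapamil = 2.2),
      kin_bdt = 0.11, kin_btb = 0.12
    ),
    section = list(
      shape = c(224, 224), pixel_size = 2, thickness = 20,
      n_lesions = 4, lesion_radius = c(14, 22),
      fold_aib = 4.9, fold_r123 = 0.98,
      n_bbb = 20, n_btb = 12, mean_bbb = 22.6, mean_btb = 22.9,
      vessel_sd = 10, tissue_level = 10, blur_sigma = 0.8, noise_sd = 1
    ),
    autorad = list(downsample_factor = 4, background = 50,
                   shift_px = c(4L, -4L), noise_sd = 0.5),
    bdt_margin_px = 24,
    efflux_threshold = 1.0
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Simulate one complete dual-tracer study with recorded ground truth
#'
#' Generates every input the analysis pipeline consumes: a fluorescence
#' standards table, perfusion records (baseline, impermeant-tracer,
#' inhibitor, and tumor-region groups), a four-channel section with vessel
#' and lesion ground-truth masks, and a coarse autoradiograph of the same
#' slice. All randomness flows from `seed` through named substreams, so
#' regenerating with the same seed and configuration is byte-identical.
#'
#' @param seed integer top-level seed.
#' @param config list of overrides merged over [default_study_config()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   (CSV tables, TIFF images + JSON sidecars, label masks, and a
#'   `ground_truth.json`).
#' @return list with `standards`, `perfusion` (all groups, one data.frame),
#'   `section` (the [generate_section()] result), `autorad`,
#'   `ground_truth`, `config`, `seed`.
#' @export
simulate_study <- function(seed = 1, config = list(), out_dir = NULL) {
  cfg <- merge_config(default_study_config(), config)
  kc <- cfg$kinetics
  sc <- cfg$section

  standards <- do.call(generate_standards, c(cfg$standards, list(seed = seed)))

  perf <- list(
    generate_perfusion_series(kc$true_kin, kc$v0, kc$cstar, kc$times,
                              kc$noise_cv, kc$n_per_time, seed = seed),
    generate_perfusion_series(0, kc$v0, 10, kc$times, kc$noise_cv,
                              kc$n_per_group, tracer = "sucrose",
                              seed = seed),
    generate_perfusion_series(kc$kin_bdt, kc$v0, kc$cstar, kc$single_time,
                              kc$noise_cv, kc$n_per_group, region = "BDT",
                              seed = seed),
    generate_perfusion_series(kc$kin_btb, kc$v0, kc$cstar, kc$single_time,
                              kc$noise_cv, kc$n_per_group, region = "lesion",
                              seed = seed),
    generate_perfusion_series(kc$true_kin, kc$v0, kc$cstar, kc$single_time,
                              kc$noise_cv, kc$n_per_group,
                              inhibitor = "vehicle", seed = seed)
  )
  for (i in seq_along(kc$inhibitors)) {
    perf <- c(perf, list(generate_perfusion_series(
      kc$inhibitors[[i]], kc$v0, kc$cstar, kc$single_time, kc$noise_cv,
      kc$n_per_group, inhibitor = names(kc$inhibitors)[i], seed = seed)))
  }
  perfusion <- do.call(rbind, perf)

  lesions <- random_lesion_spec(sc$n_lesions, sc$shape, sc$lesion_radius,
                                sc$fold_aib, sc$fold_r123, seed = seed)
  vessels <- random_vessel_spec(sc$n_bbb, sc$n_btb, sc$shape, lesions,
                                mean_bbb = sc$mean_bbb,
                                mean_btb = sc$mean_btb, sd = sc$vessel_sd,
                                seed = seed)
  section <- generate_section(sc$shape, sc$pixel_size, sc$thickness,
                              vessels, lesions,
                              tissue_level = sc$tissue_level,
                              blur_sigma = sc$blur_sigma,
                              noise_sd = sc$noise_sd, seed = seed)
  autorad <- generate_autoradiograph(section, cfg$autorad$downsample_factor,
                                     background = cfg$autorad$background,
                                     shift_px = cfg$autorad$shift_px,
                                     noise_sd = cfg$autorad$noise_sd,
                                     seed = seed)

  ground_truth <- list(
    true_kin = kc$true_kin, true_v0 = kc$v0,
    calib_slope = cfg$standards$slope,
    calib_intercept = cfg$standards$intercept,
    inhibitor_kins = as.list(kc$inhibitors),
    lesion_folds = list(aib = lesions$fold_aib, r123 = lesions$fold_r123),
    vessel_intensities = stats::setNames(vessels$pgp_intensity,
                                         vessels$vessel_id),
    vessel_classes = stats::setNames(vessels$class, vessels$vessel_id),
    shift_px = autorad$shift_px,
    seed = seed
  )

  study <- list(standards = standards, perfusion = perfusion,
                section = section, autorad = autorad,
                ground_truth = ground_truth, config = cfg, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(standards, file.path(out_dir, "standards.csv"),
                     row.names = FALSE)
    utils::write.csv(perfusion, file.path(out_dir, "perfusion.csv"),
                     row.names = FALSE)
    write_section_image(section$image, file.path(out_dir, "section"))
    write_label_mask(section$vessel_mask,
                     file.path(out_dir, "vessel_mask.tif"))
    write_label_mask(section$lesion_mask,
                     file.path(out_dir, "lesion_mask.tif"))
    write_autoradiograph(autorad, file.path(out_dir, "autorad"))
    jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

# Translate `img` content by -shift (undo a known displacement), filling
# exposed borders with `fill`.
apply_shift <- function(img, shift, fill) {
  out <- matrix(fill, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) + shift[1]
  src_c <- seq_len(ncol(img)) + shift[2]
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

# Assign each segmented vessel the class of the ground-truth vessel it
# overlaps most.
match_vessel_classes <- function(labels, gt_mask, gt_classes) {
  ids <- sort(unique(labels[labels > 0]))
  cls <- vapply(ids, function(k) {
    over <- gt_mask[labels == k]
    over <- over[over > 0]
    if (!length(over)) return(NA_character_)
    gt_classes[[as.character(names(which.max(table(over))))]]
  }, character(1))
  data.frame(vessel_id = ids, class = cls)
}

#' Run the full dual-tracer analysis pipeline on a synthetic study
#'
#' Executes simulate -> calibrate -> kinetics -> efflux screen -> imaging
#' quantification -> statistics and assembles the provenance-stamped
#' report: the fitted standard curve; the K_in table (multipoint baseline
#' fit, sucrose vascular volume, single-time-point estimates for the
#' inhibitor and tumor-region groups, inhibitor fold changes, one-way
#' ANOVA with Dunnett contrasts, BDT-vs-lesion t-test); the passive-line
#' efflux screen with R123's measured K_in appended; per-vessel
#' transporter expression with a BBB-vs-BTB t-test; autoradiograph
#' co-registration; and per-lesion fold changes with fold-vs-size and
#' tracer-vs-tracer correlations.
#'
#' @inheritParams simulate_study
#' @param out_dir optional directory; when given the simulated inputs and
#'   `report.json` are written there.
#' @return a `btb_report` (see [build_report()]).
#' @export
run_pipeline <- function(seed = 1, config = list(), out_dir = NULL) {
  study <- simulate_study(seed = seed, config = config, out_dir = out_dir)
  cfg <- study$config
  perf <- study$perfusion

  grp <- function(tracer = "R123", region = "normal", inhibitor = "none") {
    perf[perf$tracer == tracer & perf$region == region &
           perf$inhibitor == inhibitor, , drop = FALSE]
  }

  curve <- fit_standard_curve(study$standards)

  v0_est <- vascular_volume(grp(tracer = "sucrose"))
  baseline <- fit_kin(grp())
  single_kin <- function(records) {
    kin_single_timepoint(records$qstar_ug_per_g, records$cstar_ug_per_ml,
                         records$time_s, v0_est$v0)
  }
  kin_groups <- list(
    baseline = single_kin(grp(inhibitor = "vehicle")),
    bdt = single_kin(grp(region = "BDT")),
    btb = single_kin(grp(region = "lesion"))
  )
  for (inh in names(cfg$kinetics$inhibitors)) {
    kin_groups[[inh]] <- single_kin(grp(inhibitor = inh))
  }
  folds <- vapply(names(cfg$kinetics$inhibitors), function(inh) {
    inhibitor_fold(kin_groups[[inh]]$kin, baseline$kin)
  }, numeric(1))
  dunnett <- anova_dunnett(
    kin_groups$baseline$per_record_kin,
    lapply(kin_groups[names(cfg$kinetics$inhibitors)],
           function(k) k$per_record_kin),
    seed = substream_seed(study$seed, "dunnett")
  )
  bdt_vs_btb <- two_sample_t(kin_groups$bdt$per_record_kin,
                             kin_groups$btb$per_record_kin)

  compounds <- load_reference_compounds()
  compounds <- rbind(compounds, data.frame(
    name = "R123_measured", logd = 1.51, kin_ul_s_g = baseline$kin,
    known_class = "unknown"))
  screen <- efflux_screen(compounds, threshold = cfg$efflux_threshold)

  img <- study$section$image
  mask <- segment_vessels(img$channels$endothelial)
  classes <- match_vessel_classes(mask$labels, study$section$vessel_mask,
                                  as.list(study$ground_truth$vessel_classes))
  expr <- vessel_expression(img$channels$pgp, mask, classes)
  by_class <- split(expr$per_vessel$mean_intensity, expr$per_vessel$class)
  expr_test <- two_sample_t(by_class$bbb, by_class$btb)

  reg <- register_modalities(img$channels$nuclei, study$autorad,
                             max_shift = 10)
  f <- study$autorad$downsample_factor
  up <- study$autorad$activity[rep(seq_len(nrow(study$autorad$activity)),
                                   each = f),
                               rep(seq_len(ncol(study$autorad$activity)),
                                   each = f)]
  up <- up[seq_len(nrow(img$channels$nuclei)),
           seq_len(ncol(img$channels$nuclei))]
  aligned <- apply_shift(up, reg$shift, fill = study$autorad$background)

  bdt <- bdt_mask(study$section$lesion_mask, cfg$bdt_margin_px)
  folds_r123 <- lesion_fold_change(img$channels$r123,
                                   study$section$lesion_mask, bdt,
                                   img$pixel_size)
  folds_aib <- lesion_fold_change(aligned, study$section$lesion_mask, bdt,
                                  img$pixel_size)
  lesion_table <- data.frame(
    lesion_id = folds_aib$lesion_id, area_mm2 = folds_aib$area_mm2,
    fold_aib = folds_aib$fold, fold_r123 = folds_r123$fold
  )
  correlations <- list(
    aib_vs_size = correlate(lesion_table$area_mm2, lesion_table$fold_aib),
    r123_vs_size = correlate(lesion_table$area_mm2, lesion_table$fold_r123),
    aib_vs_r123 = correlate(lesion_table$fold_aib, lesion_table$fold_r123)
  )

  report <- build_report(
    calibration = list(slope = curve$slope, intercept = curve$intercept,
                       r_squared = curve$r_squared,
                       n_points = curve$n_points),
    kinetics = list(
      v0 = v0_est, multipoint = list(
        kin = baseline$kin, kin_se = baseline$kin_se, v0 = baseline$v0,
        v0_se = baseline$v0_se, n = baseline$n,
        r_squared = baseline$r_squared),
      groups = lapply(kin_groups, function(k) {
        list(kin = k$kin, kin_se = k$kin_se, n = k$n, method = k$method,
             v0_source = k$v0_source)
      }),
      inhibitor_folds = as.list(folds),
      dunnett = list(F = dunnett$statistic, p = dunnett$p_value,
                     critical_value = dunnett$critical_value,
                     comparisons = dunnett$comparisons),
      bdt_vs_btb_t = list(t = bdt_vs_btb$statistic, p = bdt_vs_btb$p_value)
    ),
    efflux = list(
      line = list(slope = screen$line$slope,
                  intercept = screen$line$intercept,
                  residual_sd = screen$line$residual_sd, n = screen$line$n),
      deviations = screen$deviations
    ),
    imaging = list(
      n_vessels = mask$n_vessels,
      expression_summary = expr$summary,
      bbb_vs_btb_t = list(t = expr_test$statistic, p = expr_test$p_value),
      registration = list(shift = as.integer(reg$shift),
                          correlation = reg$correlation),
      lesions = lesion_table,
      correlations = lapply(correlations, function(cc) {
        list(r_squared = cc$r_squared, slope = cc$slope, n = cc$n)
      })
    ),
    config = cfg, seed = study$seed
  )
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Assemble the end-to-end analysis report
#'
#' Collects the per-stage outputs into one provenance-stamped structure.
#' Stages passed as `NULL` are recorded as explicit gaps rather than
#' silently dropped. Reports carry no timestamps, so the same seed and
#' configuration always produce byte-identical JSON.
#'
#' @param calibration,kinetics,efflux,imaging per-stage result lists (or
#'   NULL if the stage did not run).
#' @param config the study configuration to echo.
#' @param seed the top-level seed.
#' @return object of class `btb_report`.
#' @export
build_report <- function(calibration = NULL, kinetics = NULL, efflux = NULL,
                         imaging = NULL, config = NULL, seed = NULL) {
  stages <- list(calibration = calibration, kinetics = kinetics,
                 efflux = efflux, imaging = imaging)
  gaps <- names(stages)[vapply(stages, is.null, logical(1))]
  structure(
    list(
      schema_version = "1.0",
      package_version = as.character(utils::packageVersion("btbquant")),
      seed = seed,
      gaps = gaps,
      calibration = calibration,
      kinetics = kinetics,
      efflux = efflux,
      imaging = imaging,
      config = config
    ),
    class = "btb_report"
  )
}

#' Write a report as JSON
#' @param report a [build_report()] object.
#' @param path output `.json` path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Validate a report against the packaged schema
#'
#' Checks that every field required by the shipped report schema
#' (`inst/extdata/report_schema.json`) is present and that completed
#' stages are not also listed as gaps.
#'
#' @param report a `btb_report` or a list read back from `report.json`.
#' @return TRUE invisibly; errors describe missing fields.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report_schema.json",
                             package = "btbquant", mustWork = TRUE)
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  missing <- setdiff(schema$required, names(report))
  if (length(missing)) {
    stop("report missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  done <- setdiff(c("calibration", "kinetics", "efflux", "imaging"),
                  report$gaps)
  for (st in done) {
    if (is.null(report[[st]])) {
      stop(sprintf("stage `%s` neither present nor declared a gap", st),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.btb_report <- function(x, ...) {
  cat(sprintf("btbquant report (schema %s, seed %s)\n", x$schema_version,
              format(x$seed)))
  if (length(x$gaps)) cat("  missing stages:", paste(x$gaps, collapse = ", "), "\n")
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: slope %.4g, intercept %.4g, r^2 %.4f\n",
                x$calibration$slope, x$calibration$intercept,
                x$calibration$r_squared))
  }
  if (!is.null(x$kinetics)) {
    cat(sprintf("  K_in (multipoint): %.4g +/- %.3g uL/s/g; V0 %.4g mL/g\n",
                x$kinetics$multipoint$kin, x$kinetics$multipoint$kin_se,
                x$kinetics$v0$v0))
    f <- unlist(x$kinetics$inhibitor_folds)
    cat("  inhibitor folds:",
        paste(sprintf("%s %.3g", names(f), f), collapse = ", "), "\n")
  }
  if (!is.null(x$imaging)) {
    cat(sprintf("  vessels: %d; registration shift (%d, %d), r %.3f\n",
                x$imaging$n_vessels, x$imaging$registration$shift[1],
                x$imaging$registration$shift[2],
                x$imaging$registration$correlation))
    cat(sprintf("  lesion folds (AIB): %s\n",
                paste(sprintf("%.3g", x$imaging$lesions$fold_aib),
                      collapse = ", ")))
  }
  invisible(x)
}
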