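#' Measure one phantom end to end
#'
#' Renders the before and after images of a phantom, segments and measures
#' the nuclei, and computes the specimen's rate report: SMC deformation rate
#' (morphometry), arterial dilatation rate (inner diameters measured from the
#' images), vessel-wall transformation rate (from the geometries) and, for
#' the heating arm, the media area-conservation ratio measured from the
#' images.
#'
#' @param phantom a [generate_phantom()] object.
#' @param pixel_size mm per pixel; `NULL` picks per image automatically.
#' @param params a [segmentation_params()].
#' @return one-row data frame: specimen_id, condition, arm,
#'   target_dilatation_rate, n_before, n_after, deformation_rate,
#'   dilatation_rate, transformation_rate, area_ratio (NA for the
#'   conventional arm).
#' @export
measure_phantom <- function(phantom, pixel_size = NULL,
                            params = segmentation_params()) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  img_b <- render_histology_image(phantom, "before", pixel_size)
  img_a <- render_histology_image(phantom, "after", pixel_size)
  m_b <- measure_nuclei(img_b, params = params)
  m_a <- measure_nuclei(img_a, params = params)
  s_b <- summarize_specimen(m_b)
  s_a <- summarize_specimen(m_a)
  defo <- deformation_rate(s_a, s_b, n_boot = 0)$rate
  dila <- dilatation_rate_ex_vivo(measure_inner_diameter(img_a),
                                  measure_inner_diameter(img_b))
  trans <- transformation_rate(phantom$geometry_before,
                               phantom$geometry_after)
  aratio <- if (phantom$arm == "heating") area_ratio(img_b, img_a) else NA_real_
  data.frame(specimen_id = phantom$specimen_id,
             condition = phantom$condition,
             arm = phantom$arm,
             target_dilatation_rate = phantom$target_dilatation_rate,
             n_before = s_b$n_nuclei, n_after = s_a$n_nuclei,
             deformation_rate = defo,
             dilatation_rate = dila,
             transformation_rate = trans,
             area_ratio = aratio)
}

#' Configuration of a full synthetic experiment
#'
#' Bundles the cohort, protocol and measurement settings of one end-to-end
#' synthetic experiment. Defaults emulate the in-vivo design: balloon peak
#' temperatures 65/75/85 degC, 6 specimens per condition, 15 s heating.
#'
#' @param t_balloon_levels balloon peak temperatures, degC.
#' @param n_specimens_per_condition specimens per heating condition.
#' @param nuclei_per_specimen nuclei per specimen.
#' @param baseline_aspect_mean,baseline_aspect_sd,baseline_short_axis,orientation_jitter_sd,measurement_noise_cv
#'   see [cohort_config()].
#' @param rng_seed integer seed for the whole experiment.
#' @param heating_time heating time, s.
#' @param inner_diameter,media_thickness,axial_stretch before-state vessel
#'   geometry.
#' @param include_conventional also run a conventional-balloon arm (nuclear
#'   shape unchanged).
#' @param conventional_pressures balloon pressures of the conventional arm,
#'   MPa (labels only; no constitutive tissue model is in scope).
#' @param n_conventional_per_pressure specimens per conventional condition.
#' @param pixel_size mm per pixel for rendering; `NULL` = automatic.
#' @param balloon_pressure heating-arm balloon pressure, MPa (metadata).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(t_balloon_levels = c(65, 75, 85),
                              n_specimens_per_condition = 6,
                              nuclei_per_specimen = 100,
                              baseline_aspect_mean = 2.5,
                              baseline_aspect_sd = 0.4,
                              baseline_short_axis = 0.008,
                              orientation_jitter_sd = 0.1,
                              measurement_noise_cv = 0.02,
                              rng_seed = 1,
                              heating_time = 15,
                              inner_diameter = 1.46,
                              media_thickness = 0.54,
                              axial_stretch = 1.2,
                              include_conventional = FALSE,
                              conventional_pressures = 1.0,
                              n_conventional_per_pressure = 6,
                              pixel_size = NULL,
                              balloon_pressure = 0.35) {
  structure(list(t_balloon_levels = t_balloon_levels,
                 n_specimens_per_condition = n_specimens_per_condition,
                 nuclei_per_specimen = nuclei_per_specimen,
                 baseline_aspect_mean = baseline_aspect_mean,
                 baseline_aspect_sd = baseline_aspect_sd,
                 baseline_short_axis = baseline_short_axis,
                 orientation_jitter_sd = orientation_jitter_sd,
                 measurement_noise_cv = measurement_noise_cv,
                 rng_seed = as.integer(rng_seed),
                 heating_time = heating_time,
                 inner_diameter = inner_diameter,
                 media_thickness = media_thickness,
                 axial_stretch = axial_stretch,
                 include_conventional = include_conventional,
                 conventional_pressures = conventional_pressures,
                 n_conventional_per_pressure = n_conventional_per_pressure,
                 pixel_size = pixel_size,
                 balloon_pressure = balloon_pressure),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Keys mirror the [experiment_config()] argument names exactly.
#'
#' @param path a `.yaml`/`.yml`/`.json` file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("config file %s not found", path))
  vals <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(experiment_config)))
  if (length(unknown)) {
    abort_validation(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  do.call(experiment_config, vals)
}

experiment_cohort_config <- function(config, arm) {
  geometry <- vessel_geometry(inner_diameter = config$inner_diameter,
                              wall_thickness = config$media_thickness,
                              axial_stretch = config$axial_stretch)
  if (arm == "heating") {
    cohort_config(n_specimens_per_condition = config$n_specimens_per_condition,
                  t_balloon_levels = config$t_balloon_levels,
                  nuclei_per_specimen = config$nuclei_per_specimen,
                  baseline_aspect_mean = config$baseline_aspect_mean,
                  baseline_aspect_sd = config$baseline_aspect_sd,
                  baseline_short_axis = config$baseline_short_axis,
                  orientation_jitter_sd = config$orientation_jitter_sd,
                  measurement_noise_cv = config$measurement_noise_cv,
                  rng_seed = config$rng_seed,
                  geometry = geometry, arm = "heating")
  } else {
    cohort_config(n_specimens_per_condition = config$n_conventional_per_pressure,
                  t_balloon_levels = config$conventional_pressures,
                  nuclei_per_specimen = config$nuclei_per_specimen,
                  baseline_aspect_mean = config$baseline_aspect_mean,
                  baseline_aspect_sd = config$baseline_aspect_sd,
                  baseline_short_axis = config$baseline_short_axis,
                  orientation_jitter_sd = config$orientation_jitter_sd,
                  measurement_noise_cv = config$measurement_noise_cv,
                  rng_seed = config$rng_seed + 500000L,
                  geometry = geometry, arm = "conventional")
  }
}

#' Run a full synthetic experiment
#'
#' Generates the cohort(s), renders every before/after image pair, measures
#' the nuclei, computes every specimen's rates and the cohort statistics
#' (per-condition means, the deformation-vs-transformation Pearson
#' correlation, Student t tests between adjacent heating conditions), and
#' optionally writes all artefacts (`rates.csv`, `report.json`, `report.md`,
#' `ground_truth.csv`, `provenance.json`) to a directory. Fully reproducible
#' from the seed: the same configuration yields a byte-identical report.
#' Raw p values are reported without multiple-testing correction.
#'
#' @param config an [experiment_config()] or the path to a YAML/JSON file.
#' @param out_dir optional output directory (created if missing).
#' @param link dose-response link, see [generate_cohort()].
#' @param verbose print per-specimen progress to stderr.
#' @return an object of class `experiment_report`: list with `rates`,
#'   `condition_summary`, `pearson_r`, `t_tests`, `provenance`.
#' @export
run_experiment <- function(config, out_dir = NULL, link = NULL,
                           verbose = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))

  cohorts <- list()
  if (length(config$t_balloon_levels) > 0) {
    cohorts <- list(generate_cohort(experiment_cohort_config(config, "heating"),
                                    link = link))
  }
  if (isTRUE(config$include_conventional)) {
    cohorts <- c(cohorts,
                 list(generate_cohort(experiment_cohort_config(config, "conventional"))))
  }
  if (length(cohorts) == 0) {
    abort_validation("experiment has no arms: give `t_balloon_levels` or `include_conventional`")
  }
  phantoms <- do.call(c, lapply(cohorts, unclass))

  rows <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    if (verbose) {
      message(sprintf("measuring specimen %s (%s, condition %s)",
                      phantoms[[i]]$specimen_id, phantoms[[i]]$arm,
                      phantoms[[i]]$condition))
    }
    rows[[i]] <- measure_phantom(phantoms[[i]],
                                 pixel_size = config$pixel_size)
    rows[[i]]$specimen_id <- sprintf("%s-%s", substr(phantoms[[i]]$arm, 1, 4),
                                     rows[[i]]$specimen_id)
  }
  rates <- do.call(rbind, rows)

  agg <- do.call(rbind, lapply(split(rates, list(rates$arm, rates$condition),
                                     drop = TRUE), function(g) {
    data.frame(arm = g$arm[1L], condition = g$condition[1L], n = nrow(g),
               deformation_rate_mean = mean(g$deformation_rate),
               deformation_rate_sd = stats::sd(g$deformation_rate),
               dilatation_rate_mean = mean(g$dilatation_rate),
               dilatation_rate_sd = stats::sd(g$dilatation_rate),
               transformation_rate_mean = mean(g$transformation_rate),
               area_ratio_max = if (all(is.na(g$area_ratio))) NA_real_
                                else max(g$area_ratio))
  }))
  heat <- rates[rates$arm == "heating", ]
  agg <- agg[order(agg$arm, suppressWarnings(as.numeric(agg$condition))), ]
  rownames(agg) <- NULL

  pearson_r <- if (nrow(heat) >= 3 &&
                   stats::sd(heat$deformation_rate) > 0 &&
                   stats::sd(heat$transformation_rate) > 0) {
    pearson_correlation(heat$deformation_rate, heat$transformation_rate)
  } else NA_real_

  lev <- unique(heat$condition)
  t_tests <- NULL
  if (length(lev) >= 2) {
    pairs <- cbind(lev[-length(lev)], lev[-1L])
    t_tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      ga <- heat$deformation_rate[heat$condition == pairs[k, 1L]]
      gb <- heat$deformation_rate[heat$condition == pairs[k, 2L]]
      if (length(ga) < 2 || length(gb) < 2) return(NULL)
      tt <- two_sample_t_test(ga, gb)
      data.frame(condition_a = pairs[k, 1L], condition_b = pairs[k, 2L],
                 statistic = tt$statistic, p_value = tt$p_value)
    }))
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile()
  writeLines(cfg_json, tf)
  provenance <- list(package = "smcdeform",
                     package_version = as.character(utils::packageVersion("smcdeform")),
                     r_version = R.version.string,
                     rng_seed = config$rng_seed,
                     config_md5 = unname(tools::md5sum(tf)))
  unlink(tf)

  report <- structure(list(rates = rates, condition_summary = agg,
                           pearson_r = pearson_r, t_tests = t_tests,
                           provenance = provenance, config = config),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_experiment_report(report, out_dir,
                                                 phantoms = phantoms)
  report
}

#' Write an experiment report to a directory
#'
#' @param report an `experiment_report` from [run_experiment()].
#' @param out_dir output directory (created if missing).
#' @param phantoms optional phantom list; when given, the cohort ground truth
#'   is written too.
#' @return `out_dir`, invisibly.
#' @export
write_experiment_report <- function(report, out_dir, phantoms = NULL) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rates, file.path(out_dir, "rates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(condition_summary = report$condition_summary,
         pearson_r = report$pearson_r,
         t_tests = report$t_tests,
         provenance = report$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(phantoms)) {
    write_ground_truth(phantoms, file.path(out_dir, "ground_truth.csv"))
  }
  md <- c("# Synthetic dilatation experiment report", "",
          sprintf("Deformation-vs-transformation Pearson r: %s",
                  format(report$pearson_r, digits = 4)), "",
          "| arm | condition | n | deformation rate | dilatation rate | transformation rate | max area ratio |",
          "|---|---|---|---|---|---|---|",
          vapply(seq_len(nrow(report$condition_summary)), function(i) {
            g <- report$condition_summary[i, ]
            sprintf("| %s | %s | %d | %.3f +/- %.3f | %.3f +/- %.3f | %.3f | %s |",
                    g$arm, g$condition, g$n,
                    g$deformation_rate_mean, g$deformation_rate_sd,
                    g$dilatation_rate_mean, g$dilatation_rate_sd,
                    g$transformation_rate_mean,
                    ifelse(is.na(g$area_ratio_max), "-",
                           sprintf("%.4f", g$area_ratio_max)))
          }, ""))
  if (!is.null(report$t_tests) && nrow(report$t_tests)) {
    md <- c(md, "", "## Student t tests (deformation rate, adjacent conditions; raw p values)",
            "", "| condition a | condition b | t | p |", "|---|---|---|---|",
            vapply(seq_len(nrow(report$t_tests)), function(i) {
              g <- report$t_tests[i, ]
              sprintf("| %s | %s | %.3f | %.4g |",
                      g$condition_a, g$condition_b, g$statistic, g$p_value)
            }, ""))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Synthetic dilatation experiment\n")
  cat(sprintf("  %d specimens, deformation-vs-transformation r = %s\n",
              nrow(x$rates), format(x$pearson_r, digits = 4)))
  print(x$condition_summary, digits = 4)
  invisible(x)
}

#' @export
plot.experiment_report <- function(x, ...) {
  heat <- x$rates[x$rates$arm == "heating", ]
  cond <- suppressWarnings(as.numeric(heat$condition))
  if (all(is.na(cond))) cond <- as.numeric(factor(heat$condition))
  graphics::plot(cond, heat$deformation_rate,
                 xlab = "condition (T_balloon, degC)",
                 ylab = "rate", pch = 19, ...)
  graphics::points(cond, heat$dilatation_rate, pch = 1)
  graphics::legend("topleft", pch = c(19, 1),
                   legend = c("deformation rate", "dilatation rate"),
                   bty = "n")
  invisible(x)
}
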