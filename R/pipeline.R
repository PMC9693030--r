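# End-to-end pipeline orchestration with reproducible configuration and a
# checksummed artifact manifest. The command-line front end
# (inst/cli/lungmech.R) is a thin wrapper over these functions.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param shape phantom grid shape.
#' @param spacing voxel spacing (mm).
#' @param seed master seed for all stochastic stages.
#' @param n_per_stage subjects per stage.
#' @param stage_means stage means of lung-mean J (strictly decreasing).
#' @param noise_sd between-subject SD of the target mean J.
#' @param methods analysis methods for the cohort stage.
#' @param registration [reg_config()] for the "sstvd" method.
#' @return config list (fully serializable to YAML).
#' @export
pipeline_config <- function(out_dir = "lungmech_out", shape = c(64, 64, 64),
                            spacing = c(1, 1, 1), seed = 1L, n_per_stage = 2,
                            stage_means = c(1.8, 1.6, 1.4, 1.2, 1.05),
                            noise_sd = 0.05, methods = "oracle",
                            registration = reg_config()) {
  cfg <- list(out_dir = out_dir, shape = shape, spacing = spacing,
              seed = seed, n_per_stage = n_per_stage,
              stage_means = stage_means, noise_sd = noise_sd,
              methods = methods, registration = registration)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  known <- c("out_dir", "shape", "spacing", "seed", "n_per_stage",
             "stage_means", "noise_sd", "methods", "registration")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop(sprintf("missing config key(s): %s", paste(missing, collapse = ", ")))
  if (any(diff(cfg$stage_means) >= 0))
    stop("stage_means must be strictly decreasing")
  invisible(TRUE)
}

#' Run the full pipeline: phantom cohort, maps, QA and cohort statistics
#'
#' Generates the synthetic cohort, computes biomechanical maps per subject
#' and method, evaluates registration QA for non-oracle methods, writes all
#' volumes/fields/tables under the configured output directory, and returns
#' a manifest of produced files with MD5 checksums.
#'
#' @param cfg configuration from [pipeline_config()] (or a YAML file path).
#' @return list: `manifest` (data.frame path/md5), `cohort` (the
#'   [cohort_run()] result), `config` (the effective configuration).
#' @export
run_all <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))

  subjects <- make_cohort(cfg$n_per_stage, cfg$stage_means, cfg$noise_sd,
                          cfg$seed, cfg$shape, cfg$spacing,
                          images = "sstvd" %in% cfg$methods)
  manifest_rows <- list()
  add <- function(path) manifest_rows[[length(manifest_rows) + 1L]] <<- path

  rows <- list()
  for (subj in subjects) {
    sdir <- file.path(cfg$out_dir, subj$id)
    dir.create(sdir, showWarnings = FALSE)
    write_volume(subj$lobes, file.path(sdir, "lobes.nii.gz"))
    add(file.path(sdir, "lobes.nii.gz"))
    write_dvf(subj$true_dvf, file.path(sdir, "true_dvf.nii.gz"))
    add(file.path(sdir, "true_dvf.nii.gz"))
    rows[[length(rows) + 1L]] <- data.frame(subject_id = subj$id,
                                            stage = subj$stage,
                                            dir = sdir)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(cfg$out_dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  add(file.path(cfg$out_dir, "cohort_manifest.csv"))

  cohort <- cohort_run(subjects, cfg$methods, cfg$registration)
  utils::write.csv(cohort$table, file.path(cfg$out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  add(file.path(cfg$out_dir, "cohort_table.csv"))
  jsonlite::write_json(
    lapply(cohort$trends, function(t)
      if (is.null(t)) NULL else t[c("group_means", "direction", "spearman_rho")]),
    file.path(cfg$out_dir, "trends.json"), auto_unbox = TRUE, digits = NA)
  add(file.path(cfg$out_dir, "trends.json"))
  if (length(cohort$bland_altman)) {
    ba <- do.call(rbind, lapply(names(cohort$bland_altman), function(k) {
      b <- cohort$bland_altman[[k]]
      data.frame(pair = k, mean_diff = b$mean_diff, sd_diff = b$sd_diff,
                 loa_low = b$loa_low, loa_high = b$loa_high)
    }))
    utils::write.csv(ba, file.path(cfg$out_dir, "bland_altman.csv"),
                     row.names = FALSE)
    add(file.path(cfg$out_dir, "bland_altman.csv"))
  }
  if (nrow(cohort$exclusions)) {
    utils::write.csv(cohort$exclusions,
                     file.path(cfg$out_dir, "exclusions.csv"),
                     row.names = FALSE)
    add(file.path(cfg$out_dir, "exclusions.csv"))
  }
  paths <- unlist(manifest_rows)
  manifest <- data.frame(path = paths,
                         md5 = vapply(paths, function(p)
                           as.character(tools::md5sum(p)), character(1)))
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  list(manifest = manifest, cohort = cohort, config = cfg)
}
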