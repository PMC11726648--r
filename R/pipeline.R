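#' Run the full thin-patch analysis pipeline
#'
#' Orchestrates the stages end to end: normative scoring of every patient
#' (matched reference, z, exact rank p, thin calls), whole-brain and
#' ROI-restricted TPF, covariate-adjusted TPF-score models with
#' adjusted-R2 comparison, progressor labels and the visit-comparison
#' Wilcoxon table, and (optionally) the 12-cell SVM progression experiment.
#' Every artifact is a plain-text CSV/JSON under `out_dir`, and
#' `manifest.json` records seeds, parameters, package version and the md5
#' of every output so a rerun can be verified byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param study A [simulate_study()] object, or `NULL` to read from
#'   `paths`.
#' @param paths Named list of input files (used when `study` is `NULL`):
#'   `normative_thickness`, `patient_thickness`, `normative_demographics`,
#'   `patient_demographics`, `clinical`, `roi`.
#' @param roi Optional [patch_set()] overriding the study/file ROI.
#' @param alpha Thinness level (default 0.05).
#' @param age_window Matching window in years (default 2).
#' @param min_ref Minimum matched reference size (default 10).
#' @param classifier A [classifier_config()], or `NULL` to skip the SVM
#'   stage.
#' @return Invisibly, a list with the in-memory stage results
#'   (`map`, `tpf`, `glm`, `labels`, `wilcoxon`, `experiment`, `manifest`).
#' @export
run_pipeline <- function(out_dir, study = NULL, paths = NULL, roi = NULL,
                         alpha = 0.05, age_window = 2, min_ref = 10,
                         classifier = classifier_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      tp_stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "thinpatch_stage_error"))
  }

  inputs <- stage("load", {
    if (!is.null(study)) {
      stopifnot(inherits(study, "synthetic_study"))
      list(normative = study$normative,
           pat_thick = study$patients$thickness,
           pat_demo = study$patients$demographics,
           clinical = study$patients$clinical,
           roi = roi %||% patch_set(study$config$roi_patches, name = "roi"))
    } else {
      need <- c("normative_thickness", "patient_thickness",
                "normative_demographics", "patient_demographics", "clinical")
      missing <- setdiff(need, names(paths))
      if (length(missing) > 0)
        tp_stop("pipeline config missing input paths: ",
                paste(missing, collapse = ", "),
                class = "thinpatch_validation_error")
      for (p in unlist(paths)) if (!file.exists(p))
        tp_stop("input file not found: ", p,
                class = "thinpatch_validation_error")
      list(normative = list(thickness = read_thickness(paths$normative_thickness),
                            demographics = read_demographics(paths$normative_demographics)),
           pat_thick = read_thickness(paths$patient_thickness),
           pat_demo = read_demographics(paths$patient_demographics),
           clinical = read_clinical(paths$clinical),
           roi = roi %||% read_patchset(paths$roi))
    }
  })

  map <- stage("map", map_cohort(inputs$pat_thick, inputs$pat_demo,
                                 inputs$normative, alpha = alpha,
                                 age_window = age_window, min_ref = min_ref))
  utils::write.csv(tidy_patch_stats(map),
                   file.path(out_dir, "patch_stats.csv"), row.names = FALSE)

  tpf_tab <- stage("tpf", rbind(tpf(map), tpf(map, inputs$roi)))
  utils::write.csv(tpf_tab, file.path(out_dir, "tpf.csv"), row.names = FALSE)

  glm_out <- stage("associate", {
    bl <- inputs$clinical[inputs$clinical$visit == "BL", ]
    covar <- inputs$pat_demo[match(rownames(inputs$pat_thick),
                                   inputs$pat_demo$subject_id), ]
    wb <- tpf_tab[tpf_tab$patch_set == "whole_brain", ]
    rs <- tpf_tab[tpf_tab$patch_set != "whole_brain", ]
    fits <- list(); comps <- list()
    for (ms in unique(bl$measure)) {
      y <- bl$value[bl$measure == ms][match(rownames(inputs$pat_thick),
                                            bl$subject_id[bl$measure == ms])]
      fr <- fit_tpf_model(y, rs$tpf[match(rownames(inputs$pat_thick), rs$patient_id)],
                          covar, outcome_name = ms, predictor_name = "tpf_restricted")
      fu <- fit_tpf_model(y, wb$tpf[match(rownames(inputs$pat_thick), wb$patient_id)],
                          covar, outcome_name = ms, predictor_name = "tpf_whole_brain")
      fits[[paste0(ms, ".restricted")]] <- fr
      fits[[paste0(ms, ".whole_brain")]] <- fu
      comps[[ms]] <- compare_by_adjusted_r2(fr, fu)
    }
    tab <- do.call(rbind, lapply(names(comps), function(ms) {
      t <- comps[[ms]]$table
      cbind(outcome = ms, t, winner = comps[[ms]]$winner)
    }))
    utils::write.csv(tab, file.path(out_dir, "glm_comparison.csv"),
                     row.names = FALSE)
    list(fits = fits, comparisons = comps, table = tab)
  })

  labels <- stage("label", {
    out <- do.call(rbind, lapply(c("extremity", "total_motor", "cognitive"),
                                 function(ms) rbind(
                                   label_progressors(inputs$clinical, ms, "Y1"),
                                   label_progressors(inputs$clinical, ms, "Y3"))))
    utils::write.csv(out, file.path(out_dir, "progression_labels.csv"),
                     row.names = FALSE)
    out
  })

  wtab <- stage("wilcoxon", {
    out <- wilcoxon_table(inputs$clinical, visits = c("BL", "Y3"))
    utils::write.csv(out, file.path(out_dir, "wilcoxon_bl_vs_y3.csv"),
                     row.names = FALSE)
    out
  })

  experiment <- NULL
  if (!is.null(classifier)) {
    experiment <- stage("classify", run_progression_experiment(
      map, inputs$clinical, inputs$roi, classifier))
    utils::write.csv(experiment$summary,
                     file.path(out_dir, "classifier_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(experiment$reports, function(r)
        r[c("outcome", "horizon", "feature_mode", "best_hyperparameters",
            "cv_accuracy", "test_accuracy", "test_ids", "seed")]),
      file.path(out_dir, "classifier_reports.json"),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- stage("manifest", {
    params <- list(alpha = alpha, age_window = age_window, min_ref = min_ref,
                   classifier_seed = if (is.null(classifier)) NA else classifier$seed,
                   roi_name = inputs$roi$name, roi_size = length(inputs$roi),
                   n_patients = nrow(inputs$pat_thick),
                   n_normative = nrow(inputs$normative$thickness),
                   package_version = as.character(utils::packageVersion("thinpatch")))
    files <- setdiff(list.files(out_dir), "manifest.json")
    hashes <- tools::md5sum(file.path(out_dir, files))
    names(hashes) <- files
    m <- list(parameters = params, file_md5 = as.list(hashes))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(map = map, tpf = tpf_tab, glm = glm_out, labels = labels,
                 wilcoxon = wtab, experiment = experiment,
                 manifest = manifest))
}
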