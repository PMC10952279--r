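#' Write a synthetic study bundle to a directory tree
#'
#' Serializes the output of [generate_cohort()] to the layout consumed by
#' [run_pipeline()]: `controls/*.csv`, `patients/*.csv`, `volumes/*.csv`,
#' `outcomes.csv` and `ground_truth.json`.
#'
#' @param bundle result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_cohort <- function(bundle, dir) {
  for (d in file.path(dir, c("controls", "patients", "volumes")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (ct in bundle$controls)
    write_band_power_table(ct, file.path(dir, "controls",
                                         paste0(ct$subject_id, ".csv")))
  for (p in bundle$patients) {
    sid <- p$table$subject_id
    write_band_power_table(p$table,
                           file.path(dir, "patients", paste0(sid, ".csv")))
    write_delim_num(p$volumes,
                    file.path(dir, "volumes", paste0(sid, ".csv")))
  }
  utils::write.table(
    data.frame(subject = bundle$cohort$subject_id,
               outcome = bundle$cohort$outcome),
    file.path(dir, "outcomes.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  truth <- lapply(bundle$patients, function(p)
    c(list(subject = p$table$subject_id, outcome = p$outcome), p$truth))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full abnormality-mapping and marker pipeline on a directory
#'
#' Reads control and patient band-power tables plus per-patient volume
#' tables (or precomputed masks) and the outcome table, then executes the
#' stage chain: normative map construction, per-patient abnormality
#' mapping, resection labelling, marker computation, and the unified
#' cohort-level outcome analysis. Every intermediate table is written under
#' `out_dir` together with a manifest (parameters, seed, input digests)
#' sufficient to reproduce the run; identical inputs and config give
#' byte-identical outputs.
#'
#' @param input_dir directory with `controls/`, `patients/`, `volumes/`
#'   (or `masks/`) and `outcomes.csv`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and applied before any
#'   stochastic stage (the deterministic pipeline itself draws no random
#'   numbers; the seed governs optional add-ons such as the threshold
#'   simulation).
#' @param threshold_method rule for [optimal_threshold()] (`"youden"` or
#'   `"closest"`).
#' @return The `cohort_report` from [unified_outcome_analysis()],
#'   invisibly; artifacts are written under `out_dir`.
#' @export
run_pipeline <- function(input_dir, out_dir, seed = 1,
                         threshold_method = "youden") {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  control_files <- list.files(file.path(input_dir, "controls"),
                              full.names = TRUE, pattern = "\\.(csv|tsv)$")
  patient_files <- list.files(file.path(input_dir, "patients"),
                              full.names = TRUE, pattern = "\\.(csv|tsv)$")
  if (length(control_files) < 2) stop("need at least 2 control tables")
  if (length(patient_files) < 1) stop("no patient tables found")
  controls <- lapply(control_files, read_band_power_table)
  patients <- lapply(patient_files, read_band_power_table)

  norm <- build_normative_map(controls)
  write_normative_map(norm, file.path(out_dir, "normative_map.csv"))

  outcomes <- read_outcomes(file.path(input_dir, "outcomes.csv"))
  dir.create(file.path(out_dir, "abnormality"), showWarnings = FALSE)

  mask_for <- function(sid) {
    mpath <- file.path(input_dir, "masks", paste0(sid, ".csv"))
    vpath <- file.path(input_dir, "volumes", paste0(sid, ".csv"))
    if (file.exists(mpath)) return(read_resection_mask(mpath))
    if (file.exists(vpath)) {
      v <- read_volumes(vpath)
      return(label_resection(v$pre, v$post))
    }
    stop("no mask or volume table for subject ", sid)
  }

  ms <- lapply(patients, function(p) {
    abn <- abnormality_map(p, norm)
    write_abnormality_map(abn, file.path(out_dir, "abnormality",
                                         paste0(p$subject_id, ".csv")))
    marker_set(abn, mask_for(p$subject_id))
  })
  sids <- vapply(patients, function(p) p$subject_id, "")
  miss <- setdiff(sids, names(outcomes))
  if (length(miss))
    stop("outcomes.csv is missing subject(s): ", paste(miss, collapse = ", "))
  cohort <- cohort_table(sids,
                         vapply(ms, `[[`, 0, "MA_R"),
                         vapply(ms, `[[`, 0, "D_RS"),
                         vapply(ms, `[[`, 0, "AC_R"),
                         unname(outcomes[sids]))
  write_marker_table(cohort, file.path(out_dir, "markers.csv"))

  report <- unified_outcome_analysis(cohort, method = threshold_method)
  jsonlite::write_json(
    list(marker_stats = report$marker_stats,
         n_flags_auc = report$n_flags_auc, n_flags_p = report$n_flags_p,
         flags = report$flags,
         flag_rates = as.data.frame(report$flag_rates)),
    file.path(out_dir, "cohort_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("megmark")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    threshold_method = threshold_method,
    input_dir = normalizePath(input_dir),
    inputs = local({
      f <- sort(c(control_files, patient_files,
                  file.path(input_dir, "outcomes.csv")))
      data.frame(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(report)
}
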