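#' Synthetic-cohort configuration
#'
#' Defines the study conditions emulated by the generator: a control cohort
#' of region x band relative power compositions, patients with injected
#' focal or distributed abnormalities, resection masks with controlled
#' overlap with the abnormal set, and binary surgical outcomes. Defaults
#' mirror a mid-resolution 114-region parcellation, 70 healthy controls and
#' 32 patients (12 good / 20 bad outcome).
#'
#' Band powers are generated as a latent Gaussian per region-band passed
#' through softmax normalization, so every row is a valid composition while
#' per-cell z-scores against the control cohort remain approximately
#' Gaussian. Abnormalities are injected on the latent scale, in units of
#' the latent noise standard deviation.
#'
#' @param n_regions number of cortical regions (default 114).
#' @param n_controls number of healthy controls (default 70).
#' @param n_good,n_bad patients per outcome group (defaults 12 and 20).
#' @param band_names band labels (default the five-band scheme's).
#' @param n_abnormal regions carrying an injected abnormality in focal
#'   scenarios (default 6).
#' @param n_abnormal_diffuse abnormal regions in the widespread scenarios
#'   (`partial`, `diffuse`), where effects grade from a full-strength core
#'   down to a near-zero penumbra (default 60).
#' @param effect_size injected latent shift in units of `noise_sd`
#'   (default 6).
#' @param resection_size regions resected (default 6).
#' @param noise_sd latent per-cell noise standard deviation (default 0.15).
#' @param region_spread standard deviation of per-region latent mean
#'   offsets, drawn once per cohort (default 0.3).
#' @param label_noise probability a scenario's deterministic outcome label
#'   is flipped, mimicking imperfect real-world separation (default 0.1).
#' @param seed integer seed; every generator call is deterministic given
#'   the config (default 1).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_regions = 114, n_controls = 70,
                         n_good = 12, n_bad = 20,
                         band_names = default_band_scheme()$name,
                         n_abnormal = 6, n_abnormal_diffuse = 60,
                         effect_size = 6, resection_size = 6,
                         noise_sd = 0.15, region_spread = 0.3,
                         label_noise = 0.1, seed = 1) {
  stopifnot(n_regions >= 2, n_controls >= 2, n_good >= 1, n_bad >= 1,
            n_abnormal >= 1, n_abnormal_diffuse >= 1,
            effect_size >= 0, resection_size >= 1,
            noise_sd >= 0, region_spread >= 0,
            label_noise >= 0, label_noise <= 1)
  if (resection_size >= n_regions)
    stop("resection_size must be smaller than n_regions")
  if (max(n_abnormal, n_abnormal_diffuse) + resection_size > n_regions)
    stop("abnormal set plus resection exceed the region count")
  structure(list(n_regions = n_regions, n_controls = n_controls,
                 n_good = n_good, n_bad = n_bad, band_names = band_names,
                 n_abnormal = n_abnormal,
                 n_abnormal_diffuse = n_abnormal_diffuse,
                 effect_size = effect_size, resection_size = resection_size,
                 noise_sd = noise_sd, region_spread = region_spread,
                 label_noise = label_noise, seed = seed),
            class = "synth_config")
}

synth_region_ids <- function(cfg) sprintf("roi_%03d", seq_len(cfg$n_regions))

# cohort-level latent means: band-specific baselines (broadly 1/f-like,
# alpha-dominant) plus region-specific offsets drawn once per cohort
synth_latent_means <- function(cfg) {
  base <- c(0.6, 0.3, 0.7, 0.1, -0.7)[seq_along(cfg$band_names)]
  if (length(base) < length(cfg$band_names))
    base <- rep_len(base, length(cfg$band_names))
  offs <- matrix(stats::rnorm(cfg$n_regions * length(cfg$band_names),
                              sd = cfg$region_spread),
                 cfg$n_regions)
  sweep(offs, 2, base, `+`)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# one subject's table from latent means (+ optional injected latent shift)
synth_subject_table <- function(cfg, latent_mu, subject_id, shift = NULL) {
  lat <- latent_mu + matrix(stats::rnorm(length(latent_mu),
                                         sd = cfg$noise_sd),
                            nrow(latent_mu))
  if (!is.null(shift)) lat <- lat + shift
  v <- softmax_rows(lat)
  dimnames(v) <- list(synth_region_ids(cfg), cfg$band_names)
  band_power_table(v, subject_id = subject_id)
}

#' Generate a synthetic control cohort
#'
#' @param cfg a [synth_config()].
#' @param latent_mu optional regions x bands latent mean matrix (drawn via
#'   the config seed when omitted) so patients can share the cohort's
#'   baseline.
#' @return List of `n_controls` [band_power_table()] objects.
#' @export
generate_controls <- function(cfg, latent_mu = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  if (is.null(latent_mu)) latent_mu <- synth_latent_means(cfg)
  lapply(seq_len(cfg$n_controls), function(k)
    synth_subject_table(cfg, latent_mu, sprintf("control_%03d", k)))
}

#' Generate one synthetic patient with known ground truth
#'
#' The patient is sampled from the control-generating model, then an
#' effect-size shift (in latent noise SD units) is added to one band in
#' each true abnormal region. Focal scenarios (`clean`, `mislocalized`)
#' inject a compact set of near-full-strength effects; widespread scenarios
#' (`partial`, `diffuse`) inject a graded field whose effects run from the
#' full effect size at the core down to near zero at the penumbra. The
#' resection mask encodes the scenario's failure mechanism:
#' \describe{
#'   \item{mislocalized}{resection disjoint from the (focal) abnormal set
#'     (mechanism 1: abnormalities not targeted, low MA_R).}
#'   \item{partial}{resection covers a strict subset of the widespread
#'     abnormal set — its weakest-effect penumbra — sparing the
#'     highest-effect regions (mechanism 2: D_RS above chance).}
#'   \item{diffuse}{abnormalities spread over many regions; the resection
#'     covers only the few strongest (mechanism 3: low AC_R despite a
#'     well-targeted resection).}
#'   \item{clean}{resection covers the full (focal) abnormal set (good
#'     outcome).}
#' }
#' Outcome is `bad` for the first three scenarios and `good` for `clean`,
#' flipped with probability `label_noise`.
#'
#' @param cfg a [synth_config()].
#' @param scenario one of `"mislocalized"`, `"partial"`, `"diffuse"`,
#'   `"clean"`.
#' @param latent_mu cohort latent means (see [generate_controls()]).
#' @param subject_id subject label.
#' @return List with `table` (a [band_power_table()]), `mask`
#'   (a [resection_mask()]), `outcome`, and `truth` (abnormal region set,
#'   per-region injected band and effect, scenario label).
#' @export
generate_patient <- function(cfg, scenario = c("mislocalized", "partial",
                                               "diffuse", "clean"),
                             latent_mu = NULL, subject_id = "patient") {
  stopifnot(inherits(cfg, "synth_config"))
  scenario <- match.arg(scenario)
  if (is.null(latent_mu)) {
    set.seed(cfg$seed)
    latent_mu <- synth_latent_means(cfg)
  }
  rid <- synth_region_ids(cfg)
  widespread <- scenario %in% c("partial", "diffuse")
  n_abn <- if (widespread) cfg$n_abnormal_diffuse else cfg$n_abnormal
  if (scenario == "mislocalized" && n_abn + cfg$resection_size > cfg$n_regions)
    stop("resection size exceeds the regions left outside the abnormal set")
  abn_idx <- sample.int(cfg$n_regions, n_abn)
  # focal: compact near-full-strength core; widespread: graded core->penumbra
  effects <- if (widespread) cfg$effect_size * stats::runif(n_abn, 0, 1)
             else cfg$effect_size * stats::runif(n_abn, 0.8, 1.2)
  bands <- sample.int(length(cfg$band_names), n_abn, replace = TRUE)
  shift <- matrix(0, cfg$n_regions, length(cfg$band_names))
  shift[cbind(abn_idx, bands)] <- effects * cfg$noise_sd
  tab <- synth_subject_table(cfg, latent_mu, subject_id, shift = shift)
  k_res <- min(cfg$resection_size, n_abn)
  res_idx <- switch(scenario,
    mislocalized = sample(setdiff(seq_len(cfg$n_regions), abn_idx),
                          cfg$resection_size),
    partial = abn_idx[order(effects)[seq_len(k_res)]],
    diffuse = abn_idx[order(effects, decreasing = TRUE)[seq_len(k_res)]],
    clean = abn_idx
  )
  status <- rep("spared", cfg$n_regions)
  status[res_idx] <- "resected"
  outcome <- if (scenario == "clean") "good" else "bad"
  if (stats::runif(1) < cfg$label_noise)
    outcome <- setdiff(c("good", "bad"), outcome)
  list(table = tab,
       mask = resection_mask(rid, status),
       outcome = outcome,
       truth = list(scenario = scenario,
                    abnormal_regions = rid[abn_idx],
                    bands = cfg$band_names[bands],
                    effects = effects))
}

#' Generate a full synthetic study bundle
#'
#' Controls, patients (good-outcome patients drawn from the `clean`
#' scenario; bad-outcome patients cycled through `mislocalized`, `partial`
#' and `diffuse`), resection masks, pre/post volume tables consistent with
#' the masks under the >10% volume-change rule, outcomes and ground truth.
#' Scenario labels are assigned before label noise, so the realized
#' good/bad counts can deviate from `n_good`/`n_bad` when
#' `label_noise > 0`.
#'
#' @param cfg a [synth_config()].
#' @return List with `controls`, `patients` (each as in
#'   [generate_patient()], plus `volumes`, a data frame of
#'   `region, pre_volume, post_volume`), and `cohort` (a [cohort_table()]
#'   of markers computed against the generated controls' normative map).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  latent_mu <- synth_latent_means(cfg)
  controls <- lapply(seq_len(cfg$n_controls), function(k)
    synth_subject_table(cfg, latent_mu, sprintf("control_%03d", k)))
  scen <- c(rep("clean", cfg$n_good),
            rep(c("mislocalized", "partial", "diffuse"),
                length.out = cfg$n_bad))
  patients <- lapply(seq_along(scen), function(k) {
    p <- generate_patient(cfg, scen[k], latent_mu,
                          sprintf("patient_%03d", k))
    p$volumes <- volumes_from_mask(p$mask)
    p
  })
  norm <- build_normative_map(controls)
  ms <- lapply(patients, function(p)
    marker_set(abnormality_map(p$table, norm), p$mask))
  cohort <- cohort_table(
    subject_id = vapply(patients, function(p) p$table$subject_id, ""),
    MA_R = vapply(ms, `[[`, 0, "MA_R"),
    D_RS = vapply(ms, `[[`, 0, "D_RS"),
    AC_R = vapply(ms, `[[`, 0, "AC_R"),
    outcome = vapply(patients, `[[`, "", "outcome"))
  list(controls = controls, patients = patients, cohort = cohort,
       normative = norm)
}

# pre/post volumes that round-trip through label_resection to the mask:
# resected regions lose 20%, spared 0.5%, unknown 5%
volumes_from_mask <- function(mask, pre = 2000) {
  loss <- c(resected = 0.20, spared = 0.005, unknown = 0.05)
  data.frame(region = mask$region_ids,
             pre_volume = pre,
             post_volume = pre * (1 - loss[mask$status]),
             row.names = NULL, stringsAsFactors = FALSE)
}
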