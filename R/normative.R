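#' Build a normative map from control band-power tables
#'
#' For each region-band cell, computes the mean and sample standard
#' deviation (denominator n - 1; the controls are a sample of the healthy
#' population) of relative band power over the control cohort.
#'
#' @param controls list of [band_power_table()] objects with identical region
#'   and band sets (matched by label, not order).
#' @return A `normative_map` with fields `region_ids`, `band_names`, `mu`,
#'   `sigma` (both regions x bands) and `n_controls`.
#' @export
build_normative_map <- function(controls) {
  if (!is.list(controls) || length(controls) < 2)
    stop("need at least 2 control tables")
  if (!all(vapply(controls, inherits, logical(1), "band_power_table")))
    stop("controls must be band_power_table objects")
  ref <- controls[[1]]
  for (k in seq_along(controls)[-1]) {
    d <- c(setdiff(controls[[k]]$region_ids, ref$region_ids),
           setdiff(ref$region_ids, controls[[k]]$region_ids))
    if (length(d))
      stop("control region sets differ (control ", k, "): ",
           paste(unique(d), collapse = ", "))
    if (!setequal(controls[[k]]$band_names, ref$band_names))
      stop("control band sets differ (control ", k, ")")
  }
  arr <- vapply(controls,
                function(ct) ct$values[ref$region_ids, ref$band_names],
                ref$values)
  mu <- apply(arr, c(1, 2), mean)
  sigma <- apply(arr, c(1, 2), stats::sd)
  structure(list(region_ids = ref$region_ids, band_names = ref$band_names,
                 mu = mu, sigma = sigma, n_controls = length(controls)),
            class = "normative_map")
}

#' @export
print.normative_map <- function(x, ...) {
  cat(sprintf("Normative map: %d regions x %d bands from %d controls\n",
              length(x$region_ids), length(x$band_names), x$n_controls))
  invisible(x)
}

#' Patient abnormality map (maximum absolute z-score)
#'
#' z-scores each region-band relative power against the normative map,
#' `|z| = |x - mu| / sigma`, and reduces over bands by retaining the
#' maximum absolute z-score per region together with the band attaining it
#' (ties resolved to the lowest band index, delta first).
#'
#' A degenerate cell with `sigma = 0` yields z = 0 when the patient value
#' equals the control mean, and is a hard error otherwise: a silent
#' infinity would poison downstream rank statistics.
#'
#' @param patient a [band_power_table()].
#' @param norm a `normative_map` from [build_normative_map()] with matching
#'   regions and bands.
#' @return An `abnormality_map` with fields `subject_id`, `region_ids`,
#'   `max_abs_z` (non-negative, one per region) and `argmax_band`.
#' @export
abnormality_map <- function(patient, norm) {
  stopifnot(inherits(patient, "band_power_table"),
            inherits(norm, "normative_map"))
  d <- c(setdiff(patient$region_ids, norm$region_ids),
         setdiff(norm$region_ids, patient$region_ids))
  if (length(d))
    stop("patient/map region mismatch: ", paste(unique(d), collapse = ", "))
  if (!setequal(patient$band_names, norm$band_names))
    stop("patient/map band mismatch")
  x <- patient$values[norm$region_ids, norm$band_names, drop = FALSE]
  dev <- abs(x - norm$mu)
  degenerate <- norm$sigma == 0
  bad <- degenerate & dev > 0
  if (any(bad)) {
    cells <- which(bad, arr.ind = TRUE)
    stop("sigma = 0 with patient value != control mean at cell(s): ",
         paste(norm$region_ids[cells[, 1]], norm$band_names[cells[, 2]],
               sep = "/", collapse = ", "))
  }
  z <- dev
  z[!degenerate] <- dev[!degenerate] / norm$sigma[!degenerate]
  z[degenerate] <- 0
  amax <- apply(z, 1, which.max)   # first maximum: lowest band index on ties
  structure(list(subject_id = patient$subject_id,
                 region_ids = norm$region_ids,
                 max_abs_z = apply(z, 1, max),
                 argmax_band = norm$band_names[amax]),
            class = "abnormality_map")
}

#' @export
print.abnormality_map <- function(x, ...) {
  cat(sprintf("Abnormality map '%s': %d regions, max |z| range %.2f-%.2f\n",
              x$subject_id, length(x$region_ids),
              min(x$max_abs_z), max(x$max_abs_z)))
  invisible(x)
}
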