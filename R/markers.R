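#' Label regions as resected, spared or unknown from pre/post volumes
#'
#' Percent volume change is `100 * (pre - post) / pre`. A region is
#' `resected` if the change exceeds 10%, `unknown` if it lies in `(1, 10]`
#' (exactly 10% does not "exceed" 10%), and `spared` at 1% or below.
#' Apparent volume growth (post > pre), typically registration noise, is
#' clamped to 0% change with a warning.
#'
#' @param pre_vol named numeric vector of pre-operative region volumes
#'   (mm^3), all > 0.
#' @param post_vol named numeric vector of post-operative volumes over the
#'   same regions.
#' @return A `resection_mask`: fields `region_ids` and `status`, a factor in
#'   `{resected, spared, unknown}`.
#' @export
label_resection <- function(pre_vol, post_vol) {
  if (is.null(names(pre_vol)) || is.null(names(post_vol)))
    stop("volumes must be named by region")
  d <- c(setdiff(names(pre_vol), names(post_vol)),
         setdiff(names(post_vol), names(pre_vol)))
  if (length(d))
    stop("pre/post region mismatch: ", paste(unique(d), collapse = ", "))
  post_vol <- post_vol[names(pre_vol)]
  if (any(pre_vol <= 0)) stop("pre-operative volumes must be positive")
  change <- 100 * (pre_vol - post_vol) / pre_vol
  if (any(change < 0)) {
    warning("volume increase in ", sum(change < 0),
            " region(s); treating as 0% change")
    change[change < 0] <- 0
  }
  status <- ifelse(change > 10, "resected",
                   ifelse(change > 1, "unknown", "spared"))
  resection_mask(names(pre_vol), status)
}

#' Construct a resection mask
#'
#' @param region_ids character vector of unique region labels.
#' @param status character vector in `{resected, spared, unknown}`, one per
#'   region.
#' @return A `resection_mask` object.
#' @export
resection_mask <- function(region_ids, status) {
  if (length(region_ids) != length(status))
    stop("one status per region required")
  if (anyDuplicated(region_ids)) stop("region_ids must be unique")
  if (!all(status %in% c("resected", "spared", "unknown")))
    stop("status must be one of resected/spared/unknown")
  structure(list(region_ids = as.character(region_ids),
                 status = stats::setNames(as.character(status),
                                          as.character(region_ids))),
            class = "resection_mask")
}

#' @export
print.resection_mask <- function(x, ...) {
  tab <- table(factor(x$status, c("resected", "spared", "unknown")))
  cat(sprintf("Resection mask: %d resected, %d spared, %d unknown\n",
              tab["resected"], tab["spared"], tab["unknown"]))
  invisible(x)
}

# abnormality scores split by mask status, unknowns excluded from analysis
split_by_mask <- function(abn, mask) {
  stopifnot(inherits(abn, "abnormality_map"), inherits(mask, "resection_mask"))
  d <- c(setdiff(abn$region_ids, mask$region_ids),
         setdiff(mask$region_ids, abn$region_ids))
  if (length(d))
    stop("abnormality map/mask region mismatch: ",
         paste(unique(d), collapse = ", "))
  st <- mask$status[abn$region_ids]
  z <- stats::setNames(abn$max_abs_z, abn$region_ids)
  list(resected = z[st == "resected"], spared = z[st == "spared"])
}

#' Mean abnormality of the resection (MA_R)
#'
#' Arithmetic mean of the per-region maximum absolute z-scores over resected
#' regions (unknown regions excluded). Low values indicate the resected
#' tissue looked normal relative to controls, the first hypothesized
#' mechanism of surgical failure.
#'
#' @param abn an [abnormality_map()].
#' @param mask a [resection_mask()] over the same regions.
#' @return Non-negative scalar in z-units.
#' @export
mar <- function(abn, mask) {
  s <- split_by_mask(abn, mask)
  if (length(s$resected) == 0) stop("no resected regions in mask")
  mean(s$resected)
}

#' Distinguishability of resected vs spared tissue (D_RS)
#'
#' The Mann-Whitney AUC comparing the abnormality rank order of spared
#' regions against resected regions: the proportion of (resected, spared)
#' pairs in which the spared region is more abnormal, ties counting one
#' half. 0 means the most abnormal regions were all resected, 1 that they
#' were all spared, 0.5 is chance. Unknown regions are excluded.
#'
#' @inheritParams mar
#' @return Scalar in `[0, 1]`.
#' @export
drs <- function(abn, mask) {
  s <- split_by_mask(abn, mask)
  if (length(s$resected) == 0 || length(s$spared) == 0)
    stop("need at least one resected and one spared region")
  rank_auc(s$spared, s$resected)
}

# AUC = P(x > y) + 0.5 P(x = y) via midranks (Mann-Whitney U / (n_x n_y))
rank_auc <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

#' Abnormality contribution of the resection (AC_R)
#'
#' Percentage of the cortex-wide summed abnormality (sum of max |z| over
#' resected and spared regions; unknowns excluded) located in resected
#' regions. Small values indicate the resection barely altered the global
#' abnormality load, the third hypothesized failure mechanism.
#'
#' @inheritParams mar
#' @return Scalar percentage in `[0, 100]`.
#' @export
acr <- function(abn, mask) {
  s <- split_by_mask(abn, mask)
  tot <- sum(s$resected) + sum(s$spared)
  if (tot == 0) stop("total abnormality is zero; AC_R undefined")
  if (length(s$resected) == 0) {
    warning("no resected regions; AC_R = 0")
    return(0)
  }
  100 * sum(s$resected) / tot
}

#' Compute the full marker set for one patient
#'
#' @inheritParams mar
#' @param subject_id subject label; defaults to the abnormality map's.
#' @return A `marker_set`: fields `subject_id`, `MA_R`, `D_RS`, `AC_R`.
#' @export
marker_set <- function(abn, mask, subject_id = abn$subject_id) {
  structure(list(subject_id = subject_id,
                 MA_R = mar(abn, mask),
                 D_RS = drs(abn, mask),
                 AC_R = acr(abn, mask)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Markers '%s': MA_R = %.3f  D_RS = %.3f  AC_R = %.2f%%\n",
              x$subject_id, x$MA_R, x$D_RS, x$AC_R))
  invisible(x)
}
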