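#' Cohort table of per-patient markers and surgical outcomes
#'
#' @param subject_id character vector of unique subject labels.
#' @param MA_R,D_RS,AC_R numeric marker vectors (see [mar()], [drs()],
#'   [acr()]), one value per subject.
#' @param outcome character vector in `{good, bad}`; `good` is complete
#'   seizure freedom (ILAE 1), `bad` any postoperative seizures (ILAE 2+).
#' @return A `cohort_table` (a data frame).
#' @export
cohort_table <- function(subject_id, MA_R, D_RS, AC_R, outcome) {
  n <- length(subject_id)
  stopifnot(length(MA_R) == n, length(D_RS) == n, length(AC_R) == n,
            length(outcome) == n)
  if (anyDuplicated(subject_id)) stop("subject ids must be unique")
  if (!all(outcome %in% c("good", "bad")))
    stop("outcome must be 'good' or 'bad'")
  out <- data.frame(subject_id = as.character(subject_id),
                    MA_R = MA_R, D_RS = D_RS, AC_R = AC_R,
                    outcome = as.character(outcome),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' One-tailed Mann-Whitney AUC between outcome groups
#'
#' Computes the rank-based AUC as a nonparametric effect size, oriented so
#' that values above 0.5 support the stated alternative, together with a
#' one-tailed Mann-Whitney p-value. The p-value is exact (complete
#' enumeration of group assignments, valid under ties) when the combined
#' sample size is at most 20, and uses the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param good_values,bad_values numeric vectors of marker values for the
#'   good- and bad-outcome groups.
#' @param alternative `"greater"` hypothesizes the good group larger,
#'   `"less"` smaller.
#' @return List with `auc`, `p`, `U` (the Mann-Whitney statistic of the
#'   hypothesized-larger group) and `method`.
#' @export
auc_mwu <- function(good_values, bad_values,
                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(good_values) == 0 || length(bad_values) == 0)
    stop("both groups must be non-empty")
  # orient so x is the group hypothesized larger
  if (alternative == "greater") { x <- good_values; y <- bad_values }
  else { x <- bad_values; y <- good_values }
  auc <- rank_auc(x, y)
  u <- auc * length(x) * length(y)
  n <- length(x) + length(y)
  if (n <= 20) {
    p <- mwu_exact_p(x, y)
    method <- "exact enumeration"
  } else {
    p <- mwu_normal_p(x, y)
    method <- "normal approximation, tie-corrected"
  }
  list(auc = auc, p = p, U = u, method = method)
}

# exact one-tailed P(U_x >= u_obs) by enumerating all group assignments;
# midranks make this valid with ties
mwu_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  u_obs <- sum(r[seq_len(nx)])
  sums <- utils::combn(r, nx, sum)
  mean(sums >= u_obs - 1e-9)
}

mwu_normal_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y); n <- nx + ny
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  stats::pnorm((u - mu - 0.5) / sqrt(v), lower.tail = FALSE)
}

#' One-sample, one-tailed Wilcoxon signed-rank test
#'
#' Tests whether `values` differ from a reference in the stated direction.
#' Zero differences are dropped (standard signed-rank convention); tied
#' absolute differences receive midranks. The p-value is exact for up to 25
#' nonzero differences — computed by convolving the signed-rank generating
#' function over doubled midranks, which stays exact under ties — and uses
#' the tie-corrected normal approximation with continuity correction beyond.
#'
#' @param values numeric vector.
#' @param reference scalar reference value (e.g. 0.5 for chance-level
#'   D_RS, or a healthy-deviation threshold for MA_R).
#' @param alternative `"greater"` or `"less"`.
#' @return List with `W` (sum of ranks of positive differences), `p`,
#'   `n_used` (nonzero differences) and `method`.
#' @export
wilcoxon_one_sample <- function(values, reference,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- values - reference
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25) {
    p <- signed_rank_exact_p(r, w, alternative)
    method <- "exact convolution"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (alternative == "greater") (w - mu - 0.5) / sqrt(v)
         else (w - mu + 0.5) / sqrt(v)
    p <- stats::pnorm(z, lower.tail = alternative == "less")
    method <- "normal approximation, tie-corrected"
  }
  list(W = w, p = p, n_used = n, method = method)
}

# exact null distribution of W over 2^n sign patterns, by polynomial
# convolution on doubled midranks (integers even with ties)
signed_rank_exact_p <- function(ranks, w_obs, alternative) {
  r2 <- as.integer(round(2 * ranks))
  probs <- numeric(sum(r2) + 1)   # index k holds P(2W = k - 1)
  probs[1] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), probs[seq_len(length(probs) - rk)])
    probs <- 0.5 * probs + 0.5 * shifted
  }
  w2 <- as.integer(round(2 * w_obs))
  if (alternative == "greater") sum(probs[(w2 + 1):length(probs)])
  else sum(probs[seq_len(w2 + 1)])
}

#' Monte-Carlo threshold for healthy maximum absolute z-scores
#'
#' Simulates the abnormality score a healthy region would attain by chance:
#' draws `n_bands` independent standard-normal z-scores, keeps the maximum
#' absolute value, repeats `n_iter` times, and returns the empirical
#' `1 - alpha` quantile. With five bands and `alpha = 0.05` the threshold
#' is about 2.6 (closed form 2.5695, see
#' [max_abs_z_threshold_exact()]).
#'
#' @param n_bands number of independent z-scores per region (default 5).
#' @param n_iter Monte-Carlo iterations (default 100000, minimum 1000).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param seed optional integer seed for reproducibility.
#' @return Scalar threshold in z-units.
#' @export
simulate_max_abs_z_threshold <- function(n_bands = 5, n_iter = 100000,
                                         alpha = 0.05, seed = NULL) {
  stopifnot(n_bands >= 1, n_iter >= 1000)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(abs(stats::rnorm(n_iter * n_bands)), nrow = n_iter)
  maxs <- z[, 1]
  for (j in seq_len(n_bands)[-1]) maxs <- pmax(maxs, z[, j])
  unname(stats::quantile(maxs, 1 - alpha))
}

#' Closed-form healthy max-|z| threshold
#'
#' Solves `(2 * Phi(t) - 1)^n_bands = 1 - alpha` for `t`, the exact
#' `1 - alpha` quantile of the maximum of `n_bands` absolute standard
#' normals.
#'
#' @inheritParams simulate_max_abs_z_threshold
#' @return Scalar threshold in z-units.
#' @export
max_abs_z_threshold_exact <- function(n_bands = 5, alpha = 0.05) {
  stats::qnorm((1 + (1 - alpha)^(1 / n_bands)) / 2)
}

#' Optimal ROC threshold for discriminating surgical outcome
#'
#' Scans candidate cut-points (midpoints between adjacent sorted unique
#' marker values, plus minus/plus infinity) and returns the cut that best
#' discriminates bad from good outcomes: by default the maximizer of
#' Youden's J = TPR - FPR, where a subject is "flagged" when its value lies
#' beyond the cut in the failure direction (`low`: value < cut; `high`:
#' value > cut). Ties on J are broken toward the lowest FPR, then toward
#' the more extreme cut in the failure direction, favouring specificity.
#'
#' @param values numeric marker values, one per subject.
#' @param outcomes character vector in `{good, bad}`.
#' @param failure_direction `"low"` if small values mark failure (MA_R,
#'   AC_R), `"high"` if large values do (D_RS).
#' @param method `"youden"` (default) or `"closest"` (minimum Euclidean
#'   distance to the perfect corner TPR = 1, FPR = 0).
#' @return List with `threshold`, `J`, `TPR`, `FPR`.
#' @export
optimal_threshold <- function(values, outcomes,
                              failure_direction = c("low", "high"),
                              method = c("youden", "closest")) {
  failure_direction <- match.arg(failure_direction)
  method <- match.arg(method)
  stopifnot(length(values) == length(outcomes))
  if (!all(outcomes %in% c("good", "bad")))
    stop("outcomes must be 'good' or 'bad'")
  if (length(unique(outcomes)) < 2)
    stop("both outcome classes must be present")
  u <- sort(unique(values))
  cuts <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  bad <- outcomes == "bad"
  stats_at <- function(cut) {
    flag <- if (failure_direction == "low") values < cut else values > cut
    c(tpr = mean(flag[bad]), fpr = mean(flag[!bad]))
  }
  st <- vapply(cuts, stats_at, c(tpr = 0, fpr = 0))
  score <- if (method == "youden") st["tpr", ] - st["fpr", ]
           else -sqrt((1 - st["tpr", ])^2 + st["fpr", ]^2)
  best <- which(score >= max(score) - 1e-12)
  best <- best[st["fpr", best] <= min(st["fpr", best]) + 1e-12]
  pick <- if (failure_direction == "low") best[which.min(cuts[best])]
          else best[which.max(cuts[best])]
  list(threshold = cuts[pick],
       J = unname(st["tpr", pick] - st["fpr", pick]),
       TPR = unname(st["tpr", pick]), FPR = unname(st["fpr", pick]))
}

#' Marker threshold set for failure flagging
#'
#' @param mar_thresh MA_R threshold in z-units (flag when below).
#' @param drs_thresh D_RS threshold in `[0, 1]` (flag when above).
#' @param acr_thresh AC_R threshold in percent (flag when below).
#' @return A `threshold_set` object.
#' @export
threshold_set <- function(mar_thresh, drs_thresh, acr_thresh) {
  # infinite cuts are legal degenerate outputs of optimal_threshold
  # (never / always flag); range checks apply to finite values only
  if (is.finite(drs_thresh) && (drs_thresh < 0 || drs_thresh > 1))
    stop("drs_thresh must lie in [0, 1]")
  if (is.finite(acr_thresh) && (acr_thresh < 0 || acr_thresh > 100))
    stop("acr_thresh must lie in [0, 100]")
  structure(list(mar_thresh = mar_thresh, drs_thresh = drs_thresh,
                 acr_thresh = acr_thresh,
                 direction = c(MA_R = "low", D_RS = "high", AC_R = "low")),
            class = "threshold_set")
}

#' Flag markers of surgical failure
#'
#' Applies strict threshold inequalities per mechanism: mechanism 1
#' (abnormalities not targeted) flags when `MA_R < mar_thresh`; mechanism 2
#' (epileptogenic zone partially resected) when `D_RS > drs_thresh`;
#' mechanism 3 (global abnormality insufficiently altered) when
#' `AC_R < acr_thresh`. Boundary equality never flags.
#'
#' @param cohort a [cohort_table()].
#' @param thresholds a [threshold_set()].
#' @return Data frame with columns `subject_id`, `mech1`, `mech2`, `mech3`
#'   (logical flags) and `n_flags`.
#' @export
flag_failures <- function(cohort, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  mech1 <- cohort$MA_R < thresholds$mar_thresh
  mech2 <- cohort$D_RS > thresholds$drs_thresh
  mech3 <- cohort$AC_R < thresholds$acr_thresh
  data.frame(subject_id = cohort$subject_id,
             mech1 = mech1, mech2 = mech2, mech3 = mech3,
             n_flags = mech1 + mech2 + mech3,
             stringsAsFactors = FALSE)
}

#' Unified multi-marker outcome analysis
#'
#' Runs the full cohort-level validation: one-tailed Mann-Whitney AUCs per
#' marker under the directional hypotheses (good outcome implies higher
#' MA_R, lower D_RS, higher AC_R), in-sample optimal ROC thresholds per
#' marker, failure flagging of every subject, the AUC of the flag count for
#' discriminating bad outcome, and the proportions of each outcome group
#' carrying at least one, at least two, all three, or zero flags.
#'
#' @param cohort a [cohort_table()] containing both outcomes.
#' @param method threshold selection rule passed to [optimal_threshold()].
#' @return A `cohort_report` list with elements `marker_stats` (data frame:
#'   marker, auc, p, threshold), `thresholds` (a [threshold_set()]),
#'   `flags` (from [flag_failures()]), `n_flags_auc`, `n_flags_p`, and
#'   `flag_rates` (proportions by group).
#' @export
unified_outcome_analysis <- function(cohort, method = "youden") {
  stopifnot(inherits(cohort, "cohort_table"))
  g <- cohort$outcome == "good"
  if (!any(g) || all(g)) stop("cohort must contain both outcomes")
  dirs <- list(MA_R = "greater", D_RS = "less", AC_R = "greater")
  fail_dir <- c(MA_R = "low", D_RS = "high", AC_R = "low")
  marker_stats <- do.call(rbind, lapply(names(dirs), function(m) {
    a <- auc_mwu(cohort[[m]][g], cohort[[m]][!g], dirs[[m]])
    th <- optimal_threshold(cohort[[m]], cohort$outcome, fail_dir[[m]],
                            method = method)
    data.frame(marker = m, auc = a$auc, p = a$p,
               threshold = th$threshold, stringsAsFactors = FALSE)
  }))
  ths <- threshold_set(marker_stats$threshold[marker_stats$marker == "MA_R"],
                       marker_stats$threshold[marker_stats$marker == "D_RS"],
                       marker_stats$threshold[marker_stats$marker == "AC_R"])
  flags <- flag_failures(cohort, ths)
  nf <- auc_mwu(flags$n_flags[!g], flags$n_flags[g], "greater")
  rate <- function(sel) c(ge1 = mean(flags$n_flags[sel] >= 1),
                          ge2 = mean(flags$n_flags[sel] >= 2),
                          all3 = mean(flags$n_flags[sel] == 3),
                          none = mean(flags$n_flags[sel] == 0))
  structure(list(marker_stats = marker_stats, thresholds = ths,
                 flags = flags, n_flags_auc = nf$auc, n_flags_p = nf$p,
                 flag_rates = rbind(good = rate(g), bad = rate(!g)),
                 n_good = sum(g), n_bad = sum(!g)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort outcome analysis (%d good / %d bad)\n",
              x$n_good, x$n_bad))
  for (i in seq_len(nrow(x$marker_stats)))
    cat(sprintf("  %-5s AUC = %.2f  p = %.4f  threshold = %.3g\n",
                x$marker_stats$marker[i], x$marker_stats$auc[i],
                x$marker_stats$p[i], x$marker_stats$threshold[i]))
  cat(sprintf("  flag-count AUC = %.2f  p = %.4f\n",
              x$n_flags_auc, x$n_flags_p))
  cat(sprintf("  bad outcome: %.0f%% with >=1 flag, %.0f%% with >=2, %.0f%% all 3\n",
              100 * x$flag_rates["bad", "ge1"],
              100 * x$flag_rates["bad", "ge2"],
              100 * x$flag_rates["bad", "all3"]))
  invisible(x)
}
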