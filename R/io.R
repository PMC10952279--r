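#' @name megmark-io
#' @title Delimited-text readers and writers
#'
#' @description All pipeline artifacts are stored as small delimited text
#' tables (comma by default, tab accepted) so every intermediate is
#' inspectable. Numeric columns are written with 15 significant digits, so
#' write-then-read round-trips are identity to beyond 12 significant
#' digits. Region identity is matched by label, never by row order.
#'
#' Schemas:
#' \itemize{
#'   \item band-power table: `subject,region,<band...>` (default bands
#'     `delta,theta,alpha,beta,gamma`)
#'   \item normative map: comment line `# n_controls=N`, then
#'     `region,band,mu,sigma`
#'   \item abnormality map: `region,max_abs_z,argmax_band`
#'   \item volumes: `region,pre_volume,post_volume`
#'   \item resection mask: `region,status`
#'   \item markers: `subject,MA_R,D_RS,AC_R`
#'   \item outcomes: `subject,outcome`
#'   \item region time series: first column `region`, remaining columns
#'     samples (sampling rate supplied separately)
#' }
NULL

sniff_sep <- function(path) {
  l1 <- readLines(path, n = 2)
  l1 <- l1[!startsWith(l1, "#")][1]
  if (is.na(l1)) stop("empty file: ", path)
  if (grepl("\t", l1)) "\t" else ","
}

read_delim_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  df
}

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

write_delim_num <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a band-power table
#'
#' @param path delimited file with columns `subject,region,<band...>`.
#' @return A [band_power_table()]; the row-sum invariant is enforced on
#'   read.
#' @rdname megmark-io
#' @export
read_band_power_table <- function(path) {
  df <- read_delim_checked(path, c("subject", "region"))
  bands <- setdiff(names(df), c("subject", "region"))
  if (length(bands) < 1) stop(path, ": no band columns found")
  if (length(unique(df$subject)) != 1)
    stop(path, ": expected exactly one subject per file")
  v <- as.matrix(df[bands])
  if (!is.numeric(v)) stop(path, ": non-numeric band power values")
  rownames(v) <- df$region
  tryCatch(band_power_table(v, subject_id = df$subject[1]),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @param tab a [band_power_table()].
#' @param path output file path.
#' @rdname megmark-io
#' @export
write_band_power_table <- function(tab, path) {
  stopifnot(inherits(tab, "band_power_table"))
  df <- data.frame(subject = tab$subject_id, region = tab$region_ids,
                   tab$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delim_num(df, path)
  invisible(path)
}

#' @param norm a `normative_map`.
#' @rdname megmark-io
#' @export
write_normative_map <- function(norm, path) {
  stopifnot(inherits(norm, "normative_map"))
  df <- data.frame(
    region = rep(norm$region_ids, times = length(norm$band_names)),
    band = rep(norm$band_names, each = length(norm$region_ids)),
    mu = as.vector(norm$mu), sigma = as.vector(norm$sigma),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_controls=%d", norm$n_controls), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname megmark-io
#' @export
read_normative_map <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# n_controls=\\d+", hdr))
    stop(path, ": missing '# n_controls=' header line")
  n_controls <- as.integer(sub("^# n_controls=", "", hdr))
  df <- read_delim_checked(path, c("region", "band", "mu", "sigma"))
  regions <- unique(df$region); bands <- unique(df$band)
  mu <- matrix(NA_real_, length(regions), length(bands),
               dimnames = list(regions, bands))
  sigma <- mu
  mu[cbind(df$region, df$band)] <- df$mu
  sigma[cbind(df$region, df$band)] <- df$sigma
  if (anyNA(mu) || anyNA(sigma))
    stop(path, ": incomplete region x band grid")
  structure(list(region_ids = regions, band_names = bands,
                 mu = mu, sigma = sigma, n_controls = n_controls),
            class = "normative_map")
}

#' @param abn an [abnormality_map()].
#' @rdname megmark-io
#' @export
write_abnormality_map <- function(abn, path) {
  stopifnot(inherits(abn, "abnormality_map"))
  write_delim_num(data.frame(region = abn$region_ids,
                             max_abs_z = unname(abn$max_abs_z),
                             argmax_band = abn$argmax_band,
                             stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @param subject_id subject label attached on read.
#' @rdname megmark-io
#' @export
read_abnormality_map <- function(path, subject_id = "subject") {
  df <- read_delim_checked(path, c("region", "max_abs_z", "argmax_band"))
  if (any(df$max_abs_z < 0)) stop(path, ": negative max_abs_z")
  structure(list(subject_id = subject_id, region_ids = df$region,
                 max_abs_z = stats::setNames(df$max_abs_z, df$region),
                 argmax_band = df$argmax_band),
            class = "abnormality_map")
}

#' @rdname megmark-io
#' @export
read_volumes <- function(path) {
  df <- read_delim_checked(path, c("region", "pre_volume", "post_volume"))
  list(pre = stats::setNames(df$pre_volume, df$region),
       post = stats::setNames(df$post_volume, df$region))
}

#' @param mask a [resection_mask()].
#' @rdname megmark-io
#' @export
write_resection_mask <- function(mask, path) {
  stopifnot(inherits(mask, "resection_mask"))
  write_delim_num(data.frame(region = mask$region_ids,
                             status = unname(mask$status),
                             stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname megmark-io
#' @export
read_resection_mask <- function(path) {
  df <- read_delim_checked(path, c("region", "status"))
  tryCatch(resection_mask(df$region, df$status),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname megmark-io
#' @export
read_outcomes <- function(path) {
  df <- read_delim_checked(path, c("subject", "outcome"))
  if (!all(df$outcome %in% c("good", "bad")))
    stop(path, ": outcome must be 'good' or 'bad'")
  stats::setNames(df$outcome, df$subject)
}

#' @param cohort a [cohort_table()] (markers plus outcome).
#' @rdname megmark-io
#' @export
write_marker_table <- function(cohort, path) {
  df <- data.frame(subject = cohort$subject_id, MA_R = cohort$MA_R,
                   D_RS = cohort$D_RS, AC_R = cohort$AC_R,
                   stringsAsFactors = FALSE)
  write_delim_num(df, path)
  invisible(path)
}

#' @rdname megmark-io
#' @export
read_marker_table <- function(path) {
  read_delim_checked(path, c("subject", "MA_R", "D_RS", "AC_R"))
}

#' Read region time series from delimited text
#'
#' @param path file whose first column is the region id and remaining
#'   columns are samples.
#' @param fs sampling rate in Hz.
#' @rdname megmark-io
#' @export
read_region_ts <- function(path, fs) {
  df <- read_delim_checked(path, "region")
  m <- as.matrix(df[setdiff(names(df), "region")])
  if (!is.numeric(m)) stop(path, ": non-numeric samples")
  region_ts(m, df$region, fs)
}

#' @param ts a [region_ts()].
#' @rdname megmark-io
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  df <- data.frame(region = ts$region_ids, ts$data, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("region", sprintf("s%d", seq_len(ncol(ts$data))))
  write_delim_num(df, path)
  invisible(path)
}
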