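#' Frequency band scheme
#'
#' A band scheme is an ordered set of named frequency bands with half-open
#' ranges `[low, high)` in Hz, each optionally carrying excluded sub-ranges
#' (also half-open). The half-open convention guarantees that adjacent bands
#' sharing an edge (e.g. theta/alpha at 8 Hz) never double-count a frequency
#' bin, so relative band powers sum exactly to 1.
#'
#' @param name character vector of band names.
#' @param low,high numeric vectors of band edges in Hz; bands are `[low, high)`.
#' @param exclude named list mapping a band name to a two-column matrix (or a
#'   length-2 numeric) of excluded `[low, high)` sub-ranges lying inside that
#'   band.
#' @return An object of class `band_scheme`: a data frame with columns
#'   `name`, `low`, `high` and an `exclude` attribute.
#' @examples
#' default_band_scheme()
#' @export
band_scheme <- function(name, low, high, exclude = list()) {
  stopifnot(length(name) == length(low), length(low) == length(high))
  if (anyDuplicated(name)) stop("band names must be unique")
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low >= high))
    stop("each band needs finite low < high")
  ord <- order(low)
  if (any(high[ord][-length(ord)] > low[ord][-1] + 1e-12))
    stop("bands overlap after the half-open [low, high) convention")
  excl <- lapply(exclude, function(e) {
    m <- matrix(as.numeric(e), ncol = 2, byrow = FALSE)
    if (is.null(dim(e)) && length(e) == 2) m <- matrix(as.numeric(e), ncol = 2)
    m
  })
  for (bn in names(excl)) {
    if (!bn %in% name) stop("exclusion refers to unknown band: ", bn)
    b <- which(name == bn)
    m <- excl[[bn]]
    if (any(m[, 1] < low[b] - 1e-12) || any(m[, 2] > high[b] + 1e-12))
      stop("exclusions must lie inside band ", bn)
  }
  out <- data.frame(name = as.character(name), low = low, high = high,
                    stringsAsFactors = FALSE)
  attr(out, "exclude") <- excl
  class(out) <- c("band_scheme", "data.frame")
  out
}

#' Default five-band MEG scheme
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-80 Hz, with
#' 47.5-52.5 Hz excluded from gamma to mitigate UK powerline artifacts.
#'
#' @return A [band_scheme()] with five bands.
#' @export
default_band_scheme <- function() {
  band_scheme(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 80),
    exclude = list(gamma = c(47.5, 52.5))
  )
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Band scheme (", nrow(x), " bands, half-open [low, high) Hz)\n", sep = "")
  excl <- attr(x, "exclude")
  for (i in seq_len(nrow(x))) {
    e <- excl[[x$name[i]]]
    etxt <- if (!is.null(e))
      paste0("  excl ", paste(apply(e, 1, function(r)
        paste0("[", r[1], ",", r[2], ")")), collapse = ", "))
    else ""
    cat(sprintf("  %-8s [%g, %g)%s\n", x$name[i], x$low[i], x$high[i], etxt))
  }
  invisible(x)
}

# bin centers of `freqs` falling in band i of `scheme`, honouring exclusions
band_bin_index <- function(freqs, scheme, i) {
  lo <- scheme$low[i]; hi <- scheme$high[i]
  inb <- freqs >= lo & freqs < hi
  e <- attr(scheme, "exclude")[[scheme$name[i]]]
  if (!is.null(e)) {
    for (k in seq_len(nrow(e))) inb <- inb & !(freqs >= e[k, 1] & freqs < e[k, 2])
  }
  which(inb)
}
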