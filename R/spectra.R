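#' Reflectance spectra datasets
#'
#' A spectral dataset is a plain `data.frame` whose first column (named `wl`
#' by default) holds the wavelength grid in nanometres and whose remaining
#' columns each hold one reflectance measurement (percent reflectance).
#' Replicate measurements are named `<individual>_<replicate>` so that the
#' owning individual can be recovered from the column name.
#'
#' @param x data.frame with a wavelength column followed by measurement
#'   columns.
#' @param wl_col name of the wavelength column.
#' @return `x` with class `reflectance_spectra` prepended, wavelength column
#'   first and named `wl`.
#' @export
as_spectra <- function(x, wl_col = "wl") {
  if (!is.data.frame(x)) stop("`x` must be a data.frame")
  if (!wl_col %in% names(x)) {
    stop("missing wavelength column '", wl_col, "'")
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate column names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  x <- x[, c(wl_col, setdiff(names(x), wl_col)), drop = FALSE]
  names(x)[1] <- "wl"
  for (j in seq_along(x)) {
    if (!is.numeric(x[[j]])) {
      stop("non-numeric values in column '", names(x)[j], "'")
    }
    if (any(!is.finite(x[[j]]))) {
      stop("non-finite values in column '", names(x)[j], "'")
    }
  }
  if (is.unsorted(x$wl, strictly = TRUE)) {
    stop("non-monotone wavelengths")
  }
  class(x) <- c("reflectance_spectra", "data.frame")
  x
}

#' Read a wide-format reflectance CSV
#'
#' Expects a header row, comma separation and a decimal point; one wavelength
#' column plus one column per measurement.
#'
#' @param path CSV file path.
#' @inheritParams as_spectra
#' @return a `reflectance_spectra` data.frame on the file's native grid,
#'   column order preserved.
#' @export
read_spectra <- function(path, wl_col = "wl") {
  x <- utils::read.csv(path, check.names = FALSE)
  as_spectra(x, wl_col = wl_col)
}

#' Write spectra to CSV
#'
#' Full-precision round-trip companion to [read_spectra()].
#'
#' @param ds a `reflectance_spectra` data.frame.
#' @param path output file path.
#' @export
write_spectra <- function(ds, path) {
  utils::write.csv(format(as.data.frame(ds), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample metadata
#'
#' One row per individual with its morph and sex.
#'
#' @param x data.frame with columns `individual_id`, `morph`
#'   (orange/white/yellow) and `sex` (M/F).
#' @return validated data.frame of class `sample_metadata`.
#' @export
as_metadata <- function(x) {
  need <- c("individual_id", "morph", "sex")
  if (!all(need %in% names(x))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  x$individual_id <- as.character(x$individual_id)
  x$morph <- as.character(x$morph)
  x$sex <- as.character(x$sex)
  if (anyDuplicated(x$individual_id)) stop("duplicate individual_id")
  bad <- setdiff(unique(x$morph), c("orange", "white", "yellow"))
  if (length(bad)) stop("invalid morph value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(x$sex), c("M", "F"))
  if (length(bad)) stop("invalid sex value(s): ", paste(bad, collapse = ", "))
  class(x) <- c("sample_metadata", "data.frame")
  x
}

#' @rdname as_metadata
#' @param path metadata CSV path.
#' @export
read_metadata <- function(path) {
  as_metadata(utils::read.csv(path))
}

#' Recover individual ids from measurement column names
#'
#' Measurement columns follow the `<individual>_<replicate>` convention; the
#' individual id is everything before the final underscore.
#'
#' @param ids character vector of measurement ids.
#' @return character vector of individual ids.
#' @export
measurement_individual <- function(ids) {
  sub("_[^_]*$", "", ids)
}

spectra_matrix <- function(ds) {
  as.matrix(as.data.frame(ds)[, -1, drop = FALSE])
}

#' Restrict and regrid spectra to an integer 1-nm grid
#'
#' Linearly interpolates every measurement onto the integer grid `lo:hi`
#' (nm); wavelengths outside the window are dropped. The source grid must
#' cover the whole window.
#'
#' @param ds a `reflectance_spectra` data.frame.
#' @param lo,hi window bounds in nm (defaults 300 and 700).
#' @export
restrict_and_regrid <- function(ds, lo = 300, hi = 700) {
  wl <- ds$wl
  if (min(wl) > lo || max(wl) < hi) {
    stop(sprintf("source grid [%g, %g] does not cover [%g, %g]",
                 min(wl), max(wl), lo, hi))
  }
  grid <- seq.int(lo, hi)
  out <- data.frame(wl = grid)
  for (nm in names(ds)[-1]) {
    out[[nm]] <- stats::approx(wl, ds[[nm]], xout = grid)$y
  }
  as_spectra(out)
}

#' Average replicate measurements into one spectrum per individual
#'
#' Pointwise arithmetic mean of each individual's replicates. Replicates are
#' grouped by [measurement_individual()] on the column names; if `meta` is
#' supplied, every measurement must map to a known individual.
#'
#' @param ds a `reflectance_spectra` data.frame of replicate measurements.
#' @param meta optional `sample_metadata`; when given, output columns follow
#'   its individual order.
#' @return a `reflectance_spectra` data.frame keyed by individual id.
#' @export
aggregate_replicates <- function(ds, meta = NULL) {
  ids <- names(ds)[-1]
  ind <- measurement_individual(ids)
  if (!is.null(meta)) {
    unknown <- setdiff(ind, meta$individual_id)
    if (length(unknown)) {
      stop("measurement(s) with no metadata entry for individual(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    order_ind <- intersect(meta$individual_id, ind)
  } else {
    order_ind <- unique(ind)
  }
  m <- spectra_matrix(ds)
  out <- data.frame(wl = ds$wl)
  for (id in order_ind) {
    out[[id]] <- rowMeans(m[, ind == id, drop = FALSE])
  }
  as_spectra(out)
}

#' Smooth spectra by local quadratic regression
#'
#' Tricube-weighted local polynomial regression of degree 2 (`stats::loess`
#' with an exact direct fit), with `span` interpreted as the fraction of grid
#' points in the local window, evaluated back on the same grid.
#'
#' @param ds a `reflectance_spectra` data.frame.
#' @param span smoothing span as a fraction of grid points, in (0, 1].
#' @export
smooth_spectra <- function(ds, span = 0.2) {
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    stop("`span` must be a single value in (0, 1]")
  }
  wl <- ds$wl
  out <- data.frame(wl = wl)
  for (nm in names(ds)[-1]) {
    fit <- stats::loess(y ~ x, data = data.frame(x = wl, y = ds[[nm]]),
                        span = span, degree = 2, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    out[[nm]] <- stats::predict(fit, newdata = data.frame(x = wl))
  }
  as_spectra(out)
}

#' Check or repair negative reflectance values
#'
#' @param ds a `reflectance_spectra` data.frame.
#' @param fix `"error"` raises on any negative value (naming the measurement
#'   and wavelength); `"clip_zero"` sets negatives to zero and records how
#'   many were clipped in attribute `n_clipped`.
#' @export
validate_nonnegative <- function(ds, fix = c("error", "clip_zero")) {
  fix <- match.arg(fix)
  n_clipped <- 0L
  for (nm in names(ds)[-1]) {
    neg <- which(ds[[nm]] < 0)
    if (length(neg)) {
      if (fix == "error") {
        stop(sprintf("negative reflectance in measurement '%s' at %g nm (%g)",
                     nm, ds$wl[neg[1]], ds[[nm]][neg[1]]))
      }
      ds[[nm]][neg] <- 0
      n_clipped <- n_clipped + length(neg)
    }
  }
  attr(ds, "n_clipped") <- n_clipped
  ds
}

#' Standard spectral processing chain
#'
#' Restrict to the analysis window, average replicates per individual,
#' smooth, and check for negative values, in the conventional order
#' (averaging before smoothing). The order of averaging and smoothing can be
#' swapped.
#'
#' @inheritParams aggregate_replicates
#' @inheritParams restrict_and_regrid
#' @inheritParams smooth_spectra
#' @param order `"aggregate_then_smooth"` (default) or
#'   `"smooth_then_aggregate"`.
#' @param negatives policy passed to [validate_nonnegative()].
#' @return processed `reflectance_spectra`, one column per individual, with
#'   a `provenance` attribute recording the settings.
#' @export
process_spectra <- function(ds, meta = NULL, lo = 300, hi = 700, span = 0.2,
                            order = c("aggregate_then_smooth",
                                      "smooth_then_aggregate"),
                            negatives = c("error", "clip_zero")) {
  order <- match.arg(order)
  negatives <- match.arg(negatives)
  out <- restrict_and_regrid(ds, lo, hi)
  if (order == "aggregate_then_smooth") {
    out <- smooth_spectra(aggregate_replicates(out, meta), span)
  } else {
    out <- aggregate_replicates(smooth_spectra(out, span), meta)
  }
  out <- validate_nonnegative(out, negatives)
  attr(out, "provenance") <- list(lo = lo, hi = hi, span = span,
                                  order = order, negatives = negatives)
  out
}
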