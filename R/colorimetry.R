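#' Colorimetric variables
#'
#' Three standard segment-free colorimetrics of a processed reflectance
#' spectrum:
#' * brightness — mean percent reflectance over the analysed range;
#' * chroma — (Rmax - Rmin) / brightness, a dimensionless spectral contrast;
#' * hue — the wavelength at middle reflectance, i.e. the grid wavelength
#'   whose reflectance is closest to (Rmax + Rmin) / 2, ties broken toward
#'   the shorter wavelength.
#'
#' @param ds a `reflectance_spectra` data.frame (typically one column per
#'   individual after [process_spectra()]).
#' @return named numeric vector, one value per measurement column.
#' @export
brightness <- function(ds) {
  m <- spectra_matrix(ds)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty spectrum")
  colMeans(m)
}

#' @rdname brightness
#' @export
chroma <- function(ds) {
  m <- spectra_matrix(ds)
  b <- colMeans(m)
  if (any(b <= 0)) {
    stop("zero brightness for measurement '", colnames(m)[which(b <= 0)[1]], "'")
  }
  (apply(m, 2, max) - apply(m, 2, min)) / b
}

#' @rdname brightness
#' @return for `hue`, the vector carries an attribute `multiple_crossings`
#'   flagging spectra whose reflectance crosses the mid level more than once
#'   (e.g. UV-spiked spectra), for which "wavelength at middle reflectance"
#'   is ambiguous.
#' @export
hue <- function(ds) {
  m <- spectra_matrix(ds)
  wl <- ds$wl
  out <- numeric(ncol(m))
  multi <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    r <- m[, j]
    rmax <- max(r); rmin <- min(r)
    if (rmax == rmin) {
      stop("hue undefined for constant spectrum '", colnames(m)[j], "'")
    }
    rmid <- (rmax + rmin) / 2
    out[j] <- wl[which.min(abs(r - rmid))]
    s <- sign(r - rmid)
    multi[j] <- sum(diff(s[s != 0]) != 0) > 1
  }
  names(out) <- colnames(m)
  attr(out, "multiple_crossings") <- stats::setNames(multi, colnames(m))
  out
}

#' Per-individual colorimetric table
#'
#' @inheritParams brightness
#' @return data.frame with columns `individual_id`, `brightness`, `chroma`,
#'   `hue`.
#' @export
colorimetric_summary <- function(ds) {
  h <- hue(ds)
  data.frame(individual_id = names(ds)[-1],
             brightness = unname(brightness(ds)),
             chroma = unname(chroma(ds)),
             hue = as.numeric(h),
             row.names = NULL)
}

#' Summarize colorimetrics by morph and sex
#'
#' Group-level table in the usual reporting layout: per morph x sex group,
#' the sample size, mean brightness and mean chroma across individuals, and
#' the hue of the group mean spectrum (the printed-style convention). The
#' mean of per-individual hues is also emitted (`hue_indiv_mean`) since both
#' conventions are in circulation.
#'
#' @param ds processed `reflectance_spectra`, one column per individual.
#' @param meta `sample_metadata` covering every individual in `ds`.
#' @return data.frame with one row per morph x sex group.
#' @export
summarize_groups <- function(ds, meta) {
  meta <- as_metadata(as.data.frame(meta))
  ids <- names(ds)[-1]
  missing <- setdiff(ids, meta$individual_id)
  if (length(missing)) {
    stop("no metadata for individual(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  cs <- colorimetric_summary(ds)
  meta <- meta[match(ids, meta$individual_id), ]
  key <- interaction(meta$morph, meta$sex, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    if (!any(sel)) stop("empty group: ", k)
    grp_ids <- ids[sel]
    mean_spec <- data.frame(wl = ds$wl,
                            g = rowMeans(spectra_matrix(ds)[, sel, drop = FALSE]))
    data.frame(morph = meta$morph[sel][1],
               sex = meta$sex[sel][1],
               n = sum(sel),
               brightness = mean(cs$brightness[sel]),
               chroma = mean(cs$chroma[sel]),
               hue = as.numeric(hue(as_spectra(mean_spec))),
               hue_indiv_mean = mean(cs$hue[sel]))
  })
  do.call(rbind, rows)
}
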