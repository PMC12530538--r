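#' Govardovskii A1 visual-pigment template
#'
#' Alpha band of the A1 rhodopsin nomogram,
#' \deqn{S(\lambda) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, b = 0.922,
#' C = -14.9, c = 1.104, D = 0.674 and
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}}, plus the
#' standard Gaussian beta band (amplitude 0.26, peak
#' \eqn{189 + 0.315\,\lambda_{max}}, bandwidth
#' \eqn{-40.5 + 0.195\,\lambda_{max}}).
#'
#' @param lambda_max peak sensitivity in nm (within the grid).
#' @param wl wavelength grid in nm.
#' @param normalize `"area"` scales the curve to unit sum over the grid (the
#'   form used in quantum-catch integration); `"peak"` scales the maximum
#'   to 1.
#' @param beta include the beta band (default TRUE).
#' @return numeric sensitivity curve on `wl`.
#' @export
pigment_template <- function(lambda_max, wl = 300:700,
                             normalize = c("area", "peak"), beta = TRUE) {
  normalize <- match.arg(normalize)
  if (lambda_max < min(wl) || lambda_max > max(wl)) {
    stop("lambda_max outside wavelength grid")
  }
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    bwd <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((wl - lmb) / bwd)^2)
  }
  s <- s / max(s)
  if (normalize == "area") s <- s / sum(s)
  s
}

#' Construct a visual system
#'
#' Bundles the chromatic receptor sensitivity curves (3 or 4 channels, from
#' pigment templates or user-supplied curves), relative cone abundances, and
#' the receptor-noise parameters. The noise of channel i follows the neural
#' (abundance-scaled) model
#' \deqn{e_i = \omega_{ref} \sqrt{\eta_{ref} / \eta_i}}
#' where the reference channel is the long-wavelength (last) cone, so
#' \eqn{e_{ref} = \omega_{ref}} exactly. The achromatic channel defaults to
#' the LW sensitivity curve with its own Weber fraction.
#'
#' @param name system label.
#' @param lambda_max named numeric vector of peak sensitivities in nm,
#'   strictly increasing, length 3 or 4 (e.g. `c(uv=367, sw=456, mw=497,
#'   lw=562)`).
#' @param eta relative cone abundances, same length as `lambda_max`.
#' @param weber_ref Weber fraction of the reference (last, LW) channel.
#' @param achromatic list with `channel` (name of the sensitivity curve used
#'   for luminance) and `weber` (its Weber fraction); defaults to the LW
#'   channel at `weber_ref`.
#' @param wl wavelength grid.
#' @param sensitivities optional matrix (length(wl) x channels) of custom
#'   curves overriding the templates; columns are area-normalized.
#' @return object of class `visual_system` with elements `S` (area-normalized
#'   curve matrix), `e` (noise vector), `achro` (achromatic curve),
#'   `weber_achro`, and the constructor inputs.
#' @export
visual_system <- function(name, lambda_max, eta, weber_ref,
                          achromatic = NULL, wl = 300:700,
                          sensitivities = NULL) {
  k <- length(lambda_max)
  if (!k %in% c(3L, 4L)) stop("need 3 or 4 chromatic channels, got ", k)
  if (length(eta) != k) stop("`eta` length must match `lambda_max`")
  if (is.unsorted(lambda_max, strictly = TRUE)) {
    stop("`lambda_max` must be strictly increasing")
  }
  if (any(eta <= 0) || weber_ref <= 0) stop("`eta` and `weber_ref` must be > 0")
  chan <- names(lambda_max)
  if (is.null(chan)) {
    chan <- c("uv", "sw", "mw", "lw")[if (k == 4) 1:4 else c(1, 2, 4)]
    names(lambda_max) <- chan
  }
  if (is.null(sensitivities)) {
    S <- vapply(lambda_max, pigment_template, numeric(length(wl)), wl = wl)
  } else {
    if (nrow(sensitivities) != length(wl) || ncol(sensitivities) != k) {
      stop("custom sensitivity matrix does not match grid/channel count")
    }
    S <- sweep(as.matrix(sensitivities), 2, colSums(sensitivities), "/")
  }
  colnames(S) <- chan
  e <- weber_ref * sqrt(eta[k] / eta)
  names(e) <- chan
  if (is.null(achromatic)) {
    achromatic <- list(channel = chan[k], weber = weber_ref)
  }
  if (!achromatic$channel %in% chan) {
    stop("unknown achromatic channel '", achromatic$channel, "'")
  }
  structure(list(name = name, wl = wl, lambda_max = lambda_max,
                 eta = stats::setNames(eta, chan), weber_ref = weber_ref,
                 S = S, e = e,
                 achro = S[, achromatic$channel],
                 achro_channel = achromatic$channel,
                 weber_achro = achromatic$weber),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system '%s': %d chromatic channels>\n",
              x$name, ncol(x$S)))
  cat("  lambda_max:", paste(sprintf("%s=%g", names(x$lambda_max),
                                     x$lambda_max), collapse = " "), "\n")
  cat("  eta:", paste(x$eta, collapse = ":"),
      " weber_ref:", x$weber_ref, "\n")
  cat("  noise e:", paste(sprintf("%.4f", x$e), collapse = " "), "\n")
  cat(sprintf("  achromatic: %s channel, weber %g\n",
              x$achro_channel, x$weber_achro))
  invisible(x)
}

#' Load a visual system from a YAML config
#'
#' Config fields: `name`, `lambda_max` (map channel -> nm), `eta` (map
#' channel -> abundance), `weber_ref`, `achromatic: {channel, weber}`, and
#' optionally `sensitivity_csv` (a `wl` + one-column-per-channel CSV
#' overriding the pigment templates). The three study systems ship as
#' editable configs under `system.file("extdata/vision", package =
#' "morphvision")`.
#'
#' @param source path to a YAML file, or one of the built-in names
#'   `"lizard"`, `"bird"`, `"snake"`.
#' @param wl wavelength grid.
#' @export
load_visual_system <- function(source, wl = 300:700) {
  if (source %in% c("lizard", "bird", "snake")) {
    source <- system.file("extdata", "vision", paste0(source, ".yaml"),
                          package = "morphvision", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(source)
  lam <- unlist(cfg$lambda_max)
  eta <- unlist(cfg$eta)[names(lam)]
  sens <- NULL
  if (!is.null(cfg$sensitivity_csv)) {
    tab <- utils::read.csv(cfg$sensitivity_csv)
    if (min(tab$wl) > min(wl) || max(tab$wl) < max(wl)) {
      stop("custom sensitivity file does not cover the grid")
    }
    sens <- vapply(names(lam), function(ch) {
      stats::approx(tab$wl, tab[[ch]], xout = wl)$y
    }, numeric(length(wl)))
  }
  visual_system(name = cfg$name, lambda_max = lam, eta = eta,
                weber_ref = cfg$weber_ref,
                achromatic = cfg$achromatic, wl = wl,
                sensitivities = sens)
}
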