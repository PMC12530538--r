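#' Quantum catches under a visual system and illuminant
#'
#' The catch of receptor class i for a spectrum R is the unit-step Riemann
#' sum \eqn{Q_i = \sum_\lambda R(\lambda) I(\lambda) S_i(\lambda)} over the
#' 1-nm grid, for each chromatic channel and the achromatic channel; log
#' catches are \eqn{f_i = \ln Q_i}. Relative catches
#' \eqn{q_i = Q_i / \sum_j Q_j} feed the tetrahedral colorspace.
#'
#' @param ds processed `reflectance_spectra`, one column per individual, on
#'   the same grid as `vs` and `ill`.
#' @param vs a `visual_system`.
#' @param ill an `illuminant`.
#' @return object of class `catch_table`: list with `ids`, matrices `Q`,
#'   `f`, `qrel` (individuals x channels), vectors `achro_Q`, `achro_f`,
#'   the noise vector `e`, `weber_achro`, and provenance (`vs`, `ill`).
#' @export
quantum_catches <- function(ds, vs, ill) {
  if (!identical(as.numeric(ds$wl), as.numeric(vs$wl)) ||
      !identical(as.numeric(ds$wl), as.numeric(ill$wl))) {
    stop("spectra, visual system and illuminant must share one grid")
  }
  R <- spectra_matrix(ds)
  W <- vs$S * ill$irradiance          # recycles I down each channel column
  Q <- t(R) %*% W                     # individuals x channels
  achro_Q <- drop(t(R) %*% (vs$achro * ill$irradiance))
  bad <- which(Q <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("zero quantum catch for individual '%s', channel '%s'",
                 rownames(Q)[bad[1, 1]], colnames(Q)[bad[1, 2]]))
  }
  if (any(achro_Q <= 0)) {
    stop("zero achromatic quantum catch for individual '",
         names(ds)[-1][which(achro_Q <= 0)[1]], "'")
  }
  structure(list(ids = names(ds)[-1],
                 Q = Q, f = log(Q), qrel = Q / rowSums(Q),
                 achro_Q = achro_Q, achro_f = log(achro_Q),
                 e = vs$e, weber_achro = vs$weber_achro,
                 vs = vs$name, ill = ill$name),
            class = "catch_table")
}

#' @export
print.catch_table <- function(x, ...) {
  cat(sprintf("<catch_table: %d individuals x %d channels (+achro), %s / %s>\n",
              length(x$ids), ncol(x$Q), x$vs, x$ill))
  invisible(x)
}

# Receptor-noise quadratic form: Delta S^2 = df' M df with
# M = sum_{i<j} w_ij (u_i - u_j)(u_i - u_j)' / D,
# w_ij = (prod_{k != i,j} e_k)^2, D = sum_i (prod_{k != i} e_k)^2.
rnl_metric <- function(e) {
  k <- length(e)
  M <- matrix(0, k, k)
  D <- 0
  for (i in seq_len(k)) D <- D + prod(e[-i])^2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      w <- if (k > 2) prod(e[-c(i, j)])^2 else 1
      u <- numeric(k); u[i] <- 1; u[j] <- -1
      M <- M + w * tcrossprod(u)
    }
  }
  M / D
}

rnl_generic <- function(df, e) {
  sqrt(max(0, drop(t(df) %*% rnl_metric(e) %*% df)))
}

rnl_tetra <- function(df, e) {
  n <- e[1]^2 * e[2]^2 * (df[4] - df[3])^2 +
       e[1]^2 * e[3]^2 * (df[4] - df[2])^2 +
       e[1]^2 * e[4]^2 * (df[3] - df[2])^2 +
       e[2]^2 * e[3]^2 * (df[4] - df[1])^2 +
       e[2]^2 * e[4]^2 * (df[3] - df[1])^2 +
       e[3]^2 * e[4]^2 * (df[2] - df[1])^2
  d <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
       (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(n / d)
}

#' Receptor-noise-limited chromatic distance (JND)
#'
#' Perceptual distance between two stimuli from their log quantum catches
#' under the receptor-noise-limited model. For tetrachromats the standard
#' closed form is used; any other channel count routes through the generic
#' n-chromatic quadratic form (for a dichromat this reduces to
#' \eqn{|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}}).
#'
#' @param fa,fb log quantum catch vectors of the two stimuli (same visual
#'   system and illuminant).
#' @param vs the `visual_system` (supplies the noise vector), or a bare
#'   numeric noise vector `e`.
#' @param method `"auto"` picks the tetrachromat closed form when there are
#'   4 channels; `"closed"` and `"generic"` force one evaluator (used for
#'   cross-validation).
#' @return distance in JND units (>= 0).
#' @export
chromatic_distance <- function(fa, fb, vs,
                               method = c("auto", "closed", "generic")) {
  method <- match.arg(method)
  e <- if (inherits(vs, "visual_system")) vs$e else vs
  if (length(fa) != length(e) || length(fb) != length(e)) {
    stop("catch vectors and noise vector must have equal length")
  }
  df <- unname(fa - fb)
  e <- unname(e)
  if (method == "closed" || (method == "auto" && length(e) == 4)) {
    if (length(e) != 4) stop("closed form requires 4 channels")
    rnl_tetra(df, e)
  } else {
    rnl_generic(df, e)
  }
}

#' Receptor-noise-limited achromatic distance (JND)
#'
#' \eqn{\Delta L = |f_A(a) - f_A(b)| / \omega_A}: the absolute difference of
#' log achromatic catches scaled by the achromatic Weber fraction.
#'
#' @param fa,fb scalar log achromatic catches.
#' @param vs the `visual_system`, or a bare achromatic Weber fraction.
#' @export
achromatic_distance <- function(fa, fb, vs) {
  w <- if (inherits(vs, "visual_system")) vs$weber_achro else vs
  unname(abs(fa - fb) / w)
}

#' All pairwise JND distance matrices
#'
#' Symmetric zero-diagonal matrices of chromatic (dS) and achromatic (dL)
#' distances between every pair of individuals in a catch table, computed
#' via the quadratic-form representation of the receptor-noise model.
#'
#' @param ct a `catch_table`.
#' @return list with matrices `dS` and `dL` (ids as dimnames) and
#'   provenance `vs`, `ill`.
#' @export
pairwise_distance_matrices <- function(ct) {
  n <- length(ct$ids)
  if (n < 2) stop("need at least 2 individuals")
  M <- rnl_metric(ct$e)
  G <- ct$f %*% M %*% t(ct$f)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  d2[d2 < 0] <- 0
  dS <- sqrt(d2)
  dL <- abs(outer(ct$achro_f, ct$achro_f, "-")) / ct$weber_achro
  dimnames(dS) <- dimnames(dL) <- list(ct$ids, ct$ids)
  diag(dS) <- diag(dL) <- 0
  list(dS = dS, dL = dL, vs = ct$vs, ill = ct$ill)
}

# Tetrahedron vertices (rows: uv apex, then the three base cones), centroid
# at the origin, apex at z = 0.75.
tetra_vertices <- function() {
  rbind(uv = c(0, 0, 0.75),
        sw = c(-sqrt(6) / 4, -sqrt(2) / 4, -0.25),
        mw = c(sqrt(6) / 4, -sqrt(2) / 4, -0.25),
        lw = c(0, sqrt(2) / 2, -0.25))
}

#' Tetrahedral colorspace coordinates
#'
#' Maps each individual's relative quantum catches (UV, SW, MW, LW) to the
#' point inside the standard colour tetrahedron given by the convex
#' combination of its four vertices (UV apex at (0, 0, 0.75), the other
#' cones on the base plane z = -0.25). Equal stimulation of all four cones
#' maps to the achromatic origin.
#'
#' @param ct a `catch_table` from a tetrachromatic visual system.
#' @return matrix (individuals x 3) of x, y, z coordinates.
#' @export
tetra_coordinates <- function(ct) {
  if (ncol(ct$qrel) != 4) {
    stop("tetrahedral coordinates require a tetrachromatic visual system")
  }
  xyz <- ct$qrel %*% tetra_vertices()
  rownames(xyz) <- ct$ids
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
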