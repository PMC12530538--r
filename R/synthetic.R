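#' Morph reflectance profile
#'
#' Parametric description of one throat colour morph's reflectance:
#' a baseline level plus a logistic cut-on (reflectance rising from baseline
#' to baseline + amplitude around `cuton_nm`), an optional Gaussian UV spike
#' near 370 nm carried by a random subset of individuals, between-individual
#' variation of the cut-on position and amplitude, and within-individual
#' replicate noise.
#'
#' @param name morph name.
#' @param baseline baseline percent reflectance.
#' @param amplitude cut-on amplitude (percent reflectance).
#' @param cuton_nm cut-on centre (nm, inside 300-700).
#' @param steepness logistic scale of the cut-on (nm); larger = shallower.
#' @param uv_prob probability that an individual carries the UV spike.
#' @param uv_center,uv_width,uv_height Gaussian UV spike parameters (nm, nm,
#'   percent reflectance).
#' @param noise_sd replicate (within-individual) noise sd (percent
#'   reflectance).
#' @param cuton_sd,amplitude_sd between-individual sds of cut-on centre and
#'   amplitude.
#' @export
morph_profile <- function(name, baseline, amplitude, cuton_nm, steepness,
                          uv_prob = 0, uv_center = 370, uv_width = 12,
                          uv_height = 0, noise_sd = 1.5, cuton_sd = 6,
                          amplitude_sd = 5) {
  stopifnot(uv_prob >= 0, uv_prob <= 1, uv_width > 0, noise_sd >= 0,
            cuton_sd >= 0, amplitude_sd >= 0, steepness > 0,
            cuton_nm >= 300, cuton_nm <= 700)
  structure(list(name = name, baseline = baseline, amplitude = amplitude,
                 cuton_nm = cuton_nm, steepness = steepness,
                 uv_prob = uv_prob, uv_center = uv_center,
                 uv_width = uv_width, uv_height = uv_height,
                 noise_sd = noise_sd, cuton_sd = cuton_sd,
                 amplitude_sd = amplitude_sd),
            class = "morph_profile")
}

default_morph_profiles <- function() {
  list(
    # long-wavelength cut-on around 543 nm, strong spectral contrast;
    # a small fraction of individuals carries the 370-nm UV spike
    orange = morph_profile("orange", baseline = 10, amplitude = 75,
                           cuton_nm = 543, steepness = 10,
                           uv_prob = 0.09, uv_height = 12),
    # high, flatter reflectance rising from the UV with a shallow mid point
    # near 410 nm; UV spike common
    white = morph_profile("white", baseline = 10, amplitude = 55,
                          cuton_nm = 411, steepness = 25,
                          uv_prob = 0.40, uv_height = 15),
    # intermediate cut-on near 502 nm
    yellow = morph_profile("yellow", baseline = 10, amplitude = 70,
                           cuton_nm = 502, steepness = 12)
  )
}

#' Generate one individual's replicate spectra
#'
#' Draws the individual's latent spectrum (logistic cut-on with
#' individual-specific centre and amplitude, plus a Bernoulli UV spike) and
#' adds iid Gaussian replicate noise, clipping at zero.
#'
#' @param profile a `morph_profile`.
#' @param replicates number of replicate measurements.
#' @param wl wavelength grid.
#' @param seed RNG seed for this individual.
#' @return matrix (length(wl) x replicates) of percent reflectance.
#' @export
generate_individual <- function(profile, replicates = 6, wl = 300:700,
                                seed = 1) {
  with_local_seed(seed, {
    centre <- stats::rnorm(1, profile$cuton_nm, profile$cuton_sd)
    amp <- max(0, stats::rnorm(1, profile$amplitude, profile$amplitude_sd))
    has_uv <- stats::runif(1) < profile$uv_prob
    latent <- profile$baseline +
      amp / (1 + exp(-(wl - centre) / profile$steepness))
    if (has_uv) {
      latent <- latent +
        profile$uv_height * exp(-((wl - profile$uv_center) /
                                    profile$uv_width)^2)
    }
    reps <- latent + matrix(stats::rnorm(length(wl) * replicates,
                                         sd = profile$noise_sd),
                            nrow = length(wl))
    reps[reps < 0] <- 0
    attr(reps, "has_uv_spike") <- has_uv
    reps
  })
}

#' Study configuration for the synthetic generator
#'
#' @param group_sizes named integer vector of individuals per morph x sex
#'   slot, names `<morph>.<sex>` (e.g. `orange.M`).
#' @param replicates replicate measurements per individual (default 6).
#' @param wl wavelength grid.
#' @param seed master seed; all per-individual seeds derive from it, so
#'   draws are order-independent.
#' @param profiles named list of `morph_profile`s covering every morph in
#'   `group_sizes`.
#' @export
study_config <- function(group_sizes, replicates = 6, wl = 300:700,
                         seed = 2017, profiles = default_morph_profiles()) {
  stopifnot(all(group_sizes >= 0), replicates >= 1)
  morphs <- unique(sub("\\..*$", "", names(group_sizes)))
  missing <- setdiff(morphs, names(profiles))
  if (length(missing)) stop("no profile for morph(s): ",
                            paste(missing, collapse = ", "))
  structure(list(group_sizes = group_sizes, replicates = replicates,
                 wl = wl, seed = seed, profiles = profiles),
            class = "study_config")
}

#' Default synthetic study configuration
#'
#' Emulates the structure of the lizard throat colour study: 102
#' individuals (orange 23M/22F, white 13M/12F, yellow 16M/16F), six
#' replicate spectra each on the 300-700 nm grid, with morph profiles tuned
#' so group-mean hues land near 543 nm (orange), 410 nm (white) and 502 nm
#' (yellow), white spectra bright and low-chroma, and a 370-nm UV spike in
#' a subset of white and orange individuals.
#'
#' @param seed master seed (default 2017).
#' @export
default_study_config <- function(seed = 2017) {
  study_config(group_sizes = c(orange.M = 23L, orange.F = 22L,
                               white.M = 13L, white.F = 12L,
                               yellow.M = 16L, yellow.F = 16L),
               replicates = 6, seed = seed)
}

# Deterministic, order-independent per-individual seed below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647)
}

#' Generate a morph-structured spectral dataset
#'
#' One individual per configured slot; replicate columns are named
#' `<individual>_<replicate>`, metadata rows match the individuals.
#'
#' @param cfg a `study_config`.
#' @return list with `spectra` (a `reflectance_spectra` data.frame) and
#'   `metadata` (a `sample_metadata` data.frame).
#' @export
generate_dataset <- function(cfg) {
  wl <- cfg$wl
  cols <- list()
  meta <- list()
  idx <- 0L
  for (slot in names(cfg$group_sizes)) {
    parts <- strsplit(slot, ".", fixed = TRUE)[[1]]
    morph <- parts[1]; sex <- parts[2]
    n <- cfg$group_sizes[[slot]]
    if (n == 0) next
    for (i in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%s_%02d", morph, sex, i)
      reps <- generate_individual(cfg$profiles[[morph]],
                                  replicates = cfg$replicates, wl = wl,
                                  seed = derive_seed(cfg$seed, idx))
      colnames(reps) <- paste(id, seq_len(cfg$replicates), sep = "_")
      cols[[id]] <- reps
      meta[[id]] <- data.frame(individual_id = id, morph = morph, sex = sex)
    }
  }
  if (length(cols) == 0) {
    return(list(spectra = as_spectra(data.frame(wl = wl)),
                metadata = as_metadata(data.frame(
                  individual_id = character(), morph = character(),
                  sex = character()))))
  }
  spectra <- data.frame(wl = wl, do.call(cbind, unname(cols)),
                        check.names = FALSE)
  list(spectra = as_spectra(spectra),
       metadata = as_metadata(do.call(rbind, unname(meta))))
}
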