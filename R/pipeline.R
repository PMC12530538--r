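#' Configuration for a full analysis run
#'
#' @param spectra,metadata input CSV paths (wide spectra + sample
#'   metadata), or `NULL` with `simulate = TRUE` to analyse a synthetic
#'   dataset.
#' @param simulate generate the input data with [generate_dataset()].
#' @param study_cfg `study_config` used when simulating (default
#'   [default_study_config()] reseeded from `seed`).
#' @param systems character vector of visual-system sources (built-in names
#'   or YAML paths).
#' @param illuminants character vector of illuminant sources (built-in
#'   names or CSV paths).
#' @param lo,hi,span,order,negatives processing options, see
#'   [process_spectra()].
#' @param n_perm PERMANOVA permutations (default 999).
#' @param B bootstrap replicates (default 1000).
#' @param seed master seed; stage seeds are derived from it.
#' @export
analysis_config <- function(spectra = NULL, metadata = NULL,
                            simulate = is.null(spectra),
                            study_cfg = NULL,
                            systems = c("lizard", "bird", "snake"),
                            illuminants = c("d65", "forestshade"),
                            lo = 300, hi = 700, span = 0.2,
                            order = "aggregate_then_smooth",
                            negatives = "error",
                            n_perm = 999, B = 1000, seed = 2017) {
  stopifnot(n_perm >= 1, B >= 1)
  if (!simulate) {
    for (p in c(spectra, metadata)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }
  if (simulate && is.null(study_cfg)) {
    study_cfg <- default_study_config(seed = seed)
  }
  structure(list(spectra = spectra, metadata = metadata, simulate = simulate,
                 study_cfg = study_cfg, systems = systems,
                 illuminants = illuminants, lo = lo, hi = hi, span = span,
                 order = order, negatives = negatives,
                 n_perm = n_perm, B = B, seed = seed),
            class = "analysis_config")
}

#' Run the full visual-ecology analysis
#'
#' Processes the spectra, computes the colorimetric summary, then for every
#' visual system x illuminant combination: quantum catches, tetrahedral
#' coordinates (tetrachromats), pairwise JND distance matrices, bootstrap
#' group distances, pairwise PERMANOVAs on the chromatic and achromatic
#' distance matrices, and the dispersion check. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg an [analysis_config()].
#' @return list of class `result_bundle`: `colorimetrics` (group table),
#'   `colorimetrics_individual`, `models` (one entry per system x
#'   illuminant with `catches`, `coords`, `distances`, `boot`, `permanova`
#'   = list(chromatic, achromatic), `dispersion`), and `log` (seeds,
#'   settings, package version).
#' @export
run_full_analysis <- function(cfg = analysis_config()) {
  if (cfg$simulate) {
    sim <- generate_dataset(cfg$study_cfg)
    raw <- sim$spectra
    meta <- sim$metadata
  } else {
    raw <- read_spectra(cfg$spectra)
    meta <- read_metadata(cfg$metadata)
  }
  proc <- process_spectra(raw, meta, lo = cfg$lo, hi = cfg$hi,
                          span = cfg$span, order = cfg$order,
                          negatives = cfg$negatives)
  groups <- summarize_groups(proc, meta)
  indiv <- colorimetric_summary(proc)
  models <- list()
  k <- 0L
  for (sy in cfg$systems) {
    vs <- load_visual_system(sy, wl = cfg$lo:cfg$hi)
    for (il in cfg$illuminants) {
      k <- k + 1L
      ill <- load_illuminant(il, wl = cfg$lo:cfg$hi)
      key <- paste(vs$name, ill$name, sep = ".")
      ct <- quantum_catches(proc, vs, ill)
      dm <- pairwise_distance_matrices(ct)
      labels <- meta$morph[match(ct$ids, meta$individual_id)]
      boot <- boot_group_distance(ct, meta, B = cfg$B,
                                  seed = derive_seed(cfg$seed, 100 + k))
      perm_S <- pairwise_permanova(dm$dS, labels, n_perm = cfg$n_perm,
                                   seed = derive_seed(cfg$seed, 200 + k))
      perm_L <- pairwise_permanova(dm$dL, labels, n_perm = cfg$n_perm,
                                   seed = derive_seed(cfg$seed, 300 + k))
      disp_S <- dispersion_test(dm$dS, labels, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, 400 + k))
      models[[key]] <- list(
        system = vs$name, illuminant = ill$name,
        catches = ct,
        coords = if (ncol(ct$qrel) == 4) tetra_coordinates(ct) else NULL,
        distances = dm,
        boot = boot,
        permanova = list(chromatic = perm_S, achromatic = perm_L),
        dispersion = disp_S)
    }
  }
  structure(list(colorimetrics = groups,
                 colorimetrics_individual = indiv,
                 processed = proc, metadata = meta,
                 models = models,
                 log = list(seed = cfg$seed, n_perm = cfg$n_perm, B = cfg$B,
                            span = cfg$span, order = cfg$order,
                            systems = cfg$systems,
                            illuminants = cfg$illuminants,
                            simulated = cfg$simulate,
                            package_version =
                              as.character(utils::packageVersion("morphvision")))),
            class = "result_bundle")
}

#' Flatten a result bundle into reporting tables
#'
#' @param bundle a `result_bundle`.
#' @return list of data.frames: `colorimetrics` (morph x sex table),
#'   `permanova` (System/Illum/Channel/Comparison rows with df, SS, F,
#'   p_adj, R2) and `boot` (pair/channel/illuminant point + CI rows).
#' @export
bundle_tables <- function(bundle) {
  perm <- list(); boot <- list()
  for (m in bundle$models) {
    for (ch in c("chromatic", "achromatic")) {
      tab <- m$permanova[[ch]]
      perm[[length(perm) + 1L]] <-
        data.frame(system = m$system, illuminant = m$illuminant,
                   channel = ch, tab)
    }
    boot[[length(boot) + 1L]] <-
      data.frame(system = m$system, illuminant = m$illuminant, m$boot)
  }
  list(colorimetrics = bundle$colorimetrics,
       permanova = do.call(rbind, perm),
       boot = do.call(rbind, boot))
}

#' Write a result bundle to CSV files
#'
#' Emits `colorimetrics.csv`, `permanova.csv`, `boot_distances.csv`, the
#' per-model distance matrices and catch tables, and a `run_log.yaml`
#' sufficient to reproduce the run.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- bundle_tables(bundle)
  utils::write.csv(tabs$colorimetrics, file.path(dir, "colorimetrics.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$permanova, file.path(dir, "permanova.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$boot, file.path(dir, "boot_distances.csv"),
                   row.names = FALSE)
  for (key in names(bundle$models)) {
    m <- bundle$models[[key]]
    utils::write.csv(data.frame(individual_id = m$catches$ids,
                                m$catches$Q,
                                achro = m$catches$achro_Q),
                     file.path(dir, paste0("catches_", key, ".csv")),
                     row.names = FALSE)
    utils::write.csv(m$distances$dS,
                     file.path(dir, paste0("dS_", key, ".csv")))
    utils::write.csv(m$distances$dL,
                     file.path(dir, paste0("dL_", key, ".csv")))
  }
  yaml::write_yaml(bundle$log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' Re-run the published study design on deposited data
#'
#' Convenience wrapper applying the published processing settings (300-700
#' nm, replicate averaging before smoothing, span 0.2, negative-value check)
#' and the full 3-system x 2-illuminant model grid to a deposited wide
#' spectra CSV and metadata table, e.g. the study's archived supplementary
#' data.
#'
#' @param spectra_path wide reflectance CSV (wl + `<individual>_<replicate>`
#'   columns).
#' @param metadata_path metadata CSV (individual_id, morph, sex).
#' @param n_perm,B,seed inference settings.
#' @return a `result_bundle`.
#' @export
replicate_study <- function(spectra_path, metadata_path,
                            n_perm = 999, B = 1000, seed = 2017) {
  run_full_analysis(analysis_config(spectra = spectra_path,
                                    metadata = metadata_path,
                                    simulate = FALSE,
                                    n_perm = n_perm, B = B, seed = seed))
}
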