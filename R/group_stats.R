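# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Bootstrap confidence intervals for group colour distances
#'
#' Point estimate: the chromatic (and achromatic) JND distance between the
#' centroids of two groups, a centroid being the per-channel arithmetic mean
#' of log quantum catches over the group's individuals. Each bootstrap
#' replicate resamples individuals with replacement within each group,
#' recomputes the centroids and their distance; the confidence interval is
#' the 2.5/97.5 percentile over `B` replicates.
#'
#' @param ct a `catch_table`.
#' @param meta `sample_metadata` mapping each individual to its group
#'   (morph).
#' @param pairs optional list/character of group pairs (e.g.
#'   `"orange-white"`); default all unordered pairs.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed (mandatory; recorded in the output).
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per pair x channel: `pair`, `channel`
#'   (chromatic/achromatic), `point`, `lo`, `hi`, `B`, `seed`.
#' @export
boot_group_distance <- function(ct, meta, pairs = NULL, B = 1000, seed = 1,
                                level = 0.95) {
  if (B < 1) stop("B must be >= 1")
  groups <- meta$morph[match(ct$ids, meta$individual_id)]
  if (anyNA(groups)) {
    stop("no metadata for individual(s): ",
         paste(utils::head(ct$ids[is.na(groups)], 5), collapse = ", "))
  }
  lev <- sort(unique(groups))
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2, paste, collapse = "-")
  }
  idx_by_group <- lapply(stats::setNames(lev, lev), function(g) {
    which(groups == g)
  })
  small <- names(idx_by_group)[lengths(idx_by_group) < 2]
  if (length(small)) stop("group(s) with fewer than 2 members: ",
                          paste(small, collapse = ", "))
  alpha <- (1 - level) / 2
  with_local_seed(seed, {
    # per-group bootstrap centroid draws, shared across the pairs
    boot_cent <- lapply(idx_by_group, function(idx) {
      f <- ct$f[idx, , drop = FALSE]
      af <- ct$achro_f[idx]
      reps <- matrix(sample(length(idx), length(idx) * B, replace = TRUE),
                     nrow = B)
      list(f = t(apply(reps, 1, function(r) colMeans(f[r, , drop = FALSE]))),
           achro = apply(reps, 1, function(r) mean(af[r])))
    })
    out <- lapply(pairs, function(p) {
      gs <- strsplit(p, "-", fixed = TRUE)[[1]]
      if (length(gs) != 2 || !all(gs %in% lev)) {
        stop("unknown pair label '", p, "'")
      }
      i1 <- idx_by_group[[gs[1]]]; i2 <- idx_by_group[[gs[2]]]
      c1 <- colMeans(ct$f[i1, , drop = FALSE])
      c2 <- colMeans(ct$f[i2, , drop = FALSE])
      pt_S <- chromatic_distance(c1, c2, ct$e)
      pt_L <- achromatic_distance(mean(ct$achro_f[i1]), mean(ct$achro_f[i2]),
                                  ct$weber_achro)
      b1 <- boot_cent[[gs[1]]]; b2 <- boot_cent[[gs[2]]]
      dS <- vapply(seq_len(B), function(b) {
        chromatic_distance(b1$f[b, ], b2$f[b, ], ct$e)
      }, 0)
      dL <- achromatic_distance(b1$achro, b2$achro, ct$weber_achro)
      qS <- stats::quantile(dS, c(alpha, 1 - alpha), names = FALSE)
      qL <- stats::quantile(dL, c(alpha, 1 - alpha), names = FALSE)
      data.frame(pair = p,
                 channel = c("chromatic", "achromatic"),
                 point = unname(c(pt_S, pt_L)),
                 lo = c(qS[1], qL[1]), hi = c(qS[2], qL[2]),
                 B = B, seed = seed, row.names = NULL)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

ss_decomposition <- function(d2, labels) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

permanova_f <- function(ss_between, ss_within, a, n) {
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# All distinct assignments of group labels to positions with the observed
# group sizes; rows are assignments in 1..a integer coding.
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(free, g) {
    if (g == length(sizes)) {
      out <- matrix(0L, 1, n)
      out[1, free] <- g
      return(out)
    }
    picks <- utils::combn(free, sizes[g])
    do.call(rbind, lapply(seq_len(ncol(picks)), function(j) {
      sub <- rec(setdiff(free, picks[, j]), g + 1L)
      sub[, picks[, j]] <- g
      sub
    }))
  }
  rec(seq_len(n), 1L)
}

#' Distance-based PERMANOVA (one-way)
#'
#' Partitions the total sum of squared distances,
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2}, into within-group
#' (\eqn{\sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2}) and between-group
#' components, and tests the pseudo-F
#' \eqn{F = \frac{SS_B/(a-1)}{SS_W/(N-a)}} by free permutation of the group
#' labels, with \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. For small
#' samples `exact = TRUE` replaces Monte-Carlo permutation by enumeration of
#' all distinct label assignments (p = proportion of assignments with
#' \eqn{F^* \ge F}, the observed assignment included).
#'
#' @param d square symmetric nonnegative distance matrix (or `dist`).
#' @param labels group labels, one per row of `d` (>= 2 groups).
#' @param n_perm number of permutations (default 999; ignored when exact).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all assignments instead of sampling.
#' @return list of class `permanova_result`: `df` (between), `df_within`,
#'   `SS` (between), `SS_within`, `SS_total`, `F`, `R2`, `p`, `n_perm`,
#'   `seed`, `method`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1, exact = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(d < 0)) {
    stop("`d` must be a square symmetric nonnegative distance matrix")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) stop("one label per observation required")
  lev <- unique(labels)
  a <- length(lev)
  n <- nrow(d)
  if (a < 2) stop("need at least 2 groups")
  d2 <- d^2
  ss <- ss_decomposition(d2, labels)
  f_obs <- permanova_f(ss["between"], ss["within"], a, n)
  if (exact) {
    sizes <- as.integer(table(factor(labels, levels = lev)))
    if (choose(n, sizes[1]) * n > 1e7) stop("too many assignments to enumerate")
    asg <- enumerate_assignments(sizes)
    f_all <- apply(asg, 1, function(lab) {
      s <- ss_decomposition(d2, lab)
      permanova_f(s["between"], s["within"], a, n)
    })
    p <- mean(f_all >= f_obs - 1e-12)
    n_perm <- nrow(asg)
    method <- "exact"
  } else {
    group_mat <- with_local_seed(seed, {
      replicate(n_perm, sample(labels))
    })
    ssw_perm <- numeric(n_perm)
    for (g in lev) {
      Z <- group_mat == g                       # n x n_perm indicator
      ng <- sum(labels == g)
      ssw_perm <- ssw_perm + colSums((d2 %*% Z) * Z) / (2 * ng)
    }
    f_perm <- permanova_f(ss["total"] - ssw_perm, ssw_perm, a, n)
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    method <- "permutation"
  }
  structure(list(df = a - 1L, df_within = n - a,
                 SS = unname(ss["between"]), SS_within = unname(ss["within"]),
                 SS_total = unname(ss["total"]),
                 F = unname(f_obs), R2 = unname(ss["between"] / ss["total"]),
                 p = p, n_perm = n_perm, seed = seed, method = method),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations): df = %d, SS = %.5g, F = %.4g, R2 = %.4g, p = %.4g\n",
              x$method, x$n_perm, x$df, x$SS, x$F, x$R2, x$p))
  invisible(x)
}

#' Pairwise PERMANOVA with multiplicity adjustment
#'
#' One one-way PERMANOVA per unordered pair of groups, run on the submatrix
#' of those two groups, with Bonferroni adjustment across the pairs
#' (`p_adj = min(1, p * n_pairs)`).
#'
#' @inheritParams permanova
#' @param adjust `"bonferroni"` or `"none"`.
#' @return data.frame, one row per pair: `comparison`, `df`, `SS`, `F`,
#'   `R2`, `p`, `p_adj`, `n_perm`, `seed`.
#' @export
pairwise_permanova <- function(d, labels, adjust = c("bonferroni", "none"),
                               n_perm = 999, seed = 1) {
  adjust <- match.arg(adjust)
  d <- as.matrix(d)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    idx <- labels %in% p
    res <- permanova(d[idx, idx], labels[idx], n_perm = n_perm,
                     seed = seed + k - 1L)
    data.frame(comparison = paste(p, collapse = "-"),
               df = res$df, SS = res$SS, F = res$F, R2 = res$R2,
               p = res$p, n_perm = res$n_perm, seed = res$seed)
  })
  out <- do.call(rbind, rows)
  mult <- if (adjust == "bonferroni") length(pairs) else 1
  out$p_adj <- pmin(1, out$p * mult)
  out
}

#' Multivariate homogeneity of group dispersions
#'
#' Levene-type assumption check for PERMANOVA: the distance matrix is
#' embedded by principal coordinates analysis, each sample's distance to its
#' own group centroid is computed, and group differences in those distances
#' are tested by ANOVA with a permutation p-value. Implemented on top of
#' `vegan::betadisper` (centroid type) and `vegan::permutest`, which apply
#' the standard correction for negative eigenvalues of non-Euclidean
#' distance matrices.
#'
#' @inheritParams permanova
#' @return list of class `dispersion_result`: `F`, `p`, `n_perm`, `seed`,
#'   `group_dispersion` (mean distance-to-centroid per group), and the
#'   underlying `betadisper` object (`fit`).
#' @export
dispersion_test <- function(d, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  if (all(d == 0)) stop("all-zero distance matrix")
  bd <- vegan::betadisper(stats::as.dist(d), group = as.factor(labels),
                          type = "centroid")
  pt <- with_local_seed(seed, {
    vegan::permutest(bd, permutations = n_perm)
  })
  tab <- pt$tab
  structure(list(F = tab$F[1], p = tab[1, "Pr(>F)"],
                 n_perm = n_perm, seed = seed,
                 group_dispersion = tapply(bd$distances, bd$group, mean),
                 fit = bd),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion test (%d permutations): F = %.4g, p = %.4g\n",
              x$n_perm, x$F, x$p))
  print(round(x$group_dispersion, 4))
  invisible(x)
}
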