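# Statistical non-parametric mapping over the gait-cycle axis.
#
# At each of the 100 gait-phase points a classical two-way mixed-design
# ANOVA is computed (group O/T between subjects, condition sSC/SC within).
# Family-wise inference over the continuum uses the permutation
# distribution of the maximum F across the 100 points: the critical
# threshold F* is its (1-alpha) quantile, suprathreshold clusters get
# p-values from the permutation distribution of the maximum cluster
# extent, and post hoc pairwise contrasts use max-|t| permutation tests
# with Bonferroni correction.
#
# Permutation schemes respect exchangeability under each null:
#   group       - permute group labels across subjects (subjects whole)
#   condition   - swap the two condition labels independently per subject
#   interaction - condition swaps composed with group-label permutation
#                 (the standard, approximate scheme for mixed designs)

#' Construct a one-electrode mixed-design dataset
#'
#' @param data numeric array subjects x 2 conditions x timepoints
#'   (condition order sSC, SC)
#' @param group per-subject group labels, `"O"` or `"T"`
#' @param electrode optional electrode label carried along
#' @return object of class `snpm_design`
#' @export
snpm_design <- function(data, group, electrode = NA_character_) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == 2,
            dim(data)[1] == length(group))
  group <- as.character(group)
  stopifnot(all(group %in% c("O", "T")))
  if (min(table(factor(group, levels = c("O", "T")))) < 2) {
    stop("need at least 2 subjects per group")
  }
  structure(list(data = data, group = group, electrode = electrode,
                 n_subjects = dim(data)[1], n_points = dim(data)[3]),
            class = "snpm_design")
}

# sufficient pieces for the vectorized mixed ANOVA: per-subject
# condition sums/differences as subjects x timepoints matrices
design_parts <- function(design) {
  y1 <- design$data[, 1, , drop = FALSE]; dim(y1) <- dim(design$data)[c(1, 3)]
  y2 <- design$data[, 2, , drop = FALSE]; dim(y2) <- dim(design$data)[c(1, 3)]
  list(m = (y1 + y2) / 2, d = y1 - y2,
       gT = design$group == "T", n = design$n_subjects)
}

# core F computation given group-T membership (logical) and optional
# per-subject condition sign flips; m, d are subjects x T matrices
mixed_anova_F <- function(m, d, gT, flip = NULL) {
  n <- nrow(d); nT <- sum(gT); nO <- n - nT
  if (!is.null(flip)) d <- d * flip
  q_d <- colSums(d^2)
  sT <- colSums(d[gT, , drop = FALSE]); sO <- colSums(d[!gT, , drop = FALSE])
  dbT <- sT / nT; dbO <- sO / nO; db <- (sT + sO) / n
  ss_cond <- n * db^2 / 2
  ss_int <- (nT * (dbT - db)^2 + nO * (dbO - db)^2) / 2
  ss_err <- (q_d - nT * dbT^2 - nO * dbO^2) / 2

  q_m <- colSums(m^2)
  mT <- colSums(m[gT, , drop = FALSE]) / nT
  mO <- colSums(m[!gT, , drop = FALSE]) / nO
  mb <- (mT * nT + mO * nO) / n
  ss_group <- 2 * (nT * (mT - mb)^2 + nO * (mO - mb)^2)
  ss_subj <- 2 * (q_m - nT * mT^2 - nO * mO^2)

  df_err <- n - 2
  list(F_group = ss_group / (ss_subj / df_err),
       F_condition = ss_cond / (ss_err / df_err),
       F_interaction = ss_int / (ss_err / df_err),
       df = list(group = c(1, df_err), condition = c(1, df_err),
                 interaction = c(1, df_err)),
       ss = list(group = ss_group, subj = ss_subj, cond = ss_cond,
                 int = ss_int, err = ss_err))
}

#' Per-timepoint mixed-ANOVA F curves
#'
#' Classical 2 (group, between) x 2 (condition, within) mixed-design
#' ANOVA at each gait-phase point. The group effect is tested against the
#' subject-within-group mean square; condition and interaction against the
#' condition-by-subject-within-group mean square. Zero-variance
#' denominators yield `Inf` (nonzero numerator) or `NaN` (0/0) and are
#' flagged.
#'
#' @param design an [snpm_design()]
#' @return list with `F_group`, `F_condition`, `F_interaction` (length-T
#'   curves), `df` (numerator/denominator degrees of freedom) and
#'   `degenerate` (logical per timepoint: any non-finite F)
#' @export
anova_curves <- function(design) {
  p <- design_parts(design)
  res <- mixed_anova_F(p$m, p$d, p$gT)
  res$degenerate <- !is.finite(res$F_group) | !is.finite(res$F_condition) |
    !is.finite(res$F_interaction)
  res
}

# number of distinct permutations for each scheme
n_distinct_perms <- function(n, nT, effect) {
  switch(effect,
         group = choose(n, nT),
         condition = 2^n,
         interaction = 2^n * choose(n, nT))
}

# build the permutation ensemble: list with flip (P x n, +/-1 or NULL) and
# gT (P x n logical); row 1 is always the identity permutation
build_permutations <- function(n, gT_obs, effect, n_perm, seed,
                               force_monte_carlo = FALSE) {
  nT <- sum(gT_obs)
  n_exact <- n_distinct_perms(n, nT, effect)
  exhaustive <- !force_monte_carlo && is.finite(n_exact) && n_exact <= n_perm

  all_signs <- function(n) {
    g <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(g) <- NULL
    g
  }
  all_groupings <- function(n, nT) {
    sel <- utils::combn(n, nT)
    t(apply(sel, 2, function(ix) { v <- rep(FALSE, n); v[ix] <- TRUE; v }))
  }

  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  if (effect == "group") {
    if (exhaustive) {
      gT <- all_groupings(n, nT)
      # put the observed grouping first
      obs <- which(apply(gT, 1, function(r) all(r == gT_obs)))
      gT <- rbind(gT[obs, ], gT[-obs, , drop = FALSE])
    } else {
      gT <- matrix(FALSE, n_perm, n)
      gT[1, ] <- gT_obs
      for (i in 2:n_perm) gT[i, sample.int(n, nT)] <- TRUE
    }
    flip <- NULL
  } else if (effect == "condition") {
    if (exhaustive) {
      flip <- all_signs(n)
      obs <- which(apply(flip, 1, function(r) all(r == 1)))
      flip <- rbind(flip[obs, ], flip[-obs, , drop = FALSE])
    } else {
      flip <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
      flip[1, ] <- 1
    }
    gT <- matrix(rep(gT_obs, each = nrow(flip)), nrow(flip), n)
  } else { # interaction
    if (exhaustive) {
      signs <- all_signs(n)
      groups <- all_groupings(n, nT)
      flip <- signs[rep(seq_len(nrow(signs)), times = nrow(groups)), ,
                    drop = FALSE]
      gT <- groups[rep(seq_len(nrow(groups)), each = nrow(signs)), ,
                   drop = FALSE]
      obs <- which(apply(flip, 1, function(r) all(r == 1)) &
                     apply(gT, 1, function(r) all(r == gT_obs)))[1]
      keep <- c(obs, setdiff(seq_len(nrow(flip)), obs))
      flip <- flip[keep, , drop = FALSE]; gT <- gT[keep, , drop = FALSE]
    } else {
      flip <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
      flip[1, ] <- 1
      gT <- matrix(FALSE, n_perm, n)
      gT[1, ] <- gT_obs
      for (i in 2:n_perm) gT[i, sample.int(n, nT)] <- TRUE
    }
  }
  list(flip = flip, gT = gT, exhaustive = exhaustive,
       n_perm = nrow(gT))
}

# batched permutation F curves (P x T matrix) for one effect.
# Uses indicator-matrix multiplications so the whole ensemble is a handful
# of BLAS calls rather than a loop over permutations.
perm_F_matrix <- function(m, d, perms, effect) {
  n <- nrow(d); P <- perms$n_perm
  gT <- perms$gT
  nT <- rowSums(gT); nO <- n - nT
  if (effect == "group") {
    IT <- gT * 1; IO <- (!gT) * 1
    q_m <- colSums(m^2)
    mT <- (IT %*% m) / nT
    mO <- (IO %*% m) / nO
    mb <- (mT * nT + mO * nO) / n
    ss_group <- 2 * (nT * (mT - mb)^2 + nO * (mO - mb)^2)
    ss_subj <- 2 * (rep(1, P) %o% q_m - nT * mT^2 - nO * mO^2)
    ss_group / (ss_subj / (n - 2))
  } else {
    ET <- gT * perms$flip          # eps where subject in permuted T, else 0
    EO <- (!gT) * perms$flip
    q_d <- colSums(d^2)            # invariant under sign flips
    sT <- ET %*% d; sO <- EO %*% d
    dbT <- sT / nT; dbO <- sO / nO; db <- (sT + sO) / n
    ss_err <- (rep(1, P) %o% q_d - nT * dbT^2 - nO * dbO^2) / 2
    if (effect == "condition") {
      (n * db^2 / 2) / (ss_err / (n - 2))
    } else {
      ((nT * (dbT - db)^2 + nO * (dbO - db)^2) / 2) / (ss_err / (n - 2))
    }
  }
}

# row-wise max over finite entries; zero-variance timepoints are excluded
# from the max statistic (with one warning at the call site)
row_max_finite <- function(M) {
  M[!is.finite(M)] <- -Inf
  apply(M, 1, max)
}

#' Permutation threshold F* for one effect
#'
#' Runs the effect's permutation scheme and returns the (1-alpha)
#' empirical quantile of the distribution of the maximum F over the
#' gait-cycle axis. Enumerates all distinct permutations when there are no
#' more than `n_perm`; otherwise Monte Carlo with the identity permutation
#' always included.
#'
#' @param design an [snpm_design()]
#' @param effect `"group"`, `"condition"` or `"interaction"`
#' @param n_perm permutation budget (>= 100)
#' @param alpha family-wise significance level
#' @param seed integer seed for the permutation stream
#' @param force_monte_carlo sample even when exhaustive enumeration would
#'   fit the budget (used to validate the sampler against enumeration)
#' @return list: `F_star`, `perm_max` (the permutation max-F sample),
#'   `perm_F` (P x T permutation curves), `exhaustive`, `n_perm`
#' @export
permutation_threshold <- function(design, effect = c("interaction", "group",
                                                     "condition"),
                                  n_perm = 10000, alpha = 0.05, seed = 1L,
                                  force_monte_carlo = FALSE) {
  effect <- match.arg(effect)
  if (n_perm < 100) stop("n_perm must be at least 100")
  p <- design_parts(design)
  n_exact <- n_distinct_perms(p$n, sum(p$gT), effect)
  if (n_exact < 1 / alpha) {
    stop("alpha unattainable: only ", n_exact, " distinct permutations")
  }
  perms <- build_permutations(p$n, p$gT, effect, n_perm, seed,
                              force_monte_carlo = force_monte_carlo)
  Fp <- perm_F_matrix(p$m, p$d, perms, effect)
  if (any(!is.finite(Fp))) {
    warning("zero-variance timepoints excluded from the max statistic")
  }
  perm_max <- row_max_finite(Fp)
  srt <- sort(perm_max)
  F_star <- srt[ceiling((1 - alpha) * length(srt))]
  list(F_star = F_star, perm_max = perm_max, perm_F = Fp,
       exhaustive = perms$exhaustive, n_perm = perms$n_perm,
       effect = effect, alpha = alpha)
}

# run lengths of points at/above threshold: returns matrix start,end,len
# (point indices, 1-based)
supra_runs <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

# largest suprathreshold run length per row of a P x T matrix
perm_max_extents <- function(Fp, F_star) {
  apply(Fp >= F_star, 1, function(a) {
    a[is.na(a)] <- FALSE
    if (!any(a)) 0L else max(supra_runs(a)[, "len"])
  })
}

# linear interpolation of the threshold crossing, in percent of gait cycle
# (point k maps to (k-1)%, the matrix spans [0%, 100%))
cluster_bounds_pct <- function(Fc, F_star, start, end) {
  T_ <- length(Fc)
  lo <- (start - 1)
  if (start > 1 && is.finite(Fc[start - 1])) {
    lo <- (start - 1) - (Fc[start] - F_star) / (Fc[start] - Fc[start - 1])
  }
  hi <- (end - 1)
  if (end < T_ && is.finite(Fc[end + 1])) {
    hi <- (end - 1) + (Fc[end] - F_star) / (Fc[end] - Fc[end + 1])
  }
  c(max(lo, 0), min(hi, T_ - 1))
}

#' Suprathreshold cluster inference
#'
#' Clusters are maximal runs of consecutive gait-phase points with
#' `F >= F_star`. Each cluster's p-value is the proportion of
#' permutations whose largest suprathreshold run is at least as long
#' (add-one corrected). Cluster endpoints are reported in percent of the
#' gait cycle with linear interpolation at the threshold crossings.
#'
#' @param F_curve observed F curve (length T)
#' @param F_star the permutation threshold from [permutation_threshold()]
#' @param perm_F the P x T permutation F curves from the same stream
#' @return data.frame: `start_pct`, `end_pct`, `extent_points`, `F_max`,
#'   `p_cluster` (empty if nothing is suprathreshold)
#' @export
cluster_inference <- function(F_curve, F_star, perm_F) {
  above <- is.finite(F_curve) & F_curve >= F_star
  if (!any(above)) {
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0),
                      extent_points = integer(0), F_max = numeric(0),
                      p_cluster = numeric(0)))
  }
  runs <- supra_runs(above)
  extents <- perm_max_extents(perm_F, F_star)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    b <- cluster_bounds_pct(F_curve, F_star, runs[i, "start"], runs[i, "end"])
    data.frame(start_pct = b[1], end_pct = b[2],
               extent_points = runs[i, "len"],
               F_max = max(F_curve[runs[i, "start"]:runs[i, "end"]]),
               p_cluster = (1 + sum(extents >= runs[i, "len"])) /
                 (length(extents) + 1))
  })
  do.call(rbind, out)
}

#' SnPM analysis of one electrode
#'
#' Full inference for one electrode: observed F curves, permutation
#' thresholds and cluster p-values for the requested effects.
#'
#' @param design an [snpm_design()]
#' @param effects which effects to test (default all three)
#' @param n_perm,alpha,seed see [permutation_threshold()]
#' @return object of class `snpm_result`: per effect the `F` curve,
#'   `F_star`, `clusters` data.frame, plus `alpha`, `n_perm`, `seed`
#' @export
snpm_electrode <- function(design, effects = c("group", "condition",
                                               "interaction"),
                           n_perm = 10000, alpha = 0.05, seed = 1L) {
  curves <- anova_curves(design)
  res <- list()
  for (i in seq_along(effects)) {
    eff <- effects[i]
    thr <- permutation_threshold(design, eff, n_perm = n_perm, alpha = alpha,
                                 seed = seed + (i - 1L))
    Fc <- curves[[paste0("F_", eff)]]
    res[[eff]] <- list(F = Fc, F_star = thr$F_star,
                       exhaustive = thr$exhaustive, n_perm = thr$n_perm,
                       clusters = cluster_inference(Fc, thr$F_star, thr$perm_F))
  }
  structure(list(electrode = design$electrode, effects = res,
                 degenerate = curves$degenerate, alpha = alpha, seed = seed),
            class = "snpm_result")
}

#' @export
print.snpm_result <- function(x, ...) {
  cat(sprintf("snpm_result [%s], alpha = %g\n", x$electrode, x$alpha))
  for (eff in names(x$effects)) {
    e <- x$effects[[eff]]
    cat(sprintf("  %-12s F* = %.3f, %d cluster(s)\n", eff, e$F_star,
                nrow(e$clusters)))
    if (nrow(e$clusters) > 0) {
      for (i in seq_len(nrow(e$clusters))) {
        cat(sprintf("    %.1f%%-%.1f%% of gait cycle, Fmax = %.2f, p = %.4f\n",
                    e$clusters$start_pct[i], e$clusters$end_pct[i],
                    e$clusters$F_max[i], e$clusters$p_cluster[i]))
      }
    }
  }
  invisible(x)
}

# max-|t| permutation test for one pairwise contrast.
# paired: x, y are subjects x T for the same subjects -> sign flips.
# unpaired: x, y are different subject sets -> group-label permutations.
max_t_perm_test <- function(x, y, paired, n_perm, alpha, seed) {
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  if (paired) {
    d <- x - y
    n <- nrow(d)
    n_exact <- 2^n
    if (n_exact <= n_perm) {
      flip <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      dimnames(flip) <- NULL
      obs <- which(apply(flip, 1, function(r) all(r == 1)))
      flip <- rbind(flip[obs, ], flip[-obs, , drop = FALSE])
    } else {
      flip <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
      flip[1, ] <- 1
    }
    P <- nrow(flip)
    sums <- flip %*% d
    q <- colSums(d^2)
    mean_p <- sums / n
    var_p <- (rep(1, P) %o% q - n * mean_p^2) / (n - 1)
    tmat <- mean_p / sqrt(var_p / n)
  } else {
    z <- rbind(x, y)
    n1 <- nrow(x); n2 <- nrow(y); n <- n1 + n2
    n_exact <- choose(n, n1)
    if (n_exact <= n_perm) {
      sel <- utils::combn(n, n1)
      memb <- t(apply(sel, 2, function(ix) { v <- rep(FALSE, n); v[ix] <- TRUE; v }))
      obs <- which(apply(memb, 1, function(r) all(r == c(rep(TRUE, n1), rep(FALSE, n2)))))
      memb <- rbind(memb[obs, ], memb[-obs, , drop = FALSE])
    } else {
      memb <- matrix(FALSE, n_perm, n)
      memb[1, seq_len(n1)] <- TRUE
      for (i in 2:n_perm) memb[i, sample.int(n, n1)] <- TRUE
    }
    P <- nrow(memb)
    I1 <- memb * 1; I2 <- (!memb) * 1
    q <- colSums(z^2)
    s1 <- I1 %*% z; s2 <- I2 %*% z
    m1 <- s1 / n1; m2 <- s2 / n2
    ss_pooled <- (rep(1, P) %o% q - n1 * m1^2 - n2 * m2^2) / (n - 2)
    tmat <- (m1 - m2) / sqrt(ss_pooled * (1 / n1 + 1 / n2))
  }
  obs_t <- tmat[1, ]
  if (!any(is.finite(obs_t))) {            # degenerate: no variance anywhere
    return(list(t = obs_t, t_star = Inf, p = 1, n_perm = P))
  }
  perm_max <- row_max_finite(abs(tmat))
  srt <- sort(perm_max)
  t_star <- srt[ceiling((1 - alpha) * length(srt))]
  p <- (1 + sum(perm_max[-1] >= max(abs(obs_t)[is.finite(obs_t)]))) / P
  list(t = obs_t, t_star = t_star, p = min(p, 1), n_perm = P)
}

#' Bonferroni-corrected post hoc pairwise contrasts
#'
#' Runs SnPM max-|t| permutation tests over the full gait cycle for the
#' default contrast family {OSC vs OsSC (paired), TSC vs TsSC (paired),
#' OSC vs TSC (unpaired), OsSC vs TsSC (unpaired)} and multiplies each
#' p-value by the number of executed comparisons (capped at 1). Meant to
#' be run where the omnibus interaction has a significant cluster.
#'
#' @param design an [snpm_design()]
#' @param comparisons character vector of contrasts, each
#'   `"<cellA>_vs_<cellB>"`; the default family is used when `NULL`
#' @param n_perm,alpha,seed permutation settings
#' @return data.frame: `comparison`, `paired`, `p_raw`, `p_adj`,
#'   `t_star`, `max_abs_t`, and significant windows (percent) where
#'   `|t| >= t_star`, comma-separated in `windows_pct`
#' @export
posthoc <- function(design, comparisons = NULL, n_perm = 10000, alpha = 0.05,
                    seed = 1L) {
  if (is.null(comparisons)) {
    comparisons <- c("OSC_vs_OsSC", "TSC_vs_TsSC", "OSC_vs_TSC",
                     "OsSC_vs_TsSC")
  }
  cells <- list(
    OsSC = design$data[design$group == "O", 1, , drop = FALSE],
    OSC  = design$data[design$group == "O", 2, , drop = FALSE],
    TsSC = design$data[design$group == "T", 1, , drop = FALSE],
    TSC  = design$data[design$group == "T", 2, , drop = FALSE]
  )
  cells <- lapply(cells, function(a) { dim(a) <- dim(a)[c(1, 3)]; a })
  k <- length(comparisons)
  out <- lapply(seq_along(comparisons), function(i) {
    parts <- strsplit(comparisons[i], "_vs_")[[1]]
    if (length(parts) != 2 || !all(parts %in% names(cells))) {
      stop("unknown comparison: ", comparisons[i])
    }
    a <- cells[[parts[1]]]; b <- cells[[parts[2]]]
    paired <- substr(parts[1], 1, 1) == substr(parts[2], 1, 1)
    r <- max_t_perm_test(a, b, paired, n_perm, alpha, seed + i)
    wins <- ""
    above <- is.finite(r$t) & abs(r$t) >= r$t_star
    if (any(above)) {
      runs <- supra_runs(above)
      wins <- paste(sprintf("%.1f-%.1f", runs[, "start"] - 1,
                            runs[, "end"] - 1), collapse = ",")
    }
    finite_t <- abs(r$t)[is.finite(r$t)]
    data.frame(comparison = comparisons[i], paired = paired,
               p_raw = r$p, p_adj = min(1, k * r$p), t_star = r$t_star,
               max_abs_t = if (length(finite_t)) max(finite_t) else NA_real_,
               windows_pct = wins)
  })
  do.call(rbind, out)
}

#' Shapiro-Wilk normality screen of the design residuals
#'
#' Residuals are the observations centered on their group x condition
#' cell mean (per timepoint), pooled over the electrode. Advisory only:
#' the pipeline always proceeds to permutation inference, which does not
#' require normality.
#'
#' @param design an [snpm_design()]
#' @param max_n residual subsample cap (Shapiro-Wilk accepts at most 5000)
#' @return list: `statistic`, `p_value`, `n_residuals`, `normal`
#'   (p >= 0.05)
#' @export
normality_check <- function(design, max_n = 5000) {
  dat <- design$data
  n <- dim(dat)[1]
  res <- dat
  for (g in c("O", "T")) {
    sel <- design$group == g
    for (ci in 1:2) {
      cellmean <- apply(dat[sel, ci, , drop = FALSE], 3, mean)
      res[sel, ci, ] <- sweep(dat[sel, ci, , drop = FALSE], 3, cellmean)
    }
  }
  v <- as.numeric(res)
  if (length(v) < 3) stop("need at least 3 residuals")
  if (length(v) > max_n) {
    v <- v[round(seq(1, length(v), length.out = max_n))]
  }
  sw <- stats::shapiro.test(v)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n_residuals = length(v), normal = sw$p.value >= 0.05)
}

#' SnPM analysis across all electrodes
#'
#' Runs [snpm_electrode()] independently for every electrode of a cohort
#' (no correction across electrodes by default, mirroring electrode-wise
#' reporting; set `fwe_electrodes = TRUE` to Bonferroni-adjust alpha by
#' the electrode count).
#'
#' @param data named list: electrode -> subjects x 2 x T array
#'   (condition order sSC, SC)
#' @param group per-subject group labels
#' @param effects effects to test
#' @param n_perm,alpha,seed permutation settings; each electrode gets a
#'   deterministic seed derived from `seed`
#' @param fwe_electrodes divide alpha by the number of electrodes
#' @return list of `snpm_result` (named by electrode) with a `summary`
#'   data.frame attribute listing significant electrode/effect/cluster
#'   rows
#' @export
run_snpm_all_electrodes <- function(data, group,
                                    effects = c("group", "condition",
                                                "interaction"),
                                    n_perm = 10000, alpha = 0.05, seed = 1L,
                                    fwe_electrodes = FALSE) {
  a <- if (fwe_electrodes) alpha / length(data) else alpha
  results <- vector("list", length(data))
  names(results) <- names(data)
  for (i in seq_along(data)) {
    des <- snpm_design(data[[i]], group, electrode = names(data)[i])
    results[[i]] <- snpm_electrode(des, effects = effects, n_perm = n_perm,
                                   alpha = a, seed = seed + 1000L * (i - 1L))
  }
  rows <- list()
  for (el in names(results)) {
    for (eff in names(results[[el]]$effects)) {
      cl <- results[[el]]$effects[[eff]]$clusters
      if (nrow(cl) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          electrode = el, effect = eff, cl,
          F_star = results[[el]]$effects[[eff]]$F_star)
      }
    }
  }
  attr(results, "summary") <- if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(electrode = character(0), effect = character(0))
  results
}
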