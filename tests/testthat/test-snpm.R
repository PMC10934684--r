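random_design <- function(n_per_group = 4, n_points = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  snpm_design(array(rnorm(n * 2 * n_points), c(n, 2, n_points)),
              rep(c("O", "T"), each = n_per_group))
}

test_that("F curves match the textbook sum-of-squares oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    nO <- sample(3:8, 1); nT <- sample(3:8, 1)
    grp <- c(rep("O", nO), rep("T", nT))
    dat <- array(rnorm((nO + nT) * 2 * 4), c(nO + nT, 2, 4))
    res <- anova_curves(snpm_design(dat, grp))
    for (tp in 1:4) {
      o <- oracle_mixed_anova(dat[, , tp], grp)
      expect_equal(res$F_group[tp], o$F_group, tolerance = 1e-8)
      expect_equal(res$F_condition[tp], o$F_condition, tolerance = 1e-8)
      expect_equal(res$F_interaction[tp], o$F_interaction, tolerance = 1e-8)
    }
  }
})

test_that("F curves also agree with aov error-strata fits", {
  des <- random_design(4, 2, seed = 3)
  res <- anova_curves(des)
  n <- des$n_subjects
  for (tp in 1:2) {
    df <- data.frame(y = c(des$data[, 1, tp], des$data[, 2, tp]),
                     subj = factor(rep(seq_len(n), 2)),
                     grp = factor(rep(des$group, 2)),
                     cond = factor(rep(c("sSC", "SC"), each = n)))
    s <- summary(stats::aov(y ~ grp * cond + Error(subj / cond), data = df))
    expect_equal(res$F_group[tp], s[[1]][[1]]["grp", "F value"],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(res$F_condition[tp], s[[2]][[1]]["cond", "F value"],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(res$F_interaction[tp], s[[2]][[1]]["grp:cond", "F value"],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate data are flagged, pure condition shifts behave as forced", {
  dat <- array(1, c(6, 2, 2))
  des <- snpm_design(dat, rep(c("O", "T"), each = 3))
  res <- anova_curves(des)
  expect_true(all(res$degenerate))

  # additive condition effect, no noise: F_condition blows up, interaction ~ 0
  set.seed(4)
  base <- matrix(rnorm(6 * 2), 6)  # per-subject per-timepoint levels
  dat2 <- array(0, c(6, 2, 2))
  dat2[, 1, ] <- base
  dat2[, 2, ] <- base + 1
  res2 <- anova_curves(snpm_design(dat2, rep(c("O", "T"), each = 3)))
  expect_true(all(is.infinite(res2$F_condition)))
  expect_true(all(res2$degenerate))
})

test_that("exhaustive permutation enumeration matches brute force", {
  set.seed(11)
  dat <- array(rnorm(4 * 2 * 5), c(4, 2, 5))
  grp <- c("O", "O", "T", "T")
  des <- snpm_design(dat, grp)

  thr <- permutation_threshold(des, "condition", n_perm = 1000,
                               alpha = 0.25, seed = 1)
  expect_true(thr$exhaustive)
  expect_equal(thr$n_perm, 16L)
  brute <- apply(as.matrix(expand.grid(rep(list(c(1, -1)), 4))), 1,
                 function(e) {
                   d2 <- dat
                   for (j in 1:4) if (e[j] < 0) d2[j, , ] <- dat[j, 2:1, ]
                   max(anova_curves(snpm_design(d2, grp))$F_condition)
                 })
  expect_equal(sort(brute), sort(thr$perm_max))

  thr_g <- permutation_threshold(des, "group", n_perm = 1000,
                                 alpha = 0.25, seed = 1)
  expect_equal(thr_g$n_perm, 6L)   # choose(4, 2) group assignments
  brute_g <- apply(t(utils::combn(4, 2)), 1, function(ix) {
    g2 <- rep("O", 4); g2[ix] <- "T"
    max(anova_curves(snpm_design(dat, g2))$F_group)
  })
  expect_equal(sort(brute_g), sort(thr_g$perm_max))
})

test_that("alpha = 1 returns the minimum of the permutation distribution", {
  des <- random_design(2, 4, seed = 5)
  thr <- permutation_threshold(des, "condition", n_perm = 500,
                               alpha = 0.999999, seed = 2)
  expect_equal(thr$F_star, min(thr$perm_max))
})

test_that("unattainable alpha is rejected", {
  dat <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  des <- snpm_design(dat, c("O", "O", "T", "T"))
  expect_error(permutation_threshold(des, "group", n_perm = 1000,
                                     alpha = 0.05, seed = 1),
               "alpha unattainable")
})

test_that("Monte-Carlo thresholds agree with exhaustive enumeration", {
  set.seed(6)
  dat <- array(rnorm(8 * 2 * 10), c(8, 2, 10))
  des <- snpm_design(dat, rep(c("O", "T"), each = 4))
  ex <- permutation_threshold(des, "condition", n_perm = 256,
                              alpha = 0.1, seed = 1)
  expect_true(ex$exhaustive)
  mc <- permutation_threshold(des, "condition", n_perm = 4000,
                              alpha = 0.1, seed = 2,
                              force_monte_carlo = TRUE)
  # quantile agreement within the Monte-Carlo (binomial) error band:
  # compare by the exceedance probability of the MC threshold under the
  # exhaustive distribution
  p_ex <- mean(ex$perm_max >= mc$F_star)
  expect_lt(abs(p_ex - 0.1), 3 * sqrt(0.1 * 0.9 / 4000) + 1 / 256)
})

test_that("doubling the permutation budget moves F* by < Monte-Carlo error", {
  des <- random_design(12, 20, seed = 9)
  t1 <- permutation_threshold(des, "interaction", n_perm = 2000,
                              alpha = 0.05, seed = 3)
  t2 <- permutation_threshold(des, "interaction", n_perm = 4000,
                              alpha = 0.05, seed = 3)
  # binomial CI at the 95th percentile of the 2000-draw sample
  q <- mean(t2$perm_max <= t1$F_star)
  expect_lt(abs(q - 0.95), 3 * sqrt(0.05 * 0.95 / 2000) + 1e-3)
})

test_that("cluster inference finds runs and assigns add-one p-values", {
  Fc <- c(rep(1, 40), rep(10, 5), rep(1, 55))
  perm_F <- matrix(1, nrow = 199, ncol = 100)  # no permutation exceeds
  cl <- cluster_inference(Fc, 5, perm_F)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent_points, 5L)
  expect_equal(cl$F_max, 10)
  expect_lte(cl$start_pct, 40)
  expect_gte(cl$end_pct, 43)
  expect_lte(cl$p_cluster, 2 / 200)

  expect_equal(nrow(cluster_inference(rep(1, 100), 5, perm_F)), 0)
})

test_that("permutation relabeling leaves the null distribution invariant", {
  # applying a scheme-permissible relabeling to the data produces the same
  # permutation max-F multiset (exhaustive enumeration)
  set.seed(12)
  dat <- array(rnorm(4 * 2 * 6), c(4, 2, 6))
  grp <- c("O", "O", "T", "T")
  des <- snpm_design(dat, grp)
  thr <- permutation_threshold(des, "condition", n_perm = 100,
                               alpha = 0.25, seed = 1)
  dat2 <- dat
  dat2[2, , ] <- dat[2, 2:1, ]   # swap conditions for subject 2
  thr2 <- permutation_threshold(snpm_design(dat2, grp), "condition",
                                n_perm = 100, alpha = 0.25, seed = 1)
  expect_equal(sort(thr$perm_max), sort(thr2$perm_max), tolerance = 1e-12)
  expect_equal(thr$F_star, thr2$F_star, tolerance = 1e-12)
})

test_that("post hoc family behaves on degenerate and shifted data", {
  dat <- array(1, c(8, 2, 5))
  des <- snpm_design(dat, rep(c("O", "T"), each = 4))
  ph <- posthoc(des, n_perm = 200, seed = 1)
  expect_equal(nrow(ph), 4)
  expect_true(all(ph$p_adj == 1))

  # Bonferroni arithmetic: adjusted = 4 x raw, capped at 1
  set.seed(13)
  dat2 <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
  dat2[7:12, 1, ] <- dat2[7:12, 1, ] + 3     # TsSC elevated
  des2 <- snpm_design(dat2, rep(c("O", "T"), each = 6))
  ph2 <- posthoc(des2, n_perm = 500, seed = 2)
  expect_equal(ph2$p_adj, pmin(1, 4 * ph2$p_raw))
  expect_equal(ph2$comparison[which.min(ph2$p_adj)], "OsSC_vs_TsSC")
})

test_that("a TsSC-only elevation is attributed to the TsSC/OsSC contrast", {
  wins <- 0L
  for (rep in 1:50) {
    sim <- simulate_matrix_cohort(
      12, effect_spec("Fz", c(3, 8), amplitude_delta = 0.75,
                      factor = "interaction", affected_cells = "TsSC"),
      seed = 400 + rep)
    des <- snpm_design(sim$data[["Fz"]], sim$group)
    ph <- posthoc(des, n_perm = 300, seed = rep)
    # the affected contrast attains the family's smallest adjusted p
    # (permutation p-values floor at 1/(P+1), so ties count)
    p_target <- ph$p_adj[ph$comparison == "OsSC_vs_TsSC"]
    if (p_target <= min(ph$p_adj)) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.9)
})

test_that("normality screen is calibrated and has power", {
  # uniform p under normal residuals
  set.seed(14)
  ps <- replicate(200, {
    dat <- array(rnorm(24 * 2), c(24, 2, 1))
    normality_check(snpm_design(dat, rep(c("O", "T"), each = 12)))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # skewed residuals detected
  hits <- mean(replicate(100, {
    dat <- array(rexp(24 * 2), c(24, 2, 1))
    normality_check(snpm_design(dat, rep(c("O", "T"), each = 12)))$p_value
  }) < 0.05)
  expect_gt(hits, 0.9)

  dat <- array(rnorm(2 * 2 * 1), c(2, 2, 1))
  expect_error(snpm_design(dat, c("O", "T")), "at least 2")
})

test_that("detection power never decreases with effect size", {
  deltas <- c(0.2, 0.5, 0.9)
  power <- vapply(deltas, function(dl) {
    hits <- 0L
    for (rep in 1:30) {
      sim <- simulate_matrix_cohort(
        12, effect_spec("Fz", c(3, 8), amplitude_delta = dl,
                        factor = "interaction", affected_cells = "TsSC"),
        seed = 700 + rep)
      des <- snpm_design(sim$data[["Fz"]], sim$group)
      thr <- permutation_threshold(des, "interaction", n_perm = 300,
                                   alpha = 0.05, seed = rep)
      if (max(anova_curves(des)$F_interaction) >= thr$F_star) hits <- hits + 1L
    }
    hits / 30
  }, 0)
  expect_true(all(diff(power) >= -0.1))  # monotone up to simulation noise
  expect_gt(power[3], power[1])
})

test_that("whole-cohort electrode sweep is deterministic and localizes effects", {
  eff <- effect_spec("Fz", c(3, 8), amplitude_delta = 0.9,
                     factor = "interaction", affected_cells = "TsSC")
  sim <- simulate_matrix_cohort(12, eff, seed = 21,
                                electrodes = c("Fz", "Oz", "P3"))
  r1 <- run_snpm_all_electrodes(sim$data, sim$group,
                                effects = "interaction", n_perm = 300,
                                alpha = 0.05, seed = 5)
  r2 <- run_snpm_all_electrodes(sim$data, sim$group,
                                effects = "interaction", n_perm = 300,
                                alpha = 0.05, seed = 5)
  s1 <- attr(r1, "summary"); s2 <- attr(r2, "summary")
  expect_identical(s1, s2)
  expect_true("Fz" %in% s1$electrode)
  fz <- s1[s1$electrode == "Fz", ]
  expect_true(any(fz$end_pct >= 3 & fz$start_pct <= 8))
})
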