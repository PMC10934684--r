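make_two_source_mix <- function(n = 8000, rate = 512) {
  t <- (0:(n - 1)) / rate
  s <- rbind(sin(2 * pi * 3.3 * t), sign(sin(2 * pi * 1.7 * t)))
  A <- matrix(c(1, 0.4, 0.6, 1), 2)
  list(X = A %*% s, A = A, s = s)
}

test_that("fastICA separates a two-source mixture (Amari oracle)", {
  mix <- make_two_source_mix()
  d <- fit_fastica(mix$X, 2, seed = 3)
  expect_true(d$converged)
  expect_lt(amari_index(d$unmixing, mix$A), 0.05)
})

test_that("already-independent white input is recovered up to sign/permutation", {
  set.seed(8)
  s <- rbind(runif(6000, -1, 1), runif(6000, -1, 1))
  s <- s - rowMeans(s)
  d <- fit_fastica(s, 2, seed = 2)
  C <- abs(cor(t(d$sources), t(s)))
  # one-to-one matching with |r| ~ 1
  expect_true(all(apply(C, 1, max) > 0.99))
  expect_equal(sort(apply(C, 1, which.max)), 1:2)
})

test_that("decomposition is deterministic given the seed", {
  mix <- make_two_source_mix()
  d1 <- fit_fastica(mix$X, 2, seed = 7)
  d2 <- fit_fastica(mix$X, 2, seed = 7)
  expect_identical(d1$unmixing, d2$unmixing)
  d3 <- fit_fastica(mix$X, 2, seed = 8)
  expect_false(identical(d1$unmixing, d3$unmixing))
})

test_that("whitening, orthonormality and reconstruction invariants hold", {
  rec <- quick_subject(duration = 25, seed = 11)
  X <- rec$eeg
  d <- fit_fastica(X, 5, seed = 1)
  # whitened covariance = identity
  Z <- d$whitener %*% (X - d$channel_means)
  expect_lt(max(abs(tcrossprod(Z) / ncol(Z) - diag(5))), 1e-6)
  # unmixing rows orthonormal in whitened space
  expect_lt(max(abs(tcrossprod(d$whitened_unmixing) - diag(5))), 1e-6)
  # mixing . unmixing = identity on the retained subspace
  expect_lt(max(abs(d$unmixing %*% d$mixing - diag(5))), 1e-6)
  # residual energy equals the discarded eigenvalue mass
  recon <- d$mixing %*% d$sources
  resid <- (X - d$channel_means) - recon
  expect_lt(abs(sum(resid^2) / ncol(X) - sum(d$pc_values[-(1:5)])) /
              sum(d$pc_values[-(1:5)]), 1e-6)
})

test_that("rank deficiency is rejected", {
  x <- rnorm(2000)
  X <- rbind(x, 2 * x, -x)
  expect_error(fit_fastica(X, 3, seed = 1), "rank")
})

test_that("rule-based labels follow topography and spectrum", {
  # build a decomposition by hand: 3 synthetic components with known
  # scalp maps and sources, evaluated against the published default rules
  labels <- recorded_labels()
  rate <- 512; n <- 8192
  t <- (0:(n - 1)) / rate
  blink_map <- numeric(32); names(blink_map) <- labels
  blink_map[c("Fp1", "Fp2", "Fpz")] <- c(0.8, 0.8, 1)
  emg_map <- numeric(32); names(emg_map) <- labels
  emg_map[c("T7", "FC5")] <- c(1, 0.4)
  brain_map <- rep(0.4, 32); names(brain_map) <- labels
  brain_map[c("Pz", "POz", "Oz", "O1", "O2")] <- 1

  set.seed(4)
  blink_src <- rowSums(sapply(seq(1, 14, by = 2.5), function(tc)
    exp(-(t - tc)^2 / (2 * 0.08^2))))
  emg_src <- gaitwave:::band_noise(n, c(25, 80), rate)
  brain_src <- gaitwave:::band_noise(n, c(1, 30), rate)

  decomp <- structure(list(
    n_components = 3,
    mixing = cbind(blink_map, emg_map, brain_map),
    sources = rbind(blink_src, emg_src, brain_src)
  ), class = "ica_decomposition")
  rownames(decomp$mixing) <- labels

  lab <- classify_components(decomp, rate = rate)
  expect_equal(lab$label, c("ocular", "muscle", "brain"))
})

test_that("removing nothing is the identity; removing all leaves the PCA residual", {
  rec <- quick_subject(duration = 25, seed = 12)
  X <- rec$eeg
  d <- fit_fastica(X, 5, seed = 1)
  expect_identical(remove_components(X, d, integer(0)), X)
  expect_error(remove_components(X, d, 9), "out of range")

  cleaned <- remove_components(X, d, 1:5)
  # oracle: direct projection onto the retained PC subspace
  P <- d$pc_vectors[, 1:5] %*% t(d$pc_vectors[, 1:5])
  resid <- (X - d$channel_means) - P %*% (X - d$channel_means)
  expect_equal(cleaned, resid + d$channel_means, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("blink component removal decorrelates frontal channels from the blink source", {
  rec <- quick_subject(duration = 40, seed = 13)
  pre <- prefilter(rec$eeg, band_definition("delta"), notch_spec(),
                   rec$eeg_rate)
  d <- fit_fastica(pre, 5, seed = 1)
  labs <- classify_components(d, rate = rec$eeg_rate)
  blink <- rec$ground_truth$sources["blink", ]
  # identify the estimated blink component as the one most correlated
  # with the ground-truth blink source
  k <- which.max(abs(cor(t(d$sources), blink)))
  expect_equal(labs$label[k], "ocular")
  # Fp1 carries blink plus eye-movement/glossokinetic/background activity,
  # so the raw correlation is substantial but well below 1
  expect_gt(abs(cor(pre["Fp1", ], blink)), 0.4)
  cleaned <- remove_components(pre, d, k)
  expect_lt(abs(cor(cleaned["Fp1", ], blink)), 0.1)
})

test_that("five planted sources are recovered with matched |r| > 0.95", {
  # near-noiseless mixture so the top-5 subspace is exactly the 5 largest
  # sources (blink, horizontal-eye, glossokinetic, 2x EMG + delta makes 6;
  # the 5 estimated components must match 5 of them almost perfectly)
  rec <- quick_subject(duration = 40, seed = 14, background_sd = 0.01)
  pre <- prefilter(rec$eeg, band_definition("delta"), notch_spec(),
                   rec$eeg_rate)
  d <- fit_fastica(pre, 5, seed = 2)
  S_true <- rec$ground_truth$sources
  # compare in the filtered domain the decomposition saw
  S_filt <- prefilter(S_true, band_definition("delta"), notch_spec(),
                      rec$eeg_rate)
  C <- abs(cor(t(d$sources), t(S_filt)))
  matched <- apply(C, 1, max)
  expect_gt(mean(matched), 0.95)
  # distinct sources matched (no duplicate assignment)
  expect_equal(anyDuplicated(apply(C, 1, which.max)), 0L)
})
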