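# FastICA decomposition and rule-based artifact-component handling.
#
# The decomposition follows the staged fixed-point procedure: per-channel
# mean removal, covariance eigendecomposition, retention of the leading
# principal components, whitening, then symmetric fixed-point iteration
# with the tanh contrast. Five components is the working default: with a
# 30-channel walking recording the large-variance subspace is dominated by
# ocular, glossokinetic and muscle activity, so the retained components
# are typically all artifacts and removing them leaves the (smaller)
# cortical signal in the residual.

#' Fit a fastICA decomposition
#'
#' @param eeg channels x samples matrix (pre-filtered EEG, microvolts)
#' @param n_components number of components to estimate (default 5)
#' @param seed integer seed for the random orthonormal initialization
#' @param max_iter maximum fixed-point iterations
#' @param tol convergence tolerance on the per-component direction change
#' @param ortho `"symmetric"` (parallel, default) or `"deflation"`
#' @return object of class `ica_decomposition`: `unmixing`
#'   (components x channels), `mixing` (channels x components), `sources`
#'   (components x samples, zero mean), `whitener`, `channel_means`,
#'   `converged`, `iterations`
#' @export
fit_fastica <- function(eeg, n_components = 5, seed = 1L, max_iter = 1000,
                        tol = 1e-4, ortho = c("symmetric", "deflation")) {
  ortho <- match.arg(ortho)
  stopifnot(is.matrix(eeg), all(is.finite(eeg)), n_components >= 1)
  n_ch <- nrow(eeg); n_s <- ncol(eeg)
  if (n_s < 20 * n_ch) {
    warning("fewer than 20 samples per channel; ICA estimates may be unstable")
  }

  mu <- rowMeans(eeg)                    # centering (remean)
  xc <- eeg - mu
  C <- tcrossprod(xc) / n_s              # decorrelation (covariance matrix)
  eg <- eigen(C, symmetric = TRUE)       # PCA
  if (sum(eg$values > 1e-12 * eg$values[1]) < n_components) {
    stop("data rank below n_components")
  }
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  D <- eg$values[seq_len(n_components)]
  K <- diag(1 / sqrt(D), n_components) %*% t(E)   # whitener
  Z <- K %*% xc                          # whitened data, cov = I

  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }

  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  W <- sym_orth(matrix(stats::rnorm(n_components^2), n_components))

  converged <- FALSE; it <- 0L
  if (ortho == "symmetric") {
    for (it in seq_len(max_iter)) {
      WX <- W %*% Z
      G <- tanh(WX)
      gprime <- 1 - G^2
      W_new <- sym_orth(G %*% t(Z) / n_s - diag(rowMeans(gprime)) %*% W)
      delta <- max(abs(1 - abs(rowSums(W_new * W))))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
  } else {
    W <- matrix(0, n_components, n_components)
    for (p in seq_len(n_components)) {
      w <- stats::rnorm(n_components); w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- drop(crossprod(w, Z))
        g <- tanh(wx)
        w_new <- drop(Z %*% g) / n_s - mean(1 - g^2) * w
        if (p > 1) {
          proj <- W[seq_len(p - 1), , drop = FALSE]
          w_new <- w_new - drop(crossprod(proj, proj %*% w_new))
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        delta <- abs(1 - abs(sum(w_new * w)))
        w <- w_new
        if (delta < tol) break
      }
      converged <- delta < tol
      W[p, ] <- w
    }
  }
  if (!converged) {
    warning("fastICA did not converge in ", max_iter, " iterations")
  }

  unmixing <- W %*% K                           # components x channels
  mixing <- E %*% diag(sqrt(D), n_components) %*% t(W)  # channels x components
  sources <- unmixing %*% xc
  rownames(mixing) <- rownames(eeg)
  colnames(unmixing) <- rownames(eeg)
  structure(
    list(n_components = n_components, unmixing = unmixing, mixing = mixing,
         sources = sources, whitener = K, channel_means = mu,
         whitened_unmixing = W, pc_vectors = E, pc_values = eg$values,
         converged = converged, iterations = it),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("ica_decomposition: %d components, %s after %d iterations\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# fraction of a source's spectral power below / above a frequency
power_fraction <- function(x, rate, below = NULL, above = NULL) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- seq_len(floor(n / 2))
  f <- (half - 1) * rate / n
  p <- p[half]
  tot <- sum(p)
  if (tot == 0) return(0)
  if (!is.null(below)) sum(p[f < below]) / tot else sum(p[f > above]) / tot
}

#' Default thresholds for rule-based component classification
#'
#' `frontal_share`: minimum squared-weight share on Fp1/Fp2/Fpz for an
#' ocular call; `low_freq`: minimum power fraction below 4 Hz for
#' ocular/glossokinetic; `high_freq`: minimum power fraction above 20 Hz
#' for muscle; `inferior_share`: minimum squared-weight share on the
#' inferior-frontal/temporal ring for glossokinetic.
#'
#' @return named list of thresholds
#' @export
classification_thresholds <- function() {
  list(frontal_share = 0.35, low_freq = 0.5, high_freq = 0.4,
       inferior_share = 0.45)
}

#' Classify independent components as artifact or brain
#'
#' Rule-based scoring on each component's scalp map and source spectrum:
#' ocular = frontal-concentrated map with dominant sub-4 Hz power;
#' muscle = dominant power above 20 Hz; glossokinetic = low-frequency
#' with inferior-frontal/temporal weighting; otherwise brain.
#'
#' @param decomp an `ica_decomposition` with channel names on `mixing`
#' @param montage a `montage_info`
#' @param rate sampling rate of the decomposed data, Hz
#' @param thresholds see [classification_thresholds()]
#' @return data.frame with one row per component: `component`, `label`,
#'   and the rule scores (`frontal_share`, `inferior_share`,
#'   `low_freq_ratio`, `high_freq_ratio`)
#' @export
classify_components <- function(decomp, montage = montage_info(), rate = 512,
                                thresholds = classification_thresholds()) {
  labels <- rownames(decomp$mixing)
  if (is.null(labels)) stop("decomposition carries no channel labels")
  frontal <- intersect(c("Fp1", "Fp2", "Fpz"), labels)
  inferior <- intersect(c("Fp1", "Fp2", "Fpz", "F7", "F8", "T7", "T8",
                          "M1", "M2"), labels)
  out <- lapply(seq_len(decomp$n_components), function(k) {
    w2 <- decomp$mixing[, k]^2
    tot <- sum(w2)
    fr <- sum(w2[frontal]) / tot
    inf_sh <- sum(w2[inferior]) / tot
    lo <- power_fraction(decomp$sources[k, ], rate, below = 4)
    hi <- power_fraction(decomp$sources[k, ], rate, above = 20)
    label <- if (fr > thresholds$frontal_share && lo > thresholds$low_freq) {
      "ocular"
    } else if (hi > thresholds$high_freq) {
      "muscle"
    } else if (lo > thresholds$low_freq && inf_sh > thresholds$inferior_share) {
      "glossokinetic"
    } else {
      "brain"
    }
    data.frame(component = k, label = label, frontal_share = fr,
               inferior_share = inf_sh, low_freq_ratio = lo,
               high_freq_ratio = hi)
  })
  do.call(rbind, out)
}

#' Subtract rejected components from the EEG
#'
#' `cleaned = eeg - mixing[, reject] %*% sources[reject, ]`; channel means
#' are untouched, and rejecting nothing returns the input exactly.
#'
#' @param eeg the channels x samples matrix the decomposition was fit on
#' @param decomp the `ica_decomposition`
#' @param reject integer component indices to remove
#' @return cleaned EEG, same shape
#' @export
remove_components <- function(eeg, decomp, reject) {
  if (length(reject) == 0) return(eeg)
  reject <- as.integer(reject)
  if (any(reject < 1 | reject > decomp$n_components)) {
    stop("component index out of range")
  }
  eeg - decomp$mixing[, reject, drop = FALSE] %*%
    decomp$sources[reject, , drop = FALSE]
}

#' Classify and remove all non-brain components
#'
#' @inheritParams classify_components
#' @param eeg the matrix `decomp` was fit on
#' @param remove `"non_brain"` (default: drop every component not labeled
#'   brain) or `"all"` (drop the whole retained subspace, analyzing the
#'   residual)
#' @return list with `cleaned` EEG, `labels` (classification table) and
#'   `rejected` indices
#' @export
clean_artifacts <- function(eeg, decomp, montage = montage_info(), rate = 512,
                            thresholds = classification_thresholds(),
                            remove = c("non_brain", "all")) {
  remove <- match.arg(remove)
  labs <- classify_components(decomp, montage, rate, thresholds)
  rej <- if (remove == "all") seq_len(decomp$n_components)
         else labs$component[labs$label != "brain"]
  list(cleaned = remove_components(eeg, decomp, rej), labels = labs,
       rejected = rej)
}

#' Amari index between a true and an estimated unmixing
#'
#' Permutation- and scale-invariant separation error: 0 for a perfect
#' unmixing (up to permutation/sign), approaching 1 for unrelated ones.
#' Used as the independent oracle for source-recovery tests.
#'
#' @param W estimated unmixing (components x channels)
#' @param A true mixing (channels x components)
#' @return the normalized Amari index in `[0, 1]`
#' @export
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  n <- nrow(P)
  rs <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cs <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rs + cs) / (2 * n * (n - 1))
}
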