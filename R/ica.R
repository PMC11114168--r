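#' Seeded fixed-point ICA decomposition
#'
#' Symmetric fixed-point ICA (tanh contrast) on a whitened recording.
#' Indeterminacies are canonicalized so the decomposition is a pure function
#' of (recording, n_components, seed): components are ordered by explained
#' variance and each mixing column's largest-magnitude entry is made
#' positive. With all components retained and `n_components` equal to the
#' channel count, `mixing %*% sources + center` reconstructs the input to
#' numerical tolerance.
#'
#' @param recording An [eeg_recording()].
#' @param n_components Number of components (default: channel count, itself
#'   capped at 16 in the standard montage).
#' @param seed Integer seed for the random orthonormal initialisation.
#' @param maxit,tol Fixed-point iteration controls.
#' @param min_samples_factor Required samples per `n_components^2`
#'   (rule-of-thumb data-sufficiency check, default 1).
#' @return An `ica_decomposition` with fields `mixing` (channels x
#'   components), `sources` (components x samples), `center`,
#'   `n_components`, `channel_labels`, `rate`, `removed`.
#' @export
decompose_ica <- function(recording, n_components = NULL, seed = 1L,
                          maxit = 500L, tol = 1e-9, min_samples_factor = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  X <- recording$data
  M <- nrow(X); n <- ncol(X)
  if (is.null(n_components)) n_components <- M
  k <- as.integer(n_components)
  if (k > M) stop("n_components must not exceed the channel count")
  if (n < min_samples_factor * k^2)
    stop("recording too short for ", k, " components (need >= ",
         min_samples_factor * k^2, " samples)")
  center <- rowMeans(X)
  Xc <- X - center
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[k] < 1e-12 * eg$values[1])
    stop("input is rank-deficient; try fewer components")
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  d <- eg$values[seq_len(k)]
  V <- diag(1 / sqrt(d), k) %*% t(E)      # whitening, k x M
  Z <- V %*% Xc                            # k x n, cov = I
  W <- with_seed(derive_seed(seed, "ica-init"),
                 qr.Q(qr(matrix(stats::rnorm(k * k), k, k))))
  sym_decorrelate <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), k) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W_new <- tcrossprod(G, Z) / n - diag(rowMeans(1 - G^2), k) %*% W
    W_new <- sym_decorrelate(W_new)
    conv <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (conv < tol) break
  }
  S <- W %*% Z
  A <- E %*% diag(sqrt(d), k) %*% t(W)     # back-projection, M x k
  # canonicalize: order by explained variance, dominant mixing entry positive
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; S <- S[ord, , drop = FALSE]
  for (j in seq_len(k)) {
    if (A[which.max(abs(A[, j])), j] < 0) { A[, j] <- -A[, j]; S[j, ] <- -S[j, ] }
  }
  rownames(A) <- recording$channel_labels
  structure(list(mixing = A, sources = S, center = center,
                 n_components = k, channel_labels = recording$channel_labels,
                 rate = recording$rate, annotations = recording$annotations,
                 iterations = it, removed = integer(0)),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components over %d channels (%d samples)\n",
              x$n_components, length(x$channel_labels), ncol(x$sources)))
  invisible(x)
}

# Blink score for each component: frontal topography dominance of the mixing
# column, times the fraction of source power below 4 Hz, times a burstiness
# factor driven by excess kurtosis (blinks are sparse transients; stationary
# oscillations and Gaussian noise have excess kurtosis <= 0).
.blink_scores <- function(decomp) {
  A <- decomp$mixing
  S <- decomp$sources
  rate <- decomp$rate
  frontal <- intersect(frontal_channels(), rownames(A))
  n <- ncol(S)
  freqs <- seq(0, n - 1) * rate / n
  low <- freqs > 1e-12 & pmin(freqs, rate - freqs) < 4
  nondc <- freqs > 1e-12
  vapply(seq_len(decomp$n_components), function(j) {
    a2 <- A[, j]^2
    fd <- sum(a2[frontal]) / sum(a2)
    s <- S[j, ]
    pw <- Mod(stats::fft(s))^2
    lf <- sum(pw[low]) / sum(pw[nondc])
    z <- (s - mean(s)) / stats::sd(s)
    kurt <- mean(z^4)
    burst <- 1 - exp(-max(0, kurt - 3) / 3)
    fd * lf * burst
  }, numeric(1))
}

#' Automatically flag blink-artifact components
#'
#' Scores each component by (frontal dominance of its scalp projection) x
#' (fraction of source power below 4 Hz) x (burstiness from excess
#' kurtosis), and returns the indices of up to `max_remove` components whose
#' score exceeds `threshold`, best first. An empty set is a valid outcome on
#' clean data.
#'
#' @param decomp An `ica_decomposition`.
#' @param recording The recording the decomposition came from (unused beyond
#'   interface symmetry; scores are computed from the decomposition itself).
#' @param max_remove Cap on the number of flagged components (default 2).
#' @param threshold Minimum blink score (default 0.1, set from the null
#'   score distribution on blink-free synthetic sessions).
#' @return Integer vector of component indices (possibly empty), with the
#'   scores attached as attribute `"scores"`.
#' @export
identify_artifact_components <- function(decomp, recording = NULL,
                                         max_remove = 2L, threshold = 0.1) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (max_remove <= 0) return(integer(0))
  scores <- .blink_scores(decomp)
  idx <- order(scores, decreasing = TRUE)
  idx <- idx[scores[idx] > threshold]
  idx <- idx[seq_len(min(length(idx), max_remove))]
  attr(idx, "scores") <- scores
  idx
}

#' Reconstruct a recording with components removed
#'
#' Zeroes the selected source rows and back-projects. At most `max_remove`
#' components may be removed (the pipeline's cap, default 2, reflecting the
#' restriction that no more than two independent components be discarded
#' when cleaning ocular artifacts).
#'
#' @param decomp An `ica_decomposition`.
#' @param indices Integer component indices to remove (may be empty).
#' @param max_remove The removal cap (default 2).
#' @return An [eeg_recording()].
#' @export
remove_components <- function(decomp, indices = integer(0), max_remove = 2L) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  indices <- unique(as.integer(indices))
  if (length(indices) > max_remove)
    stop("at most ", max_remove, " components may be removed (asked for ",
         length(indices), ")")
  if (any(indices < 1 | indices > decomp$n_components))
    stop("component indices out of range")
  keep <- setdiff(seq_len(decomp$n_components), indices)
  X <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$sources[keep, , drop = FALSE] + decomp$center
  eeg_recording(X, decomp$rate, decomp$channel_labels, decomp$annotations)
}
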