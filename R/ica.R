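## Stacked-channel ICA and spectral component-rejection rules. The stacked
## input is cleaned scalp EEG + amplitude-matched noise channels + EMG, so
## artifact-dominated components can be recognized by their spectral match to
## the reference channels.

## FastICA with symmetric orthogonalization and tanh contrast on pre-whitened
## data; deterministic given the seed.
fastica_core <- function(Z, seed = 1, max_iter = 500, tol = 1e-7) {
  d <- nrow(Z); n <- ncol(Z)
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300))) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W_new <- tcrossprod(G, Z) / n - gprime * W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  W
}

#' Run dimensionality-reduced ICA on a stacked channel block
#'
#' PCA reduction to `n_dims` followed by FastICA (symmetric, tanh contrast) on
#' the whitened scores. Components are ordered by decreasing projected
#' variance and sign-fixed (largest-magnitude mixing weight positive), making
#' the decomposition deterministic for a fixed seed.
#'
#' @param x stacked channels x samples matrix (cleaned EEG + amplitude-matched
#'   noise + EMG).
#' @param n_dims retained dimensionality (default: all channels).
#' @param fs sampling rate, Hz (used for the per-component spectra).
#' @param seed RNG seed for the unmixing initialization.
#' @param max_iter,tol FastICA iteration controls.
#' @return object of class `component_set`: `mixing` (ch x comp), `unmixing`
#'   (comp x ch), `activations` (comp x samples), `center`, `spectra`
#'   (list with `freq` Hz and `db` comp x bins matrix, 2-100 Hz), `fs`.
#' @export
run_ica <- function(x, n_dims = NULL, fs, seed = 1, max_iter = 500,
                    tol = 1e-7) {
  n_ch <- nrow(x); n <- ncol(x)
  n_dims <- n_dims %||% n_ch
  if (n_dims > n_ch) stop("n_dims exceeds channel count")
  if (n < 20 * n_dims)
    warning("short data for ", n_dims, "-dimensional ICA (", n, " samples)")
  ctr <- rowMeans(x)
  Xc <- x - ctr
  e <- eigen(tcrossprod(Xc) / n, symmetric = TRUE)
  keep <- seq_len(n_dims)
  V <- e$vectors[, keep, drop = FALSE]
  dvals <- pmax(e$values[keep], 1e-300)
  Z <- (t(V) / sqrt(dvals)) %*% Xc            # whitened scores
  W <- fastica_core(Z, seed = seed, max_iter = max_iter, tol = tol)
  unmixing <- W %*% (t(V) / sqrt(dvals))      # comp x ch
  mixing <- V %*% (sqrt(dvals) * t(W))        # ch x comp (W orthogonal)
  ## order by projected channel-space variance; fix signs
  pv <- colSums(mixing^2)
  ord <- order(pv, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  for (j in seq_len(ncol(mixing))) {
    s <- sign(mixing[which.max(abs(mixing[, j])), j])
    if (s < 0) { mixing[, j] <- -mixing[, j]; unmixing[j, ] <- -unmixing[j, ] }
  }
  activations <- unmixing %*% Xc
  cs <- structure(list(mixing = mixing, unmixing = unmixing,
                       activations = activations, center = ctr, fs = fs,
                       n_dims = n_dims),
                  class = "component_set")
  cs$spectra <- component_spectra(cs)
  cs
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("Component set: %d components over %d channels, %d samples\n",
              nrow(x$activations), nrow(x$mixing), ncol(x$activations)))
  invisible(x)
}

#' Welch spectra of a component set (or channel block)
#'
#' 1 s Hann segments with 50% overlap, restricted to 2-100 Hz, in dB.
#'
#' @param x a `component_set` or channels x samples matrix.
#' @param fs sampling rate (taken from the component set if present).
#' @param f_lo,f_hi frequency range, Hz.
#' @return list with `freq` and `db` (rows = components/channels).
#' @export
component_spectra <- function(x, fs = NULL, f_lo = 2, f_hi = 100) {
  if (inherits(x, "component_set")) {
    fs <- x$fs
    x <- x$activations
  }
  stopifnot(!is.null(fs))
  f_hi <- min(f_hi, 0.99 * fs / 2)
  sp <- apply(x, 1, function(v) {
    p <- welch_psd(v, fs, seg_sec = 1)
    keep <- p$freq >= f_lo & p$freq <= f_hi
    10 * log10(pmax(p$power[keep], 1e-300))
  })
  p0 <- welch_psd(x[1, ], fs, seg_sec = 1)
  keep <- p0$freq >= f_lo & p0$freq <= f_hi
  list(freq = p0$freq[keep], db = t(sp))
}

#' Linear spectral slope
#'
#' Ordinary least-squares slope of power (dB) against linear frequency (Hz);
#' near-zero slopes mark spectrally flat, noise-like components.
#'
#' @param freq frequencies, Hz.
#' @param db power spectrum, dB.
#' @return slope in dB/Hz.
#' @export
spectral_slope <- function(freq, db) {
  if (length(freq) < 2) stop("need at least 2 frequency points")
  unname(coef(lm(db ~ freq))[2])
}

#' Spectral match to a reference channel
#'
#' Coefficient of determination of the component spectrum (dB) regressed on a
#' polynomial of the reference spectrum (dB). An affine match gives R^2 = 1;
#' a constant reference is defined to match nothing (R^2 = 0).
#'
#' @param comp_db component spectrum, dB.
#' @param ref_db reference spectrum, dB (same frequency grid).
#' @param poly_order polynomial order (default 2).
#' @return R^2 in [0, 1].
#' @export
match_r2 <- function(comp_db, ref_db, poly_order = 2) {
  if (sd(ref_db) <= .Machine$double.eps || var(comp_db) == 0) return(0)
  fit <- lm(comp_db ~ poly(ref_db, degree = poly_order, raw = TRUE))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((comp_db - mean(comp_db))^2)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Reject components by spectral rules
#'
#' A component is rejected when its spectral slope is at or above
#' `slope_thresh` (flat, sensor-noise-like), or when its best polynomial match
#' against any noise-layer or EMG reference spectrum reaches `r2_thresh`
#' (artifact-matching). Reasons are recorded per component.
#'
#' @param cs a `component_set`.
#' @param noise_db,emg_db reference spectra matrices (rows = channels) on the
#'   component spectra's frequency grid; either may be NULL.
#' @param slope_thresh dB/Hz (default -0.06, inclusive).
#' @param r2_thresh R^2 threshold (default 0.99, inclusive).
#' @param poly_order polynomial order for [match_r2()].
#' @return list with `kept`, `rejected` (index vectors) and `report` data
#'   frame (component, slope, best_r2, decision, reason).
#' @export
reject_components <- function(cs, noise_db = NULL, emg_db = NULL,
                              slope_thresh = -0.06, r2_thresh = 0.99,
                              poly_order = 2) {
  sp <- cs$spectra
  nc <- nrow(sp$db)
  refs <- rbind(noise_db, emg_db)
  slope <- vapply(seq_len(nc), function(j)
    spectral_slope(sp$freq, sp$db[j, ]), 0)
  best_r2 <- vapply(seq_len(nc), function(j) {
    if (is.null(refs) || nrow(refs) == 0) return(0)
    max(vapply(seq_len(nrow(refs)), function(r)
      match_r2(sp$db[j, ], refs[r, ], poly_order), 0))
  }, 0)
  flat <- slope >= slope_thresh
  match <- best_r2 >= r2_thresh
  reason <- ifelse(flat & match, "flat+match",
                   ifelse(flat, "flat", ifelse(match, "match", "")))
  rejected <- which(flat | match)
  list(kept = setdiff(seq_len(nc), rejected), rejected = rejected,
       report = data.frame(component = seq_len(nc), slope = slope,
                           best_r2 = best_r2,
                           decision = ifelse(flat | match, "reject", "keep"),
                           reason = reason))
}

#' Back-project retained components to channel space
#'
#' @param cs a `component_set`.
#' @param kept indices of retained components (must be non-empty).
#' @param rows channel rows to return (default: all; pass the scalp rows of a
#'   stacked input to recover the cleaned scalp block).
#' @return channels x samples matrix including the removed channel means.
#' @export
back_project <- function(cs, kept, rows = NULL) {
  if (!length(kept)) stop("empty kept set")
  rows <- rows %||% seq_len(nrow(cs$mixing))
  out <- cs$mixing[rows, kept, drop = FALSE] %*%
    cs$activations[kept, , drop = FALSE]
  out + cs$center[rows]
}
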