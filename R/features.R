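# Spatio-temporal SVD feature reduction: class-balanced trial selection,
# spatial modes over channels, temporal modes over samples, 25 features.

#' Select a class-balanced subset of trials
#'
#' The majority class is limited to the minority count. `"spread"` takes
#' majority trials at evenly spaced positions across the whole acquisition
#' (deterministic); `"sequential"` takes the first n, a robustness check that
#' concentrates the majority selection early in the recording.
#'
#' @param labels Chronological class labels of the candidate trials (two
#'   classes).
#' @param scheme `"spread"` or `"sequential"`.
#' @param seed Kept for interface symmetry; both schemes are deterministic.
#' @return Sorted integer indices of the selected trials.
#' @export
balance_trials <- function(labels, scheme = c("spread", "sequential"),
                           seed = NULL) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("need exactly two classes present")
  counts <- table(labels)
  if (any(counts == 0)) stop("a class has zero trials")
  m <- min(counts)
  sel <- unlist(lapply(classes, function(cl) {
    v <- which(labels == cl)
    if (length(v) == m) return(v)
    if (scheme == "spread") v[round(seq(1, length(v), length.out = m))]
    else v[seq_len(m)]
  }))
  sort(sel)
}

# Fix SVD sign ambiguity: each basis vector's largest-|.| element positive.
fix_signs <- function(U) {
  s <- vapply(seq_len(ncol(U)), function(j) {
    sign(U[which.max(abs(U[, j])), j])
  }, numeric(1))
  s[s == 0] <- 1
  sweep(U, 2, s, "*")
}

#' Dominant spatial modes of epoched data
#'
#' SVD of the channels x (trials * samples) unfolding of the pooled
#' (both-condition) data; the top `k` left singular vectors form the spatial
#' basis and each trial is projected onto it. Labels are never consulted —
#' the reduction is unsupervised.
#'
#' @param data trials x channels x samples array.
#' @param k Number of spatial modes.
#' @return List: `basis` (channels x k), `projected` (trials x k x samples),
#'   `singular_values`, `var_explained`.
#' @export
spatial_modes <- function(data, k = 5L) {
  d <- dim(data)
  if (d[2] < k) stop("fewer channels than requested modes")
  M <- matrix(aperm(data, c(2, 1, 3)), nrow = d[2])  # ch x (trials*samples)
  sv <- svd(M)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (pos < k) {
    warning("rank ", pos, " < k; reducing k")
    k <- pos
  }
  U <- fix_signs(sv$u[, seq_len(k), drop = FALSE])
  proj <- array(NA_real_, c(d[1], k, d[3]))
  for (i in seq_len(d[1])) proj[i, , ] <- crossprod(U, data[i, , ])
  list(basis = U, projected = proj, singular_values = sv$d,
       var_explained = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2))
}

#' Dominant temporal modes and the flattened feature matrix
#'
#' SVD over the samples dimension of the pooled spatially-projected data;
#' each trial's k_spatial x samples map is reduced to k_spatial x k_temporal
#' coefficients and flattened spatial-major into one feature row.
#'
#' @param projected trials x k_spatial x samples array from [spatial_modes()].
#' @param k Number of temporal modes.
#' @return List: `basis` (samples x k), `X` (trials x (k_spatial * k))
#'   coefficient matrix, `singular_values`.
#' @export
temporal_modes <- function(projected, k = 5L) {
  d <- dim(projected)
  if (d[3] < k) stop("fewer samples than requested modes")
  M <- matrix(aperm(projected, c(3, 1, 2)), nrow = d[3]) # samples x (trials*ksp)
  sv <- svd(M)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (pos < k) {
    warning("rank ", pos, " < k; reducing k")
    k <- pos
  }
  V <- fix_signs(sv$u[, seq_len(k), drop = FALSE])
  X <- t(vapply(seq_len(d[1]), function(i) {
    C <- matrix(projected[i, , ], d[2], d[3]) %*% V   # ksp x kt
    as.vector(t(C))                                    # spatial-major
  }, numeric(d[2] * k)))
  list(basis = V, X = X, singular_values = sv$d)
}

#' Build the balanced spatio-temporal feature matrix from epochs
#'
#' Balances the two percepts, then reduces the selected trials to
#' `k_spatial * k_temporal` SVD features (25 at the defaults). Both bases are
#' estimated from the pooled selected trials, blind to the labels.
#'
#' @param ep A baseline-corrected `epoch_set`.
#' @param k_spatial,k_temporal Mode counts.
#' @param scheme Balancing scheme, see [balance_trials()].
#' @param zscore Z-score the feature columns (off by default).
#' @param seed Passed to [balance_trials()].
#' @return A `feature_matrix`: `X` (trials x features), `y` (factor),
#'   `spatial_basis`, `temporal_basis`, `selected_trials` (indices into the
#'   epoch set).
#' @export
build_features <- function(ep, k_spatial = 5L, k_temporal = 5L,
                           scheme = "spread", zscore = FALSE, seed = NULL) {
  cand <- which(ep$retained)
  sel <- cand[balance_trials(ep$labels[cand], scheme, seed)]
  data <- ep$data[sel, , , drop = FALSE]
  sp <- spatial_modes(data, k_spatial)
  tm <- temporal_modes(sp$projected, k_temporal)
  X <- tm$X
  if (zscore) X <- scale(X)
  structure(list(X = X, y = factor(ep$labels[sel]),
                 spatial_basis = sp$basis, temporal_basis = tm$basis,
                 selected_trials = sel),
            class = "feature_matrix")
}

#' Temporal-only features for a single source time course
#'
#' Used for ROI-restricted analyses where one source is carried forward: each
#' trial's time course is reduced to its coefficients on the pooled temporal
#' SVD basis.
#'
#' @param tc trials x samples matrix.
#' @param k Number of temporal modes.
#' @return List: `X` (trials x k), `basis` (samples x k).
#' @export
temporal_features <- function(tc, k = 5L) {
  proj <- array(tc, c(nrow(tc), 1L, ncol(tc)))
  tm <- temporal_modes(proj, k)
  list(X = tm$X, basis = tm$basis)
}
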