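# Group-level right-temporal time-course analysis: shared first principal
# component per subject and state, difference time courses, and cluster-level
# family-wise-error control by sign-flip permutation of cluster mass.

#' Right-temporal sensor mask from channel geometry
#'
#' Selects channels over the right temporal region by position: lateral on
#' the right (`x` beyond a fraction of the head radius) and below the vertex.
#' For real recordings a named channel list can be supplied downstream
#' instead.
#'
#' @param channel_pos sensors x 3 positions (+x right, +z superior).
#' @param x_frac Minimum `x` as a fraction of the maximal sensor radius.
#' @param z_max_frac Maximum `z` as a fraction of the maximal sensor radius.
#' @return Logical mask over channels.
#' @export
right_temporal_mask <- function(channel_pos, x_frac = 0.35, z_max_frac = 0.6) {
  r <- max(sqrt(rowSums(channel_pos^2)))
  channel_pos[, 1] > x_frac * r & channel_pos[, 3] < z_max_frac * r
}

#' First principal component of right-temporal evoked responses
#'
#' PCA over the masked channels of the evoked data; by default the two
#' states' evoked responses are concatenated in time so both share a single
#' spatial component, whose per-state time courses are returned. Component
#' sign is fixed by making the largest-|loading| channel positive.
#'
#' @param pair An `evoked_pair`.
#' @param mask Logical/integer channel mask (>= 2 channels); defaults to
#'   [right_temporal_mask()] on the pair's geometry.
#' @param mode `"joint"` (shared component, default) or `"separate"`
#'   (one PCA per state).
#' @return List: `pc_gallop`, `pc_segregated` (time courses), `loadings`
#'   (per state when separate), `var_explained`.
#' @export
right_temporal_pc <- function(pair, mask = NULL,
                              mode = c("joint", "separate")) {
  mode <- match.arg(mode)
  if (is.null(mask)) mask <- right_temporal_mask(pair$channel_pos)
  Eg <- pair$evoked_gallop[mask, , drop = FALSE]
  Es <- pair$evoked_segregated[mask, , drop = FALSE]
  if (nrow(Eg) < 2L) stop("mask must select >= 2 sensors")
  if (all(Eg == 0) && all(Es == 0)) stop("all-zero evoked responses")
  pc_of <- function(M) {
    Mc <- M - rowMeans(M)
    sv <- svd(Mc, nu = 1, nv = 0)
    u <- fix_signs(sv$u)
    list(u = u, var = sv$d[1]^2 / sum(sv$d^2))
  }
  if (mode == "joint") {
    p <- pc_of(cbind(Eg, Es))
    list(pc_gallop = drop(crossprod(p$u, Eg)),
         pc_segregated = drop(crossprod(p$u, Es)),
         loadings = p$u, var_explained = p$var, mode = mode)
  } else {
    pg <- pc_of(Eg); ps <- pc_of(Es)
    list(pc_gallop = drop(crossprod(pg$u, Eg)),
         pc_segregated = drop(crossprod(ps$u, Es)),
         loadings = list(gallop = pg$u, segregated = ps$u),
         var_explained = c(gallop = pg$var, segregated = ps$var), mode = mode)
  }
}

# Supra-threshold clusters of a t time course: runs of |t| > tcrit, scored by
# mass (sum of |t| in the run). Returns start/end sample and mass.
find_clusters <- function(tvals, tcrit) {
  above <- abs(tvals) > tcrit
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(i)
               sum(abs(tvals[starts[i]:ends[i]])), numeric(1)))
}

max_cluster_mass <- function(tvals, tcrit) {
  cl <- find_clusters(tvals, tcrit)
  if (is.null(cl)) 0 else max(cl$mass)
}

#' Cluster-corrected group test of a difference time course
#'
#' Pointwise one-sample t-test across subjects; contiguous runs exceeding the
#' two-sided uncorrected threshold form clusters scored by mass (summed |t|).
#' Family-wise error is controlled against the maximum-cluster-mass null from
#' random sign flips of whole subjects — flipping entire time courses, so each
#' subject's temporal autocorrelation is preserved under the null.
#'
#' @param per_subject_diff subjects x samples matrix of difference time
#'   courses (gallop minus segregated first principal component).
#' @param alpha_cluster Cluster-level FWE threshold.
#' @param p_uncorrected Two-sided pointwise threshold forming clusters.
#' @param n_perm Number of sign-flip permutations (>= 100 required).
#' @param fs Sampling rate mapping samples to ms.
#' @param seed Integer seed for the sign flips.
#' @return A `group_timecourse`: `t` (pointwise), `group_mean`, `sem`,
#'   `clusters` data.frame (`start_ms`, `end_ms` half-open, `cluster_stat`,
#'   `p_fwe`, `significant`), `tcrit`, `null_max_mass`.
#' @export
cluster_test <- function(per_subject_diff, alpha_cluster = 0.05,
                         p_uncorrected = 0.005, n_perm = 1000L, fs = 300,
                         seed = 1L) {
  X <- as.matrix(per_subject_diff)
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 subjects")
  if (n_perm < 100L) stop("n_perm < 100 gives an unstable null; refusing")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  tvals <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  tcrit <- stats::qt(1 - p_uncorrected / 2, n - 1)
  obs <- find_clusters(tvals, tcrit)
  m2 <- colMeans(X^2)
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    mp <- signs %*% X / n
    vp <- pmax((matrix(m2, n_perm, ncol(X), byrow = TRUE) - mp^2), 0) *
      n / (n - 1)
    tp <- ifelse(vp > 0, mp / sqrt(vp / n), 0)
    apply(tp, 1, max_cluster_mass, tcrit = tcrit)
  })
  clusters <- if (is.null(obs)) {
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               cluster_stat = numeric(0), p_fwe = numeric(0),
               significant = logical(0))
  } else {
    p_fwe <- vapply(obs$mass, function(mm)
      (1 + sum(null_max >= mm)) / (1 + n_perm), numeric(1))
    data.frame(start_ms = (obs$start - 1) / fs * 1000,
               end_ms = obs$end / fs * 1000,
               cluster_stat = obs$mass, p_fwe = p_fwe,
               significant = p_fwe <= alpha_cluster)
  }
  structure(list(t = tvals, group_mean = m, sem = s / sqrt(n),
                 clusters = clusters, tcrit = tcrit,
                 null_max_mass = null_max, fs = fs, n_subjects = n),
            class = "group_timecourse")
}

#' Group analysis from per-subject evoked pairs
#'
#' Extracts each subject's right-temporal first-PC time course per state,
#' stacks the gallop-minus-segregated differences, and runs the
#' cluster-corrected group test. Also returns plot-ready mean +/- 1 and 2 SEM
#' bands with the per-subject traces.
#'
#' @param pairs List of `evoked_pair` objects (one per subject).
#' @param mask Optional shared channel mask.
#' @param ... Passed to [cluster_test()].
#' @return List: `per_subject_diff`, `test` (a `group_timecourse`),
#'   `time_ms`, `band` (mean, sem).
#' @export
group_timecourse <- function(pairs, mask = NULL, ...) {
  diffs <- t(vapply(pairs, function(p) {
    pc <- right_temporal_pc(p, mask)
    pc$pc_gallop - pc$pc_segregated
  }, numeric(ncol(pairs[[1]]$evoked_gallop))))
  fs <- pairs[[1]]$fs_hz
  test <- cluster_test(diffs, fs = fs, ...)
  list(per_subject_diff = diffs, test = test,
       time_ms = (seq_len(ncol(diffs)) - 1) / fs * 1000,
       band = list(mean = test$group_mean, sem = test$sem))
}
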