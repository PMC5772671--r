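# Minimum-norm source analysis: temporal-mode reduction, ridge-form inverse
# operator, posterior-variance source ranking, distance-constrained top-k
# selection, and sphere-ROI restricted analyses.

#' Source space: grid positions plus lead field
#'
#' @param positions n_sources x 3 MNI coordinates (mm).
#' @param lead_field sensors x sources matrix (fixed orientation).
#' @param labels Optional per-source ROI tags.
#' @return A `source_space`.
#' @export
source_space <- function(positions, lead_field, labels = NULL) {
  positions <- as.matrix(positions)
  lead_field <- as.matrix(lead_field)
  if (nrow(positions) != ncol(lead_field))
    stop("positions rows must match lead_field columns")
  if (any(!is.finite(positions))) stop("non-finite source coordinates")
  if (any(colSums(lead_field^2) == 0)) stop("zero-norm lead-field column")
  structure(list(positions = positions, lead_field = lead_field,
                 labels = labels),
            class = "source_space")
}

#' Minimum-norm inversion of epoched sensor data
#'
#' The sensor data are first reduced to their top `n_temporal_modes` temporal
#' SVD modes (basis estimated from the pooled retained trials), then each
#' trial is mapped to sources with the ridge-form minimum-norm operator
#' `J = L' (L L' + lambda I)^-1 Y`. The per-source posterior variance is the
#' variance of its reconstructed time course pooled over retained trials,
#' and is what ranks sources downstream.
#'
#' @param ep An `epoch_set` (only retained trials are inverted).
#' @param space A [source_space()].
#' @param lambda_reg Regularization; default
#'   `trace(L L') / (n_sensors * snr^2)`.
#' @param n_temporal_modes Temporal modes kept before inversion (16 by
#'   default); use `NULL` to skip the reduction.
#' @param snr Assumed amplitude SNR for the default lambda.
#' @return A `source_epochs`: `J` (trials x sources x samples, retained trials
#'   only), `posterior_variance`, `inverse_operator`, `lambda_reg`,
#'   `temporal_basis`, `trials` (indices into the epoch set), `y` (labels of
#'   those trials), `positions`.
#' @export
min_norm_invert <- function(ep, space, lambda_reg = NULL,
                            n_temporal_modes = 16L, snr = 3) {
  sel <- which(ep$retained)
  d <- dim(ep$data)
  L <- space$lead_field
  if (nrow(L) != d[2]) stop("sensor dimension does not match lead field")
  G <- tcrossprod(L)                      # sensors x sensors
  if (is.null(lambda_reg)) lambda_reg <- sum(diag(G)) / (nrow(L) * snr^2)
  if (lambda_reg <= 0 && rcond_sym(G) < 1e-12)
    stop("lambda_reg must be > 0 for a rank-deficient lead field")
  Vt <- NULL
  data <- ep$data[sel, , , drop = FALSE]
  if (!is.null(n_temporal_modes) && n_temporal_modes < d[3]) {
    M <- matrix(aperm(data, c(3, 1, 2)), nrow = d[3])
    sv <- svd(M, nu = min(n_temporal_modes, d[3]), nv = 0)
    Vt <- sv$u[, seq_len(min(n_temporal_modes, ncol(sv$u))), drop = FALSE]
  }
  K <- t(solve(G + diag(lambda_reg, nrow(G)), L))   # sources x sensors
  n_src <- ncol(L)
  J <- array(NA_real_, c(length(sel), n_src, d[3]))
  for (i in seq_along(sel)) {
    Y <- data[i, , ]
    if (!is.null(Vt)) Y <- Y %*% Vt %*% t(Vt)
    J[i, , ] <- K %*% Y
  }
  pv <- apply(J, 2, function(m) stats::var(as.vector(m)))
  structure(list(J = J, posterior_variance = pv, inverse_operator = K,
                 lambda_reg = lambda_reg, temporal_basis = Vt,
                 trials = sel, y = ep$labels[sel],
                 positions = space$positions, fs_hz = ep$fs_hz),
            class = "source_epochs")
}

#' Select top-variance sources with a minimum-separation constraint
#'
#' Greedy: repeatedly take the highest-posterior-variance source at least
#' `min_dist_mm` from every already-selected source, until `k` are found or
#' the grid is exhausted.
#'
#' @param posterior_variance Per-source variance.
#' @param positions n_sources x 3 coordinates (mm).
#' @param k Number of sources wanted.
#' @param min_dist_mm Minimum pairwise separation.
#' @return Integer indices, ordered by selection (descending variance).
#' @export
select_top_sources <- function(posterior_variance, positions, k = 5L,
                               min_dist_mm = 15) {
  positions <- as.matrix(positions)
  ord <- order(posterior_variance, decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == k) break
    if (!length(chosen)) { chosen <- i; next }
    dists <- sqrt(rowSums((positions[chosen, , drop = FALSE] -
                             matrix(positions[i, ], length(chosen), 3,
                                    byrow = TRUE))^2))
    if (all(dists >= min_dist_mm)) chosen <- c(chosen, i)
  }
  if (length(chosen) < k)
    warning("only ", length(chosen), " source(s) satisfy the separation")
  stopifnot(pairwise_min_dist(positions[chosen, , drop = FALSE]) >=
              min_dist_mm || length(chosen) < 2L)
  chosen
}

pairwise_min_dist <- function(P) {
  if (nrow(P) < 2L) return(Inf)
  min(stats::dist(P))
}

#' Spherical region-of-interest specification
#'
#' @param name ROI label.
#' @param center MNI coordinates (mm).
#' @param radius_mm Sphere radius.
#' @return A `roi_spec`.
#' @export
roi_spec <- function(name, center, radius_mm = 10) {
  if (radius_mm <= 0) stop("radius must be > 0")
  structure(list(name = name, center = as.numeric(center),
                 radius_mm = radius_mm),
            class = "roi_spec")
}

#' A-priori auditory/parietal ROI set
#'
#' Right auditory cortex (54, -14, 11), left auditory cortex (-49, -20, 5)
#' and right posterior intraparietal sulcus (34, -72, 38), each a sphere of
#' the given radius.
#'
#' @param radius_mm Sphere radius applied to all three.
#' @return Named list of [roi_spec()] objects.
#' @export
default_rois <- function(radius_mm = 10) {
  list(rAC = roi_spec("rAC", c(54, -14, 11), radius_mm),
       lAC = roi_spec("lAC", c(-49, -20, 5), radius_mm),
       rPIPS = roi_spec("rPIPS", c(34, -72, 38), radius_mm))
}

#' Read an ROI table from a plain tabular file
#'
#' Expects columns `name`, `x`, `y`, `z`, `radius` (whitespace- or
#' comma-separated with a header row).
#'
#' @param path File path.
#' @return Named list of [roi_spec()] objects.
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl("\\.csv$", path)) "," else "")
  need <- c("name", "x", "y", "z", "radius")
  if (!all(need %in% names(tab)))
    stop("ROI table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    roi_spec(tab$name[i], c(tab$x[i], tab$y[i], tab$z[i]), tab$radius[i]))
  names(out) <- tab$name
  out
}

#' Restrict source epochs to the best source inside an ROI sphere
#'
#' Selects the maximum-posterior-variance grid source within the sphere and
#' returns its single-trial time courses; downstream ROI features use
#' temporal SVD modes of this one source.
#'
#' @param src A `source_epochs` from [min_norm_invert()].
#' @param roi A [roi_spec()].
#' @return List: `tc` (trials x samples), `source_index`, `y`, `roi`.
#' @export
roi_restrict <- function(src, roi) {
  d2 <- rowSums(sweep(src$positions, 2, roi$center)^2)
  inside <- which(d2 <= roi$radius_mm^2)
  if (!length(inside))
    stop("ROI '", roi$name, "' contains no grid source")
  best <- inside[which.max(src$posterior_variance[inside])]
  list(tc = src$J[, best, ], source_index = best, y = src$y, roi = roi)
}

#' Balance source epochs across the two percepts
#'
#' Applies [balance_trials()] to the labels of a `source_epochs` object and
#' subsets the reconstructed trials accordingly, so ROI and top-source
#' analyses see equal class counts.
#'
#' @param src A `source_epochs`.
#' @param scheme Balancing scheme, see [balance_trials()].
#' @return The subsetted `source_epochs`.
#' @export
balance_source_trials <- function(src, scheme = "spread") {
  sel <- balance_trials(src$y, scheme)
  src$J <- src$J[sel, , , drop = FALSE]
  src$y <- src$y[sel]
  src$trials <- src$trials[sel]
  src
}

#' CVA screen over a set of ROIs
#'
#' For each ROI: restrict to its best source, build temporal SVD features,
#' and run CVA of features against the percept labels. Failures in single
#' ROIs are reported and skipped so a screen over many regions completes.
#'
#' @param src A `source_epochs` whose trials are already class-balanced.
#' @param rois Named list of [roi_spec()] objects.
#' @param k_temporal Temporal modes per ROI.
#' @param alpha Significance threshold.
#' @param method CVA p-value method.
#' @return The [cva_screen()] data.frame over the ROIs (failed ROIs carry
#'   `NA` statistics).
#' @export
multi_roi_screen <- function(src, rois, k_temporal = 5L, alpha = 0.05,
                             method = "bartlett") {
  sets <- list()
  failed <- character(0)
  for (nm in names(rois)) {
    res <- tryCatch({
      rr <- roi_restrict(src, rois[[nm]])
      tf <- temporal_features(rr$tc, k_temporal)
      list(X = tf$X, y = rr$y)
    }, error = function(e) {
      warning("ROI '", nm, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, nm) else sets[[nm]] <- res
  }
  out <- cva_screen(sets, alpha, method)
  if (length(failed)) {
    pad <- data.frame(name = failed, wilks_lambda = NA, chi2 = NA,
                      df = NA, p = NA, significant = NA)
    n_sig <- attr(out, "n_significant")
    out <- rbind(out, pad)
    attr(out, "n_significant") <- n_sig
  }
  out
}
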