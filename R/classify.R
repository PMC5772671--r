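# SVM classification: repeated stratified 10-fold cross-validation, binomial
# above-chance inference, and the two-stage logarithmic grid search for the
# RBF kernel-scale / box-constraint pair.

#' SVM cross-validation specification
#'
#' The RBF kernel is parameterized as
#' `K(x, x') = exp(-||x - x'||^2 / (2 * kernel_scale^2))`, so a larger kernel
#' scale gives a smoother decision function; `box_constraint` is the usual
#' soft-margin cost C.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param kernel_scale RBF kernel width (ignored for linear).
#' @param box_constraint Soft-margin cost.
#' @param folds Cross-validation folds.
#' @param repetitions Number of re-randomized CV repetitions.
#' @param seed Integer seed for fold assignment.
#' @return An `svm_spec`.
#' @export
svm_spec <- function(kernel = c("linear", "rbf"), kernel_scale = 1,
                     box_constraint = 1, folds = 10L, repetitions = 100L,
                     seed = 1L) {
  kernel <- match.arg(kernel)
  if (folds < 2L) stop("folds must be >= 2")
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (kernel_scale <= 0 || box_constraint <= 0)
    stop("kernel_scale and box_constraint must be positive")
  structure(list(kernel = kernel, kernel_scale = kernel_scale,
                 box_constraint = box_constraint, folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "svm_spec")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# to folds round-robin, so every fold keeps the class balance.
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

fit_predict_svm <- function(X, y, train, test, spec,
                            kernel_scale = spec$kernel_scale,
                            box_constraint = spec$box_constraint) {
  if (spec$kernel == "linear") {
    m <- e1071::svm(X[train, , drop = FALSE], y[train], kernel = "linear",
                    cost = box_constraint, scale = FALSE)
  } else {
    m <- e1071::svm(X[train, , drop = FALSE], y[train], kernel = "radial",
                    gamma = 1 / (2 * kernel_scale^2),
                    cost = box_constraint, scale = FALSE)
  }
  stats::predict(m, X[test, , drop = FALSE])
}

# One full k-fold pass; returns overall accuracy on the held-out trials.
cv_once <- function(X, y, spec, fold_assign,
                    kernel_scale = spec$kernel_scale,
                    box_constraint = spec$box_constraint) {
  correct <- logical(length(y))
  for (k in sort(unique(fold_assign))) {
    test <- which(fold_assign == k)
    train <- which(fold_assign != k)
    if (length(unique(y[train])) < 2L) return(NA_real_)
    pred <- fit_predict_svm(X, y, train, test, spec,
                            kernel_scale, box_constraint)
    correct[test] <- pred == y[test]
  }
  mean(correct)
}

#' Repeated cross-validated SVM accuracy with binomial inference
#'
#' Stratified k-fold cross-validation, re-randomized each repetition from the
#' seeded stream; the reported accuracy is the mean over repetitions of the
#' held-out-trial accuracy. Fold models never see their test trials — bases
#' and hyperparameters are fixed before this function is called.
#'
#' @param F A `feature_matrix`, or a list with `X` and `y` (balanced classes).
#' @param spec An [svm_spec()].
#' @param chance Chance level for the binomial test.
#' @return A `classification_result`: `mean_accuracy`,
#'   `per_repetition_accuracies`, `n_trials`, `p_binomial`, `spec`.
#' @export
crossval_accuracy <- function(F, spec = svm_spec(), chance = 0.5) {
  X <- as.matrix(F$X); y <- factor(F$y)
  n <- nrow(X)
  if (n < spec$folds) stop("fewer trials than folds")
  accs <- with_seed(spec$seed, {
    vapply(seq_len(spec$repetitions), function(r) {
      for (attempt in 1:20) {
        fa <- stratified_folds(y, spec$folds)
        a <- cv_once(X, y, spec, fa)
        if (!is.na(a)) return(a)
      }
      stop("could not stratify a class into every training fold")
    }, numeric(1))
  })
  mean_acc <- mean(accs)
  structure(list(mean_accuracy = mean_acc,
                 per_repetition_accuracies = accs,
                 n_trials = n,
                 p_binomial = binomial_above_chance(mean_acc, n, chance),
                 chosen_params = list(kernel_scale = spec$kernel_scale,
                                      box_constraint = spec$box_constraint),
                 spec = spec),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s SVM: %.1f%% correct over %d trials, binomial p = %.3g\n",
              x$spec$kernel, 100 * x$mean_accuracy, x$n_trials, x$p_binomial))
  invisible(x)
}

#' One-sided binomial test of above-chance classification
#'
#' Treats the mean cross-validated accuracy over all trials as `k` successes
#' out of `n` Bernoulli(chance) trials and reports the upper-tail p-value
#' `P(K >= k)`. (Anticonservative under cross-validation dependence; see
#' [permutation_pvalue()] for a calibrated alternative.)
#'
#' @param mean_accuracy Fraction correct.
#' @param n_trials Number of trials.
#' @param chance Null success probability.
#' @return p-value.
#' @export
binomial_above_chance <- function(mean_accuracy, n_trials, chance = 0.5) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  k <- round(mean_accuracy * n_trials)
  stats::pbinom(k - 1, n_trials, chance, lower.tail = FALSE)
}

#' Permutation p-value for cross-validated accuracy
#'
#' Re-runs the cross-validation with label permutations to build a null for
#' the mean accuracy, giving an inference calibrated under the CV dependence
#' that the binomial test ignores.
#'
#' @param F Feature matrix (as in [crossval_accuracy()]).
#' @param spec An [svm_spec()]; `repetitions` is forced to 1 per permutation.
#' @param n_perm Number of permutations.
#' @param observed Optional precomputed observed mean accuracy.
#' @return List with `p`, `observed`, `null_accuracies`.
#' @export
permutation_pvalue <- function(F, spec = svm_spec(), n_perm = 200L,
                               observed = NULL) {
  X <- as.matrix(F$X); y <- factor(F$y)
  if (is.null(observed))
    observed <- crossval_accuracy(F, spec)$mean_accuracy
  spec1 <- spec; spec1$repetitions <- 1L
  null_acc <- with_seed(spec$seed + 77L, {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      fa <- stratified_folds(yp, spec$folds)
      cv_once(X, yp, spec1, fa)
    }, numeric(1))
  })
  list(p = (1 + sum(null_acc >= observed, na.rm = TRUE)) / (1 + n_perm),
       observed = observed, null_accuracies = null_acc)
}

#' Two-stage grid specification for the RBF search
#'
#' Stage 1 spans kernel scale 1e-3 to 1e15 and box constraint 1e-3 to 1e9 on
#' a 9 x 9 logarithmically equally spaced grid; stage 2 re-searches a 9 x 9
#' log grid spanning +/- one stage-1 grid step around the stage-1 winner
#' (clipped at the stage-1 bounds).
#'
#' @param grid_size Points per parameter per stage.
#' @param kernel_scale_range,box_constraint_range Stage-1 bounds.
#' @return A `grid_spec`.
#' @export
grid_spec <- function(grid_size = 9L,
                      kernel_scale_range = c(1e-3, 1e15),
                      box_constraint_range = c(1e-3, 1e9)) {
  if (any(c(kernel_scale_range, box_constraint_range) <= 0))
    stop("grid bounds must be positive")
  structure(list(grid_size = as.integer(grid_size),
                 kernel_scale_range = kernel_scale_range,
                 box_constraint_range = box_constraint_range),
            class = "grid_spec")
}

log_grid <- function(range, n) {
  if (n == 1L || range[1] == range[2]) return(rep(sqrt(prod(range)), 1L))
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

# Evaluate every (ks, bc) pair with a single k-fold CV under one shared fold
# assignment; ties broken toward the simplest model: lowest box constraint,
# then lowest kernel scale.
eval_grid <- function(X, y, ks_vals, bc_vals, spec, fold_assign) {
  tab <- expand.grid(kernel_scale = ks_vals, box_constraint = bc_vals,
                     KEEP.OUT.ATTRS = FALSE)
  tab$accuracy <- vapply(seq_len(nrow(tab)), function(i) {
    cv_once(X, y, spec, fold_assign,
            kernel_scale = tab$kernel_scale[i],
            box_constraint = tab$box_constraint[i])
  }, numeric(1))
  ord <- order(-tab$accuracy, tab$box_constraint, tab$kernel_scale)
  list(table = tab, best = tab[ord[1], ])
}

#' Two-stage RBF hyperparameter grid search
#'
#' Stage 1: one stratified k-fold CV per point of the 9 x 9 log grid, all
#' points sharing a single fold assignment drawn from the seeded stream.
#' Stage 2: a fresh 9 x 9 log grid spanning one stage-1 step either side of
#' the stage-1 winner (clipped to the stage-1 bounds), evaluated the same way
#' with a fresh fold assignment. Ties prefer the lowest box constraint, then
#' the lowest kernel scale.
#'
#' @param F Feature matrix (list with `X`, `y`).
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param folds CV folds per evaluation.
#' @return List: `kernel_scale`, `box_constraint`, `stage1`, `stage2`
#'   (evaluation tables), `fold_seed_stage2` (for oracle re-checks).
#' @export
grid_search_rbf <- function(F, grid = grid_spec(), seed = 1L, folds = 10L) {
  X <- as.matrix(F$X); y <- factor(F$y)
  spec <- svm_spec("rbf", folds = folds, repetitions = 1L, seed = seed)
  n <- grid$grid_size
  ks1 <- log_grid(grid$kernel_scale_range, n)
  bc1 <- log_grid(grid$box_constraint_range, n)
  fa1 <- with_seed(seed, stratified_folds(y, folds))
  s1 <- eval_grid(X, y, ks1, bc1, spec, fa1)
  step_ks <- if (n > 1) ks1[2] / ks1[1] else 1
  step_bc <- if (n > 1) bc1[2] / bc1[1] else 1
  clip <- function(r, bounds) c(max(r[1], bounds[1]), min(r[2], bounds[2]))
  ks_r <- clip(c(s1$best$kernel_scale / step_ks,
                 s1$best$kernel_scale * step_ks), grid$kernel_scale_range)
  bc_r <- clip(c(s1$best$box_constraint / step_bc,
                 s1$best$box_constraint * step_bc), grid$box_constraint_range)
  ks2 <- log_grid(ks_r, n)
  bc2 <- log_grid(bc_r, n)
  fa2 <- with_seed(seed + 1L, stratified_folds(y, folds))
  s2 <- eval_grid(X, y, ks2, bc2, spec, fa2)
  list(kernel_scale = s2$best$kernel_scale,
       box_constraint = s2$best$box_constraint,
       stage1 = s1$table, stage2 = s2$table,
       stage2_fold_assign = fa2)
}

#' Full non-linear SVM analysis: grid search then repeated CV
#'
#' @param F Feature matrix.
#' @param grid A [grid_spec()].
#' @param spec An [svm_spec()] giving folds/repetitions/seed; the kernel is
#'   forced to `"rbf"` and the searched parameters are filled in.
#' @return A `classification_result` with `chosen_params` from the search.
#' @export
rbf_classify <- function(F, grid = grid_spec(), spec = svm_spec("rbf")) {
  gs <- grid_search_rbf(F, grid, seed = spec$seed, folds = spec$folds)
  spec$kernel <- "rbf"
  spec$kernel_scale <- gs$kernel_scale
  spec$box_constraint <- gs$box_constraint
  res <- crossval_accuracy(F, spec)
  res$grid_search <- gs
  res
}
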