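#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random positive outranks a random
#' negative, computed from midranks so ties count 1/2. The curve lists
#' (FPR, TPR) at every distinct score threshold, from (0,0) to (1,1).
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels 0/1 (or two-level) labels; both classes required.
#' @return List with `auc` and `curve` (data frame `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop("both classes must be present")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)                     # midranks handle ties
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Assemble a classification design from a cohort
#'
#' Selects the two groups of a pairwise contrast and the requested feature
#' set: `FA` (ROI-mean FA), a single ALPS laterality (`ALPS_L`, `ALPS_R`,
#' `ALPS_Bi`), or FA combined with one ALPS laterality (`FA+ALPS_L`, ...).
#' Rows with a missing feature are dropped (count returned). Features are
#' returned unstandardized; z-scoring happens inside the evaluation loop on
#' training data only.
#'
#' @param cohort Cohort data frame with `group` and the feature columns.
#' @param feature_set One of `FA`, `ALPS_L`, `ALPS_R`, `ALPS_Bi`,
#'   `FA+ALPS_L`, `FA+ALPS_R`, `FA+ALPS_Bi`.
#' @param pair Character vector of two group labels; the second is coded 1.
#' @return List with `X` (matrix), `y` (0/1 integer), `n_dropped`.
#' @export
build_features <- function(cohort, feature_set, pair) {
  sets <- list(
    FA = "FA_mean", ALPS_L = "L_ALPS", ALPS_R = "R_ALPS",
    ALPS_Bi = "Bi_ALPS",
    `FA+ALPS_L` = c("FA_mean", "L_ALPS"),
    `FA+ALPS_R` = c("FA_mean", "R_ALPS"),
    `FA+ALPS_Bi` = c("FA_mean", "Bi_ALPS"))
  if (!feature_set %in% names(sets))
    stop("unknown feature set '", feature_set, "'; one of: ",
         paste(names(sets), collapse = ", "))
  cols <- sets[[feature_set]]
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop("missing feature columns: ",
                         paste(miss, collapse = ", "))
  sel <- cohort$group %in% pair
  sub <- cohort[sel, , drop = FALSE]
  if (length(unique(sub$group[!is.na(sub$group)])) < 2L)
    stop("both groups of the pair must be present")
  keep <- stats::complete.cases(sub[, cols, drop = FALSE])
  sub <- sub[keep, , drop = FALSE]
  y <- as.integer(sub$group == pair[2])
  if (min(table(y)) < 10L)
    stop("each group needs >= 10 subjects with complete features")
  X <- as.matrix(sub[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = y, n_dropped = sum(!keep))
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Decision scores of a linear/RBF SVM oriented so that higher = class 1.
svm_scores <- function(fit, newdata, positive = "1") {
  pr <- attr(stats::predict(fit, newdata, decision.values = TRUE),
             "decision.values")
  s <- drop(pr)
  # e1071 orients decision values toward the first factor level of y
  if (grepl(paste0("^", positive, "/"), colnames(pr)[1])) s else -s
}

train_scale <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0] <- 1
  list(tr = scale(Xtr, mu, sd), te = scale(Xte, mu, sd))
}

# Mean 5-fold CV AUC on the training portion for one cost value.
cv_auc <- function(X, y, cost, folds, kernel) {
  k <- max(folds)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      return(NA_real_)
    sc <- train_scale(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fit <- e1071::svm(sc$tr, factor(y[tr], levels = c(0, 1)),
                      kernel = kernel, cost = cost, scale = FALSE)
    roc_auc(svm_scores(fit, sc$te), y[te])$auc
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Repeated-split SVM evaluation with ROC/AUC
#'
#' The disease-classification protocol: per repeat, a stratified 4:1
#' train/test split; 5-fold cross-validation on the training portion
#' selects the SVM cost from a fixed grid; the model is refit on the full
#' training set (features z-scored with training statistics only) and its
#' decision scores on the held-out fifth give one test ROC/AUC. The mean
#' AUC over repeats (default 100) and its 2.5/97.5 percentile interval are
#' reported, together with a pooled ROC curve over all repeats. All
#' randomness derives from `seed` (per-repeat seeds are `seed * 1000 + r`).
#'
#' @param X Feature matrix (subjects x features).
#' @param y 0/1 labels.
#' @param n_repeats Number of split repeats.
#' @param test_fraction Held-out fraction per repeat (default 0.2 = 4:1).
#' @param cv_folds Folds of the inner cost-selection CV.
#' @param cost_grid Candidate SVM regularization constants.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param seed Integer seed.
#' @return A `classification_result` list: `mean_auc`, `ci` (2.5/97.5
#'   percentiles), `aucs` (per repeat), `costs` (chosen per repeat),
#'   `pooled_roc` (data frame), `n`, `n_repeats`.
#' @export
svm_repeated_eval <- function(X, y, n_repeats = 100L, test_fraction = 0.2,
                              cv_folds = 5L,
                              cost_grid = c(0.01, 0.1, 1, 10, 100),
                              kernel = "linear", seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (min(table(y)) < cv_folds)
    stop("too few subjects in a class for ", cv_folds, "-fold CV")
  aucs <- numeric(n_repeats)
  costs <- numeric(n_repeats)
  pooled_scores <- list(); pooled_labels <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(as.integer(seed) * 1000L + r)
    for (attempt in 1:10) {
      te <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(length(idx) * test_fraction)))
      }))
      tr <- setdiff(seq_along(y), te)
      if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) break
      if (attempt == 10) stop("could not draw a stratified split with both ",
                              "classes after 10 attempts")
    }
    folds <- stratified_folds(y[tr], cv_folds)
    cvs <- vapply(cost_grid,
                  function(cc) cv_auc(X[tr, , drop = FALSE], y[tr], cc,
                                      folds, kernel), 0)
    best <- cost_grid[which.max(cvs)]    # ties: smallest cost wins
    sc <- train_scale(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fit <- e1071::svm(sc$tr, factor(y[tr], levels = c(0, 1)),
                      kernel = kernel, cost = best, scale = FALSE)
    s <- svm_scores(fit, sc$te)
    aucs[r] <- roc_auc(s, y[te])$auc
    costs[r] <- best
    pooled_scores[[r]] <- s; pooled_labels[[r]] <- y[te]
  }
  pooled <- roc_auc(unlist(pooled_scores), unlist(pooled_labels))
  structure(list(
    mean_auc = mean(aucs),
    ci = stats::quantile(aucs, c(0.025, 0.975), names = FALSE),
    aucs = aucs, costs = costs, pooled_roc = pooled$curve,
    n = length(y), n_repeats = n_repeats), class = "classification_result")
}

#' Run the full pairwise classification experiment
#'
#' Evaluates the given feature sets on the three pairwise group contrasts
#' (NC vs MCI, MCI vs AD, NC vs AD) with [svm_repeated_eval()].
#'
#' @param cohort Cohort data frame.
#' @param feature_sets Character vector of feature-set names (see
#'   [build_features()]).
#' @param pairs List of 2-vectors of group labels.
#' @param ... Passed to [svm_repeated_eval()].
#' @param seed Integer base seed; each (pair, set) cell gets a distinct
#'   derived seed.
#' @return Data frame with one row per (pair, feature set): `mean_auc`,
#'   `ci_low`, `ci_high`, `n`; per-cell results attached as the
#'   `"results"` attribute.
#' @export
run_classification <- function(cohort,
                               feature_sets = c("FA", "ALPS_Bi", "FA+ALPS_Bi"),
                               pairs = list(c("NC", "MCI"), c("MCI", "AD"),
                                            c("NC", "AD")),
                               seed = 1L, ...) {
  rows <- list(); details <- list()
  cell <- 0L
  for (pr in pairs) for (fs in feature_sets) {
    cell <- cell + 1L
    d <- build_features(cohort, fs, pr)
    res <- svm_repeated_eval(d$X, d$y, seed = as.integer(seed) + cell, ...)
    nm <- paste0(pr[1], "_vs_", pr[2], ":", fs)
    details[[nm]] <- res
    rows[[nm]] <- data.frame(
      pair = paste0(pr[1], "_vs_", pr[2]), feature_set = fs,
      mean_auc = res$mean_auc, ci_low = res$ci[1], ci_high = res$ci[2],
      n = res$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "results") <- details
  out
}
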