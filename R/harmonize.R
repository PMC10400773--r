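#' Empirical-Bayes ComBat harmonization of image features
#'
#' Removes additive (location) and multiplicative (scale) scanner/batch
#' effects from a subjects-by-features table while preserving the effects
#' of biological covariates, following the parametric empirical-Bayes
#' location/scale algorithm of Johnson et al.: features are standardized by
#' their covariate-adjusted mean and pooled SD, per-batch location and
#' scale estimates are shrunk toward a pooled prior (normal on location,
#' inverse-gamma on scale, hyperparameters by moment matching, iterative
#' conditional updates to convergence), and the adjusted data are
#' back-transformed with the covariate structure re-added.
#'
#' Shrinkage pools information across features, so with a single feature
#' the EB step is undefined and the unshrunk per-batch estimates are used
#' (recorded in the returned model). A single batch degrades to
#' pass-through with a warning.
#'
#' @param features Numeric matrix or data frame, subjects x features.
#' @param batch Batch labels, length = number of subjects; every batch
#'   needs >= 2 subjects.
#' @param covariates Optional design matrix / data frame of biological
#'   covariates to protect (no intercept column; factors are expanded).
#' @param eb Apply empirical-Bayes shrinkage (default TRUE).
#' @param conv Convergence tolerance of the EB updates.
#' @param max_iter Iteration cap of the EB updates.
#' @return List with `harmonized` (same shape as `features`) and `model`
#'   (a `combat_model`: batch estimates, shrunk `gamma_star` / `delta_star2`,
#'   prior hyperparameters, pooled variance).
#' @export
combat_harmonize <- function(features, batch, covariates = NULL, eb = TRUE,
                             conv = 1e-4, max_iter = 100L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  batch <- factor(batch)
  if (length(batch) != n) stop("batch length must match number of subjects")
  nb <- table(batch)
  if (nlevels(batch) < 2L) {
    warning("single batch: harmonization is a pass-through")
    model <- structure(list(degenerate = TRUE, batch_levels = levels(batch)),
                       class = "combat_model")
    return(list(harmonized = features, model = model))
  }
  if (any(nb < 2L))
    stop("every batch needs >= 2 subjects; smallest has ", min(nb))
  batchmod <- stats::model.matrix(~ 0 + batch)
  if (!is.null(covariates)) {
    cov <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                      drop = FALSE]
    design <- cbind(batchmod, cov)
  } else design <- batchmod
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design: covariates confounded with batch ",
         "(or with each other)")
  B <- nlevels(batch)
  # covariate-adjusted standardization (feature-wise)
  B_hat <- solve(crossprod(design), crossprod(design, X))      # (B+q) x p
  grand_mean <- drop((nb / n) %*% B_hat[seq_len(B), , drop = FALSE])
  resid <- X - design %*% B_hat
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled <= 0)) stop("feature with zero pooled variance")
  tmp <- design; tmp[, seq_len(B)] <- 0
  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE) + tmp %*% B_hat
  s_data <- (X - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_hat <- apply(s_data, 2, function(col) tapply(col, batch, mean))
  delta_hat <- apply(s_data, 2, function(col) tapply(col, batch, stats::var))
  gamma_hat <- matrix(gamma_hat, B, p); delta_hat <- matrix(delta_hat, B, p)

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta_hat)
  s2_d <- apply(delta_hat, 1, stats::var)
  aprior <- (2 * s2_d + m_d^2) / s2_d
  bprior <- (m_d * s2_d + m_d^3) / s2_d

  eb_ok <- eb && p >= 2L && all(is.finite(t2)) && all(t2 > 0) &&
    all(is.finite(aprior)) && all(is.finite(bprior))
  if (eb_ok) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (b in seq_len(B)) {
      sd_b <- s_data[batch == levels(batch)[b], , drop = FALSE]
      n_b <- nrow(sd_b)
      g_old <- gamma_hat[b, ]; d_old <- delta_hat[b, ]
      for (it in seq_len(max_iter)) {
        g_new <- (t2[b] * n_b * gamma_hat[b, ] + d_old * gamma_bar[b]) /
          (t2[b] * n_b + d_old)
        sum2 <- colSums(sweep(sd_b, 2, g_new)^2)
        d_new <- (0.5 * sum2 + bprior[b]) / (n_b / 2 + aprior[b] - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / d_old)
        g_old <- g_new; d_old <- d_new
        if (change < conv) break
      }
      gamma_star[b, ] <- g_old; delta_star[b, ] <- d_old
    }
  } else {
    gamma_star <- gamma_hat; delta_star <- delta_hat
  }

  adj <- s_data
  for (b in seq_len(B)) {
    sel <- batch == levels(batch)[b]
    adj[sel, ] <- sweep(sweep(s_data[sel, , drop = FALSE], 2,
                              gamma_star[b, ]),
                        2, sqrt(delta_star[b, ]), "/")
  }
  harmonized <- adj * matrix(sqrt(var_pooled), n, p, byrow = TRUE) + stand_mean
  if (is.data.frame(features)) {
    out <- features
    out[] <- harmonized
  } else out <- harmonized
  model <- structure(list(
    degenerate = FALSE, eb = eb_ok, batch_levels = levels(batch),
    n_per_batch = as.integer(nb), coef = B_hat, grand_mean = grand_mean,
    var_pooled = var_pooled, gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star2 = delta_star,
    prior = list(gamma_bar = gamma_bar, tau2 = t2,
                 lambda = aprior, theta = bprior)),
    class = "combat_model")
  list(harmonized = out, model = model)
}

#' Intraclass correlation coefficient for test-retest agreement
#'
#' ICC(2,1): two-way random effects, absolute agreement, single
#' measurement, from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. This form
#' penalizes a systematic offset between sessions, which is the right
#' sensitivity for across-scanner retest data; ICC(3,1) (consistency) is
#' available via `type`.
#'
#' @param session1,session2 Paired measurements (equal length, n >= 2).
#' @param type `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return ICC estimate (<= 1).
#' @export
icc <- function(session1, session2, type = c("ICC2_1", "ICC3_1")) {
  type <- match.arg(type)
  if (length(session1) != length(session2)) stop("sessions differ in length")
  n <- length(session1)
  if (n < 2L) stop("need at least 2 subjects")
  y <- cbind(session1, session2)
  if (stats::var(as.vector(y)) == 0)
    stop("all values identical: ICC undefined")
  k <- 2
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC2_1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Paired t test on two sessions
#'
#' Standard paired t on the within-subject differences, two-sided p from
#' the t distribution with n - 1 df. Errors (rather than returning an
#' infinite statistic) when the differences have zero variance.
#'
#' @param session1,session2 Paired measurements (equal length, n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_t <- function(session1, session2) {
  if (length(session1) != length(session2)) stop("sessions differ in length")
  n <- length(session1)
  if (n < 2L) stop("need at least 2 pairs")
  d <- session1 - session2
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1,
                                 mean_diff = 0, n = n))
    stop("zero-variance nonzero differences: t statistic is infinite")
  }
  ht <- stats::t.test(session1, session2, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = unname(ht$estimate), n = n)
}
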