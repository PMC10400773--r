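#' Read and validate a cohort CSV
#'
#' @param path CSV with a header; must contain `subject_id` and `group`,
#'   and whatever stage-specific columns the downstream call needs. Group
#'   labels must be NC/MCI/AD, WMH (if present) an integer in 0..6,
#'   subject ids unique. Empty fields become NA.
#' @return A `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("subject_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- !df$group %in% c("NC", "MCI", "AD")
  if (any(bad))
    stop("unknown group label in rows ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(df$group[bad]), collapse = ", "))
  df$group <- factor(df$group, levels = c("NC", "MCI", "AD"))
  if ("WMH" %in% names(df)) {
    w <- df$WMH[!is.na(df$WMH)]
    if (any(w < 0 | w > 6 | w != round(w)))
      stop("column WMH must be an integer in [0, 6]; offending rows: ",
           paste(which(!is.na(df$WMH) &
                         (df$WMH < 0 | df$WMH > 6 | df$WMH != round(df$WMH))),
                 collapse = ", "))
  }
  alps_cols <- intersect(c("L_ALPS", "R_ALPS", "Bi_ALPS"), names(df))
  for (cn in alps_cols)
    if (any(df[[cn]] <= 0, na.rm = TRUE))
      stop("column ", cn, " must be > 0 where present")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' Numeric columns are serialized with 10 significant digits so that
#' re-runs with identical seeds produce byte-identical files. The
#' ground-truth sidecar attribute (if any) is deliberately not written.
#'
#' @param cohort Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (cn in names(df))
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- formatC(df[[cn]], digits = 10, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build a covariate design matrix from cohort columns
#'
#' Expands the named columns into a numeric design (no intercept column);
#' character and factor columns become indicator contrasts (e.g. sex).
#'
#' @param data Data frame.
#' @param covariates Character vector of column names.
#' @return Numeric matrix with one row per subject, or NULL if
#'   `covariates` is empty.
#' @export
covariate_design <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  if (length(covariates) == 0L) return(NULL)
  d <- as.data.frame(data[, covariates, drop = FALSE])
  for (cn in names(d)) if (is.character(d[[cn]])) d[[cn]] <- factor(d[[cn]])
  stats::model.matrix(~ ., data = d)[, -1, drop = FALSE]
}

#' OLS residualization against covariates
#'
#' Residuals of `values` on `[intercept, covariates]`. NA rows (in either
#' values or covariates) stay NA in the output; the fit uses complete rows
#' only. Residual mean is zero by construction.
#'
#' @param values Numeric vector.
#' @param covariates Matrix / data frame of covariates (no intercept
#'   column), or NULL for simple centering.
#' @return Residual vector, same length as `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates)) return(values - mean(values, na.rm = TRUE))
  X <- cbind(1, as.matrix(covariates))
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(X) & !is.na(values)
  if (sum(ok) <= ncol(X)) stop("insufficient complete observations (",
                               sum(ok), ") for ", ncol(X) - 1, " covariates")
  qrX <- qr(X[ok, , drop = FALSE])
  if (qrX$rank < ncol(X)) stop("rank-deficient covariate design")
  out <- rep(NA_real_, n)
  out[ok] <- qr.resid(qrX, values[ok])
  out
}

star_code <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Classical one-way F test with (k-1, N-k) degrees of freedom plus Tukey
#' HSD pairwise comparisons, the default post-hoc of common ANOVA tooling.
#' Pairwise Welch t tests with BH adjustment are available as an
#' alternative. Significance stars follow the * p < 0.05 / ** p < 0.01
#' convention.
#'
#' @param values Numeric response (typically covariate-residualized ALPS).
#' @param group Factor of group labels (>= 2 levels, each n >= 2).
#' @param posthoc `"tukey"` (default) or `"welch_bh"`.
#' @return List with `F`, `p`, `df` (length 2), and `posthoc` (data frame
#'   with comparison, difference, adjusted p, stars).
#' @export
anova_oneway <- function(values, group, posthoc = c("tukey", "welch_bh")) {
  posthoc <- match.arg(posthoc)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(factor(group[ok]))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs >= 2 subjects")
  if (all(tapply(values, group, stats::var) == 0))
    stop("zero within-group variance")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]; pv <- s[["Pr(>F)"]][1]
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$group
    ph <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"],
                     stars = star_code(tk[, "p adj"]),
                     row.names = NULL, stringsAsFactors = FALSE)
  } else {
    lv <- levels(group)
    prs <- utils::combn(lv, 2)
    res <- apply(prs, 2, function(pr) {
      ht <- stats::t.test(values[group == pr[2]], values[group == pr[1]])
      c(diff = unname(diff(rev(ht$estimate))), p = ht$p.value)
    })
    p_adj <- stats::p.adjust(res["p", ], method = "BH")
    ph <- data.frame(comparison = paste(prs[2, ], prs[1, ], sep = "-"),
                     diff = res["diff", ], p_adj = p_adj,
                     stars = star_code(p_adj),
                     row.names = NULL, stringsAsFactors = FALSE)
  }
  list(F = Fv, p = pv, df = c(s$Df[1], s$Df[2]), posthoc = ph)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the shared
#' covariates, with the two-sided p-value from
#' `t = r sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` df (k covariates).
#' Pairwise-complete observations are used. With no covariates this is the
#' plain Pearson correlation and its usual t test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional matrix / data frame of covariates.
#' @return List with `r`, `p`, `df`, `n` (complete observations used),
#'   `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates))
    ok <- ok & stats::complete.cases(as.matrix(covariates))
  n <- sum(ok)
  if (n <= k + 2L) stop("insufficient observations (", n, ") for ", k,
                        " covariates")
  cv <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE]
  rx <- residualize(x[ok], cv)
  ry <- residualize(y[ok], cv)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant residuals: correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n, n_covariates = k)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values (`q_(i) = min_{j >= i} m p_(j) / j`, reported in the
#' original order) via `stats::p.adjust(method = "BH")`, plus the rejection
#' set at level `alpha`.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param alpha FDR level.
#' @return List with `q` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) < 1L) stop("need at least one p-value")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Feature-by-scale partial-correlation program
#'
#' Computes the covariate-adjusted partial correlation between every
#' imaging feature and every cognitive scale, then applies BH-FDR across
#' the whole grid (one family per call; call separately for the
#' domain-general and domain-specific scale families to mirror separate
#' figure families). Pairwise deletion per cell, with the effective n
#' reported.
#'
#' @param cohort A cohort data frame.
#' @param features Character vector of feature columns
#'   (e.g. `c("L_ALPS", "R_ALPS", "Bi_ALPS")`).
#' @param scales Character vector of scale columns.
#' @param covariates Character vector of covariate columns (default: the
#'   gender/age/education/WMH adjustment set).
#' @param alpha FDR level.
#' @return Data frame with one row per (feature, scale) cell: `r`, `p`,
#'   `q`, `n`, `stars` (on q), sorted by q.
#' @export
run_correlation_program <- function(cohort, features, scales,
                                    covariates = c("sex", "age",
                                                   "education", "WMH"),
                                    alpha = 0.05) {
  miss <- setdiff(c(features, scales), names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cv <- covariate_design(cohort, covariates)
  grid <- expand.grid(feature = features, scale = scales,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cohort[[grid$feature[i]]]
    y <- cohort[[grid$scale[i]]]
    if (all(is.na(y))) stop("scale ", grid$scale[i], " is all-missing")
    pc <- partial_correlation(x, y, cv)
    data.frame(feature = grid$feature[i], scale = grid$scale[i],
               r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bh_fdr(out$p, alpha)
  out$q <- adj$q
  out$significant <- adj$reject
  out$stars <- star_code(out$q)
  out[order(out$q, out$p), ]
}
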