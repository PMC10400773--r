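test_that("residualization satisfies the normal equations", {
  set.seed(30)
  n <- 100
  # orthogonal covariate: residuals are just centered values
  v <- rnorm(n)
  x <- rep(c(-1, 1), n / 2)
  v_orth <- v - mean(v) - sum((v - mean(v)) * x) / sum(x^2) * x  # force orthogonality
  expect_equal(residualize(v_orth, cbind(x)), v_orth - mean(v_orth),
               tolerance = 1e-10)
  # exact linear function -> zero residuals
  X <- cbind(rnorm(n), rnorm(n))
  y <- 2 + 3 * X[, 1] - 0.5 * X[, 2]
  expect_lt(max(abs(residualize(y, X))), 1e-10)
  # residuals orthogonal to every covariate column, mean zero
  y2 <- rnorm(n)
  r <- residualize(y2, X)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
  # rank-deficient design rejected
  expect_error(residualize(y2, cbind(X, X[, 1])), "rank")
  # NAs propagate without breaking the fit
  y3 <- y2; y3[5] <- NA
  r3 <- residualize(y3, X)
  expect_true(is.na(r3[5]))
  expect_equal(sum(is.na(r3)), 1L)
})

test_that("one-way ANOVA agrees with hand-computed oracles", {
  # two groups: F equals the squared pooled t statistic
  set.seed(31)
  g <- factor(rep(c("a", "b"), each = 15))
  y <- rnorm(30) + (g == "b") * 0.8
  res <- anova_oneway(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # textbook three-group data against manual sums of squares
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- factor(rep(c("g1", "g2", "g3"), each = 3))
  gm <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  res <- anova_oneway(y, g)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$df, c(2, 6))
  expect_equal(nrow(res$posthoc), 3L)
  expect_true(all(res$posthoc$stars %in% c("ns", "*", "**")))

  # invariance to shift and scale of the response
  res2 <- anova_oneway(10 + 3 * y, g)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
  expect_error(anova_oneway(y[1:4], factor(c("a", "a", "b", "c"))),
               ">= 2 subjects")
})

test_that("partial correlation matches the residualize-then-Pearson oracle", {
  set.seed(32)
  # k = 0 reduces to plain Pearson
  x <- rnorm(50); y <- rnorm(50)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  # y = x -> r = 1 regardless of covariates
  cv <- matrix(rnorm(100), 50)
  expect_equal(partial_correlation(x, x, cv)$r, 1, tolerance = 1e-12)
  # 100 random instances with 4 covariates against the brute-force oracle
  for (i in 1:100) {
    n <- sample(20:60, 1)
    cv <- matrix(rnorm(n * 4), n)
    x <- rnorm(n); y <- rnorm(n)
    pc <- partial_correlation(x, y, cv)
    rx <- resid(lm(x ~ cv)); ry <- resid(lm(y ~ cv))
    r_oracle <- cor(rx, ry)
    expect_equal(pc$r, r_oracle, tolerance = 1e-12)
    df <- n - 2 - 4
    t_oracle <- r_oracle * sqrt(df / (1 - r_oracle^2))
    expect_equal(pc$p, 2 * pt(-abs(t_oracle), df), tolerance = 1e-12)
  }
  # one-covariate case equals the textbook recursion
  for (i in 1:20) {
    n <- 40
    z <- rnorm(n); x <- rnorm(n) + z; y <- rnorm(n) - 0.5 * z
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    recursion <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(partial_correlation(x, y, cbind(z))$r, recursion,
                 tolerance = 1e-12)
  }
})

test_that("BH-FDR reproduces the step-up rule and its monotonicity", {
  expect_equal(bh_fdr(0.03)$q, 0.03)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q,
               c(0.04, 0.04, 0.04, 0.04))                  # hand-computed
  expect_equal(bh_fdr(rep(1, 5))$q, rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  p <- runif(50)
  q <- bh_fdr(p)$q
  # q monotone non-decreasing in sorted-p order
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # rejections form a suffix of the p-sorted list and nest as alpha grows
  for (alpha in c(0.05, 0.2, 0.5)) {
    rej <- bh_fdr(p, alpha)$reject[order(p)]
    if (any(rej)) expect_true(all(rej[seq_len(max(which(rej)))]))
  }
  expect_true(all(bh_fdr(p, 0.05)$reject <= bh_fdr(p, 0.2)$reject))
})

test_that("the correlation program covers the grid and applies one FDR family", {
  co <- generate_cohort(cohort_gen_spec(
    n_per_group = c(NC = 40L, MCI = 40L, AD = 40L), seed = 34L))
  scales <- default_scale_params()$scale
  res <- run_correlation_program(co, c("L_ALPS", "R_ALPS", "Bi_ALPS"), scales)
  expect_equal(nrow(res), 3 * 13)
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$q >= res$p - 1e-15))
  # q values agree with applying BH to the grid p-values
  expect_equal(sort(res$q), sort(bh_fdr(res$p)$q))
  expect_error(run_correlation_program(co, "NOT_A_COL", scales),
               "missing columns")
})

test_that("programmed correlations are recovered by the program", {
  spec <- cohort_gen_spec(n_per_group = c(NC = 5000L, MCI = 2L, AD = 2L),
                          hemi_sd = 0, batch_shift = c(0, 0, 0),
                          batch_scale = c(1, 1, 1),
                          batch_shift_fa = c(0, 0, 0), seed = 35L)
  co <- generate_cohort(spec)
  co <- co[co$group == "NC", ]
  res <- run_correlation_program(co, "Bi_ALPS", c("MMSE", "IADL"),
                                 covariates = c("age", "education", "WMH"))
  expect_lt(abs(res$r[res$scale == "MMSE"] - 0.24), 0.05)
  expect_lt(abs(res$r[res$scale == "IADL"] - (-0.27)), 0.05)
})
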