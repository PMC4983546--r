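test_that("age quartiles are deterministic near-equal bins", {
  cv <- make_covar_table(103)
  x <- build_covariates(cv)
  counts <- c(103 - sum(x[, c("age_q2", "age_q3", "age_q4")]),
              colSums(x[, c("age_q2", "age_q3", "age_q4")]))
  expect_true(max(counts) - min(counts) <= 1)
  expect_identical(x, build_covariates(cv))
  expect_true(all(c("sex", "pc1", "studystudy2") %in% colnames(x)))
})

test_that("OLS recovers a perfect fit and matches the normal equations", {
  withr::with_seed(41, {
    prs <- rnorm(200)
    r <- ols_incremental(prs, prs)
    expect_equal(r$beta_std, 1, tolerance = 1e-12)
    expect_equal(r$r2_inc, 1, tolerance = 1e-12)

    # 20-row fixture against solve(X'X) X'y
    n <- 20
    cv <- cbind(c1 = rnorm(n), c2 = rnorm(n))
    x <- rnorm(n)
    y <- 0.5 * x + cv %*% c(0.3, -0.2) + rnorm(n)
    fit <- ols_incremental(y, x, cv)
    xs <- as.numeric(scale(x))
    xm <- cbind(1, cv, xs)
    beta_or <- solve(crossprod(xm), crossprod(xm, y))
    expect_equal(fit$beta_std, beta_or[4] / sd(y), tolerance = 1e-10)
    res <- y - xm %*% beta_or
    r2_full_or <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(fit$r2_full, r2_full_or, tolerance = 1e-10)
    # r2_inc ties to the squared t mapping: r2_inc = t^2 (1 - R2_full)/(n - p)
    expect_equal(fit$r2_inc,
                 fit$tstat^2 * (1 - fit$r2_full) / (n - 4),
                 tolerance = 1e-10)
  })
})

test_that("OLS under the null has nominal size and vanishing r2_inc", {
  out <- withr::with_seed(43, {
    t(vapply(seq_len(300), function(i) {
      y <- rnorm(2000)
      prs <- rnorm(2000)
      f <- ols_incremental(y, prs)
      c(rej = f$pvalue < 0.05, r2 = f$r2_inc)
    }, numeric(2)))
  })
  expect_lt(abs(mean(out[, "rej"]) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(out[, "r2"]), 3 / 2000)
})

test_that("rank-deficient designs raise an error naming the column", {
  withr::with_seed(47, {
    cv <- cbind(c1 = rnorm(50), c1dup = 0)
    cv[, 2] <- cv[, 1]
    expect_error(ols_incremental(rnorm(50), rnorm(50), cv),
                 "rank deficient.*c1dup|rank deficient.*c1")
  })
})

test_that("intercept-only multinomial reproduces observed frequencies", {
  withr::with_seed(53, {
    lev <- sample(0:4, 600, TRUE, prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
    # constant PRS is aliased with the intercept, so fit a zero-effect
    # column via standardize = FALSE on pure noise with beta fixed at 0 by
    # using the intercept-only design: supply prs as a column of zeros is
    # rank-deficient, so instead check fitted probabilities from a noise
    # PRS fit with the PRS effect profiled out at its tiny estimate.
    fit <- multinomial_fit(lev, rnorm(600))
    # average fitted category probabilities equal observed frequencies
    # (score equations for the intercepts)
    expect_equal(unname(colMeans(fit$fitted)),
                 as.numeric(prop.table(table(factor(lev, levels = 0:4)))),
                 tolerance = 1e-10)
  })
})

test_that("two-level multinomial equals binary logistic regression", {
  withr::with_seed(59, {
    n <- 800
    x <- rnorm(n)
    cv <- cbind(c1 = rnorm(n))
    eta <- -0.3 + 0.6 * x + 0.4 * cv[, 1]
    lev <- rbinom(n, 1, plogis(eta))
    fit <- multinomial_fit(lev, x, cv, standardize = FALSE)
    glmfit <- glm(lev ~ cv + x, family = binomial,
                  control = glm.control(epsilon = 1e-13))
    expect_lt(max(abs(fit$coefficients[, 1] - coef(glmfit))), 1e-8)
    xm <- cbind(1, cv, x)
    p <- plogis(drop(xm %*% fit$coefficients[, 1]))
    se_or <- sqrt(diag(solve(crossprod(xm, xm * (p * (1 - p))))))
    expect_lt(abs(fit$prs$se - se_or[length(se_or)]), 1e-10)
  })
})

test_that("slopes are invariant to PRS location shifts", {
  withr::with_seed(61, {
    n <- 1000
    x <- rnorm(n)
    f <- 0.5 * x + rnorm(n)
    lev <- findInterval(f, quantile(f, c(0.25, 0.5, 0.75)))
    fit1 <- multinomial_fit(lev, x, standardize = FALSE)
    fit2 <- multinomial_fit(lev, x + 5, standardize = FALSE)
    expect_equal(fit1$prs$b, fit2$prs$b, tolerance = 1e-7)
    expect_false(isTRUE(all.equal(fit1$coefficients[1, ],
                                  fit2$coefficients[1, ])))
    # row order does not matter
    perm <- sample(n)
    fit3 <- multinomial_fit(lev[perm], x[perm], standardize = FALSE)
    expect_equal(fit1$prs$b, fit3$prs$b, tolerance = 1e-8)
  })
})

test_that("multinomial errors on degenerate outcomes and separation", {
  expect_error(multinomial_fit(rep(1, 100), rnorm(100)), "single level")
  withr::with_seed(67, {
    x <- c(rnorm(50, -3), rnorm(50, 3))
    lev <- rep(0:1, each = 50)  # perfectly separated
    expect_error(multinomial_fit(lev, x), "separation")
  })
})

test_that("Wald contrasts follow the closed form", {
  fake <- structure(list(
    prs = data.frame(level = 1:2, b = c(0.5, 0.1), se = c(0.2, 0.2),
                     z = c(2.5, 0.5), or = exp(c(0.5, 0.1))),
    prs_vcov = diag(c(0.04, 0.04))), class = "multinom_fit")
  w <- wald_pair(fake, 1, 2)
  expect_equal(w$statistic, 0.16 / 0.08)
  expect_equal(w$pvalue, pchisq(2, 1, lower.tail = FALSE))
  # equal coefficients give statistic 0, p 1
  fake$prs$b <- c(0.3, 0.3)
  w0 <- wald_pair(fake, 1, 2)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$pvalue, 1)
  expect_error(wald_pair(fake, 1, 1))
  expect_error(wald_pair(fake, 1, 3), "non-reference")
})

test_that("all six pairwise contrasts are emitted for a 5-level fit", {
  withr::with_seed(71, {
    n <- 1500
    x <- rnorm(n)
    f <- 0.4 * x + rnorm(n)
    lev <- findInterval(f, quantile(f, c(0.2, 0.4, 0.6, 0.8)))
    fit <- multinomial_fit(lev, x)
    w <- wald_all_pairs(fit)
    expect_equal(nrow(w), 6)
    expect_true(all(w$statistic >= 0))
  })
})

test_that("zero-variance gensub reduces the adjusted rerun to the raw fit", {
  withr::with_seed(73, {
    n <- 600
    x <- rnorm(n)
    lev <- findInterval(0.4 * x + rnorm(n), c(-0.5, 0.5))
    raw <- multinomial_fit(lev, x)
    expect_warning(adj <- adjusted_rerun(lev, x, NULL, rep(0, n)),
                   "zero variance")
    expect_equal(adj$prs$b, raw$prs$b, tolerance = 1e-8)
  })
})

test_that("adjustment attenuates mediated effects but keeps direct paths", {
  lam <- c(0.8, 0.65, 0.8, 0.8, 0.8)
  cuts <- c(-1, 0, 1)
  run_rep <- function(i, direct) {
    withr::with_seed(8000 + i, {
      n <- 1200
      prs <- rnorm(n)
      f <- 0.25 * prs + rnorm(n, 0, sqrt(1 - 0.25^2))
      ind <- sapply(lam, function(l) {
        y <- l * f + rnorm(n, 0, sqrt(1 - l^2))
        findInterval(y, c(-1.2, -0.4, 0.4, 1.2))
      })
      ystar <- 0.8 * f + direct * prs +
        rnorm(n, 0, sqrt(max(1 - 0.64 - direct^2, 0.1)))
      lev <- findInterval(ystar, cuts)
      gensub <- factor_scores(fit_one_factor(ind), ind)
      un <- multinomial_fit(lev, prs)
      ad <- adjusted_rerun(lev, prs, NULL, gensub)
      c(z_un = max(abs(un$prs$z)), z_ad = max(abs(ad$prs$z)),
        p_ad = min(2 * pnorm(-abs(ad$prs$z))))
    })
  }
  med <- t(vapply(1:100, run_rep, numeric(3), direct = 0))
  expect_gt(mean(med[, "z_ad"] < med[, "z_un"]), 0.9)
  dir <- t(vapply(1:60, run_rep, numeric(3), direct = 0.35))
  expect_gt(mean(dir[, "p_ad"] < 0.05), 0.8)
})
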