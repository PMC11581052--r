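# Group-level inference: frequentist GLM with EMM contrasts, and the
# precision-weighted Bayesian GLM with model reduction.

toy_groups <- function(ya, yb, label = c("a", "b")) {
  data.frame(y = c(ya, yb),
             group = rep(label, c(length(ya), length(yb))))
}

test_that("a two-group toy contrast is hand-computable", {
  dat <- toy_groups(c(1, 1, 1), c(2, 2, 2))
  # a noiseless toy: lm warns about the perfect fit, which is the point
  res <- suppressWarnings(fit_group_glm(dat, "y",
                                        covariates = character(0)))
  expect_equal(res$contrasts$estimate, -1, tolerance = 1e-10)
  expect_equal(res$emm$emmean, c(1, 2), tolerance = 1e-10)
  expect_equal(res$eta_p2, 1, tolerance = 1e-10)
})

test_that("EMMs equal raw group means under orthogonal covariates", {
  # each group carries the same covariate cells, so adjustment is exact
  dat <- data.frame(
    y = c(10, 11, 12, 13, 20, 21, 22, 23, 5, 6, 7, 8),
    group = rep(c("g1", "g2", "g3"), each = 4),
    age = rep(c(25, 25, 45, 45), 3),
    sex = rep(c("male", "female", "male", "female"), 3))
  res <- suppressWarnings(fit_group_glm(dat, "y"))
  raw <- tapply(dat$y, dat$group, mean)
  expect_equal(res$emm$emmean, as.numeric(raw[res$emm$group]),
               tolerance = 1e-8)
})

test_that("contrast estimates are antisymmetric under group reversal", {
  set.seed(31)
  dat <- data.frame(y = rnorm(30),
                    group = rep(c("a", "b"), each = 15))
  r1 <- fit_group_glm(dat, "y", covariates = character(0))
  dat$group <- factor(dat$group, levels = c("b", "a"))
  r2 <- fit_group_glm(dat, "y", covariates = character(0))
  expect_equal(r1$contrasts$estimate, -r2$contrasts$estimate,
               tolerance = 1e-10)
  expect_equal(r1$f, r2$f, tolerance = 1e-10)
})

test_that("the omnibus F holds its size under the null", {
  set.seed(32)
  ps <- replicate(300, {
    dat <- data.frame(y = rnorm(45),
                      group = rep(c("a", "b", "c"), each = 15),
                      age = rnorm(45, 35, 10),
                      sex = sample(c("male", "female"), 45, TRUE))
    fit_group_glm(dat, "y")$p
  })
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
  # p-values should be roughly uniform
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 1e-3)
})

test_that("rank-deficient designs are rejected with the column named", {
  dat <- data.frame(y = rnorm(12),
                    group = rep(c("a", "b"), each = 6),
                    age = rep(30, 12),
                    sex = rep("male", 12))
  expect_error(fit_group_glm(dat, "y"), "alias")
})

test_that("group sizes below the minimum are rejected", {
  dat <- toy_groups(c(1, 2), c(3, 4, 5))
  expect_error(fit_group_glm(dat, "y", covariates = character(0)),
               "3 observations")
})

test_that("the PEB GLM reduces to weighted least squares estimates", {
  set.seed(33)
  n <- 120
  X <- cbind("(Intercept)" = 1,
             effect = rnorm(n), age_c = rnorm(n))
  b <- c(0.2, 0.8, -0.5)
  y <- drop(X %*% b) + rnorm(n, 0, 0.3)
  s2 <- rep(0.09, n)
  res <- peb_bayes_glm(y, X, s2)
  ols <- coef(lm(y ~ X[, "effect"] + X[, "age_c"]))
  expect_equal(unname(res$full_posterior$mean), unname(ols),
               tolerance = 1e-6)
})

test_that("planted effects are retained with strong posterior probability", {
  set.seed(34)
  hits <- replicate(20, {
    n <- 150 * 2
    g <- rep(c(-0.5, 0.5), each = 150)
    X <- cbind("(Intercept)" = 1, group = g, age_c = rnorm(n))
    y <- 0.7 * g + rnorm(n, 0, 1) + rnorm(n, 0, 0.4)
    res <- peb_bayes_glm(y, X, s2 = rep(0.16, n))
    eff <- res$effects[res$effects$effect == "group", ]
    eff$retained && eff$post_prob > 0.95
  })
  expect_gte(mean(hits), 0.9)
})

test_that("null effects are zeroed out by model reduction", {
  set.seed(35)
  zeroed <- replicate(20, {
    n <- 120
    X <- cbind("(Intercept)" = 1, group = rep(c(-0.5, 0.5), each = 60),
               age_c = rnorm(n))
    y <- rnorm(n, 0.3, 1)
    res <- peb_bayes_glm(y, X, s2 = rep(0.2, n))
    !res$effects$retained[res$effects$effect == "group"]
  })
  expect_gt(mean(zeroed), 0.5)
})

test_that("PEB input validation rejects bad designs and variances", {
  X <- cbind("(Intercept)" = 1, g = rnorm(10))
  expect_error(peb_bayes_glm(rnorm(10), X, s2 = c(rep(1, 9), -1)),
               "positive")
  expect_error(peb_bayes_glm(rnorm(10), X[, 2, drop = FALSE], rep(1, 10)),
               "Intercept")
})

test_that("frequentist and PEB analyses agree in sign on strong effects", {
  set.seed(36)
  n <- 90
  dat <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                    age = rnorm(n, 35, 10),
                    sex = sample(c("male", "female"), n, TRUE))
  shift <- c(a = -0.6, b = 0, c = 0.6)[dat$group]
  dat$p_t <- rnorm(n, shift, 0.5)
  dat$p_var <- rep(0.1, n)
  fre <- fit_group_glm(dat, "p_t")
  peb <- peb_parameter_tests(dat, params = "p")$p
  # EMM ordering a < c must match the PEB group-effect signs
  emm <- setNames(fre$emm$emmean, fre$emm$group)
  expect_lt(emm[["a"]], emm[["c"]])
  ga <- peb$effects[peb$effects$effect == "group_a", ]
  expect_true(ga$retained)
  expect_lt(ga$post_mean, 0)
})
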