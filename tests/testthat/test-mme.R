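make_grouped_data <- function(n_groups, reps, s2u = 1, s2e = 0.5,
                              beta_x = 0.4) {
  n <- n_groups * reps
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = reps)
  x <- rnorm(n)
  u <- rnorm(n_groups, 0, sqrt(s2u))
  data.frame(id = as.character(seq_len(n)), g = g, x = x,
             y = 1 + beta_x * x + u[as.integer(factor(g))] +
               rnorm(n, 0, sqrt(s2e)))
}

test_that("build_design expands factors, covariates and QTL columns", {
  d <- data.frame(id = as.character(1:6), y = rnorm(6),
                  sex = rep(c("f", "m"), 3), w = rnorm(6))
  ds <- build_design(y ~ sex + w, d)
  expect_equal(ncol(ds$X), 3)  # intercept + sexm + w
  expect_equal(ds$rank, 3)

  q <- matrix(rnorm(6), 6, 1, dimnames = list(d$id, "qtl_add"))
  ds2 <- build_design(y ~ sex, d, qtl_columns = q)
  expect_true("qtl_add" %in% colnames(ds2$X))

  ## rows with missing response or missing QTL coefficient are dropped
  d$y[2] <- NA; q[4, 1] <- NA
  ds3 <- build_design(y ~ sex, d, qtl_columns = q)
  expect_equal(ds3$ids, setdiff(d$id, c("2", "4")))

  ## duplicated column triggers the rank-deficiency error
  d2 <- data.frame(id = as.character(1:6), y = rnorm(6), a = 1:6,
                   b = 2 * (1:6))
  expect_error(build_design(y ~ a + b, d2), "rank deficient.*b")
})

test_that("random-term incidence maps rows to covariance labels", {
  d <- data.frame(id = as.character(1:4), y = rnorm(4))
  K <- cov_matrix(diag(4), as.character(1:4))
  ds <- build_design(y ~ 1, d, random = list(u = K))
  expect_equal(dim(ds$random$u$Z), c(4L, 4L))
  expect_equal(as.matrix(ds$random$u$Z), diag(4), ignore_attr = TRUE)
  ## level missing from the covariance labels is an error
  K2 <- cov_matrix(diag(3), as.character(1:3))
  expect_error(build_design(y ~ 1, d, random = list(u = K2)), "missing")
})

test_that("solve_mme reduces to OLS without random terms", {
  withr::local_seed(1)
  d <- data.frame(id = as.character(1:30), x = rnorm(30))
  d$y <- 2 + 0.7 * d$x + rnorm(30)
  ds <- build_design(y ~ x, d)
  sm <- solve_mme(ds, list(residual = 1.3, components = numeric(0)))
  ref <- lm(y ~ x, d)
  expect_equal(unname(sm$b), unname(coef(ref)), tolerance = 1e-10)
})

test_that("BLUPs shrink level means by r/(r + lambda) in a balanced design", {
  withr::local_seed(2)
  q <- 6; r <- 5
  d <- make_grouped_data(q, r, beta_x = 0)
  ds <- build_design(y ~ 1, d, random = list(g = "identity"))
  vc <- list(residual = 0.5, components = 2)
  sm <- solve_mme(ds, vc)
  lam <- vc$residual / vc$components
  gm <- tapply(d$y, d$g, mean)
  shrink <- r / (r + lam)
  expect_equal(unname(sm$u$g), as.numeric(shrink * (gm - sm$b[1])),
               tolerance = 1e-8)
  ## infinite-shrinkage limit: u -> 0 as s2_g -> 0
  sm0 <- solve_mme(ds, list(residual = 0.5, components = 1e-10))
  expect_lt(max(abs(sm0$u$g)), 1e-6)
})

test_that("sparse and dense MME solutions agree", {
  withr::local_seed(3)
  d <- make_grouped_data(8, 4)
  ds <- build_design(y ~ x, d, random = list(g = "identity"))
  vc <- list(residual = 0.6, components = 1.1)
  a <- solve_mme(ds, vc, method = "dense")
  b <- solve_mme(ds, vc, method = "sparse")
  expect_equal(a$b, b$b, tolerance = 1e-8)
  expect_equal(a$u$g, b$u$g, tolerance = 1e-8)
  expect_equal(a$logdetM, b$logdetM, tolerance = 1e-8)
})

test_that("REML log-likelihood matches dense-algebra evaluation", {
  withr::local_seed(4)
  d <- make_grouped_data(8, 4)  # 32 records
  K <- crossprod(matrix(rnorm(64), 8)) / 8 + diag(8)
  Kc <- cov_matrix(K, sprintf("g%02d", 1:8))
  ds <- build_design(y ~ x, d, random = list(g = Kc))
  Z <- as.matrix(ds$random$g$Z)
  for (vc in list(list(residual = 0.5, components = 1),
                  list(residual = 2, components = 0.3))) {
    expect_equal(reml_loglik(ds, vc, "REML"),
                 dense_loglik(ds$y, ds$X, Z, K, vc$components, vc$residual,
                              "REML"),
                 tolerance = 1e-6)
    expect_equal(reml_loglik(ds, vc, "ML"),
                 dense_loglik(ds$y, ds$X, Z, K, vc$components, vc$residual,
                              "ML"),
                 tolerance = 1e-6)
  }
})

test_that("log-likelihood is invariant to record order", {
  withr::local_seed(5)
  d <- make_grouped_data(6, 4)
  vc <- list(residual = 0.7, components = 0.9)
  ds <- build_design(y ~ x, d, random = list(g = "identity"))
  pi <- sample(nrow(d))
  ds2 <- build_design(y ~ x, d[pi, ], random = list(g = "identity"))
  expect_equal(reml_loglik(ds, vc), reml_loglik(ds2, vc), tolerance = 1e-9)
})

test_that("adding an irrelevant fixed column never lowers the ML loglik", {
  withr::local_seed(6)
  d <- data.frame(id = as.character(1:40), x = rnorm(40), junk = rnorm(40))
  d$y <- 1 + 0.5 * d$x + rnorm(40)
  vc <- list(residual = 1, components = numeric(0))
  l0 <- reml_loglik(build_design(y ~ x, d), vc, "ML")
  l1 <- reml_loglik(build_design(y ~ x + junk, d), vc, "ML")
  expect_gte(l1, l0 - 1e-10)
})

test_that("EM-REML fixed point equals closed-form balanced one-way REML", {
  withr::local_seed(7)
  d <- make_grouped_data(8, 6, s2u = 2, s2e = 0.5, beta_x = 0)
  ds <- build_design(y ~ 1, d, random = list(g = "identity"))
  est <- reml_em(ds, tol = 1e-12, max_iter = 5000)
  ref <- anova_reml(d$y, d$g)
  expect_gt(ref["s2u"], 0)  # interior solution required for the identity
  expect_equal(est$vc$components, unname(ref["s2u"]), tolerance = 1e-5)
  expect_equal(est$vc$residual, unname(ref["s2e"]), tolerance = 1e-5)
  expect_true(est$converged)
})

test_that("EM-REML agrees with lme4 on a random-intercept model", {
  withr::local_seed(8)
  d <- make_grouped_data(12, 5)
  fit <- qmm(y ~ x, d, random = list(g = "identity"), tol = 1e-10,
             max_iter = 5000)
  lm4 <- lme4::lmer(y ~ x + (1 | g), d, REML = TRUE)
  vcr <- as.data.frame(lme4::VarCorr(lm4))$vcov
  expect_equal(unname(fit$vc[c("g", "residual")]), vcr, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(lm4)),
               tolerance = 1e-5)
  expect_equal(unname(fit$se),
               unname(coef(summary(lm4))[, "Std. Error"]), tolerance = 1e-4)
  expect_equal(fit$loglik_reml, as.numeric(logLik(lm4)), tolerance = 1e-6)
})

test_that("EM-REML maximum matches a 1-D grid search of the REML loglik", {
  withr::local_seed(9)
  n_hit <- 0
  for (rep in 1:6) {
    d <- make_grouped_data(6, 5, s2u = runif(1, 0.5, 2),
                           s2e = runif(1, 0.3, 1))
    ds <- build_design(y ~ x, d, random = list(g = "identity"))
    est <- reml_em(ds, tol = 1e-12, max_iter = 5000)
    gam_em <- est$vc$components / est$vc$residual
    lgrid <- seq(log(1e-3), log(1e3), length.out = 241)
    ll <- vapply(lgrid, function(lg) {
      g <- exp(lg)
      ## profile over the residual variance at fixed ratio
      f <- function(s2e) reml_loglik(ds, list(residual = s2e,
                                              components = g * s2e))
      stats::optimize(f, c(1e-4, 50), maximum = TRUE)$objective
    }, 0)
    gam_grid <- exp(lgrid[which.max(ll)])
    step <- diff(lgrid[1:2])
    if (gam_em > 2e-3 && gam_grid > exp(lgrid[1])) {
      expect_lt(abs(log(gam_em) - log(gam_grid)), step + 1e-8)
      n_hit <- n_hit + 1
    }
  }
  expect_gte(n_hit, 4)  # most draws give an interior optimum
})

test_that("REML log-likelihood trace is monotone non-decreasing", {
  withr::local_seed(10)
  for (rep in 1:25) {
    d <- make_grouped_data(5, 4, s2u = runif(1, 0.05, 2),
                           s2e = runif(1, 0.2, 2))
    ds <- build_design(y ~ x, d, random = list(g = "identity"))
    est <- reml_em(ds, tol = 1e-9, max_iter = 400)
    expect_true(all(diff(est$trace) >= -1e-8 * (1 + abs(est$trace[-1]))))
  }
})

test_that("estimates are equivariant under scaling of the response", {
  withr::local_seed(11)
  d <- make_grouped_data(8, 5)
  fit1 <- qmm(y ~ x, d, random = list(g = "identity"), tol = 1e-10,
              max_iter = 5000)
  d2 <- d; d2$y <- 10 * d$y
  fit2 <- qmm(y ~ x, d2, random = list(g = "identity"), tol = 1e-10,
              max_iter = 5000)
  expect_equal(unname(fit2$vc), unname(100 * fit1$vc), tolerance = 1e-5)
  expect_equal(unname(fit2$coefficients), unname(10 * fit1$coefficients),
               tolerance = 1e-6)
})

test_that("a truly null variance component is estimated near zero", {
  ## EM approaches a boundary optimum slowly, so this run uses a long
  ## iteration budget
  withr::local_seed(12)
  d <- make_grouped_data(100, 5, s2u = 0, s2e = 1, beta_x = 0.3)
  fit <- qmm(y ~ x, d, random = list(g = "identity"), tol = 1e-10,
             max_iter = 20000)
  expect_lt(fit$vc[["g"]], 1e-3)
})

test_that("non-convergence is flagged", {
  withr::local_seed(13)
  d <- make_grouped_data(6, 4)
  ds <- build_design(y ~ 1, d, random = list(g = "identity"))
  est <- reml_em(ds, tol = 1e-14, max_iter = 3)
  expect_false(est$converged)
  expect_equal(est$n_iterations, 3L)
})
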