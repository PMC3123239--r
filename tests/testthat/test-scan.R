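test_that("p-values from LRT statistics follow the chi-square and mixture nulls", {
  expect_equal(pvalue_from_lrt(0, 1), 1)
  expect_equal(pvalue_from_lrt(3.84, 1), 0.05, tolerance = 2e-3)
  expect_equal(pvalue_from_lrt(3.84, 1),
               pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(pvalue_from_lrt(2.71, 1, "mixture50"), 0.05, tolerance = 5e-3)
  expect_equal(pvalue_from_lrt(2.71, 1, "mixture50"),
               0.5 * pchisq(2.71, 1, lower.tail = FALSE))
  expect_equal(pvalue_from_lrt(0, 1, "mixture50"), 1)
  expect_equal(pvalue_from_lrt(c(1, 2), c(1, 2)),
               pchisq(c(1, 2), c(1, 2), lower.tail = FALSE))
  ## tiny negatives are clipped, real negatives and df < 1 are errors
  expect_equal(pvalue_from_lrt(-1e-9, 1), 1)
  expect_error(pvalue_from_lrt(-1, 1), "negative")
  expect_error(pvalue_from_lrt(1, 0), "df")
})

test_that("fixed-mode association equals the standard regression LRT", {
  withr::local_seed(30)
  sim <- simulate_cross(sim_design(n_f2 = 80, h2 = 0, seed = 30))
  cr <- sim$cross
  sc <- scan_association(y ~ sex, cr, snps = c("m02", "m05"))
  for (k in 1:2) {
    snp <- sc$marker[k]
    lam <- snp_lambda(cr$genos, snp)[cr$pheno$id]
    d <- cbind(cr$pheno, lam = lam)
    l1 <- logLik(lm(y ~ sex + lam, d))
    l0 <- logLik(lm(y ~ sex, d))
    expect_equal(sc$LRT[k], as.numeric(2 * (l1 - l0)), tolerance = 1e-6)
    expect_equal(sc$df[k], 1)
  }
})

test_that("textbook regression LRT reproduced on a 12-record dataset", {
  ## hand-built: y regressed on a -1/0/1 code, no other structure
  d <- data.frame(id = as.character(1:12),
                  y = c(4.1, 3.9, 5.2, 5.0, 4.8, 5.1,
                        6.2, 5.8, 6.1, 4.2, 5.1, 6.0))
  lam <- c(-1, -1, 0, 0, 0, 0, 1, 1, 1, -1, 0, 1)
  cols <- matrix(lam, 12, 1, dimnames = list(d$id, "snp"))
  full <- qmm(y ~ 1, d, qtl_columns = cols)
  red <- qmm(y ~ 1, d)
  lrt <- 2 * (full$loglik_ml - red$loglik_ml)
  ## profile-ML Gaussian LRT: n log(RSS0 / RSS1)
  r1 <- sum(resid(lm(d$y ~ lam))^2)
  r0 <- sum(resid(lm(d$y ~ 1))^2)
  expect_equal(lrt, 12 * log(r0 / r1), tolerance = 1e-8)
  ## and the slope matches least squares
  expect_equal(unname(coef(full)["snp"]), unname(coef(lm(d$y ~ lam))[2]),
               tolerance = 1e-8)
})

test_that("scan profiles locate a strong simulated QTL", {
  withr::local_seed(31)
  sim <- simulate_cross(sim_design(n_f2 = 150, h2 = 0, seed = 31,
                                   qtl = list(pos_cM = 17, a = -1, d = 0)))
  cr <- sim$cross
  sc <- scan_qtl(y ~ sex, cr, effects = "add", step = 2)
  expect_s3_class(sc, "qmm_scan")
  am <- attr(sc, "argmax")
  expect_lt(abs(am$pos_cM - 17), 11)
  expect_lt(am$p, 1e-4)
  expect_true(all(sc$df == 1))
  expect_true(all(sc$p > 0 & sc$p <= 1))
  expect_true(all(sc$LRT >= 0))
  ## additive+dominance scan carries 2 df at every position
  sc2 <- scan_qtl(y ~ sex, cr, effects = c("add", "dom"), step = 10)
  expect_true(all(sc2$df == 2))
  ## plot method draws without error
  pf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pf); plot(sc); grDevices::dev.off()
  expect_true(file.size(pf) > 0)
})

test_that("profiles are invariant to record order", {
  withr::local_seed(32)
  sim <- simulate_cross(sim_design(n_f2 = 60, h2 = 0, seed = 32))
  cr <- sim$cross
  sc1 <- scan_qtl(y ~ sex, cr, effects = "add", step = 10)
  cr2 <- cr
  cr2$pheno <- cr$pheno[sample(nrow(cr$pheno)), ]
  sc2 <- scan_qtl(y ~ sex, cr2, effects = "add", step = 10)
  expect_equal(sc1$LRT, sc2$LRT, tolerance = 1e-8)
})

test_that("LRT is additive over nested fixed-effect chains at common vc", {
  withr::local_seed(33)
  sim <- simulate_cross(sim_design(n_f2 = 100, h2 = 0.3, seed = 33))
  cr <- sim$cross
  d <- cr$pheno
  Ainv <- pedigree_A_inverse(cr$ped)
  rnd <- list(u = list(K_inv = Ainv))
  po <- origin_posteriors(cr, "1", 17, individuals = d$id)
  co <- qtl_coefficients(po[, , 1, drop = FALSE])
  vc <- qmm(y ~ sex, d, random = rnd, tol = 1e-6, max_iter = 300)$vc_list
  m0 <- qmm(y ~ 1, d, random = rnd, vc = vc)
  m1 <- qmm(y ~ sex, d, random = rnd, vc = vc)
  m2 <- qmm(y ~ sex, d, random = rnd, vc = vc,
            qtl_columns = co[, "add", drop = FALSE])
  lrt20 <- 2 * (m2$loglik_ml - m0$loglik_ml)
  lrt21 <- 2 * (m2$loglik_ml - m1$loglik_ml)
  lrt10 <- 2 * (m1$loglik_ml - m0$loglik_ml)
  expect_equal(lrt20, lrt21 + lrt10, tolerance = 1e-6)
})

test_that("nested QTL coefficients give one column per level", {
  withr::local_seed(34)
  sim <- simulate_cross(sim_design(n_f2 = 120, h2 = 0, seed = 34))
  cr <- sim$cross
  sc <- scan_qtl(y ~ sex, cr, effects = "add", nest = "sex", step = 25)
  expect_true(all(sc$df == 2))
  expect_true(all(c("qtl_add:sexf", "qtl_add:sexm") %in% names(sc)))
})

test_that("monomorphic SNPs are skipped with a warning", {
  withr::local_seed(35)
  sim <- simulate_cross(sim_design(n_f2 = 40, h2 = 0, seed = 35))
  cr <- sim$cross
  ## overwrite one marker with a constant genotype
  j <- 3
  cr$genos$a1[, j] <- 1L
  cr$genos$a2[, j] <- 1L
  expect_warning(sc <- scan_association(y ~ sex, cr,
                                        snps = cr$genos$markers[c(2, 3)]),
                 "skipped")
  expect_equal(nrow(sc), 1L)
})

test_that("random-mode association tests the SNP variance component", {
  withr::local_seed(36)
  sim <- simulate_cross(sim_design(n_f2 = 100, h2 = 0, seed = 36))
  cr <- sim$cross
  sc <- scan_association(y ~ sex, cr, snps = c("m04"), mode = "random",
                         tol = 1e-6, max_iter = 300)
  expect_equal(sc$df, 1)
  expect_true(sc$p > 0 && sc$p <= 1)
  ## strong QTL at 17 cM: nearby SNP variance component clearly non-zero
  expect_lt(sc$p, 0.01)
})

test_that("conditional tests separate duplicated terms with an error", {
  withr::local_seed(37)
  sim <- simulate_cross(sim_design(n_f2 = 60, h2 = 0, seed = 37))
  cr <- sim$cross
  lam <- snp_lambda(cr$genos, "m04")
  cols <- matrix(lam, ncol = 1, dimnames = list(names(lam), "snp"))
  expect_error(conditional_test(y ~ sex, cr$pheno, cols, cols),
               "confounded")
})

test_that("conditional tests attribute signal to the generating term", {
  withr::local_seed(38)
  ## phenotype generated by the SNP (marker m08), not by a QTL elsewhere
  sim <- simulate_cross(sim_design(n_f2 = 200, h2 = 0, seed = 38,
                                   qtl = list(pos_cM = 17, a = 0, d = 0)))
  cr <- sim$cross
  lam <- snp_lambda(cr$genos, "m08")
  d <- cr$pheno
  d$y <- d$y + 0.8 * lam[d$id]
  po <- origin_posteriors(cr, "1", 0, individuals = d$id)
  co <- qtl_coefficients(po[, , 1, drop = FALSE])[, "add", drop = FALSE]
  colnames(co) <- "qtl_add"
  snpcol <- matrix(lam, ncol = 1, dimnames = list(names(lam), "snp"))
  ct <- conditional_test(y ~ sex, d, co, snpcol, names = c("qtl", "snp"))
  expect_lt(ct$p[ct$term == "snp"], 0.01)
  expect_gt(ct$p[ct$term == "qtl"], 0.05)
})
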