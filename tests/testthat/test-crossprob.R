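make_f2_cross <- function(mpos, geno_strings, pheno = NULL) {
  nm <- length(mpos)
  map <- genetic_map(paste0("m", seq_len(nm)), rep("1", nm), mpos)
  tiny_f2_cross(geno_from_strings(geno_strings), map, pheno)
}

test_that("Haldane map function and scan grid behave", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(20), (1 - exp(-0.4)) / 2)
  expect_lte(haldane_r(1e6), 0.5)
  expect_gt(haldane_r(100), haldane_r(10))
  map <- genetic_map(paste0("m", 1:3), "1", c(0, 7.5, 20))
  g <- scan_grid(map, "1", step = 1)
  expect_true(all(c(0, 7.5, 20) %in% g))
  expect_equal(min(g), 0)
  expect_equal(max(g), 20)
  expect_error(scan_grid(map, "chr99"), "no markers")
})

test_that("posterior is a delta at a fully informative marker", {
  cr <- make_f2_cross(10, matrix("11", 1, 1, dimnames = list("X", NULL)))
  po <- origin_posteriors(cr, "1", 10, individuals = "X")
  expect_equal(po["X", , 1], c(p11 = 1, p12 = 0, p21 = 0, p22 = 0))
  ## heterozygote: symmetric mixture of the two ordered configurations
  cr2 <- make_f2_cross(10, matrix("12", 1, 1, dimnames = list("X", NULL)))
  po2 <- origin_posteriors(cr2, "1", 10, individuals = "X")
  expect_equal(po2["X", , 1], c(p11 = 0, p12 = .5, p21 = .5, p22 = 0))
})

test_that("additive coefficient decays as exp(-2d) from an informative marker", {
  cr <- make_f2_cross(10, matrix("11", 1, 1, dimnames = list("X", NULL)))
  po <- origin_posteriors(cr, "1", 30, individuals = "X")
  co <- qtl_coefficients(po[, , 1, drop = FALSE])
  r <- haldane_r(20)
  expect_equal(unname(co[, "add"]), (1 - r)^2 - r^2, tolerance = 1e-12)
  expect_equal(unname(co[, "add"]), exp(-0.4), tolerance = 1e-12)
  expect_equal(unname(co[, "dom"]), 2 * r * (1 - r), tolerance = 1e-12)
})

test_that("ungenotyped F2 falls back to the prior with a warning", {
  cr <- make_f2_cross(10, matrix("00", 1, 1, dimnames = list("X", NULL)))
  expect_warning(po <- origin_posteriors(cr, "1", 10, individuals = "X"),
                 "no genotyped marker")
  expect_equal(unname(po[1, , 1]), rep(0.25, 4))
  co <- qtl_coefficients(po[, , 1, drop = FALSE])
  expect_equal(unname(co[, "add"]), 0)
  expect_equal(unname(co[, "dom"]), 0.5)
})

test_that("forward-backward equals brute-force enumeration (F2, <= 5 markers)", {
  withr::local_seed(42)
  mpos <- c(0, 4, 11, 23, 40)
  for (rep in 1:8) {
    gs <- matrix(sample(c("11", "12", "22", "00"), 5, TRUE,
                        prob = c(.3, .3, .3, .1)), 1, 5,
                 dimnames = list("X", NULL))
    cr <- make_f2_cross(mpos, gs)
    qpos <- runif(1, 0, 40)
    po <- suppressWarnings(
      origin_posteriors(cr, "1", qpos, individuals = "X"))
    a1 <- as.integer(substr(gs, 1, 1)); a1[a1 == 0] <- NA
    a2 <- as.integer(substr(gs, 2, 2)); a2[a2 == 0] <- NA
    ref <- enum_origin_posterior(a1, a2, mpos, qpos)
    expect_lt(max(abs(po[1, , 1] - ref[1, ])), 1e-10)
  }
})

test_that("enumeration also matches under partially informative lines", {
  withr::local_seed(7)
  mpos <- c(0, 10, 25)
  gs <- matrix(c("12", "22", "11"), 1, 3, dimnames = list("X", NULL))
  map <- genetic_map(paste0("m", 1:3), "1", mpos)
  cr <- tiny_f2_cross(geno_from_strings(gs), map)
  cr$line_freqs <- rbind(c(0.1, 0.2, 0.05), c(0.9, 0.95, 0.8))
  for (qpos in c(0, 5, 17, 25)) {
    po <- origin_posteriors(cr, "1", qpos, individuals = "X")
    ## enumeration with locus-specific line frequencies
    ref <- local({
      a1 <- c(1, 2, 1); a2 <- c(2, 2, 1)
      loci <- sort(unique(c(mpos, qpos)))
      obs <- match(loci, mpos)
      r <- haldane_r(diff(loci))
      chainp <- function(o) {
        p <- 0.5
        for (t in seq_along(r))
          p <- p * if (o[t] == o[t + 1]) (1 - r[t]) else r[t]
        p
      }
      fprob <- function(a, l, k) if (a == 2) cr$line_freqs[l, k] else
        1 - cr$line_freqs[l, k]
      emis <- function(op, om) {
        p <- 1
        for (t in seq_along(loci)) {
          k <- obs[t]
          if (is.na(k)) next
          x <- a1[k]; y <- a2[k]
          p <- p * if (x == y) fprob(x, op[t], k) * fprob(x, om[t], k) else
            fprob(x, op[t], k) * fprob(y, om[t], k) +
            fprob(y, op[t], k) * fprob(x, om[t], k)
        }
        p
      }
      L <- length(loci)
      grid <- as.matrix(expand.grid(rep(list(1:2), L)))
      tq <- match(qpos, loci)
      out <- numeric(4)
      for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
        op <- grid[i, ]; om <- grid[j, ]
        st <- 2L * (op[tq] - 1L) + om[tq]
        out[st] <- out[st] + chainp(op) * chainp(om) * emis(op, om)
      }
      out / sum(out)
    })
    expect_lt(max(abs(po[1, , 1] - ref)), 1e-10)
  }
})

test_that("backcross constrains the maternal gamete to the recurrent line", {
  ## BC individual: F1 sire x L1 dam
  map <- genetic_map(c("m1", "m2"), "1", c(0, 15))
  ped <- pedigree(c("L1", "L2", "L1b", "F1", "X"),
                  c("0", "0", "0", "L1", "F1"),
                  c("0", "0", "0", "L2", "L1b"))
  g <- genotypes(c("L1", "L2", "L1b", "F1", "X"), c("m1", "m2"),
                 rbind(c(1, 1), c(2, 2), c(1, 1), c(1, 1), c(1, 1)),
                 rbind(c(1, 1), c(2, 2), c(1, 1), c(2, 2), c(2, 1)))
  cr <- cross_data(ped, g, map, c(L1 = 1, L2 = 2, L1b = 1))
  po <- origin_posteriors(cr, "1", c(0, 7, 15), individuals = "X")
  ## maternal origin always line 1: p12 = p22 = 0 everywhere
  expect_equal(max(po["X", c("p12", "p22"), ]), 0)
  ## at m1 the paternal allele is 2 -> origin line 2: state p21
  expect_equal(unname(po["X", , 1]), c(0, 0, 1, 0))
  ## enumeration cross-check at the midpoint
  ref <- enum_origin_posterior(c(1, 1), c(2, 1), c(0, 15), 7,
                               maternal_fixed = 1)
  expect_lt(max(abs(po[1, , 2] - ref[1, ])), 1e-10)
})

test_that("F3 posteriors are proper and delta at informative markers", {
  ## build a three-generation cross by simulation
  sim <- simulate_cross(sim_design(n_f2 = 0, n_f3 = 30, seed = 5))
  cr <- sim$cross
  ids <- cr$pheno$id
  po <- origin_posteriors(cr, "1", c(0, 13, 50), individuals = ids)
  sums <- apply(po, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  ## at marker m01 (0 cM) a homozygous 11 F3 must be (1,1) for sure
  hom11 <- ids[cr$genos$a1[ids, 1] == 1 & cr$genos$a2[ids, 1] == 1]
  if (length(hom11))
    expect_lt(max(abs(po[hom11, "p11", 1] - 1)), 1e-9)
})

test_that("QTL coefficients follow the ordered-state contrasts", {
  p <- rbind(X = c(1, 0, 0, 0))
  colnames(p) <- c("p11", "p12", "p21", "p22")
  co <- qtl_coefficients(p)
  expect_equal(unname(co[, c("add", "dom", "imp_pat", "imp_mat")]),
               c(1, 0, 1, 1))
  p2 <- rbind(X = c(0, .5, .5, 0)); colnames(p2) <- colnames(p)
  co2 <- qtl_coefficients(p2)
  expect_equal(unname(co2[, "add"]), 0)
  expect_equal(unname(co2[, "dom"]), 1)
  expect_equal(unname(co2[, "imp_pat"]), 0)
  ## reciprocal ordered heterozygotes: opposite imprinting signs
  p3 <- rbind(X = c(0, 1, 0, 0)); colnames(p3) <- colnames(p)
  p4 <- rbind(X = c(0, 0, 1, 0)); colnames(p4) <- colnames(p)
  expect_equal(unname(qtl_coefficients(p3)[, "imp_pat"]), 1)
  expect_equal(unname(qtl_coefficients(p3)[, "imp_mat"]), -1)
  expect_equal(qtl_coefficients(p3)[, "imp_pat"],
               -qtl_coefficients(p4)[, "imp_pat"], ignore_attr = TRUE)
})

test_that("SNP lambda coding is -1/0/+1 with missing preserved", {
  g <- geno_from_strings(rbind(a = "22", b = "12", c = "11", d = "00"))
  lam <- snp_lambda(g, "m1")
  expect_equal(unname(lam), c(1, 0, -1, NA))
  g2 <- genotypes("a", "m1", matrix(3L), matrix(3L))
  expect_error(snp_lambda(g2, "m1"), "biallelic")
})

test_that("imprinted SNP coding resolves parent-of-origin where forced", {
  ped <- pedigree(c("s", "d", "c1", "c2", "c3", "c4"),
                  c("0", "0", "s", "s", "s", "s"),
                  c("0", "0", "d", "d", "d", "d"))
  map <- genetic_map("m1", "1", 0)
  mk_cross <- function(gs) {
    g <- geno_from_strings(matrix(gs, ncol = 1,
                                  dimnames = list(names(gs), NULL)))
    cross_data(pedigree(c("s", "d", names(gs)[-(1:2)]),
                        c("0", "0", rep("s", length(gs) - 2)),
                        c("0", "0", rep("d", length(gs) - 2))),
               g, map, c(s = 1, d = 2))
  }
  ## child 12, sire 11, dam 22: paternal allele is 1 ->
  ## under maternal imprinting (paternal expressed) lambda = -1
  cr <- mk_cross(c(s = "11", d = "22", x = "12"))
  expect_equal(unname(snp_lambda_imprinted(cr, "m1", "maternal")["x"]), -1)
  expect_equal(unname(snp_lambda_imprinted(cr, "m1", "paternal")["x"]), 1)
  ## all-heterozygous trio: origin ambiguous, excluded
  cr2 <- mk_cross(c(s = "12", d = "12", x = "12"))
  expect_true(is.na(snp_lambda_imprinted(cr2, "m1", "maternal")["x"]))
  ## homozygous child is always determined
  cr3 <- mk_cross(c(s = "12", d = "12", x = "22"))
  expect_equal(unname(snp_lambda_imprinted(cr3, "m1", "maternal")["x"]), 1)
  ## Mendelian inconsistency: excluded with a warning
  cr4 <- mk_cross(c(s = "11", d = "11", x = "12"))
  expect_warning(lam <- snp_lambda_imprinted(cr4, "m1", "maternal"),
                 "inconsistent")
  expect_true(is.na(lam["x"]))
})

test_that("epistasis columns are elementwise coefficient products", {
  co_f <- function(add, dom) {
    m <- cbind(add = add, dom = dom, imp_pat = 0, imp_mat = 0)
    rownames(m) <- paste0("i", seq_along(add))
    m
  }
  cA <- co_f(c(1, 0, -1), c(0, 1, 0))
  cB <- co_f(c(1, -1, 1), c(0, 0, 1))
  expect_equal(unname(epistasis_columns(cA, cB, "aa")[, 1]), c(1, 0, -1))
  expect_equal(unname(epistasis_columns(cA, cB, "ad")[, 1]), c(0, 0, -1))
  expect_equal(unname(epistasis_columns(cA, cB, "dd")[, 1]), c(0, 0, 0))
  u <- epistasis_columns(cA, cB, "user",
                         pairs = list(c("add", "add"), c("dom", "add")))
  expect_equal(colnames(u), c("add:add", "dom:add"))
  ## zero additive coefficients -> zero interaction column
  expect_equal(unname(epistasis_columns(co_f(0, 1), co_f(1, 0), "aa")[, 1]),
               0)
  expect_error(epistasis_columns(cA, cB, "zz"))
  ## F2 with both loci fully informative: products stay in {-1, 0, 1}
  withr::local_seed(9)
  add_vals <- sample(c(-1, 0, 1), 20, TRUE)
  prod_col <- epistasis_columns(co_f(add_vals, 0),
                                co_f(sample(c(-1, 0, 1), 20, TRUE), 0),
                                "aa")
  expect_true(all(prod_col %in% c(-1, 0, 1)))
})
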