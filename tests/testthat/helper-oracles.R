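# Independent oracles used across tests: Monte-Carlo gene dropping for
# pedigree relationships, brute-force enumeration of line-origin posteriors,
# closed-form balanced one-way REML, and dense-algebra REML evaluation.
# These deliberately avoid the package's own computational paths.

# Monte-Carlo gene dropping: founders get unique allele labels, alleles
# drop down the pedigree; additive relationship a_ij is estimated as half
# the expected number of IBD matches among the four allele comparisons
# (a_ii = 1 + P(the two alleles of i are IBD)).
gene_drop_A <- function(ped, R = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  P <- matrix(0L, n, R)
  M <- matrix(0L, n, R)
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      P[i, ] <- 2L * i - 1L
      M[i, ] <- 2L * i
    } else {
      s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
      pick <- stats::runif(R) < 0.5
      P[i, ] <- ifelse(pick, P[s, ], M[s, ])
      pick <- stats::runif(R) < 0.5
      M[i, ] <- ifelse(pick, P[d, ], M[d, ])
    }
  }
  A <- matrix(0, n, n)
  SE <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      x <- as.numeric(P[i, ] == M[i, ])
      A[i, i] <- 1 + mean(x)
      SE[i, i] <- stats::sd(x) / sqrt(R)
    } else {
      x <- (as.numeric(P[i, ] == P[j, ]) + as.numeric(P[i, ] == M[j, ]) +
              as.numeric(M[i, ] == P[j, ]) + as.numeric(M[i, ] == M[j, ])) / 2
      A[i, j] <- A[j, i] <- mean(x)
      SE[i, j] <- SE[j, i] <- stats::sd(x) / sqrt(R)
    }
  }
  dimnames(A) <- dimnames(SE) <- list(ped$id, ped$id)
  list(A = A, SE = SE)
}

# Random pedigree: nf founders then random matings among earlier
# individuals (inbreeding allowed unless non_inbred).
random_pedigree <- function(n = 20, nf = 6, non_inbred = FALSE) {
  id <- as.character(seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  A <- diag(nf)
  for (i in (nf + 1):n) {
    repeat {
      pr <- sample(seq_len(i - 1L), 2)
      if (!non_inbred || A[pr[1], pr[2]] == 0) break
    }
    sire[i] <- id[pr[1]]; dam[i] <- id[pr[2]]
    ## grow A by the tabular rule to screen matings
    newrow <- (A[seq_len(i - 1L), pr[1]] + A[seq_len(i - 1L), pr[2]]) / 2
    A <- rbind(cbind(A, newrow), c(newrow, 1 + A[pr[1], pr[2]] / 2))
  }
  pedigree(id, sire, dam)
}

# Brute-force line-origin posterior for one F2 (or BC) individual: full
# enumeration over ordered origin configurations of the two gametes, each
# an independent 2-state Markov chain under the Haldane map.
enum_origin_posterior <- function(a1, a2, mpos, qpos, lf2 = c(0, 1),
                                  maternal_fixed = NULL) {
  loci <- sort(unique(c(mpos, qpos)))
  L <- length(loci)
  obs <- match(loci, mpos)
  r <- (1 - exp(-2 * diff(loci) / 100)) / 2
  chainp <- function(o) {
    p <- 0.5
    for (t in seq_len(L - 1L))
      p <- p * if (o[t] == o[t + 1L]) (1 - r[t]) else r[t]
    p
  }
  fprob <- function(a, l) if (a == 2) lf2[l] else 1 - lf2[l]
  emis <- function(op, om) {
    p <- 1
    for (t in seq_len(L)) {
      k <- obs[t]
      if (is.na(k) || is.na(a1[k])) next
      x <- a1[k]; y <- a2[k]
      p <- p * if (x == y) fprob(x, op[t]) * fprob(x, om[t]) else
        fprob(x, op[t]) * fprob(y, om[t]) + fprob(y, op[t]) * fprob(x, om[t])
    }
    p
  }
  grid <- as.matrix(expand.grid(rep(list(1:2), L)))
  tq <- match(qpos, loci)
  out <- matrix(0, 1, 4, dimnames = list(NULL, c("p11", "p12", "p21", "p22")))
  for (i in seq_len(nrow(grid))) {
    op <- grid[i, ]
    pp <- chainp(op)
    om_set <- if (is.null(maternal_fixed)) seq_len(nrow(grid)) else NA
    if (is.null(maternal_fixed)) {
      for (j in seq_len(nrow(grid))) {
        om <- grid[j, ]
        w <- pp * chainp(om) * emis(op, om)
        st <- 2L * (op[tq] - 1L) + om[tq]
        out[1, st] <- out[1, st] + w
      }
    } else {
      om <- rep(maternal_fixed, L)
      w <- pp * emis(op, om)
      st <- 2L * (op[tq] - 1L) + om[tq]
      out[1, st] <- out[1, st] + w
    }
  }
  out / sum(out)
}

# Closed-form REML for the balanced one-way layout y_ij = mu + u_i + e_ij
# (q groups, r reps): s2e = MSE, s2u = (MSA - MSE)/r.
anova_reml <- function(y, group) {
  q <- length(unique(group))
  r <- length(y) / q
  gm <- tapply(y, group, mean)
  msa <- r * sum((gm - mean(y))^2) / (q - 1)
  mse <- sum((y - gm[group])^2) / (q * (r - 1))
  c(s2u = (msa - mse) / r, s2e = mse)
}

# Dense-algebra REML / ML log-likelihood for one random term.
dense_loglik <- function(y, X, Z, K, s2u, s2e, type = "REML") {
  n <- length(y)
  V <- Z %*% K %*% t(Z) * s2u + diag(s2e, n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  res <- y - X %*% b
  yPy <- drop(t(res) %*% Vi %*% res)
  ldV <- determinant(V, logarithm = TRUE)$modulus[1]
  if (type == "REML") {
    ldX <- determinant(XVX, logarithm = TRUE)$modulus[1]
    -(ldV + ldX + yPy + (n - ncol(X)) * log(2 * pi)) / 2
  } else {
    -(ldV + yPy + n * log(2 * pi)) / 2
  }
}

# Small helper: build a genotypes object from a character matrix like
# "12" per (individual, marker).
geno_from_strings <- function(g) {
  a1 <- apply(g, 1:2, function(s) as.integer(substr(s, 1, 1)))
  a2 <- apply(g, 1:2, function(s) as.integer(substr(s, 2, 2)))
  a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
  ids <- rownames(g); if (is.null(ids)) ids <- paste0("i", seq_len(nrow(g)))
  mks <- colnames(g); if (is.null(mks)) mks <- paste0("m", seq_len(ncol(g)))
  genotypes(ids, mks, a1, a2)
}

# Minimal F2 cross around a supplied F2 genotype matrix (one F1 pair).
tiny_f2_cross <- function(f2_geno, map, pheno = NULL) {
  nf2 <- length(f2_geno$ids)
  ped <- pedigree(c("L1", "L2", "F1a", "F1b", f2_geno$ids),
                  c("0", "0", "L1", "L1", rep("F1a", nf2)),
                  c("0", "0", "L2", "L2", rep("F1b", nf2)))
  nm <- length(f2_geno$markers)
  pad <- function(v) matrix(rep(v, nm), 4, nm)
  a1 <- rbind(pad(c(1L, 2L, 1L, 1L)), f2_geno$a1)
  a2 <- rbind(pad(c(1L, 2L, 2L, 2L)), f2_geno$a2)
  g <- genotypes(c("L1", "L2", "F1a", "F1b", f2_geno$ids),
                 f2_geno$markers, a1, a2)
  cross_data(ped, g, map, c(L1 = 1, L2 = 2), pheno = pheno)
}
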