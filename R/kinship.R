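## Relationship matrices: pedigree A and A-inverse, marker-based raw and
## standardized genomic relationship matrices, allele frequencies.

#' Numerator relationship matrix (tabular method)
#'
#' Computes the additive (numerator) relationship matrix A from a pedigree by
#' the tabular method. A quantifies the expected proportion of alleles
#' identical by descent conditional on the pedigree: founders (individuals
#' with both parents unknown) are taken to be unrelated and non-inbred,
#' `a_ij = (a_{i,sire(j)} + a_{i,dam(j)}) / 2` for `i` preceding `j`, and
#' `a_jj = 1 + a_{sire(j),dam(j)} / 2`.
#'
#' @param ped a [pedigree] (topologically sorted by construction).
#' @return A [cov_matrix] of kind `"A"`.
#' @export
pedigree_A <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[i, s] else 0
      ad_ <- if (d > 0L) A[i, d] else 0
      A[i, j] <- (as_ + ad_) / 2
      A[j, i] <- A[i, j]
    }
    A[j, j] <- 1 + (if (s > 0L && d > 0L) A[s, d] / 2 else 0)
  }
  cov_matrix(A, ped$id, kind = "A")
}

#' Inverse numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules (default), which assume
#' non-inbred parents: for each individual, contributions 2, -1, 0.5 (both
#' parents known), 4/3, -2/3, 1/3 (one parent) or 1 (none) are added at the
#' individual/parent positions. With `exact = TRUE` the tabular A of
#' [pedigree_A()] is inverted numerically instead, which is exact under
#' inbreeding as well.
#'
#' @param ped a [pedigree].
#' @param exact invert the tabular A instead of using Henderson's rules.
#' @return A [cov_matrix] of kind `"A_inverse"`.
#' @export
pedigree_A_inverse <- function(ped, exact = FALSE) {
  if (exact) {
    A <- pedigree_A(ped)
    return(cov_matrix(solve(A$values), ped$id, kind = "A_inverse"))
  }
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  Ainv <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    np <- (s > 0L) + (d > 0L)
    if (np == 2L) {
      Ainv[j, j] <- Ainv[j, j] + 2
      for (p in c(s, d)) {
        Ainv[j, p] <- Ainv[j, p] - 1
        Ainv[p, j] <- Ainv[p, j] - 1
        Ainv[p, p] <- Ainv[p, p] + 0.5
      }
      Ainv[s, d] <- Ainv[s, d] + 0.5
      Ainv[d, s] <- Ainv[d, s] + 0.5
    } else if (np == 1L) {
      p <- max(s, d)
      Ainv[j, j] <- Ainv[j, j] + 4 / 3
      Ainv[j, p] <- Ainv[j, p] - 2 / 3
      Ainv[p, j] <- Ainv[p, j] - 2 / 3
      Ainv[p, p] <- Ainv[p, p] + 1 / 3
    } else {
      Ainv[j, j] <- Ainv[j, j] + 1
    }
  }
  cov_matrix(Ainv, ped$id, kind = "A_inverse")
}

#' Allele frequencies and derived per-SNP constants
#'
#' For each biallelic SNP (alleles coded 1 and 2) computes `q`, the frequency
#' of allele 2 among non-missing genotypes, the genotypic mean
#' `mu = 2q - 1` on the -1/0/+1 coding, and the genotype variance
#' `d = 2q(1 - q)`.
#'
#' @param genos a [genotypes] object with biallelic 1/2-coded markers.
#' @return A `data.frame` (class `allele_freqs`) with columns `marker`, `q`,
#'   `mu`, `d`, `n_obs`.
#' @export
allele_freqs <- function(genos) {
  .check_biallelic(genos)
  n2 <- colSums(genos$a1 == 2L, na.rm = TRUE) +
        colSums(genos$a2 == 2L, na.rm = TRUE)
  nobs <- colSums(!is.na(genos$a1))
  if (any(nobs == 0L))
    stop("SNP(s) with no observed genotypes: ",
         paste(genos$markers[nobs == 0L], collapse = ", "))
  q <- n2 / (2 * nobs)
  out <- data.frame(marker = genos$markers, q = q, mu = 2 * q - 1,
                    d = 2 * q * (1 - q), n_obs = nobs,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("allele_freqs", "data.frame")
  out
}

.check_biallelic <- function(genos) {
  codes <- unique(c(genos$a1[!is.na(genos$a1)], genos$a2[!is.na(genos$a2)]))
  if (length(codes) && !all(codes %in% c(1L, 2L))) {
    bad <- apply(genos$a1, 2, function(x) any(!x %in% c(1L, 2L), na.rm = TRUE)) |
           apply(genos$a2, 2, function(x) any(!x %in% c(1L, 2L), na.rm = TRUE))
    stop("non-biallelic marker(s) (allele codes other than 1/2): ",
         paste(genos$markers[bad], collapse = ", "))
  }
  invisible(TRUE)
}

## -1/0/+1 coded dosage matrix M (11 -> -1, 12 -> 0, 22 -> +1), with missing
## entries imputed at the SNP mean 2q - 1 so they contribute 0 after centring.
.dosage_matrix <- function(genos, freqs) {
  M <- (genos$a1 + genos$a2) - 3L
  M <- matrix(as.numeric(M), nrow = length(genos$ids),
              dimnames = list(genos$ids, genos$markers))
  if (anyNA(M)) {
    mu <- rep(freqs$mu, each = nrow(M))
    M[is.na(M)] <- mu[is.na(M)]
  }
  M
}

#' Raw molecular relationship matrix
#'
#' `G = M M' / n` where `M` is the m-individual by n-SNP matrix of genotype
#' codes -1, 0 and +1 for genotypes 11, 12 and 22: the scaled number of
#' alleles shared between individuals, averaged over markers. Missing
#' genotypes are imputed at the SNP mean code `2q - 1`.
#'
#' @param genos a [genotypes] object with biallelic 1/2-coded markers.
#' @return A [cov_matrix] of kind `"G_raw"`.
#' @export
raw_G <- function(genos) {
  fr <- allele_freqs(genos)
  M <- .dosage_matrix(genos, fr)
  G <- tcrossprod(M) / ncol(M)
  cov_matrix(G, genos$ids, kind = "G_raw")
}

#' Standardized molecular relationship matrix
#'
#' `G* = W D^{-1} W' / n` where `w_ij = m_ij - mu_j` centres the -1/0/+1
#' genotype codes at the per-SNP mean `mu_j = 2q_j - 1` and `D` is diagonal
#' with the genotype variances `2 q_j (1 - q_j)`. Monomorphic SNPs
#' (`d_j = 0`) are dropped and `n` reduced accordingly, with a warning
#' listing them.
#'
#' @param genos a [genotypes] object with biallelic 1/2-coded markers.
#' @param freqs optional [allele_freqs]; by default computed from `genos`
#'   (a frequency table computed from a reference sample may be supplied).
#' @return A [cov_matrix] of kind `"G_std"`.
#' @export
standardized_G <- function(genos, freqs = allele_freqs(genos)) {
  stopifnot(identical(as.character(freqs$marker), genos$markers))
  keep <- freqs$d > 0
  if (!any(keep))
    stop("all SNPs are monomorphic; standardized G is undefined")
  if (!all(keep))
    warning("dropping ", sum(!keep), " monomorphic SNP(s): ",
            paste(utils::head(genos$markers[!keep], 10), collapse = ", "))
  M <- .dosage_matrix(genos, freqs)[, keep, drop = FALSE]
  W <- sweep(M, 2, freqs$mu[keep])
  Wd <- sweep(W, 2, freqs$d[keep], "/")
  G <- tcrossprod(Wd, W) / sum(keep)
  cov_matrix(G, genos$ids, kind = "G_std")
}
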