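## Line-origin probabilities in two-line crosses, and their conversion to
## QTL regression coefficients (additive, dominance, imprinting), SNP lambda
## codes and epistatic interaction columns.
##
## Ordered-state convention: the FIRST index is the paternal-gamete origin.
## States are (paternal origin, maternal origin) in the order
## (1,1), (1,2), (2,1), (2,2), referred to as p11, p12, p21, p22.

#' Haldane map function
#'
#' Recombination fraction between two loci `d_cM` centimorgans apart under
#' the Haldane (no-interference) model: `r = (1 - exp(-2 d)) / 2` with `d`
#' in Morgans.
#'
#' @param d_cM map distance in centimorgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Bundle cross data
#'
#' Collects the pieces of a two-line cross analysis: pedigree, marker
#' genotypes, genetic map, the assignment of pedigree founders to the two
#' founder lines, and (optionally) the phenotype table and per-line marker
#' allele frequencies.
#'
#' By default the founder lines are assumed fixed for alternative alleles at
#' every marker (line 1 carries allele 1, line 2 allele 2). Partially
#' informative markers can be described through `line_freqs`, a 2 x n-marker
#' matrix giving the frequency of allele 2 in each line's gametes.
#'
#' @param ped a [pedigree].
#' @param genos a [genotypes] object (alleles coded 1/2).
#' @param map a [genetic_map] whose markers match `genos`.
#' @param lines named vector (names = founder ids) with values 1 or 2; by
#'   default founders are split by the `line` column of `pheno` if present.
#' @param pheno optional phenotype `data.frame` (first column `id`).
#' @param line_freqs optional 2 x n-marker matrix of allele-2 frequencies
#'   per line; default `rbind(0, 1)` (lines fixed for alternative alleles).
#' @return An object of class `cross_data`.
#' @export
cross_data <- function(ped, genos, map, lines = NULL, pheno = NULL,
                       line_freqs = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(map, "genetic_map"))
  if (!identical(genos$markers, map$marker))
    stop("genotype markers do not match the map")
  if (!is.null(lines)) {
    lines <- stats::setNames(as.integer(lines), names(lines))
    if (!all(lines %in% c(1L, 2L)))
      stop("founder line assignments must be 1 or 2")
    founders <- ped$id[ped$founder]
    unassigned <- setdiff(founders, names(lines))
    if (length(unassigned))
      stop("founder(s) not assigned to a line: ",
           paste(utils::head(unassigned, 5), collapse = ", "))
  }
  if (is.null(line_freqs)) {
    line_freqs <- rbind(rep(0, nrow(map)), rep(1, nrow(map)))
  } else {
    line_freqs <- as.matrix(line_freqs)
    stopifnot(nrow(line_freqs) == 2L, ncol(line_freqs) == nrow(map))
  }
  structure(list(ped = ped, genos = genos, map = map, lines = lines,
                 pheno = pheno, line_freqs = line_freqs),
            class = "cross_data")
}

#' @export
print.cross_data <- function(x, ...) {
  cat("Cross data:", nrow(x$ped), "individuals,", nrow(x$map), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Default scan grid
#'
#' Positions every `step` cM from the first to the last marker of a
#' chromosome, always including the marker positions themselves.
#'
#' @param map a [genetic_map].
#' @param chrom chromosome label.
#' @param step grid step in cM (default 1).
#' @return Sorted numeric vector of positions (cM).
#' @export
scan_grid <- function(map, chrom, step = 1) {
  pos <- map$pos_cM[map$chrom == chrom]
  if (!length(pos)) stop("no markers on chromosome ", chrom)
  lo <- min(pos); hi <- max(pos)
  sort(unique(c(seq(lo, hi, by = step), pos, hi)))
}

## P(observed allele a | gamete from line l) at marker j
.allele_prob <- function(a, lf2) {
  ## lf2: frequency of allele 2 in the line's gametes (vector over loci)
  out <- numeric(length(a))
  out[!is.na(a) & a == 2L] <- lf2[!is.na(a) & a == 2L]
  out[!is.na(a) & a == 1L] <- 1 - lf2[!is.na(a) & a == 1L]
  out
}

#' Line-origin posterior probabilities
#'
#' Computes, for each requested individual and query position, the posterior
#' probability of the four ordered line-origin states (paternal, maternal
#' gamete origin) given all marker data on the chromosome, by a
#' forward-backward hidden Markov model. Transitions between adjacent loci
#' occur at the Haldane recombination fraction, independently for the
#' paternal and the maternal meiosis. Emissions use the per-line marker
#' allele frequencies (lines fixed for alternative alleles by default).
#'
#' The pedigree is processed in topological order: founders of the pure
#' lines have degenerate posteriors; for every other individual the hidden
#' chain is the pair of meiosis indicators of its two parental gametes, and
#' the transmitted origin at a locus is drawn from the parent's marginal
#' ordered-origin posterior for the indicated gamete. This is exact for F2
#' and backcross individuals (whose parents' gamete origins are degenerate)
#' and a stated approximation for F3 and later generations, where
#' within-parent linkage beyond the chain is ignored.
#'
#' @param cross a [cross_data].
#' @param chrom chromosome label.
#' @param positions query positions in cM (clamped to the marker span).
#' @param individuals ids to report (default: all non-founders with a
#'   phenotype row if `cross$pheno` is present, else all individuals).
#' @return Array `[individual, state, position]` with states
#'   `p11, p12, p21, p22`; each slice sums to 1.
#' @export
origin_posteriors <- function(cross, chrom, positions, individuals = NULL) {
  ped <- cross$ped
  map <- cross$map
  on_chr <- which(map$chrom == chrom)
  if (!length(on_chr)) stop("no markers on chromosome ", chrom)
  mpos <- map$pos_cM[on_chr]
  loci <- sort(unique(c(mpos, positions)))
  L <- length(loci)
  obs_idx <- match(round(loci, 9), round(mpos, 9))  # NA for silent loci
  qpos_idx <- match(round(positions, 9), round(loci, 9))

  if (is.null(cross$lines))
    stop("origin probabilities require founder line assignments ",
         "(see cross_data)")
  n <- nrow(ped)
  ids <- ped$id
  idx <- seq_len(n); names(idx) <- ids
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  ## genotype alleles at chromosome loci, aligned to pedigree rows
  g_row <- match(ids, cross$genos$ids)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  has_g <- !is.na(g_row)
  mk <- !is.na(obs_idx)
  a1[has_g, mk] <- cross$genos$a1[g_row[has_g], on_chr[obs_idx[mk]]]
  a2[has_g, mk] <- cross$genos$a2[g_row[has_g], on_chr[obs_idx[mk]]]

  ## per-line allele-2 frequency at each locus (NA at silent loci, unused)
  lf <- matrix(NA_real_, 2, L)
  lf[, mk] <- cross$line_freqs[, on_chr[obs_idx[mk]], drop = FALSE]

  ## transition matrices between consecutive loci (shared by all meioses)
  r <- haldane_r(diff(loci))
  T2 <- lapply(r, function(rr) matrix(c(1 - rr, rr, rr, 1 - rr), 2, 2))

  ## posterior over ordered origin states, all individuals x 4 x L
  post <- array(NA_real_, c(n, 4, L))
  ## founders: delta at (line, line)
  for (f in which(ped$founder)) {
    l <- cross$lines[[ids[f]]]
    s <- if (l == 1L) 1L else 4L
    post[f, , ] <- 0
    post[f, s, ] <- 1
  }

  ## pedigree depth levels (parents strictly earlier)
  depth <- integer(n)
  for (j in seq_len(n)) {
    dp <- 0L
    if (si[j] > 0L) dp <- max(dp, depth[si[j]] + 1L)
    if (di[j] > 0L) dp <- max(dp, depth[di[j]] + 1L)
    depth[j] <- dp
  }
  no_marker <- logical(n)

  for (lev in sort(unique(depth[depth > 0L]))) {
    I <- which(depth == lev & !ped$founder)
    if (!length(I)) next
    k <- length(I)
    if (any(si[I] == 0L | di[I] == 0L))
      stop("non-founder with an unknown parent cannot be placed in the ",
           "cross: ", ids[I[si[I] == 0L | di[I] == 0L]][1])
    ## parents' gamete-origin marginals, k x L each (P(origin = 1))
    sp <- post[si[I], , , drop = FALSE]
    dp <- post[di[I], , , drop = FALSE]
    qs_pat <- sp[, 1, ] + sp[, 2, , drop = TRUE]   # sire paternal gamete
    qs_mat <- sp[, 1, ] + sp[, 3, , drop = TRUE]   # sire maternal gamete
    qd_pat <- dp[, 1, ] + dp[, 2, , drop = TRUE]
    qd_mat <- dp[, 1, ] + dp[, 3, , drop = TRUE]
    dim(qs_pat) <- dim(qs_mat) <- dim(qd_pat) <- dim(qd_mat) <- c(k, L)

    ## emission over origin combos e[k, 4, L]; 1 at silent/missing loci
    e <- array(1, c(k, 4, L))
    for (j in which(mk)) {
      x <- a1[I, j]; y <- a2[I, j]
      obs <- !is.na(x)
      if (!any(obs)) next
      f1x <- .allele_prob(x, rep(lf[1, j], k))
      f2x <- .allele_prob(x, rep(lf[2, j], k))
      f1y <- .allele_prob(y, rep(lf[1, j], k))
      f2y <- .allele_prob(y, rep(lf[2, j], k))
      hom <- !is.na(x) & x == y
      ## unordered pair {x,y}: f_op(x) f_om(y) [+ f_op(y) f_om(x) if x != y]
      e11 <- f1x * f1y + ifelse(hom, 0, f1y * f1x)
      e12 <- f1x * f2y + ifelse(hom, 0, f1y * f2x)
      e21 <- f2x * f1y + ifelse(hom, 0, f2y * f1x)
      e22 <- f2x * f2y + ifelse(hom, 0, f2y * f2x)
      e[cbind(which(obs), 1L, j)] <- e11[obs]
      e[cbind(which(obs), 2L, j)] <- e12[obs]
      e[cbind(which(obs), 3L, j)] <- e21[obs]
      e[cbind(which(obs), 4L, j)] <- e22[obs]
    }
    no_marker[I] <- rowSums(!is.na(a1[I, , drop = FALSE])) == 0L

    ## emissions over meiosis states m = (mp, mm), order (p,p),(p,m),(m,p),(m,m)
    Em <- array(NA_real_, c(k, 4, L))
    for (j in seq_len(L)) {
      ej <- e[, , j, drop = FALSE]; dim(ej) <- c(k, 4)
      ## h[mm, op] = sum_om qd[mm, om] e[op, om]
      h_p1 <- qd_pat[, j] * ej[, 1] + (1 - qd_pat[, j]) * ej[, 2]  # mm=p, op=1
      h_p2 <- qd_pat[, j] * ej[, 3] + (1 - qd_pat[, j]) * ej[, 4]  # mm=p, op=2
      h_m1 <- qd_mat[, j] * ej[, 1] + (1 - qd_mat[, j]) * ej[, 2]
      h_m2 <- qd_mat[, j] * ej[, 3] + (1 - qd_mat[, j]) * ej[, 4]
      Em[, 1, j] <- qs_pat[, j] * h_p1 + (1 - qs_pat[, j]) * h_p2  # (p,p)
      Em[, 2, j] <- qs_pat[, j] * h_m1 + (1 - qs_pat[, j]) * h_m2  # (p,m)
      Em[, 3, j] <- qs_mat[, j] * h_p1 + (1 - qs_mat[, j]) * h_p2  # (m,p)
      Em[, 4, j] <- qs_mat[, j] * h_m1 + (1 - qs_mat[, j]) * h_m2  # (m,m)
    }

    ## forward-backward over meiosis states (uniform prior)
    Emat <- function(A, j) matrix(A[, , j], k, 4)
    alpha <- array(NA_real_, c(k, 4, L))
    a_cur <- matrix(0.25, k, 4) * Emat(Em, 1)
    sc <- rowSums(a_cur)
    zero <- sc <= 0
    if (any(zero)) { a_cur[zero, ] <- 0.25; sc[zero] <- 1 }
    alpha[, , 1] <- a_cur / sc
    for (j in seq_len(L - 1L)) {
      T4 <- kronecker(T2[[j]], T2[[j]])
      prop <- Emat(alpha, j) %*% T4
      a_cur <- prop * Emat(Em, j + 1L)
      sc <- rowSums(a_cur)
      zero <- sc <= 0
      if (any(zero)) {  # impossible observation: drop it (genotype error)
        a_cur[zero, ] <- prop[zero, , drop = FALSE]
        sc[zero] <- rowSums(a_cur[zero, , drop = FALSE])
      }
      alpha[, , j + 1L] <- a_cur / sc
    }
    beta <- array(NA_real_, c(k, 4, L))
    beta[, , L] <- 1
    for (j in seq(L - 1L, by = -1L, length.out = L - 1L)) {
      T4 <- kronecker(T2[[j]], T2[[j]])
      b_next <- Emat(beta, j + 1L) * Emat(Em, j + 1L)
      b_cur <- b_next %*% t(T4)
      sc <- rowSums(b_cur)
      sc[sc <= 0] <- 1
      beta[, , j] <- b_cur / sc
    }
    gamma <- alpha * beta
    gs <- apply(gamma, c(1, 3), sum)
    bad <- gs <= 0
    if (any(bad)) gs[bad] <- 1
    dim(gs) <- c(k, L)

    ## convert meiosis-state posterior to origin posterior per locus:
    ## P(op, om | .) = sum_m gamma(m)/Em(m) qs[mp,op] qd[mm,om] e[op,om]
    for (j in seq_len(L)) {
      g <- Emat(gamma, j) / gs[, j]
      ej <- Emat(e, j)
      w <- g / Emat(Em, j)
      w[!is.finite(w)] <- 0
      sP <- cbind(qs_pat[, j], qs_pat[, j], qs_mat[, j], qs_mat[, j])
      dP <- cbind(qd_pat[, j], qd_mat[, j], qd_pat[, j], qd_mat[, j])
      ## joint over (op, om): accumulate over the 4 meiosis states
      p <- matrix(0, k, 4)
      for (m in 1:4) {
        qp1 <- sP[, m]; qm1 <- dP[, m]
        wm <- w[, m]
        p[, 1] <- p[, 1] + wm * qp1 * qm1 * ej[, 1]
        p[, 2] <- p[, 2] + wm * qp1 * (1 - qm1) * ej[, 2]
        p[, 3] <- p[, 3] + wm * (1 - qp1) * qm1 * ej[, 3]
        p[, 4] <- p[, 4] + wm * (1 - qp1) * (1 - qm1) * ej[, 4]
      }
      ps <- rowSums(p)
      fix <- ps <= 0
      if (any(fix)) { p[fix, ] <- 0.25; ps[fix] <- 1 }
      post[I, , j] <- p / ps
    }
  }

  if (is.null(individuals)) {
    individuals <- if (!is.null(cross$pheno))
      intersect(cross$pheno$id, ids[!ped$founder]) else ids
  }
  sel <- idx[as.character(individuals)]
  if (anyNA(sel))
    stop("individual(s) not in pedigree: ",
         paste(individuals[is.na(sel)], collapse = ", "))
  if (any(no_marker[sel]))
    warning(sum(no_marker[sel]), " individual(s) have no genotyped marker ",
            "on chromosome ", chrom, "; prior posteriors returned")
  out <- post[sel, , qpos_idx, drop = FALSE]
  dimnames(out) <- list(individuals, c("p11", "p12", "p21", "p22"),
                        format(positions, trim = TRUE))
  out
}

#' QTL regression coefficients from line-origin posteriors
#'
#' Converts ordered line-origin posteriors into the expected QTL design
#' coefficients of the fixed-effect line-cross parameterization:
#' `c_add = p11 - p22` (line-1 minus line-2 dosage contrast),
#' `c_dom = p12 + p21` (heterozygosity probability),
#' `c_imp_pat = (p11 + p12) - (p21 + p22)` (paternal-allele line contrast,
#' fitted when the maternal copy is silenced, i.e. maternal imprinting) and
#' `c_imp_mat = (p11 + p21) - (p12 + p22)` (maternal-allele contrast).
#'
#' @param post array from [origin_posteriors()] (or a single
#'   individuals x 4 matrix).
#' @return If `post` has one position: matrix individuals x 4 with columns
#'   `add`, `dom`, `imp_pat`, `imp_mat`; otherwise a 3-d array
#'   `[individual, coefficient, position]`.
#' @export
qtl_coefficients <- function(post) {
  if (length(dim(post)) == 2L) post <- array(post, c(dim(post), 1L),
                                             dimnames = c(dimnames(post),
                                                          list(NULL)))
  co <- array(NA_real_, c(dim(post)[1], 4, dim(post)[3]),
              dimnames = list(dimnames(post)[[1]],
                              c("add", "dom", "imp_pat", "imp_mat"),
                              dimnames(post)[[3]]))
  co[, 1, ] <- post[, 1, ] - post[, 4, ]
  co[, 2, ] <- post[, 2, ] + post[, 3, ]
  co[, 3, ] <- post[, 1, ] + post[, 2, ] - post[, 3, ] - post[, 4, ]
  co[, 4, ] <- post[, 1, ] + post[, 3, ] - post[, 2, ] - post[, 4, ]
  if (dim(co)[3] == 1L) {
    out <- co[, , 1, drop = FALSE]
    dim(out) <- dim(co)[1:2]
    dimnames(out) <- dimnames(co)[1:2]
    out
  } else co
}

#' SNP additive coding
#'
#' The -1/0/+1 indicator for a biallelic SNP: genotype 22 codes +1,
#' 11 codes -1, 12 codes 0; missing stays missing.
#'
#' @param genos a [genotypes] object.
#' @param marker marker name.
#' @return Named numeric vector over `genos$ids`.
#' @export
snp_lambda <- function(genos, marker) {
  j <- match(marker, genos$markers)
  if (is.na(j)) stop("unknown marker: ", marker)
  x <- genos$a1[, j]; y <- genos$a2[, j]
  ok <- is.na(x) | (x %in% c(1L, 2L) & y %in% c(1L, 2L))
  if (!all(ok)) stop("marker ", marker, " is not biallelic 1/2-coded")
  stats::setNames(as.numeric(x + y - 3L), genos$ids)
}

#' Parent-of-origin SNP coding for imprinting analyses
#'
#' Determines, where logically forced by the trio genotypes, which of the
#' child's alleles is of paternal and maternal origin, and returns the
#' -1/+1 code of the expressed allele: under maternal imprinting the
#' paternal allele is expressed (`mode = "maternal"`), and vice versa.
#' Homozygous children are always determined; a heterozygous child is
#' determined only when the parents' genotypes are consistent with exactly
#' one assignment. Undetermined or Mendelian-inconsistent trios are excluded
#' (`NA`) so they do not contribute to the likelihood.
#'
#' @param cross a [cross_data] (pedigree + genotypes).
#' @param marker marker name.
#' @param mode `"maternal"` (paternal allele expressed) or `"paternal"`
#'   (maternal allele expressed) imprinting.
#' @return Named numeric vector over the pedigree ids: +1 if the expressed
#'   allele is 2, -1 if allele 1, `NA` if excluded.
#' @export
snp_lambda_imprinted <- function(cross, marker,
                                 mode = c("maternal", "paternal")) {
  mode <- match.arg(mode)
  genos <- cross$genos
  ped <- cross$ped
  j <- match(marker, genos$markers)
  if (is.na(j)) stop("unknown marker: ", marker)
  gx <- genos$a1[, j]; gy <- genos$a2[, j]
  gid <- genos$ids
  get_g <- function(id) {
    k <- match(id, gid)
    if (is.na(k)) c(NA_integer_, NA_integer_) else c(gx[k], gy[k])
  }
  carries <- function(g, a) !anyNA(g) && a %in% g
  out <- stats::setNames(rep(NA_real_, nrow(ped)), ped$id)
  n_incons <- 0L
  for (i in seq_len(nrow(ped))) {
    ch <- get_g(ped$id[i])
    if (anyNA(ch)) next
    if (ch[1] == ch[2]) {
      pat <- ch[1]; mat <- ch[1]
    } else {
      if (is.na(ped$sire[i]) || is.na(ped$dam[i])) next
      sg <- get_g(ped$sire[i]); dg <- get_g(ped$dam[i])
      if (anyNA(sg) || anyNA(dg)) next
      c12 <- carries(sg, 1L) && carries(dg, 2L)  # pat=1, mat=2
      c21 <- carries(sg, 2L) && carries(dg, 1L)  # pat=2, mat=1
      if (c12 && c21) next                  # ambiguous: excluded
      if (!c12 && !c21) { n_incons <- n_incons + 1L; next }
      pat <- if (c12) 1L else 2L
      mat <- if (c12) 2L else 1L
    }
    expressed <- if (mode == "maternal") pat else mat
    out[i] <- if (expressed == 2L) 1 else -1
  }
  if (n_incons > 0L)
    warning(n_incons, " Mendelian-inconsistent trio(s) at marker ", marker,
            " excluded")
  out
}

#' Epistatic interaction columns
#'
#' Elementwise products of QTL coefficient columns for two loci. The
#' predetermined schemes are `"aa"` (add x add), `"ad"`, `"da"` and `"dd"`;
#' `scheme = "user"` takes an explicit list of effect pairs, e.g.
#' `list(c("add", "dom"), c("dom", "dom"))`.
#'
#' @param coefA,coefB coefficient matrices from [qtl_coefficients()] for the
#'   two partner loci (same individuals, same order).
#' @param scheme interaction scheme.
#' @param pairs list of effect-name pairs when `scheme = "user"`.
#' @return Matrix of interaction columns (named `A:B` per effect pair).
#' @export
epistasis_columns <- function(coefA, coefB,
                              scheme = c("aa", "ad", "da", "dd", "user"),
                              pairs = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(coefA) == nrow(coefB))
  eff <- c(a = "add", d = "dom")
  if (scheme == "user") {
    if (is.null(pairs)) stop("scheme 'user' requires 'pairs'")
  } else {
    s <- strsplit(scheme, "")[[1]]
    pairs <- list(c(eff[[s[1]]], eff[[s[2]]]))
  }
  cols <- vapply(pairs, function(pr) {
    if (!pr[1] %in% colnames(coefA) || !pr[2] %in% colnames(coefB))
      stop("unknown effect in epistasis pair: ", paste(pr, collapse = " x "))
    coefA[, pr[1]] * coefB[, pr[2]]
  }, numeric(nrow(coefA)))
  cols <- matrix(cols, nrow = nrow(coefA))
  colnames(cols) <- vapply(pairs, function(pr)
    paste0(pr[1], ":", pr[2]), character(1))
  rownames(cols) <- rownames(coefA)
  cols
}
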