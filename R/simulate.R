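## Seed-controlled simulator of two-line cross data (pedigree, genotypes
## under Haldane meiosis, map, phenotypes with QTL + polygenic + residual
## components) and of SNP panels with optional population structure.

#' Describe a simulated cross design
#'
#' The default emulates a two-line intercross of about 500 phenotyped F2
#' individuals genotyped at markers spaced every 5 cM, with an additive QTL
#' of one phenotypic standard deviation and a polygenic heritability of 0.4
#' (heritability is defined over the polygenic + residual variance,
#' excluding the QTL). F3 and backcross individuals can be added; founder
#' lines are fixed for alternative marker alleles.
#'
#' @param n_f2,n_f3,n_bc numbers of phenotyped F2, F3 and backcross (to
#'   line 1) individuals.
#' @param n_founders founders per line (default 30, giving one F1 per
#'   founder pair and offspring spread over many F1 couples, as in typical
#'   resource populations; too few families makes pedigree-based
#'   heritability estimates imprecise regardless of offspring count).
#' @param chr_length_cM chromosome length (one chromosome).
#' @param marker_step_cM marker spacing; markers run from 0 to the
#'   chromosome end.
#' @param qtl list with `pos_cM`, `a` (additive), `d` (dominance),
#'   optionally `i_pat`, `i_mat` (imprinting effects). `a` is the half
#'   difference between the two homozygous line-origin genotypes.
#' @param h2 polygenic heritability sigma_u^2 / (sigma_u^2 + sigma_e^2).
#' @param var_p non-QTL phenotypic variance sigma_u^2 + sigma_e^2.
#' @param mu intercept.
#' @param sex_effect additive fixed effect of sex "m" vs "f".
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_f2 = 500, n_f3 = 0, n_bc = 0, n_founders = 30,
                       chr_length_cM = 50, marker_step_cM = 5,
                       qtl = list(pos_cM = 17, a = -1, d = 0),
                       h2 = 0.4, var_p = 1, mu = 10, sex_effect = 0.5,
                       seed = 1) {
  stopifnot(h2 >= 0, h2 < 1, var_p > 0, n_f2 + n_f3 + n_bc > 0)
  qtl <- utils::modifyList(list(pos_cM = 17, a = 0, d = 0, i_pat = 0,
                                i_mat = 0), as.list(qtl))
  if (qtl$pos_cM < 0 || qtl$pos_cM > chr_length_cM)
    stop("QTL position outside the chromosome")
  structure(list(n_f2 = n_f2, n_f3 = n_f3, n_bc = n_bc,
                 n_founders = n_founders, chr_length_cM = chr_length_cM,
                 marker_step_cM = marker_step_cM, qtl = qtl, h2 = h2,
                 var_p = var_p, mu = mu, sex_effect = sex_effect,
                 seed = seed),
            class = "sim_design")
}

## A haplotype is a step function of line origin along the chromosome:
## list(br = breakpoint starts (first 0), or = origin per segment).
.hap_const <- function(l) list(br = 0, or = l)
.hap_at <- function(h, x) h$or[findInterval(x, h$br)]

## One meiosis under the Haldane model: Poisson crossover count, uniform
## positions, no interference; returns the transmitted haplotype.
.meiosis <- function(hp, hm, len_cM) {
  k <- stats::rpois(1, len_cM / 100)
  xs <- if (k > 0) sort(stats::runif(k, 0, len_cM)) else numeric(0)
  start_p <- stats::runif(1) < 0.5
  seg <- c(0, xs)
  use_p <- rep(c(start_p, !start_p), length.out = length(seg))
  br_all <- sort(unique(c(seg, hp$br, hm$br)))
  or <- vapply(seq_along(br_all), function(i) {
    x <- br_all[i]
    onp <- use_p[findInterval(x, seg)]
    if (onp) .hap_at(hp, x) else .hap_at(hm, x)
  }, 0)
  keep <- c(TRUE, diff(or) != 0)
  list(br = br_all[keep], or = or[keep])
}

#' Simulate a two-line cross
#'
#' Generates pedigree, fully line-informative marker genotypes produced by
#' Haldane-model meiosis, and phenotypes
#' `y = mu + sex + c_add a + c_dom d + c_imp effects + u + e` with
#' `u ~ N(0, A sigma_u^2)` (A from the simulated pedigree) and
#' `e ~ N(0, sigma_e^2)`, where the QTL coefficients are the true
#' line-origin codes at the QTL position. Founders and intermediate parents
#' carry genotypes but no phenotypes.
#'
#' @param design a [sim_design].
#' @param dir optional directory: writes `pedigree.txt`, `genotypes.txt`,
#'   `map.txt`, `phenotypes.txt`, `truth.txt` (the truth file is for
#'   validation only and is never read by analysis code).
#' @return A list with `cross` (a [cross_data] including the phenotype
#'   table), `truth` (per-phenotyped-individual true QTL codes, `u`, `e`),
#'   `design`, and `files` (paths, when `dir` is given).
#' @export
simulate_cross <- function(design = sim_design(), dir = NULL) {
  set.seed(design$seed)
  len <- design$chr_length_cM
  mpos <- seq(0, len, by = design$marker_step_cM)
  nm <- length(mpos)
  map <- genetic_map(sprintf("m%02d", seq_len(nm)), rep("1", nm), mpos)

  nf <- design$n_founders
  id_l1 <- sprintf("L1_%02d", seq_len(nf))
  id_l2 <- sprintf("L2_%02d", seq_len(nf))
  ped_id <- c(id_l1, id_l2)
  ped_sire <- rep(NA_character_, 2 * nf)
  ped_dam <- rep(NA_character_, 2 * nf)
  haps <- list()
  for (i in id_l1) haps[[i]] <- list(p = .hap_const(1), m = .hap_const(1))
  for (i in id_l2) haps[[i]] <- list(p = .hap_const(2), m = .hap_const(2))

  add_ind <- function(id, sire, dam) {
    ped_id <<- c(ped_id, id)
    ped_sire <<- c(ped_sire, sire)
    ped_dam <<- c(ped_dam, dam)
    hs <- haps[[sire]]; hd <- haps[[dam]]
    haps[[id]] <<- list(p = .meiosis(hs$p, hs$m, len),
                        m = .meiosis(hd$p, hd$m, len))
  }

  ## F1: one per founder pair
  id_f1 <- sprintf("F1_%02d", seq_len(nf))
  for (i in seq_len(nf)) add_ind(id_f1[i], id_l1[i], id_l2[i])

  pick2 <- function(pool) sample(pool, 2)
  ## phenotyped F2
  id_f2 <- if (design$n_f2 > 0) sprintf("F2_%04d", seq_len(design$n_f2))
           else character(0)
  for (id in id_f2) { pr <- pick2(id_f1); add_ind(id, pr[1], pr[2]) }
  ## F3 need F2 parents of their own
  id_f3 <- character(0)
  if (design$n_f3 > 0) {
    npar <- max(4L, ceiling(design$n_f3 / 5))
    id_f2p <- sprintf("F2P_%03d", seq_len(npar))
    for (id in id_f2p) { pr <- pick2(id_f1); add_ind(id, pr[1], pr[2]) }
    id_f3 <- sprintf("F3_%04d", seq_len(design$n_f3))
    for (id in id_f3) { pr <- pick2(id_f2p); add_ind(id, pr[1], pr[2]) }
  }
  ## backcross to line 1
  id_bc <- if (design$n_bc > 0) sprintf("BC_%04d", seq_len(design$n_bc))
           else character(0)
  for (id in id_bc)
    add_ind(id, sample(id_f1, 1), sample(id_l1, 1))

  ped <- pedigree(ped_id, ped_sire, ped_dam)

  ## genotypes: allele = line origin at the marker (lines fixed 1 vs 2)
  n_all <- length(ped_id)
  a1 <- matrix(NA_integer_, n_all, nm, dimnames = list(ped_id, map$marker))
  a2 <- a1
  for (i in ped_id) {
    a1[i, ] <- vapply(mpos, function(x) .hap_at(haps[[i]]$p, x), 0)
    a2[i, ] <- vapply(mpos, function(x) .hap_at(haps[[i]]$m, x), 0)
  }
  genos <- genotypes(ped_id, map$marker, a1, a2)

  ## polygenic values down the pedigree (founders N(0, s2u); offspring
  ## midparent + Mendelian sampling, inbreeding-adjusted via diag(A))
  s2u <- design$h2 * design$var_p
  s2e <- design$var_p - s2u
  A <- pedigree_A(ped)$values
  uu <- stats::setNames(numeric(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    if (ped$founder[i]) {
      uu[i] <- stats::rnorm(1, 0, sqrt(s2u))
    } else {
      s <- ped$sire[i]; d <- ped$dam[i]
      fs <- A[s, s] - 1; fd <- A[d, d] - 1
      msv <- s2u * (0.5 - 0.25 * (fs + fd))
      uu[i] <- 0.5 * (uu[s] + uu[d]) + stats::rnorm(1, 0, sqrt(msv))
    }
  }

  ## phenotypes for the final generations
  id_ph <- c(id_f2, id_f3, id_bc)
  np <- length(id_ph)
  qp <- design$qtl$pos_cM
  op <- vapply(id_ph, function(i) .hap_at(haps[[i]]$p, qp), 0)
  om <- vapply(id_ph, function(i) .hap_at(haps[[i]]$m, qp), 0)
  c_add <- (op == 1) + (om == 1) - 1
  c_dom <- as.numeric(op != om)
  c_ip <- ifelse(op == 1, 1, -1)
  c_im <- ifelse(om == 1, 1, -1)
  sex <- sample(c("f", "m"), np, replace = TRUE)
  e <- stats::rnorm(np, 0, sqrt(s2e))
  y <- design$mu + design$sex_effect * (sex == "m") +
    c_add * design$qtl$a + c_dom * design$qtl$d +
    c_ip * design$qtl$i_pat + c_im * design$qtl$i_mat +
    uu[id_ph] + e
  pheno <- data.frame(id = id_ph, y = y, sex = sex,
                      generation = c(rep("F2", length(id_f2)),
                                     rep("F3", length(id_f3)),
                                     rep("BC", length(id_bc))),
                      stringsAsFactors = FALSE)
  truth <- data.frame(id = id_ph, c_add = c_add, c_dom = c_dom,
                      c_imp_pat = c_ip, c_imp_mat = c_im,
                      u = unname(uu[id_ph]), e = e,
                      stringsAsFactors = FALSE)

  lines <- stats::setNames(c(rep(1L, nf), rep(2L, nf)), c(id_l1, id_l2))
  cross <- cross_data(ped, genos, map, lines, pheno = pheno)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hdr <- paste0("simulated cross, seed ", design$seed)
    files <- list(pedigree = file.path(dir, "pedigree.txt"),
                  genotypes = file.path(dir, "genotypes.txt"),
                  map = file.path(dir, "map.txt"),
                  phenotypes = file.path(dir, "phenotypes.txt"),
                  truth = file.path(dir, "truth.txt"))
    write_pedigree(ped, files$pedigree, hdr)
    write_genotypes(genos, files$genotypes, hdr)
    write_map(map, files$map, hdr)
    write_phenotypes(pheno, files$phenotypes, hdr)
    write_phenotypes(truth, files$truth, c(hdr, "truth file: tests only"))
  }
  list(cross = cross, truth = truth, design = design, files = files)
}

#' Simulate a SNP panel
#'
#' Draws Hardy-Weinberg genotypes at independent biallelic SNPs, optionally
#' in differentiated subpopulations: each subpopulation's allele frequency
#' drifts from the ancestral frequency following a Balding-Nichols Beta
#' distribution with differentiation parameter `Fst`.
#'
#' @param m individuals.
#' @param n SNPs.
#' @param maf_range ancestral allele-2 frequencies drawn uniformly in this
#'   interval (within (0, 0.5]; the frequency is used as drawn, so allele 2
#'   is the minor allele ancestrally).
#' @param structure `NULL` for a single panmictic population, or a list
#'   `list(k = , Fst = )` for `k` equal-sized subpopulations at the given
#'   differentiation.
#' @param seed RNG seed.
#' @return A list: `genos` (a [genotypes] object, ids `S001`...),
#'   `subpop` (integer vector), `q` (ancestral frequencies).
#' @export
simulate_snp_panel <- function(m, n, maf_range = c(0.1, 0.5),
                               structure = NULL, seed = 1) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(seed)
  q <- stats::runif(n, maf_range[1], maf_range[2])
  k <- if (is.null(structure)) 1L else structure$k
  subpop <- sort(rep_len(seq_len(k), m))
  qs <- matrix(rep(q, each = k), nrow = k)
  if (!is.null(structure) && structure$Fst > 0) {
    Fst <- structure$Fst
    a <- q * (1 - Fst) / Fst
    b <- (1 - q) * (1 - Fst) / Fst
    for (s in seq_len(k)) qs[s, ] <- stats::rbeta(n, a, b)
  }
  ids <- sprintf("S%03d", seq_len(m))
  pm <- qs[subpop, , drop = FALSE]
  a1 <- matrix(1L + (stats::runif(m * n) < pm), m, n)
  a2 <- matrix(1L + (stats::runif(m * n) < pm), m, n)
  g <- genotypes(ids, sprintf("snp%04d", seq_len(n)), a1, a2)
  list(genos = g, subpop = subpop, q = q)
}
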