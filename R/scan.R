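## Positional QTL scans, per-SNP association scans, nested-model
## likelihood-ratio tests and conditional linkage-vs-LD comparisons.

#' P-value from a likelihood-ratio statistic
#'
#' Upper tail of the chi-square distribution with `df` degrees of freedom,
#' or, for a variance-component test on the boundary, the 50:50 mixture of
#' a point mass at zero and a chi-square: `p = 0.5 P(chisq_df > stat)`
#' (plus 0.5 when the statistic is exactly zero, so `p = 1` there).
#'
#' @param stat LRT statistic(s); small negative values (> -1e-6) are
#'   clipped to zero.
#' @param df degrees of freedom (>= 1).
#' @param null `"chisq"` or `"mixture50"`.
#' @return P-value(s) in `(0, 1]`.
#' @export
pvalue_from_lrt <- function(stat, df, null = c("chisq", "mixture50")) {
  null <- match.arg(null)
  if (any(df < 1)) stop("df must be >= 1")
  if (any(stat < -1e-6)) stop("negative LRT statistic")
  stat <- pmax(stat, 0)
  tail <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (null == "chisq") tail else 0.5 * tail + 0.5 * (stat == 0)
}

## Drop qtl columns that are (numerically) linearly dependent on the null
## design; returns the kept column indices.
.independent_columns <- function(Xnull, cols, tol = 1e-8) {
  keep <- integer(0)
  Xc <- Xnull
  for (j in seq_len(ncol(cols))) {
    cj <- cols[, j]
    fit <- stats::lm.fit(Xc, cj)
    if (sqrt(sum(fit$residuals^2)) > tol * max(1, sqrt(sum(cj^2)))) {
      keep <- c(keep, j)
      Xc <- cbind(Xc, cj)
    }
  }
  keep
}

## QTL coefficient columns at one position, with optional nesting within a
## cross-classified column of `data`.
.qtl_design_columns <- function(co, effects, nest = NULL, data = NULL,
                                id = "id", prefix = "qtl") {
  cols <- co[, effects, drop = FALSE]
  colnames(cols) <- paste0(prefix, "_", effects)
  if (is.null(nest)) return(cols)
  if (is.null(data) || !nest %in% names(data))
    stop("nesting column '", nest, "' not found in the data")
  lev_by_id <- tapply(as.character(data[[nest]]), as.character(data[[id]]),
                      function(x) x[1])
  lv <- lev_by_id[rownames(cols)]
  levels_all <- sort(unique(stats::na.omit(as.character(data[[nest]]))))
  out <- do.call(cbind, lapply(levels_all, function(l) {
    m <- cols * as.numeric(lv == l)
    colnames(m) <- paste0(colnames(cols), ":", nest, l)
    m
  }))
  rownames(out) <- rownames(cols)
  out
}

#' Likelihood-ratio QTL scan along chromosomes
#'
#' At each grid position the line-origin QTL coefficients are computed from
#' the marker data, appended to the fixed-effect design, and the model is
#' compared with the reduced model without the QTL by a likelihood-ratio
#' test (ML log-likelihoods, since the models differ in fixed effects).
#' By default the variance components are re-estimated by REML at every
#' position; `fix_vc = TRUE` reuses the reduced-model estimates, which is
#' much faster and usually indistinguishable.
#'
#' @param fixed fixed-effect formula (response on the left).
#' @param cross a [cross_data] with a phenotype table.
#' @param random named list of random terms (see [build_design()]).
#' @param effects QTL effects to fit: subset of
#'   `c("add", "dom", "imp_pat", "imp_mat")`.
#' @param chrom chromosome(s) to scan (default: all in the map).
#' @param step grid step in cM (default 1; marker positions always
#'   included).
#' @param grid explicit position vector (overrides `step`; single
#'   chromosome only).
#' @param nest optional column name of `cross$pheno`: the QTL coefficients
#'   are nested within its levels (one column per level).
#' @param fix_vc reuse the reduced-model variance components along the scan.
#' @param id id column name.
#' @param tol,max_iter EM-REML controls for the per-position fits.
#' @return A `data.frame` of class `qmm_scan`: columns `chrom`, `pos_cM`,
#'   `LRT`, `df`, `p` and estimate/SE pairs per QTL column, with attributes
#'   `argmax` (row of the maximum LRT; ties broken toward the lowest cM)
#'   and `null` (the reduced-model fit).
#' @export
scan_qtl <- function(fixed, cross, random = NULL,
                     effects = "add", chrom = NULL, step = 1, grid = NULL,
                     nest = NULL, fix_vc = FALSE, id = "id",
                     tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(cross, "cross_data"))
  data <- cross$pheno
  if (is.null(data)) stop("cross has no phenotype table")
  effects <- match.arg(effects, c("add", "dom", "imp_pat", "imp_mat"),
                       several.ok = TRUE)
  if (is.null(chrom)) chrom <- unique(cross$map$chrom)
  if (!is.null(grid) && length(chrom) > 1L)
    stop("an explicit grid requires a single chromosome")
  null_fit <- qmm(fixed, data, random = random, id = id, tol = tol,
                  max_iter = max_iter)
  rows <- list()
  for (ch in chrom) {
    positions <- if (!is.null(grid)) sort(unique(grid)) else
      scan_grid(cross$map, ch, step)
    if (!length(positions)) stop("empty scan grid on chromosome ", ch)
    post <- origin_posteriors(cross, ch, positions,
                              individuals = intersect(
                                data$id, cross$ped$id[!cross$ped$founder]))
    for (ix in seq_along(positions)) {
      co <- qtl_coefficients(post[, , ix, drop = FALSE])
      cols <- .qtl_design_columns(co, effects, nest, data, id)
      res <- .fit_and_test(fixed, data, random, cols, null_fit, fix_vc, id,
                           tol = tol, max_iter = max_iter)
      rows[[length(rows) + 1L]] <-
        c(list(chrom = ch, pos_cM = positions[ix]), res)
    }
  }
  .as_scan(rows, null_fit, type = "position")
}

.fit_and_test <- function(fixed, data, random, cols, null_fit, fix_vc, id,
                          subset_ids = NULL, tol = 1e-8, max_iter = 1000) {
  ds0 <- null_fit$design
  ## align columns to the null design rows to test independence
  ridx <- match(ds0$ids, rownames(cols))
  cols_n <- cols[ridx, , drop = FALSE]
  ok <- stats::complete.cases(cols_n)
  keep <- .independent_columns(ds0$X[ok, , drop = FALSE],
                               cols_n[ok, , drop = FALSE])
  est <- rep(NA_real_, ncol(cols))
  se <- rep(NA_real_, ncol(cols))
  names(est) <- names(se) <- colnames(cols)
  if (!length(keep))
    return(list(LRT = 0, df = ncol(cols), p = 1, est = est, se = se,
                df_used = 0L))
  cols_kept <- cols[, keep, drop = FALSE]
  vc0 <- if (fix_vc) null_fit$vc_list else NULL
  warm <- if (!fix_vc) null_fit$vc_list else NULL  # EM warm start
  full <- qmm(fixed, data, random = random, qtl_columns = cols_kept,
              vc = vc0, fix_vc = fix_vc, id = id, tol = tol,
              max_iter = max_iter, start = warm)
  if (!all(ok)) {
    ## some individuals lack coefficients: refit the reduced model on the
    ## same subset so the likelihoods are comparable
    sub <- data[as.character(data$id) %in% full$design$ids, , drop = FALSE]
    red <- qmm(fixed, sub, random = random, vc = vc0, fix_vc = fix_vc,
               id = id, tol = tol, max_iter = max_iter, start = warm)
  } else red <- null_fit
  lrt <- max(0, 2 * (full$loglik_ml - red$loglik_ml))
  df <- length(keep)
  cn <- colnames(cols)[keep]
  est[cn] <- full$coefficients[cn]
  se[cn] <- full$se[cn]
  list(LRT = lrt, df = df, p = pvalue_from_lrt(lrt, df), est = est, se = se,
       df_used = df)
}

.as_scan <- function(rows, null_fit, type) {
  first <- rows[[1L]]
  base <- data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
                     stringsAsFactors = FALSE)
  poscol <- if (type == "position") "pos_cM" else "marker"
  base[[poscol]] <- if (type == "position")
    vapply(rows, `[[`, 0, "pos_cM") else vapply(rows, `[[`, "", "marker")
  base$LRT <- vapply(rows, `[[`, 0, "LRT")
  base$df <- vapply(rows, `[[`, 0, "df")
  base$p <- vapply(rows, `[[`, 0, "p")
  for (nm in names(first$est)) {
    base[[nm]] <- vapply(rows, function(r) unname(r$est[nm]), 0)
    base[[paste0("se_", nm)]] <- vapply(rows, function(r) unname(r$se[nm]), 0)
  }
  am <- which.max(base$LRT)  # which.max takes the first (lowest cM) on ties
  structure(base, argmax = base[am, , drop = FALSE], null = null_fit,
            scan_type = type, class = c("qmm_scan", "data.frame"))
}

#' @export
print.qmm_scan <- function(x, ...) {
  am <- attr(x, "argmax")
  cat("QTL scan profile:", nrow(x), "test(s)\n")
  cat("Maximum LRT", format(am$LRT, digits = 6), "(df", am$df, ", p",
      format(am$p, digits = 4), ") at ",
      if (attr(x, "scan_type") == "position")
        paste0(am$chrom, ":", am$pos_cM, " cM") else am$marker, "\n")
  invisible(x)
}

#' @export
summary.qmm_scan <- function(object, ...) attr(object, "argmax")

#' Plot a scan profile
#'
#' Plots `-log10(p)` against map position (or SNP index), one panel track
#' per chromosome, base graphics.
#'
#' @param x a `qmm_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qmm_scan <- function(x, ...) {
  ylab <- expression(-log[10](p))
  if (attr(x, "scan_type") == "position") {
    chs <- unique(x$chrom)
    offs <- 0
    xs <- numeric(nrow(x))
    for (ch in chs) {
      i <- x$chrom == ch
      xs[i] <- x$pos_cM[i] + offs
      offs <- max(xs[i]) + 10
    }
    graphics::plot(xs, -log10(x$p), type = "l", xlab = "position (cM)",
                   ylab = ylab, ...)
  } else {
    graphics::plot(seq_len(nrow(x)), -log10(x$p), type = "h", xlab = "SNP",
                   ylab = ylab, ...)
  }
  invisible(x)
}

#' Per-SNP association scan
#'
#' Tests each SNP for association with the trait. In `mode = "fixed"` the
#' -1/0/+1 additive code (or the parent-of-origin code under imprinting) is
#' added to the fixed design and tested by a 1-df likelihood-ratio test; in
#' `mode = "random"` the SNP effect is a random term with the genotype code
#' as incidence and its variance component is tested against the 50:50
#' boundary mixture null. Individuals with a missing (or, under imprinting,
#' undeterminable) code are excluded for that SNP, and the reduced model is
#' refit on the same subset. A polygenic or genomic random term in `random`
#' provides structure correction.
#'
#' @param fixed fixed-effect formula.
#' @param cross a [cross_data] (phenotypes + genotypes; the pedigree is only
#'   used for imprinting codes).
#' @param snps marker names to test (default: all markers).
#' @param random named list of random terms.
#' @param mode `"fixed"` or `"random"` SNP effect.
#' @param imprinting `NULL` (additive coding) or `"maternal"` / `"paternal"`
#'   (imprinting mode, see [snp_lambda_imprinted()]).
#' @param fix_vc reuse null-model variance components (default `TRUE` in
#'   fixed mode when random terms are present).
#' @param id id column name.
#' @param tol,max_iter EM-REML controls.
#' @return A `qmm_scan` data.frame with one row per tested SNP (skipped
#'   SNPs are omitted, with a warning).
#' @export
scan_association <- function(fixed, cross, snps = NULL, random = NULL,
                             mode = c("fixed", "random"), imprinting = NULL,
                             fix_vc = mode[1] == "fixed" && length(random) > 0,
                             id = "id", tol = 1e-8, max_iter = 1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(cross, "cross_data"))
  data <- cross$pheno
  if (is.null(data)) stop("cross has no phenotype table")
  if (is.null(snps)) snps <- cross$genos$markers
  null_fit <- qmm(fixed, data, random = random, id = id, tol = tol,
                  max_iter = max_iter)
  rows <- list()
  skipped <- character(0)
  for (snp in snps) {
    lam <- if (is.null(imprinting)) snp_lambda(cross$genos, snp) else
      snp_lambda_imprinted(cross, snp, mode = imprinting)
    lam_obs <- lam[!is.na(lam)]
    if (length(unique(lam_obs)) < 2L) {
      skipped <- c(skipped, snp)
      next
    }
    cols <- matrix(lam, ncol = 1, dimnames = list(names(lam), "snp"))
    if (mode == "fixed") {
      res <- .fit_and_test(fixed, data, random, cols, null_fit, fix_vc, id,
                           tol = tol, max_iter = max_iter)
    } else {
      res <- .random_snp_test(fixed, data, random, cols, null_fit, id,
                              tol = tol, max_iter = max_iter)
    }
    rows[[length(rows) + 1L]] <- c(list(chrom = .marker_chrom(cross, snp),
                                        marker = snp), res)
  }
  if (length(skipped))
    warning("skipped SNP(s) with fewer than 2 genotype classes: ",
            paste(utils::head(skipped, 10), collapse = ", "))
  if (!length(rows)) stop("no testable SNPs")
  .as_scan(rows, null_fit, type = "snp")
}

.marker_chrom <- function(cross, snp) {
  j <- match(snp, cross$map$marker)
  if (is.na(j)) "NA" else cross$map$chrom[j]
}

.random_snp_test <- function(fixed, data, random, cols, null_fit, id,
                             tol = 1e-8, max_iter = 1000) {
  lam <- cols[, 1]
  ids <- as.character(data$id)
  lam_row <- lam[ids]
  ok <- !is.na(lam_row)
  sub <- data[ok, , drop = FALSE]
  Zsnp <- matrix(lam_row[ok], ncol = 1, dimnames = list(NULL, "snp"))
  r_full <- c(random, list(snp = list(Z = Zsnp)))
  full <- qmm(fixed, sub, random = r_full, id = id, tol = tol,
              max_iter = max_iter)
  red <- if (all(ok)) null_fit else
    qmm(fixed, sub, random = random, id = id, tol = tol,
        max_iter = max_iter)
  lrt <- max(0, 2 * (full$loglik_reml - red$loglik_reml))
  k <- length(full$vc)
  est <- stats::setNames(full$vc[["snp"]], "snp")
  list(LRT = lrt, df = 1, p = pvalue_from_lrt(lrt, 1, "mixture50"),
       est = est, se = stats::setNames(NA_real_, "snp"), df_used = 1L)
}

#' Conditional likelihood-ratio tests between two genetic terms
#'
#' Fits the full model containing both term A and term B (each a matrix of
#' fixed-effect columns, e.g. QTL coefficients and a SNP code) and returns
#' the likelihood-ratio test of each term conditional on the other:
#' `LRT(full vs full - A)` and `LRT(full vs full - B)`. Used to separate a
#' linkage signal from a linkage-disequilibrium signal at a correlated SNP.
#'
#' @param fixed fixed-effect formula.
#' @param data phenotype `data.frame`.
#' @param colsA,colsB matrices of fixed-effect columns for the two terms
#'   (rownames = individual ids).
#' @param random named list of random terms.
#' @param names length-2 labels for the two terms.
#' @param fix_vc reuse the full model's variance components in the reduced
#'   fits (default `FALSE`: each model re-estimated by REML).
#' @param id id column name.
#' @param tol,max_iter EM-REML controls.
#' @return `data.frame` of class `qmm_tests` with one row per term:
#'   `term`, `LRT`, `df`, `p` (chi-square null).
#' @export
conditional_test <- function(fixed, data, colsA, colsB, random = NULL,
                             names = c("A", "B"), fix_vc = FALSE, id = "id",
                             tol = 1e-8, max_iter = 1000) {
  colsA <- as.matrix(colsA); colsB <- as.matrix(colsB)
  if (is.null(colnames(colsA)))
    colnames(colsA) <- paste0(names[1], seq_len(ncol(colsA)))
  if (is.null(colnames(colsB)))
    colnames(colsB) <- paste0(names[2], seq_len(ncol(colsB)))
  ## align both term matrices on the data ids
  ids <- as.character(data$id)
  align <- function(m) {
    if (is.null(rownames(m))) {
      if (nrow(m) != nrow(data)) stop("term columns cannot be aligned")
      rownames(m) <- ids
      m
    } else m[match(ids, rownames(m)), , drop = FALSE]
  }
  colsA <- align(colsA); colsB <- align(colsB)
  rownames(colsA) <- rownames(colsB) <- ids
  both <- cbind(colsA, colsB)
  full <- tryCatch(
    qmm(fixed, data, random = random, qtl_columns = both, id = id,
        tol = tol, max_iter = max_iter),
    error = function(e) {
      if (grepl("rank deficient", conditionMessage(e)))
        stop("terms '", names[1], "' and '", names[2],
             "' are confounded (perfectly collinear)", call. = FALSE)
      stop(e)
    })
  ## collinearity check: within the fitted design, B must add rank beyond A
  X0 <- full$design$X[, setdiff(colnames(full$design$X),
                                colnames(both)), drop = FALSE]
  XA <- full$design$X[, colnames(colsA), drop = FALSE]
  XB <- full$design$X[, colnames(colsB), drop = FALSE]
  if (!length(.independent_columns(cbind(X0, XA), XB)) ||
      !length(.independent_columns(cbind(X0, XB), XA)))
    stop("terms '", names[1], "' and '", names[2],
         "' are confounded (perfectly collinear)")
  vc0 <- if (fix_vc) full$vc_list else NULL
  sub <- data[as.character(data$id) %in% full$design$ids, , drop = FALSE]
  redA <- qmm(fixed, sub, random = random, qtl_columns = colsB, vc = vc0,
              fix_vc = fix_vc, id = id, tol = tol, max_iter = max_iter)
  redB <- qmm(fixed, sub, random = random, qtl_columns = colsA, vc = vc0,
              fix_vc = fix_vc, id = id, tol = tol, max_iter = max_iter)
  lrtA <- max(0, 2 * (full$loglik_ml - redA$loglik_ml))
  lrtB <- max(0, 2 * (full$loglik_ml - redB$loglik_ml))
  out <- data.frame(
    term = names,
    LRT = c(lrtA, lrtB),
    df = c(ncol(colsA), ncol(colsB)),
    p = c(pvalue_from_lrt(lrtA, ncol(colsA)),
          pvalue_from_lrt(lrtB, ncol(colsB))),
    stringsAsFactors = FALSE)
  attr(out, "full") <- full
  class(out) <- c("qmm_tests", "data.frame")
  out
}

#' @export
print.qmm_tests <- function(x, ...) {
  cat("Conditional likelihood-ratio tests (each term given the other):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
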