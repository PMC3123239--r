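## Henderson's mixed-model equations and EM-REML variance-component
## estimation.
##
## The model is y = X b + sum_k Z_k u_k + e with u_k ~ N(0, K_k s2_k)
## mutually independent and e ~ N(0, I s2_e). The MME coefficient matrix is
##   M = [[X'X, X'Z], [Z'X, Z'Z + K^-1 lambda]],  lambda_k = s2_e / s2_k,
## and Var([b; u - u_hat]) = M^-1 s2_e.

#' Build a design system
#'
#' Assembles the response, fixed-effect design and random-term incidence /
#' covariance structures for a model. Rows with a missing response, missing
#' model covariates or missing required QTL coefficients are dropped.
#'
#' @param fixed two-sided formula for the response and fixed effects, e.g.
#'   `y ~ sex + covar`. Factors are expanded to indicator columns with the
#'   reference level dropped; an intercept is included unless removed in the
#'   formula.
#' @param data `data.frame`; must contain an id column (see `id`) when
#'   random terms keyed by individual are used.
#' @param random named list of random-term descriptors. Each element is a
#'   [cov_matrix] (grouping column: the element's name if present in `data`,
#'   else the id column; levels are the matrix labels), the string
#'   `"identity"` (grouping column as above, identity covariance), or a list
#'   with an explicit numeric incidence matrix `Z` (n x q) and optional
#'   `K`/`K_inv` (identity if neither given).
#' @param qtl_columns optional numeric matrix of extra fixed-effect columns
#'   (QTL coefficients, SNP codes, epistasis products); rows must be named
#'   by individual id or match `data` row-for-row. Rows with `NA` are
#'   dropped from the analysis.
#' @param id name of the id column in `data` (default `"id"`).
#' @return A list of class `design_system`: `y`, `X`, `random` (each with
#'   `Z`, `Kinv`, `logdetK`, `q`), `ids` (per kept row), `rank`.
#' @export
build_design <- function(fixed, data, random = NULL, qtl_columns = NULL,
                         id = "id") {
  stopifnot(inherits(fixed, "formula"), length(fixed) == 3L)
  mf <- stats::model.frame(fixed, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  ids <- if (id %in% names(data)) as.character(data[[id]]) else
    as.character(seq_len(nrow(data)))

  Q <- NULL
  if (!is.null(qtl_columns)) {
    Q <- as.matrix(qtl_columns)
    if (!is.null(rownames(Q)) && !identical(rownames(Q), ids)) {
      ridx <- match(ids, rownames(Q))
      Q <- Q[ridx, , drop = FALSE]
    }
    if (nrow(Q) != nrow(data))
      stop("qtl_columns rows cannot be aligned to the data")
    keep <- keep & stats::complete.cases(Q)
  }
  if (!any(keep)) stop("no complete observations left")
  mf <- mf[keep, , drop = FALSE]
  ids <- ids[keep]
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!is.null(Q)) {
    Q <- Q[keep, , drop = FALSE]
    colnames(Q) <- colnames(qtl_columns)
    X <- cbind(X, Q)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("fixed-effect design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }

  rts <- list()
  if (length(random)) {
    if (is.null(names(random)) || any(!nzchar(names(random))))
      stop("random terms must be named")
    if (anyDuplicated(names(random))) stop("random-term names must be unique")
    dat_kept <- data[keep, , drop = FALSE]
    for (nm in names(random)) {
      spec <- random[[nm]]
      if (is.character(spec) && identical(spec, "identity")) spec <- list()
      if (inherits(spec, "cov_matrix")) spec <- list(K = spec)
      if (!is.list(spec)) stop("invalid random-term spec for '", nm, "'")
      if (!is.null(spec$Z)) {
        Z <- Matrix::Matrix(spec$Z[keep, , drop = FALSE], sparse = TRUE)
        q <- ncol(Z)
        labels <- colnames(spec$Z)
        if (is.null(labels)) labels <- as.character(seq_len(q))
      } else {
        gcol <- if (nm %in% names(dat_kept)) nm else id
        if (!gcol %in% names(dat_kept))
          stop("random term '", nm, "': no grouping column '", gcol, "'")
        grp <- as.character(dat_kept[[gcol]])
        if (!is.null(spec$K) || !is.null(spec$K_inv)) {
          labels <- if (!is.null(spec$K)) spec$K$labels else spec$K_inv$labels
        } else labels <- sort(unique(grp))
        j <- match(grp, labels)
        if (anyNA(j))
          stop("random term '", nm, "': level(s) missing from covariance ",
               "labels: ", paste(utils::head(unique(grp[is.na(j)]), 5),
                                 collapse = ", "))
        q <- length(labels)
        Z <- Matrix::sparseMatrix(i = seq_along(grp), j = j, x = 1,
                                  dims = c(length(grp), q))
      }
      if (!is.null(spec$K_inv)) {
        Kinv <- as.matrix(spec$K_inv)
        ch <- tryCatch(chol(Kinv), error = function(e)
          stop("random term '", nm, "': K_inv is not positive definite"))
        logdetK <- -2 * sum(log(diag(ch)))
      } else if (!is.null(spec$K)) {
        K <- as.matrix(spec$K)
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) {
          ## singular relationship matrix (common for standardized G):
          ## blend in a small ridge to make it invertible
          eps <- 1e-6 * mean(diag(K))
          message("random term '", nm,
                  "': covariance is singular; adding ridge ", signif(eps, 3))
          ch <- chol(K + diag(eps, nrow(K)))
        }
        logdetK <- 2 * sum(log(diag(ch)))
        Kinv <- chol2inv(ch)
      } else {
        Kinv <- diag(q)
        logdetK <- 0
      }
      rts[[nm]] <- list(name = nm, Z = Z, Kinv = Kinv, logdetK = logdetK,
                        q = q, labels = labels)
    }
  }
  structure(list(y = as.numeric(y), X = X, random = rts, ids = ids,
                 rank = qrX$rank),
            class = "design_system")
}

## Precompute the pieces of the MME that do not depend on the variance
## components.
.mme_blocks <- function(ds) {
  X <- ds$X
  y <- ds$y
  Zs <- lapply(ds$random, `[[`, "Z")
  W <- if (length(Zs)) cbind(X, do.call(cbind, lapply(Zs, as.matrix))) else X
  list(WtW = crossprod(W), Wty = drop(crossprod(W, y)), yty = sum(y^2),
       p = ncol(X), q = vapply(ds$random, `[[`, 0L, "q"))
}

.assemble_M <- function(blocks, ds, vc) {
  M <- blocks$WtW
  off <- blocks$p
  for (k in seq_along(ds$random)) {
    qk <- blocks$q[k]
    idx <- off + seq_len(qk)
    lam <- vc$residual / vc$components[k]
    M[idx, idx] <- M[idx, idx] + ds$random[[k]]$Kinv * lam
    off <- off + qk
  }
  M
}

#' Solve Henderson's mixed-model equations
#'
#' Computes the GLS fixed-effect solutions, the BLUPs of each random term,
#' their standard errors from the inverse coefficient matrix, and the
#' log-determinant pieces needed by the likelihood.
#'
#' @param ds a `design_system` from [build_design()].
#' @param vc variance components: list with `residual` (scalar > 0) and
#'   `components` (one per random term, in order).
#' @param method `"dense"` (full inverse, needed for EM and standard errors)
#'   or `"sparse"` (solutions only, sparse Cholesky).
#' @return List with `b`, `u` (list), `se_b`, `Cinv` (dense method only),
#'   `logdetM`, `yPy`, `logdet_ZZK` and bookkeeping fields.
#' @export
solve_mme <- function(ds, vc, method = c("dense", "sparse")) {
  method <- match.arg(method)
  stopifnot(vc$residual > 0)
  if (length(ds$random) && any(vc$components <= 0))
    stop("variance components must be strictly positive to solve the MME")
  blocks <- .mme_blocks(ds)
  M <- .assemble_M(blocks, ds, vc)
  neq <- nrow(M)
  if (method == "dense") {
    Md <- as.matrix(M)
    R <- tryCatch(chol(Md), error = function(e)
      stop("mixed-model equations are singular"))
    Cinv <- chol2inv(R)
    sol <- drop(Cinv %*% blocks$Wty)
    logdetM <- 2 * sum(log(diag(R)))
  } else {
    Ms <- methods::as(Matrix::Matrix(M, sparse = TRUE), "symmetricMatrix")
    ch <- Matrix::Cholesky(Ms, LDL = FALSE, perm = TRUE)
    sol <- drop(Matrix::solve(ch, blocks$Wty))
    logdetM <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus[1]
    Cinv <- NULL
  }
  p <- blocks$p
  b <- sol[seq_len(p)]
  names(b) <- colnames(ds$X)
  u <- list()
  off <- p
  for (k in seq_along(ds$random)) {
    qk <- blocks$q[k]
    u[[ds$random[[k]]$name]] <-
      stats::setNames(sol[off + seq_len(qk)], ds$random[[k]]$labels)
    off <- off + qk
  }
  yPy <- (blocks$yty - sum(sol * blocks$Wty)) / vc$residual
  ## log|Z'Z + lambda K^-1| for the ML likelihood
  logdet_ZZK <- 0
  if (length(ds$random)) {
    idx <- (p + 1L):neq
    Muu <- as.matrix(M[idx, idx])
    Ruu <- chol(Muu)
    logdet_ZZK <- 2 * sum(log(diag(Ruu)))
  }
  list(b = b, u = u,
       se_b = if (!is.null(Cinv))
         sqrt(pmax(diag(Cinv)[seq_len(p)], 0) * vc$residual) else NULL,
       Cinv = Cinv, logdetM = logdetM, logdet_ZZK = logdet_ZZK,
       yPy = yPy, blocks = blocks, neq = neq)
}

.loglik_from_solution <- function(ds, vc, sm, type = c("REML", "ML")) {
  type <- match.arg(type)
  N <- length(ds$y)
  p <- ds$rank
  q <- sum(vapply(ds$random, `[[`, 0L, "q"))
  sumK <- if (length(ds$random))
    sum(vapply(seq_along(ds$random), function(k)
      ds$random[[k]]$q * log(vc$components[k]) + ds$random[[k]]$logdetK,
      0)) else 0
  if (type == "REML") {
    m2l <- (N - p - q) * log(vc$residual) + sumK + sm$logdetM + sm$yPy +
      (N - p) * log(2 * pi)
  } else {
    if (!length(ds$random)) {
      ## profile ML for a pure fixed-effects Gaussian model
      rss <- sm$yPy * vc$residual
      s2 <- rss / N
      m2l <- N * log(2 * pi * s2) + N
    } else {
      logdetV <- (N - q) * log(vc$residual) + sumK + sm$logdet_ZZK
      m2l <- logdetV + sm$yPy + N * log(2 * pi)
    }
  }
  -m2l / 2
}

#' Restricted (or marginal) log-likelihood of a design system
#'
#' Evaluates the REML log-likelihood
#' `-2 l = log|V| + log|X' V^-1 X| + y' P y + (N - p) log 2 pi`
#' through the mixed-model-equation decomposition, or the (unrestricted)
#' Gaussian ML log-likelihood `-2 l = log|V| + y' P y + N log 2 pi`. For a
#' model with no random terms `type = "ML"` returns the profile ML
#' log-likelihood (residual variance at its MLE), so that likelihood-ratio
#' tests between nested fixed-effect models are the classical ones.
#'
#' @param ds a `design_system`.
#' @param vc variance components (`residual`, `components`).
#' @param type `"REML"` or `"ML"`.
#' @return Log-likelihood (scalar).
#' @export
reml_loglik <- function(ds, vc, type = c("REML", "ML")) {
  type <- match.arg(type)
  sm <- solve_mme(ds, vc)
  .loglik_from_solution(ds, vc, sm, type)
}

#' EM-REML estimation of variance components
#'
#' Iterates the standard expectation-maximization REML updates
#' `s2_k <- (u_k' K_k^-1 u_k + s2_e tr(K_k^-1 C^kk)) / q_k` and
#' `s2_e <- (y'y - b' X'y - sum_k u_k' Z_k'y) / (N - rank X)`,
#' where `C^kk` is the k-th diagonal block of the inverse MME coefficient
#' matrix. The REML log-likelihood is non-decreasing along the iterations;
#' a numerical decrease beyond `1e-8` (relative) raises a warning.
#'
#' @param ds a `design_system`.
#' @param start optional starting values (list `residual`, `components`);
#'   default splits the phenotypic variance equally.
#' @param tol convergence tolerance on the relative change of the REML
#'   log-likelihood (default `1e-8`).
#' @param max_iter maximum EM iterations (default 1000).
#' @param floor variance floor as a fraction of the phenotypic variance
#'   (default `1e-10`); a component at the floor is reported as 0 in
#'   summaries but kept at the floor internally.
#' @return List: `vc` (with `residual`, `components`), `loglik` (REML at the
#'   estimate), `trace` (per-iteration log-likelihood), `n_iterations`,
#'   `converged`.
#' @export
reml_em <- function(ds, start = NULL, tol = 1e-8, max_iter = 1000,
                    floor = 1e-10) {
  N <- length(ds$y)
  p <- ds$rank
  nk <- length(ds$random)
  vary <- stats::var(ds$y)
  if (vary <= 0) vary <- 1
  if (nk == 0L) {
    sm0 <- solve_mme(ds, list(residual = 1, components = numeric(0)))
    rss <- sm0$yPy * 1
    vc <- list(residual = rss / (N - p), components = numeric(0))
    sm <- solve_mme(ds, vc)
    ll <- .loglik_from_solution(ds, vc, sm, "REML")
    return(list(vc = vc, loglik = ll, trace = ll, n_iterations = 0L,
                converged = TRUE))
  }
  if (is.null(start))
    start <- list(residual = vary / 2,
                  components = rep(vary / (2 * nk), nk))
  stopifnot(start$residual > 0, all(start$components > 0))
  vc <- start
  vfloor <- floor * vary
  blocks <- .mme_blocks(ds)
  qs <- blocks$q

  ## one EM sweep: the REML log-likelihood at `vc` and the updated vc
  em_once <- function(vc) {
    M <- .assemble_M(blocks, ds, vc)
    R <- chol(as.matrix(M))
    Cinv <- chol2inv(R)
    sol <- drop(Cinv %*% blocks$Wty)
    sm <- list(logdetM = 2 * sum(log(diag(R))),
               yPy = (blocks$yty - sum(sol * blocks$Wty)) / vc$residual)
    ll <- .loglik_from_solution(ds, vc, sm, "REML")
    off <- blocks$p
    newc <- vc$components
    ubits <- 0
    for (k in seq_len(nk)) {
      idx <- off + seq_len(qs[k])
      uk <- sol[idx]
      Kinv <- ds$random[[k]]$Kinv
      tr_k <- sum(Kinv * Cinv[idx, idx])
      newc[k] <- (drop(crossprod(uk, Kinv %*% uk)) + vc$residual * tr_k) /
        qs[k]
      ubits <- ubits + sum(uk * blocks$Wty[idx])
      off <- off + qs[k]
    }
    b <- sol[seq_len(blocks$p)]
    rss <- blocks$yty - sum(b * blocks$Wty[seq_len(blocks$p)]) - ubits
    list(ll = ll,
         vc_new = list(residual = max(rss / (N - p), vfloor),
                       components = pmax(newc, vfloor)))
  }

  trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  ## history of log variance components for Aitken extrapolation
  th_hist <- NULL
  th_of <- function(v) log(c(v$components, v$residual))
  vc_of <- function(th) {
    v <- pmax(exp(th), vfloor)
    list(residual = v[nk + 1L], components = v[seq_len(nk)])
  }
  it <- 0L
  prev_vc <- NULL
  n_damp <- 0L
  while (it < max_iter) {
    it <- it + 1L
    st <- em_once(vc)
    if (length(trace) && st$ll < ll_old - 1e-10 * (1 + abs(ll_old)) &&
        !is.null(prev_vc) && n_damp < 10L) {
      ## the previous step overshot (possible off the EM path, e.g. right
      ## after an accelerated jump): halve it in log space and retry
      vc <- vc_of((th_of(prev_vc) + th_of(vc)) / 2)
      n_damp <- n_damp + 1L
      next
    }
    n_damp <- 0L
    if (length(trace) && st$ll < ll_old - 1e-8 * (1 + abs(ll_old)))
      warning("REML log-likelihood decreased at iteration ", it,
              " (", format(ll_old), " -> ", format(st$ll), ")")
    trace <- c(trace, st$ll)
    if (is.finite(ll_old) &&
        abs(st$ll - ll_old) < tol * (1 + abs(ll_old))) {
      converged <- TRUE
      break
    }
    ll_old <- st$ll
    prev_vc <- vc
    vc <- st$vc_new
    th <- th_of(vc)
    th_hist <- rbind(th_hist, th)
    if (nrow(th_hist) > 3L) th_hist <- th_hist[-1L, , drop = FALSE]
    if (nrow(th_hist) == 3L && it < max_iter) {
      ## EM converges linearly; extrapolate each log-component along its
      ## estimated geometric path (Aitken), accepting the jump only if it
      ## does not decrease the likelihood (monotonicity safeguard)
      d1 <- th_hist[2L, ] - th_hist[1L, ]
      d2 <- th_hist[3L, ] - th_hist[2L, ]
      rr <- ifelse(abs(d1) > 1e-14, d2 / d1, 0)
      gain <- ifelse(rr > 0 & rr < 0.9999, d2 * rr / (1 - rr), 0)
      ## cap the jump: extreme variance ratios make the MME ill-conditioned
      gain <- pmin(pmax(gain, -log(1e4)), log(1e4))
      th_cand <- pmax(th + gain, log(1e-8 * vary))
      gain <- th_cand - th
      if (any(gain != 0)) {
        ## try the full extrapolation, then halved gains if it overshoots
        for (half in 0:2) {
          cand <- vc_of(th + gain / 2^half)
          st2 <- em_once(cand)
          if (st2$ll >= ll_old) break
          st2 <- NULL
        }
        if (!is.null(st2)) {
          it <- it + 1L
          trace <- c(trace, st2$ll)
          if (abs(st2$ll - ll_old) < tol * (1 + abs(ll_old))) {
            vc <- cand
            converged <- TRUE
            break
          }
          ll_old <- st2$ll
          prev_vc <- cand
          vc <- st2$vc_new
          th_hist <- NULL
        }
      }
    }
  }
  list(vc = vc, loglik = trace[length(trace)], trace = trace,
       n_iterations = length(trace), converged = converged)
}
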