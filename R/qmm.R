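## Front-end model fitting function and S3 methods.

#' Fit a linear mixed model with optional QTL terms
#'
#' Fits `y = X b + sum_k Z_k u_k + e` where the fixed part is given by a
#' formula (plus optional QTL coefficient columns) and each random term
#' carries a covariance structure: the pedigree numerator relationship
#' matrix, a marker-based genomic relationship matrix, a user-supplied
#' matrix or the identity. Variance components are estimated by EM-REML
#' through Henderson's mixed-model equations; solutions and standard errors
#' come from the inverse coefficient matrix.
#'
#' @param fixed two-sided formula, e.g. `length ~ sex + hamwt`.
#' @param data `data.frame` with the response, effect columns and an id
#'   column.
#' @param random named list of random terms (see [build_design()]).
#' @param qtl_columns optional matrix of fixed QTL coefficient columns
#'   (from [qtl_coefficients()], [snp_lambda()], [epistasis_columns()], ...)
#'   with rownames the individual ids.
#' @param vc optional variance components (list `residual`, `components`);
#'   when supplied with `fix_vc = TRUE` no EM iteration is run.
#' @param fix_vc keep `vc` fixed instead of estimating (default `TRUE` when
#'   `vc` is given).
#' @param id id column name (default `"id"`).
#' @param tol,max_iter EM-REML convergence controls (see [reml_em()]).
#' @param start optional EM starting values.
#' @return An object of class `qmm` with `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `fitted`, `residuals`, `predict` and `simulate`
#'   methods. Components include `coefficients`, `se`, `u` (BLUPs), `vc`
#'   (named variance components incl. `residual`), `loglik_reml`,
#'   `loglik_ml`, `n_iterations`, `converged`.
#' @examples
#' d <- data.frame(id = as.character(1:40), y = rnorm(40),
#'                 g = gl(2, 20, labels = c("f", "m")))
#' fit <- qmm(y ~ g, d)
#' coef(fit)
#' @export
qmm <- function(fixed, data, random = NULL, qtl_columns = NULL, vc = NULL,
                fix_vc = !is.null(vc), id = "id", tol = 1e-8,
                max_iter = 1000, start = NULL) {
  cl <- match.call()
  ds <- build_design(fixed, data, random = random, qtl_columns = qtl_columns,
                     id = id)
  nk <- length(ds$random)
  if (fix_vc) {
    if (is.null(vc)) stop("fix_vc = TRUE requires 'vc'")
    if (length(vc$components) != nk)
      stop("vc has ", length(vc$components), " components but the model has ",
           nk, " random terms")
    est <- list(vc = vc, trace = numeric(0),
                n_iterations = 0L, converged = TRUE)
  } else {
    est <- reml_em(ds, start = start, tol = tol, max_iter = max_iter)
  }
  sm <- solve_mme(ds, est$vc)
  ll_reml <- .loglik_from_solution(ds, est$vc, sm, "REML")
  ll_ml <- .loglik_from_solution(ds, est$vc, sm, "ML")
  fitted <- drop(ds$X %*% sm$b)
  for (k in seq_len(nk))
    fitted <- fitted + drop(as.matrix(ds$random[[k]]$Z %*% sm$u[[k]]))
  vcnames <- c(names(ds$random), "residual")
  structure(list(
    call = cl, formula = fixed, design = ds,
    coefficients = sm$b, se = stats::setNames(sm$se_b, names(sm$b)),
    u = sm$u,
    vc = stats::setNames(c(est$vc$components, est$vc$residual), vcnames),
    vc_list = est$vc,
    loglik_reml = ll_reml, loglik_ml = ll_ml,
    trace = est$trace, n_iterations = est$n_iterations,
    converged = est$converged, fix_vc = fix_vc,
    fitted.values = fitted, residuals = ds$y - fitted,
    solution = sm, n = length(ds$y)),
    class = "qmm")
}

#' @export
print.qmm <- function(x, digits = 4, ...) {
  cat("Linear mixed model fit by EM-REML (qmm)\n")
  cat("  n =", x$n, " fixed effects:", length(x$coefficients),
      " random terms:", length(x$u), "\n")
  cat("  REML log-likelihood:", format(x$loglik_reml, digits = 8), "\n")
  if (!x$converged) cat("  WARNING: EM-REML did not converge\n")
  cat("Variance components:\n")
  print(signif(x$vc, digits))
  cat("Fixed effects:\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.qmm <- function(object, ...) object$coefficients

#' @export
fitted.qmm <- function(object, ...) object$fitted.values

#' @export
residuals.qmm <- function(object, ...) object$residuals

#' @export
logLik.qmm <- function(object, REML = TRUE, ...) {
  ll <- if (REML) object$loglik_reml else object$loglik_ml
  attr(ll, "df") <- length(object$coefficients) + length(object$vc)
  attr(ll, "nobs") <- object$n
  class(ll) <- "logLik"
  ll
}

#' @export
vcov.qmm <- function(object, ...) {
  p <- length(object$coefficients)
  V <- object$solution$Cinv[seq_len(p), seq_len(p), drop = FALSE] *
    object$vc[["residual"]]
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' @export
predict.qmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(stats::terms(object$formula))
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
  X <- stats::model.matrix(tt, mf)
  fixed_cols <- intersect(colnames(X), names(object$coefficients))
  drop(X[, fixed_cols, drop = FALSE] %*%
         object$coefficients[fixed_cols])
}

#' @export
simulate.qmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ds <- object$design
  n <- object$n
  mu <- drop(ds$X %*% object$coefficients)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    y <- mu + stats::rnorm(n, 0, sqrt(object$vc[["residual"]]))
    for (k in seq_along(ds$random)) {
      Kinv <- ds$random[[k]]$Kinv
      ## draw u ~ N(0, K s2_k) using the inverse Cholesky
      R <- chol(Kinv)
      z <- stats::rnorm(ds$random[[k]]$q)
      u <- backsolve(R, z) * sqrt(object$vc[[k]])
      y <- y + drop(as.matrix(ds$random[[k]]$Z %*% u))
    }
    out[, s] <- y
  }
  as.data.frame(out)
}

#' @export
summary.qmm <- function(object, ...) {
  z <- object$coefficients / object$se
  coefs <- data.frame(Estimate = object$coefficients, SE = object$se,
                      z = z, p = 2 * stats::pnorm(-abs(z)))
  out <- list(call = object$call, coefficients = coefs, vc = object$vc,
              loglik_reml = object$loglik_reml, loglik_ml = object$loglik_ml,
              n = object$n, n_iterations = object$n_iterations,
              converged = object$converged)
  class(out) <- "summary.qmm"
  out
}

#' @export
print.summary.qmm <- function(x, digits = 4, ...) {
  cat("Call: "); print(x$call)
  cat("n =", x$n, "; EM-REML iterations:", x$n_iterations,
      if (!x$converged) "(not converged)" else "", "\n")
  cat("\nVariance components:\n")
  print(signif(x$vc, digits))
  cat("\nFixed effects:\n")
  stats::printCoefmat(as.matrix(x$coefficients), digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nREML log-likelihood:", format(x$loglik_reml, digits = 8), "\n")
  invisible(x)
}

#' Solutions table of a fitted model
#'
#' Flat table of fixed-effect estimates (with standard errors) and random
#' BLUPs, as written by [write_solutions()].
#'
#' @param fit a `qmm` object.
#' @return `data.frame` with columns `term`, `level`, `estimate`, `SE`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "qmm"))
  out <- data.frame(term = "fixed", level = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    SE = unname(fit$se), stringsAsFactors = FALSE)
  for (nm in names(fit$u))
    out <- rbind(out, data.frame(term = nm, level = names(fit$u[[nm]]),
                                 estimate = unname(fit$u[[nm]]), SE = NA_real_,
                                 stringsAsFactors = FALSE))
  out
}
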