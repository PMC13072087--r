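#' Generalized least squares with a fixed phylogenetic covariance
#'
#' Profile GLS estimates for a linear model whose errors have covariance
#' proportional to a known matrix V:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, the ML variance scale
#' `sigma2 = r' V^-1 r / n` (r the GLS residuals), and the Gaussian
#' log-likelihood `-n/2 log(2 pi sigma2) - log|V|/2 - n/2`. Everything
#' is computed through the Cholesky factor of V (whitening); V is never
#' inverted explicitly.
#'
#' @param y Numeric response vector.
#' @param X Design matrix with an intercept column; rows ordered to
#'   match V's taxa.
#' @param V Covariance matrix (positive definite), e.g. from
#'   [phylo_vcv()] after [lambda_transform()].
#' @return List with `beta`, `sigma2` (ML, floored at 1e-12 on perfect
#'   fits with `degenerate = TRUE`), `loglik`, `rss_whitened`, `r2`
#'   (whitened-space coefficient of determination against the GLS
#'   intercept-only model under the same V), `se_beta`, `n`, and
#'   `degenerate`.
#' @export
gls_profile <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  U <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is singular or not positive definite ",
         "(reciprocal condition number ", format(rcond(V), digits = 3), ")"))
  .gls_core(y, X, U, compute_extras = TRUE)
}

# whitened-space GLS given the upper Cholesky factor U of V.
# compute_extras adds r2, standard errors and the degenerate flag;
# the lambda profile loop only needs beta/sigma2/loglik.
.gls_core <- function(y, X, U, compute_extras = FALSE) {
  n <- length(y)
  Wy <- backsolve(U, y, transpose = TRUE)
  WX <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(WX)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is collinear after whitening ",
         "(condition number ", format(kappa(WX), digits = 3), ")")
  }
  beta <- qr.coef(qrX, Wy)
  names(beta) <- colnames(X)
  res <- Wy - WX %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  degenerate <- FALSE
  if (sigma2 < 1e-12) {
    sigma2 <- 1e-12
    degenerate <- TRUE
  }
  logdet <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  out <- list(beta = beta, sigma2 = sigma2, loglik = loglik,
              rss_whitened = rss, n = n, degenerate = degenerate)
  if (compute_extras) {
    W1 <- backsolve(U, rep(1, n), transpose = TRUE)
    mu <- sum(W1 * Wy) / sum(W1 * W1)
    tss <- sum((Wy - W1 * mu)^2)
    if (tss <= 0) {
      warning("response is constant after whitening; r2 defined as 0")
      out$r2 <- 0
    } else {
      out$r2 <- 1 - rss / tss
    }
    xtxi <- solve(crossprod(WX))
    s2u <- if (n > ncol(X)) rss / (n - ncol(X)) else NA_real_
    out$se_beta <- sqrt(pmax(s2u * diag(xtxi), 0))
    names(out$se_beta) <- colnames(X)
  }
  out
}

#' Fit a phylogenetic regression under Pagel's lambda model
#'
#' Single-predictor PGLS: the error covariance is
#' `sigma2 * lambda_transform(phylo_vcv(tree), lambda)`, with lambda
#' estimated by maximum likelihood over \[0, 1\] (bounded scalar search,
#' tolerance 1e-6, restarted on the sub-intervals \[0, 0.5\],
#' \[0.25, 0.75\] and \[0.5, 1\] and checked against both endpoints, so a
#' flat or bimodal profile cannot trap the optimizer). Branch-length
#' power transforms (kappa, delta) are left at 1. Species present in the
#' tree but missing from the data (or vice versa in the data) are
#' dropped pairwise and the tree is re-pruned for each fit.
#'
#' @param y,x Named numeric vectors (names are species labels matching
#'   the tree's tip labels after [normalize_species_labels()]).
#' @param tree A `phylo` object whose tips cover the data species.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @return Object of class `pgls_fit`: a list with `lambda` (the
#'   estimate), `beta` (intercept and slope), `sigma2` (ML), `loglik`,
#'   `r2`, `p_slope` (two-sided t test on the slope, n - 2 df),
#'   `t_slope`, `se_slope`, `n`, `converged`, `degenerate`, and the
#'   profile log-likelihoods at the endpoints (`loglik_lambda0`,
#'   `loglik_lambda1`).
#' @examples
#' tree <- simulate_yule_tree(50, seed = 7)
#' sim <- simulate_regression_dataset(tree, slope = -0.6, lam = 0.8,
#'                                    sigma2 = 0.5, seed = 7)
#' fit <- fit_pgls_lambda(sim$y, sim$x, tree)
#' fit$lambda; fit$beta
#' @export
fit_pgls_lambda <- function(y, x, tree, lambda = "ML") {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(y)) || is.null(names(x))) {
    stop("y and x must be named by species")
  }
  names(y) <- normalize_species_labels(names(y))
  names(x) <- normalize_species_labels(names(x))
  y <- y[!is.na(y)]
  x <- x[!is.na(x)]
  common <- intersect(intersect(names(y), names(x)), tree$tip.label)
  orphan <- setdiff(union(names(y), names(x)), tree$tip.label)
  if (length(common) == 0L) {
    stop("no overlap between data species and tree tips; data species ",
         "missing from tree: ", paste(utils::head(orphan, 10), collapse = ", "))
  }
  if (length(common) < 4L) {
    stop("need at least 4 species with complete data and a tip, got ",
         length(common))
  }
  tr <- prune_tree(tree, common)
  ord <- tr$tip.label
  yv <- as.numeric(y[ord])
  xv <- as.numeric(x[ord])
  X <- cbind(intercept = 1, slope = xv)
  V <- phylo_vcv(tr)
  d <- diag(V)
  n <- length(yv)

  loglik_at <- function(lam) {
    Vl <- lam * V
    diag(Vl) <- d
    U <- tryCatch(chol(Vl), error = function(e) NULL)
    if (is.null(U)) return(-Inf)
    .gls_core(yv, X, U)$loglik
  }

  converged <- TRUE
  if (identical(lambda, "ML")) {
    cand_l <- c(0, 1)
    cand_f <- c(loglik_at(0), loglik_at(1))
    for (iv in list(c(0, 0.5), c(0.25, 0.75), c(0.5, 1))) {
      op <- stats::optimize(loglik_at, interval = iv, maximum = TRUE,
                            tol = 1e-6)
      cand_l <- c(cand_l, op$maximum)
      cand_f <- c(cand_f, op$objective)
    }
    if (all(!is.finite(cand_f))) {
      stop("likelihood not computable for any lambda; ",
           "covariance matrix singular (duplicate tip rows?)")
    }
    best <- which.max(cand_f)
    lam_hat <- cand_l[best]
    if (!is.finite(cand_f[best])) converged <- FALSE
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L ||
        lambda < 0 || lambda > 1) {
      stop("lambda must be \"ML\" or a single value in [0, 1]")
    }
    lam_hat <- as.numeric(lambda)
  }

  Vl <- lambda_transform(V, lam_hat)
  fit <- gls_profile(yv, X, Vl)
  se <- unname(fit$se_beta["slope"])
  degenerate_test <- FALSE
  if (!is.finite(se) || se == 0) {
    p <- 0
    tval <- Inf * sign(unname(fit$beta["slope"]))
    degenerate_test <- TRUE
  } else {
    tval <- unname(fit$beta["slope"]) / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }

  structure(list(lambda = lam_hat,
                 beta = c(intercept = unname(fit$beta["intercept"]),
                          slope = unname(fit$beta["slope"])),
                 sigma2 = fit$sigma2,
                 loglik = fit$loglik,
                 r2 = fit$r2,
                 p_slope = p,
                 t_slope = tval,
                 se_slope = se,
                 n = n,
                 converged = converged,
                 degenerate = fit$degenerate || degenerate_test,
                 loglik_lambda0 = loglik_at(0),
                 loglik_lambda1 = loglik_at(1),
                 species = ord),
            class = "pgls_fit")
}

#' Two-sided t test on the PGLS slope
#'
#' The slope's standard error uses the unbiased whitened residual
#' variance (RSS / (n - 2)) and `(X' V^-1 X)^-1` under the fitted
#' lambda; the reference distribution is t with n - 2 df.
#'
#' @param fit A `pgls_fit` object.
#' @return The two-sided p-value (0 flags a degenerate zero-SE fit).
#' @export
slope_test <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$p_slope
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Pagel lambda model, ML)\n")
  cat(sprintf("  n = %d species\n", x$n))
  cat(sprintf("  lambda = %.4f   sigma2 = %.6g   logLik = %.4f\n",
              x$lambda, x$sigma2, x$loglik))
  cat(sprintf("  intercept = %.6g   slope = %.6g (SE %.3g)\n",
              x$beta["intercept"], x$beta["slope"], x$se_slope))
  cat(sprintf("  r2 = %.4f   p(slope) = %.4g%s\n", x$r2, x$p_slope,
              if (x$degenerate) "   [degenerate]" else ""))
  invisible(x)
}
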