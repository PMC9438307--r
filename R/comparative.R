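# Phylogenetic comparative statistics: PGLS with maximum-likelihood Pagel's
# lambda, phylogenetic-signal likelihood-ratio tests, and per-branch event
# correlations.
#
# The residual covariance is C(lambda): the Brownian-motion covariance of the
# tree with off-diagonal entries (shared path lengths) multiplied by lambda,
# diagonal untouched. lambda is estimated by golden-section search of the
# profile log-likelihood on [0, 1] (tolerance 1e-6) with explicit endpoint
# checks.

golden_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(maximum = x, objective = f(x))
}

lambda_cov <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# GLS fit of y ~ X under covariance V (ML sigma^2 profiled out)
gls_profile <- function(X, y, V) {
  n <- length(y)
  L <- chol(V)                       # V = t(L) %*% L with L upper-triangular
  Xt <- backsolve(L, X, transpose = TRUE)
  yt <- backsolve(L, y, transpose = TRUE)
  qr_ <- qr(Xt)
  if (qr_$rank < ncol(X)) stop("singular design (constant predictor?)")
  beta <- qr.coef(qr_, yt)
  resid <- yt - Xt %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / n
  ll <- -n / 2 * log(2 * pi * sigma2) - sum(log(diag(L))) - n / 2
  list(beta = beta, rss = rss, sigma2 = sigma2, logLik = ll,
       Xt = Xt, yt = yt, L = L)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y ~ x` by GLS under the lambda-scaled Brownian covariance of the
#' tree. `lambda_mode = "ML"` maximises the profile likelihood on \[0, 1\];
#' a numeric value fixes lambda. The slope p-value uses a t statistic with
#' n - 2 df; R-squared is computed in the lambda-whitened space.
#'
#' @param x,y named numeric vectors (names = species).
#' @param tree rooted `phylo` with branch lengths.
#' @param lambda_mode `"ML"` or a fixed numeric lambda in \[0, 1\].
#' @return object of class `pgls_result`: `intercept`, `slope`, `lambda`,
#'   `r_squared`, `p_value`, `n`, `logLik`, `se_slope`, `t_slope`.
#' @export
pgls_fit <- function(x, y, tree, lambda_mode = "ML") {
  if (is.null(names(x)) || is.null(names(y))) stop("x and y must be named by species")
  common <- intersect(intersect(names(x), names(y)), tree$tip.label)
  if (length(common) < 4) stop("need >= 4 species shared by traits and tree")
  tr <- ape::keep.tip(tree, common)
  ord <- tr$tip.label
  xv <- as.numeric(x[ord]); yv <- as.numeric(y[ord])
  if (anyNA(xv) || anyNA(yv)) stop("missing trait values")
  if (var(xv) == 0) stop("constant predictor")
  n <- length(ord)
  C <- ape::vcv(tr)
  X <- cbind(`(Intercept)` = 1, x = xv)
  ll_of <- function(lam) gls_profile(X, yv, lambda_cov(C, lam))$logLik
  if (identical(lambda_mode, "ML")) {
    opt <- golden_max(ll_of, 0, 1)
    cands <- c(0, opt$maximum, 1)
    lls <- vapply(cands, ll_of, 0)
    lambda <- cands[which.max(lls)]
  } else {
    lambda <- as.numeric(lambda_mode)
    if (is.na(lambda) || lambda < 0 || lambda > 1) stop("lambda must be in [0,1]")
  }
  fit <- gls_profile(X, yv, lambda_cov(C, lambda))
  # slope inference (unbiased sigma^2, n - 2 df)
  XtX_inv <- chol2inv(qr.R(qr(fit$Xt)))
  s2 <- fit$rss / (n - 2)
  se <- sqrt(s2 * diag(XtX_inv))
  tstat <- fit$beta[2] / se[2]
  p <- 2 * pt(-abs(tstat), df = n - 2)
  # R^2 in whitened space against the GLS intercept-only model
  fit0 <- gls_profile(X[, 1, drop = FALSE], yv, lambda_cov(C, lambda))
  r2 <- 1 - fit$rss / fit0$rss
  structure(list(intercept = unname(fit$beta[1]), slope = unname(fit$beta[2]),
                 lambda = lambda, r_squared = r2, p_value = p, n = n,
                 logLik = fit$logLik, se_slope = unname(se[2]),
                 t_slope = unname(tstat)), class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("PGLS (n = %d): y = %.4g + %.4g x | lambda = %.3f, R2 = %.3f, p = %.3g\n",
              x$n, x$intercept, x$slope, x$lambda, x$r_squared, x$p_value))
  invisible(x)
}

#' Phylogenetic signal of a trait (Pagel's lambda)
#'
#' Maximum-likelihood lambda for an intercept-only model, with a
#' likelihood-ratio test against lambda = 0 (chi-squared, 1 df).
#'
#' @param trait named numeric vector (names = species).
#' @param tree rooted `phylo`.
#' @return object of class `signal_result`: `lambda`, `logLik`, `logLik0`,
#'   `p_value`, `n`.
#' @export
pagel_lambda_signal <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait must be named by species")
  common <- intersect(names(trait), tree$tip.label)
  if (length(common) < 3) stop("need >= 3 species")
  tr <- ape::keep.tip(tree, common)
  yv <- as.numeric(trait[tr$tip.label])
  if (var(yv) == 0) stop("zero-variance trait")
  C <- ape::vcv(tr)
  X <- matrix(1, length(yv), 1)
  ll_of <- function(lam) gls_profile(X, yv, lambda_cov(C, lam))$logLik
  opt <- golden_max(ll_of, 0, 1)
  cands <- c(0, opt$maximum, 1)
  lls <- vapply(cands, ll_of, 0)
  lambda <- cands[which.max(lls)]
  ll1 <- max(lls); ll0 <- lls[1]
  p <- pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
  structure(list(lambda = lambda, logLik = ll1, logLik0 = ll0,
                 p_value = p, n = length(yv)), class = "signal_result")
}

#' Pearson correlation of per-branch event counts
#'
#' Product-moment correlation with a two-sided t-test.
#'
#' @param events_a,events_b paired numeric vectors (e.g. per-branch losses of
#'   two families over the same retained branches).
#' @return list: `r`, `p_value`, `n`.
#' @export
branch_correlation <- function(events_a, events_b) {
  if (length(events_a) != length(events_b)) stop("unequal vector lengths")
  keep <- !is.na(events_a) & !is.na(events_b)
  a <- events_a[keep]; b <- events_b[keep]
  n <- length(a)
  if (n < 3) stop("need >= 3 paired observations")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in event vector")
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = p, n = n)
}

#' PGLS report over standard trait pairs
#'
#' One PGLS fit per requested (predictor, response) pair; species missing
#' either trait are dropped pairwise (count reported). Pairs with fewer than
#' 4 usable species are skipped with a warning.
#'
#' @param traits data.frame with a `species` column and numeric trait
#'   columns.
#' @param tree rooted `phylo`.
#' @param pairs list of `c(x, y)` trait-name pairs; default: the three
#'   family-size pairs and lamellae against each family and the total.
#' @return data.frame: `x`, `y`, `n`, `dropped`, `lambda`, `slope`,
#'   `intercept`, `r_squared`, `p_value`.
#' @export
repertoire_report <- function(traits, tree, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- list(c("OR", "TAAR"), c("OR", "OlfC"), c("TAAR", "OlfC"),
                  c("OR", "lamellae"), c("TAAR", "lamellae"),
                  c("OlfC", "lamellae"), c("total", "lamellae"))
    pairs <- Filter(function(p) all(p %in% names(traits)), pairs)
  }
  rows <- list()
  for (p in pairs) {
    xn <- p[1]; yn <- p[2]
    ok <- !is.na(traits[[xn]]) & !is.na(traits[[yn]]) &
      traits$species %in% tree$tip.label
    dropped <- sum(!ok)
    if (sum(ok) < 4) {
      warning("pair ", xn, " ~ ", yn, " skipped: fewer than 4 usable species")
      next
    }
    x <- setNames(traits[[xn]][ok], traits$species[ok])
    y <- setNames(traits[[yn]][ok], traits$species[ok])
    fit <- tryCatch(pgls_fit(x, y, tree), error = function(e) {
      warning("pair ", xn, " ~ ", yn, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      x = xn, y = yn, n = fit$n, dropped = dropped, lambda = fit$lambda,
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared, p_value = fit$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
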