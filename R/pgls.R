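#' Phylogenetic generalized least squares regression
#'
#' Fits a linear regression across species whose residual covariance reflects
#' shared evolutionary history: under a Brownian-motion model, residuals of
#' two species covary in proportion to the branch length they share from the
#' root. The strength of that phylogenetic signal is governed by Pagel's
#' \eqn{\lambda}, a multiplier on the off-diagonal covariance entries,
#' estimated by profile maximum likelihood on \eqn{[0, 1]} (or held fixed).
#' With \eqn{\lambda = 0} the fit reduces exactly to ordinary least squares.
#'
#' For allometric scaling analyses both variables are log10-transformed
#' before fitting, so the slope \eqn{b} in
#' \eqn{\log y = b \log x + \mathrm{intercept}} is the scaling exponent
#' (isometry: 2/3 for an area on a volume, 1 for a volume on a volume).
#' For network-metric analyses both sides are z-scored across species so the
#' slope is a standardized coefficient \eqn{\beta}; see \code{\link{ztrans}}.
#'
#' @param formula model formula, e.g. \code{log10(surface_area) ~ log10(cerebral_volume)}.
#' @param data data.frame with one row per species; row names (or a
#'   \code{species} column) must match the tree's leaf labels.
#' @param tree a \code{"phylo"} tree covering all species in \code{data}.
#' @param lambda \code{"ML"} (profile maximum likelihood over \eqn{[0,1]},
#'   search tolerance \code{1e-6}) or a fixed numeric value in \eqn{[0,1]}.
#' @param level confidence level for slope intervals (default 0.95).
#' @return An object of class \code{"pgls"} with components including
#'   \code{coefficients}, \code{se}, \code{ci} (per-coefficient bounds),
#'   \code{lambda} (estimate), \code{logLik}, \code{r.squared},
#'   \code{adj.r.squared}, \code{p.value} (per coefficient, t-test with
#'   \eqn{n - p} df), \code{residuals} (raw scale), \code{fitted},
#'   \code{degenerate} (TRUE when the residual variance is numerically zero,
#'   in which case SEs are 0 and p-values NA), and bookkeeping fields.
#' @examples
#' tr <- simulate_tree(8, birth_rate = 1, seed = 1)
#' d <- data.frame(x = rnorm(8), row.names = tr$tip.label)
#' d$y <- 0.85 * d$x + rnorm(8, sd = 0.05)
#' fit <- pgls(y ~ x, data = d, tree = tr)
#' coef(fit)
#' @seealso \code{\link{summary.pgls}}, \code{\link{rma_fit}}
#' @export
pgls <- function(formula, data, tree, lambda = "ML", level = 0.95) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  validate_phylo_tree(tree)

  rn <- if (!is.null(data$species)) as.character(data$species) else rownames(data)
  if (is.null(rn) || anyDuplicated(rn)) {
    stop_("data must identify species uniquely via row names or a 'species' column")
  }
  rownames(data) <- rn
  tips <- tree$tip.label
  if (!setequal(rn, tips)) {
    missing_in_data <- setdiff(tips, rn)
    missing_in_tree <- setdiff(rn, tips)
    stop_("species sets do not match: ",
          if (length(missing_in_data)) paste0("absent from data: ", paste(missing_in_data, collapse = ", "), "; ") else "",
          if (length(missing_in_tree)) paste0("absent from tree: ", paste(missing_in_tree, collapse = ", ")) else "")
  }
  data <- data[tips, , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (n < 3L) stop_("PGLS needs at least 3 species")

  C <- brownian_covariance(tree)$C[tips, tips]

  if (identical(lambda, "ML") || identical(lambda, "ml")) {
    opt <- stats::optimize(function(l) .pgls_profile_loglik(l, y, X, C),
                           interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    # the interior optimum can be beaten by an endpoint when the profile is
    # monotone; check both ends explicitly
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective,
            .pgls_profile_loglik(0, y, X, C),
            .pgls_profile_loglik(1, y, X, C))
    lam_hat <- cand[which.max(ll)]
    lambda_mode <- "ML"
  } else {
    stopifnot(is.numeric(lambda), length(lambda) == 1L)
    if (lambda < 0 || lambda > 1) stop_("fixed lambda must lie in [0, 1]")
    lam_hat <- lambda
    lambda_mode <- "fixed"
  }

  fit <- .pgls_gls(y, X, lambda_transform(C, lam_hat)$C)
  df <- n - p
  degenerate <- fit$rss_w <= max(1e-12 * fit$tss_w, 1e-24)

  if (degenerate) {
    se <- rep(0, p)
    tval <- rep(NA_real_, p)
    pval <- rep(NA_real_, p)
    ci <- cbind(lower = fit$beta, upper = fit$beta)
  } else {
    sigma2 <- fit$rss_w / df
    se <- sqrt(diag(fit$XtVinvX_inv) * sigma2)
    tval <- fit$beta / se
    pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    tq <- stats::qt(1 - (1 - level) / 2, df = df)
    ci <- cbind(lower = fit$beta - tq * se, upper = fit$beta + tq * se)
  }
  rownames(ci) <- names(fit$beta) <- colnames(X)
  names(se) <- names(tval) <- names(pval) <- colnames(X)

  r2 <- if (fit$tss_w > 0) 1 - fit$rss_w / fit$tss_w else NA_real_
  adj_r2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_

  structure(list(
    coefficients = fit$beta,
    se = se,
    t.value = tval,
    p.value = pval,
    ci = ci,
    level = level,
    lambda = lam_hat,
    lambda_mode = lambda_mode,
    logLik = .pgls_profile_loglik(lam_hat, y, X, C),
    r.squared = r2,
    adj.r.squared = adj_r2,
    residuals = fit$resid_raw,
    fitted.values = fit$fitted,
    sigma2 = if (degenerate) 0 else fit$rss_w / df,
    degenerate = degenerate,
    n = n,
    df.residual = df,
    C = C,
    y = y,
    X = X,
    call = match.call(),
    formula = formula,
    species = tips
  ), class = "pgls")
}

#' Fit a PGLS scaling regression from trait vectors
#'
#' Vector interface to \code{\link{pgls}} for callers that hold aligned trait
#' vectors rather than a data.frame. Transforms (log10 for scaling exponents,
#' z-scores for standardized coefficients) are the caller's responsibility.
#'
#' @param y,x numeric vectors named by species (or in tree leaf order).
#' @param tree a \code{"phylo"} tree.
#' @param lambda \code{"ML"} or a fixed value in \eqn{[0,1]}.
#' @return A \code{"pgls"} fit; the slope is \code{coef(fit)["x"]}.
#' @export
fit_pgls <- function(y, x, tree, lambda = "ML") {
  stopifnot(is.numeric(y), is.numeric(x), length(y) == length(x))
  nms <- names(y) %||% names(x) %||% tree$tip.label
  if (length(nms) != length(y)) stop_("cannot align traits with tree leaves")
  d <- data.frame(y = as.numeric(y), x = as.numeric(x), row.names = nms)
  pgls(y ~ x, data = d, tree = tree, lambda = lambda)
}

# Profile (over beta, sigma2) ML log-likelihood of lambda.
.pgls_profile_loglik <- function(lambda, y, X, C) {
  V <- lambda_transform(C, lambda)$C
  n <- length(y)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  fit <- .pgls_gls(y, X, V, chol_V = L)
  sigma2_ml <- fit$rss_w / n
  if (sigma2_ml <= 0) sigma2_ml <- .Machine$double.xmin
  logdetV <- 2 * sum(log(diag(L)))
  -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
}

# Core GLS solve via Cholesky whitening. Returns estimates plus the whitened
# residual and total sums of squares used for R^2 and SEs.
.pgls_gls <- function(y, X, V, chol_V = NULL) {
  L <- chol_V %||% chol(V)                     # V = t(L) %*% L, L upper
  # whiten: solve t(L) z = v  => z = backsolve(L, v, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  XtX_inv <- chol2inv(chol(XtX))
  beta <- drop(XtX_inv %*% crossprod(Xw, yw))
  fitted_w <- drop(Xw %*% beta)
  resid_w <- yw - fitted_w
  rss_w <- sum(resid_w^2)
  # total SS around the GLS (whitened-space) estimate of the mean
  onew <- backsolve(L, rep(1, length(y)), transpose = TRUE)
  mu_gls <- sum(onew * yw) / sum(onew^2)
  tss_w <- sum((yw - mu_gls * onew)^2)
  fitted_raw <- drop(X %*% beta)
  list(beta = beta, XtVinvX_inv = XtX_inv, rss_w = rss_w, tss_w = tss_w,
       fitted = fitted_raw, resid_raw = y - fitted_raw, chol_V = L)
}

#' Reduced major axis regression
#'
#' Symmetric line fit used as a robustness check on scaling exponents:
#' slope \eqn{= \mathrm{sign}(r) \cdot SD(y)/SD(x)}, intercept through the
#' means. Unlike OLS, exchanging x and y inverts the slope.
#'
#' @param y,x numeric vectors, length \eqn{\ge 3}.
#' @return A list with \code{slope} and \code{intercept}.
#' @examples
#' rma_fit(c(1, 3, 5), c(1, 2, 3))  # slope 2, intercept -1
#' @export
rma_fit <- function(y, x) {
  stopifnot(is.numeric(y), is.numeric(x), length(y) == length(x))
  if (length(y) < 3L) stop_("reduced major axis fit needs n >= 3")
  sy <- stats::sd(y); sx <- stats::sd(x)
  if (sx == 0 || sy == 0) stop_("zero variance in x or y")
  r <- stats::cor(x, y)
  if (r == 0) stop_("zero correlation: RMA slope sign undefined")
  slope <- sign(r) * sy / sx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' z-score a vector across species
#'
#' Standardizes to mean 0, SD 1 across species, the transform applied to both
#' sides of network-metric regressions so slopes are standardized
#' coefficients.
#'
#' @param v numeric vector.
#' @return z-scored vector.
#' @export
ztrans <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) stop_("cannot z-transform a constant vector")
  (v - mean(v)) / s
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic generalized least squares fit\n")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat("  n = ", x$n, " species; Pagel's lambda = ",
      format(x$lambda, digits = 4),
      if (x$lambda_mode == "ML") " (ML)" else " (fixed)", "\n", sep = "")
  cat("  coefficients:\n")
  print(x$coefficients)
  if (x$degenerate) cat("  note: residual variance is degenerate (exact fit)\n")
  invisible(x)
}

#' Summarize a PGLS fit
#'
#' @param object a \code{"pgls"} fit.
#' @param ... unused.
#' @return A \code{"summary.pgls"} object with a coefficient table
#'   (estimate, SE, CI bounds, t, p), \eqn{\lambda}, and fit statistics.
#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `CI lower` = object$ci[, "lower"],
               `CI upper` = object$ci[, "upper"],
               `t value` = object$t.value,
               `Pr(>|t|)` = object$p.value)
  structure(list(coefficients = tab, lambda = object$lambda,
                 lambda_mode = object$lambda_mode,
                 r.squared = object$r.squared,
                 adj.r.squared = object$adj.r.squared,
                 logLik = object$logLik, n = object$n,
                 level = object$level,
                 degenerate = object$degenerate,
                 formula = object$formula, call = object$call),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("PGLS regression (Brownian motion, Pagel's lambda ",
      if (x$lambda_mode == "ML") "ML" else "fixed", ")\n", sep = "")
  cat("formula: ", deparse(x$formula), "   n = ", x$n, "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
                      cs.ind = 1:4, tst.ind = 5)
  cat("\nlambda = ", format(x$lambda, digits = 4),
      ";  adj. R^2 = ", format(x$adj.r.squared, digits = 4),
      ";  logLik = ", format(x$logLik, digits = 6), "\n", sep = "")
  if (x$degenerate) cat("note: residual variance degenerate; SEs are 0, p undefined\n")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) {
  V <- object$sigma2 * chol2inv(chol(crossprod(
    backsolve(chol(lambda_transform(object$C, object$lambda)$C),
              object$X, transpose = TRUE))))
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' @export
confint.pgls <- function(object, parm, level = NULL, ...) {
  ci <- object$ci
  if (!is.null(level) && level != object$level) {
    tq <- stats::qt(1 - (1 - level) / 2, df = object$df.residual)
    ci <- cbind(lower = object$coefficients - tq * object$se,
                upper = object$coefficients + tq * object$se)
    rownames(ci) <- names(object$coefficients)
  }
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' Residuals of a PGLS fit
#'
#' @param object a \code{"pgls"} fit.
#' @param type \code{"response"} (raw scale) or \code{"normalized"}
#'   (whitened by the Cholesky factor of the fitted covariance; approximately
#'   i.i.d. under the model).
#' @param ... unused.
#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "response") return(r)
  L <- chol(lambda_transform(object$C, object$lambda)$C)
  drop(backsolve(L, r, transpose = TRUE))
}

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' Predict from a PGLS fit
#'
#' Population-level prediction \eqn{X \beta} for new predictor values (no
#' phylogenetic conditioning on observed residuals).
#'
#' @param object a \code{"pgls"} fit.
#' @param newdata data.frame of predictor values; if missing, fitted values.
#' @param ... unused.
#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  drop(X %*% object$coefficients)
}

#' Simulate responses from a fitted PGLS model
#'
#' Draws new response vectors from \eqn{N(X\hat\beta,\,
#' \hat\sigma^2 V(\hat\lambda))}, the fitted phylogenetic error model.
#'
#' @param object a \code{"pgls"} fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data.frame with \code{nsim} columns, rows named by species.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  V <- lambda_transform(object$C, object$lambda)$C * object$sigma2
  L <- if (object$sigma2 > 0) chol(V) else NULL
  mu <- object$fitted.values
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      if (is.null(L)) mu else mu + drop(t(L) %*% stats::rnorm(object$n))
    }, numeric(object$n))
  })
  out <- as.data.frame(sims, row.names = object$species)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a PGLS scaling fit
#'
#' Scatter of the (transformed) data with the fitted regression line and the
#' confidence band for the mean, in base graphics.
#'
#' @param x a \code{"pgls"} fit with a single predictor.
#' @param ... passed to \code{plot.default}.
#' @export
plot.pgls <- function(x, ...) {
  if (ncol(x$X) != 2L) stop_("plot.pgls supports single-predictor fits")
  xv <- x$X[, 2]
  graphics::plot(xv, x$y, xlab = colnames(x$X)[2], ylab = "response", ...)
  ord <- order(xv)
  graphics::lines(xv[ord], x$fitted.values[ord], lwd = 2)
  if (!x$degenerate) {
    Vb <- vcov(x)
    grid <- seq(min(xv), max(xv), length.out = 50)
    Xg <- cbind(1, grid)
    se_mean <- sqrt(rowSums((Xg %*% Vb) * Xg))
    tq <- stats::qt(1 - (1 - x$level) / 2, df = x$df.residual)
    mu <- drop(Xg %*% x$coefficients)
    graphics::lines(grid, mu + tq * se_mean, lty = 2)
    graphics::lines(grid, mu - tq * se_mean, lty = 2)
  }
  invisible(x)
}
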