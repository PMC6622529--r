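#' Build a design matrix for areal regression
#'
#' Assembles the outcome vector and predictor matrix (with intercept) from
#' a unit-level table.  No missing values are allowed: drop or impute
#' before modelling.
#'
#' @param data data.frame of unit-level variables.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @return A list of class \code{"design_matrix"}: \code{y}, \code{X}
#'   (n x (k+1) with leading intercept column), \code{labels},
#'   \code{standardized}.
#' @export
design_matrix <- function(data, outcome, predictors) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(predictors %in% names(data)))
  y <- as.numeric(data[[outcome]])
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  if (anyNA(y) || anyNA(X)) stop("design matrix contains missing values")
  structure(list(y = y, X = X, labels = colnames(X), outcome = outcome,
                 standardized = FALSE),
            class = "design_matrix")
}

#' Standardize predictors (z-scores)
#'
#' Centers and scales every non-intercept column to mean 0, sd 1; the
#' outcome is untouched.  A consequence used as a sanity check throughout:
#' the OLS intercept on standardized predictors equals mean(y).
#' Idempotent up to floating point.
#'
#' @param d a [design_matrix].
#' @return The standardized [design_matrix].
#' @export
standardize_predictors <- function(d) {
  stopifnot(inherits(d, "design_matrix"))
  X <- d$X
  for (j in seq_len(ncol(X))[-1]) {
    s <- stats::sd(X[, j])
    if (s == 0) stop("constant predictor column: ", colnames(X)[j])
    X[, j] <- (X[, j] - mean(X[, j])) / s
  }
  d$X <- X
  d$standardized <- TRUE
  d
}

#' Ordinary least squares fit
#'
#' Classical OLS with analytic standard errors and the Gaussian
#' log-likelihood (ML variance RSS/n).
#'
#' @param d a [design_matrix].
#' @return A list of class \code{"ols_fit"}: beta, se, residuals, sigma2
#'   (ML), loglik, fitted, df_residual, n, labels.
#' @export
ols_fit <- function(d) {
  stopifnot(inherits(d, "design_matrix"))
  X <- d$X; y <- d$y
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more observations than parameters")
  qr_x <- qr(X)
  if (qr_x$rank < k) stop("rank-deficient design matrix")
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(XtX_inv) * rss / (n - k))
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(beta = stats::setNames(as.numeric(beta), d$labels),
                 se = stats::setNames(se, d$labels),
                 residuals = as.numeric(res), fitted = as.numeric(X %*% beta),
                 sigma2 = sigma2, loglik = loglik,
                 df_residual = n - k, n = n, labels = d$labels),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit>\n")
  print(coef_table(x))
  cat(sprintf("log-likelihood %.3f on %d obs\n", x$loglik, x$n))
  invisible(x)
}

coef_table <- function(fit) {
  z <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), z = unname(z), p = unname(p),
             stars = stars_for(p), stringsAsFactors = FALSE)
}

stars_for <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Lagrange multiplier diagnostics for spatial dependence
#'
#' The standard battery computed from OLS residuals: LM-lag, LM-error, and
#' their robust variants (each robust to local presence of the other form
#' of dependence), all distributed chi-squared(1) under the null of no
#' spatial dependence.  The recommendation applies the usual decision rule
#' to the robust pair at level \code{alpha}: both significant suggests a
#' SARAR specification (lag and error jointly), exactly one suggests that
#' single-process model, neither retains OLS.
#'
#' @param fit an [ols_fit] estimated from \code{d}.
#' @param d the [design_matrix] used for the fit.
#' @param w a row-standardized [weights_matrix].
#' @param alpha level for the recommendation rule (default 0.05).
#' @return A list of class \code{"lm_diagnostics"} with fields lm_lag,
#'   lm_error, robust_lm_lag, robust_lm_error (each statistic + p), and
#'   \code{recommendation} in \{ols, lag, error, sarar\}.
#' @export
lm_diagnostics <- function(fit, d, w, alpha = 0.05) {
  stopifnot(inherits(fit, "ols_fit"), inherits(d, "design_matrix"),
            inherits(w, "weights_matrix"))
  n <- fit$n
  W <- as_spmatrix(w)
  e <- fit$residuals
  y <- d$y; X <- d$X
  s2 <- sum(e^2) / n
  We <- as.numeric(W %*% e)
  Wy <- as.numeric(W %*% y)
  d_err <- sum(e * We) / s2
  d_lag <- sum(e * Wy) / s2
  trT <- sum(W@x^2) + sum(W * Matrix::t(W))
  Wxb <- as.numeric(W %*% fit$fitted)
  qr_x <- qr(X)
  M_Wxb <- Wxb - as.numeric(X %*% qr.coef(qr_x, Wxb))
  G_val <- sum(Wxb * M_Wxb) / s2 + trT
  safe_chi <- function(stat) {
    stat <- max(0, stat)
    list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  lm_lag <- safe_chi(if (G_val > 0) d_lag^2 / G_val else 0)
  lm_error <- safe_chi(if (trT > 0) d_err^2 / trT else 0)
  robust_lm_lag <- safe_chi(if (G_val - trT > 0)
    (d_lag - d_err)^2 / (G_val - trT) else 0)
  robust_lm_error <- safe_chi(if (trT > 0 && G_val > 0 && trT < G_val)
    (d_err - trT / G_val * d_lag)^2 / (trT * (1 - trT / G_val)) else 0)
  sig_lag <- robust_lm_lag$p <= alpha
  sig_err <- robust_lm_error$p <= alpha
  recommendation <- if (sig_lag && sig_err) "sarar"
                    else if (sig_lag) "lag"
                    else if (sig_err) "error"
                    else "ols"
  structure(list(lm_lag = lm_lag, lm_error = lm_error,
                 robust_lm_lag = robust_lm_lag,
                 robust_lm_error = robust_lm_error,
                 alpha = alpha, recommendation = recommendation),
            class = "lm_diagnostics")
}

#' @export
print.lm_diagnostics <- function(x, ...) {
  for (nm in c("lm_lag", "lm_error", "robust_lm_lag", "robust_lm_error"))
    cat(sprintf("%-16s %8.3f  (p = %.4g)\n", nm, x[[nm]]$statistic, x[[nm]]$p))
  cat("recommendation:", x$recommendation, "\n")
  invisible(x)
}

#' Instrumental-variables (2SLS) fit
#'
#' Generic two-stage least squares: regress each column of Z on the
#' instrument set H, then regress y on the fitted Z.  Used as stage one of
#' the GS2SLS estimator; exported because it is independently testable
#' against a brute-force IV oracle.
#'
#' @param y outcome vector.
#' @param Z matrix of (possibly endogenous) regressors.
#' @param H instrument matrix (must include the exogenous columns of Z).
#' @return list with \code{delta} (coefficients), \code{residuals},
#'   \code{vcov} (asymptotic, sigma2 * (Z'P_H Z)^-1), \code{sigma2}.
#' @export
iv_fit <- function(y, Z, H) {
  n <- length(y)
  qh <- qr(H)
  Zhat <- qr.fitted(qh, Z)
  A <- crossprod(Zhat, Z)
  delta <- solve(A, crossprod(Zhat, y))
  res <- as.numeric(y - Z %*% delta)
  sigma2 <- sum(res^2) / n
  ZPZ_inv <- solve(crossprod(Zhat))
  list(delta = as.numeric(delta), residuals = res,
       vcov = sigma2 * ZPZ_inv, sigma2 = sigma2)
}

# Instrument set [X, WX, W^2X, ...]: spatial lags of the exogenous
# regressors up to the given order, constant and collinear columns pruned
# by pivoted QR.
build_instruments <- function(X, W, order = 2) {
  H <- X
  lagged <- X[, -1, drop = FALSE]
  for (k in seq_len(order)) {
    lagged <- as.matrix(W %*% lagged)
    H <- cbind(H, lagged)
  }
  qh <- qr(H)
  H[, qh$pivot[seq_len(qh$rank)], drop = FALSE]
}

# Kelejian-Prucha generalized-moments estimation of the spatial error
# parameter rho from residuals u: minimize the squared norm of the three
# moment conditions in (rho, rho^2, sigma2), profiling sigma2 out
# linearly and line-searching rho.
gm_rho <- function(u, M, interval = c(-0.995, 0.995)) {
  n <- length(u)
  ub <- as.numeric(M %*% u)
  ubb <- as.numeric(M %*% ub)
  trMM <- sum(M@x^2)
  g <- c(sum(u^2), sum(ub^2), sum(u * ub)) / n
  G <- rbind(c(2 * sum(u * ub) / n, -sum(ub^2) / n, 1),
             c(2 * sum(ub * ubb) / n, -sum(ubb^2) / n, trMM / n),
             c((sum(u * ubb) + sum(ub^2)) / n, -sum(ub * ubb) / n, 0))
  obj <- function(rho) {
    a <- G[, 1] * rho + G[, 2] * rho^2 - g
    s2 <- -sum(G[, 3] * a) / sum(G[, 3]^2)
    sum((a + G[, 3] * s2)^2)
  }
  opt <- stats::optimize(obj, interval = interval)
  rho <- opt$minimum
  a <- G[, 1] * rho + G[, 2] * rho^2 - g
  s2 <- -sum(G[, 3] * a) / sum(G[, 3]^2)
  if (!is.finite(opt$objective))
    stop("generalized-moments estimation of rho failed to converge")
  list(rho = rho, sigma2 = s2, objective = opt$objective)
}

#' SARAR estimation by generalized spatial two-stage least squares
#'
#' Fits the spatial-lag + spatial-error model
#' \deqn{y = X\beta + \lambda W y + u, \qquad u = \rho M u + \varepsilon}
#' by the Kelejian-Prucha GS2SLS/GM procedure: (i) 2SLS for
#' \eqn{\delta = (\beta', \lambda)'} on \eqn{Z = [X, Wy]} with instruments
#' \eqn{[X, WX, W^2X]}; (ii) generalized-moments estimation of \eqn{\rho}
#' from the stage-one residuals; (iii) spatial Cochrane-Orcutt filtering
#' \eqn{(I - \hat\rho M)} of y and Z and a final 2SLS on the filtered
#' system.  Standard errors for \eqn{\beta} and \eqn{\lambda} are the
#' asymptotic 2SLS errors from the filtered stage; the GM estimator of
#' \eqn{\rho} does not come with a standard error (reported NA).
#'
#' Degenerate weights (no links at all) reduce the model to OLS with
#' \eqn{\lambda = \rho = 0}.
#'
#' @param d a [design_matrix].
#' @param w spatial weights for the lag term (row-standardized
#'   [weights_matrix]).
#' @param m spatial weights for the error term; defaults to \code{w}.
#' @param instrument_order highest spatial-lag order of X used as
#'   instruments (default 2).
#' @return A list of class \code{"sarar_fit"}: beta, se (for beta),
#'   lambda_lag, lambda_se, rho_err, rho_se (NA), sigma2, loglik
#'   (pseudo, Gaussian on filtered residuals), residuals, n, labels,
#'   boundary (TRUE when |lambda| >= 1).
#' @export
sarar_fit <- function(d, w, m = w, instrument_order = 2) {
  stopifnot(inherits(d, "design_matrix"), inherits(w, "weights_matrix"),
            inherits(m, "weights_matrix"))
  X <- d$X; y <- d$y
  n <- length(y); k <- ncol(X)
  if (n <= k + 2) stop("need n > k + 2 for SARAR estimation")
  W <- as_spmatrix(w); M <- as_spmatrix(m)
  if (length(W@x) == 0 || all(W@x == 0)) {
    ols <- ols_fit(d)
    return(structure(list(beta = ols$beta, se = ols$se,
                          lambda_lag = 0, lambda_se = NA_real_,
                          rho_err = 0, rho_se = NA_real_,
                          sigma2 = ols$sigma2, loglik = ols$loglik,
                          residuals = ols$residuals, n = n,
                          labels = d$labels, boundary = FALSE),
                     class = "sarar_fit"))
  }
  Wy <- as.numeric(W %*% y)
  Z <- cbind(X, spatial_lag_y = Wy)
  H <- build_instruments(X, W, order = instrument_order)
  stage1 <- iv_fit(y, Z, H)
  u <- stage1$residuals
  gm <- if (length(M@x) > 0 && any(M@x != 0)) gm_rho(u, M)
        else list(rho = 0, sigma2 = sum(u^2) / n)
  rho <- gm$rho
  y_f <- y - rho * as.numeric(M %*% y)
  Z_f <- Z - rho * as.matrix(M %*% Z)
  stage2 <- iv_fit(y_f, Z_f, H)
  delta <- stage2$delta
  se <- sqrt(diag(stage2$vcov))
  lambda <- delta[k + 1]
  eps <- stage2$residuals
  sigma2 <- sum(eps^2) / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  boundary <- abs(lambda) >= 1
  if (boundary)
    warning("spatial lag estimate on or outside the unit boundary: lambda = ",
            signif(lambda, 4))
  # residuals on the original scale: y - X beta - lambda W y
  res <- as.numeric(y - Z %*% delta)
  structure(list(beta = stats::setNames(delta[seq_len(k)], d$labels),
                 se = stats::setNames(se[seq_len(k)], d$labels),
                 lambda_lag = lambda, lambda_se = se[k + 1],
                 rho_err = rho, rho_se = NA_real_,
                 sigma2 = sigma2, loglik = loglik, residuals = res,
                 n = n, labels = d$labels, boundary = boundary),
            class = "sarar_fit")
}

#' @export
print.sarar_fit <- function(x, ...) {
  cat("<sarar_fit (GS2SLS)>\n")
  print(coef_table(x))
  cat(sprintf("lambda (spatial lag)  %8.4f (se %.4f)\n",
              x$lambda_lag, x$lambda_se))
  cat(sprintf("rho (spatial error)   %8.4f (se unavailable for GM)\n",
              x$rho_err))
  cat(sprintf("pseudo log-likelihood %.3f on %d obs\n", x$loglik, x$n))
  invisible(x)
}

#' Compare one coefficient across two fitted models
#'
#' The Clogg-Petkova-Haritou test for the change in a coefficient between
#' models: with estimates b_a, b_b and standard errors se_a, se_b,
#' \deqn{z = (b_a - b_b) / \sqrt{se_a^2 + se_b^2}}
#' under the conservative \code{"sum"} rule (always defined), or
#' \deqn{z = (b_a - b_b) / \sqrt{se_a^2 - se_b^2}}
#' under the nested-model \code{"difference"} rule, which requires
#' \code{se_a > se_b}.  Two-sided normal p-value.
#'
#' @param fit_a,fit_b fitted models ([ols_fit] or [sarar_fit]) containing
#'   \code{term}.
#' @param term coefficient name to compare.
#' @param variance_rule \code{"sum"} (default) or \code{"difference"}.
#' @return A list of class \code{"coef_comparison"}: estimate_diff, z, p,
#'   variance_rule.
#' @export
compare_coefficients <- function(fit_a, fit_b, term,
                                 variance_rule = c("sum", "difference")) {
  variance_rule <- match.arg(variance_rule)
  for (f in list(fit_a, fit_b))
    if (!(term %in% names(f$beta))) stop("term not in both fits: ", term)
  b_a <- fit_a$beta[[term]]; b_b <- fit_b$beta[[term]]
  se_a <- fit_a$se[[term]]; se_b <- fit_b$se[[term]]
  denom2 <- if (variance_rule == "sum") se_a^2 + se_b^2 else se_a^2 - se_b^2
  if (denom2 <= 0)
    stop("variance rule 'difference' requires se_a > se_b")
  z <- (b_a - b_b) / sqrt(denom2)
  structure(list(estimate_diff = b_a - b_b, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 variance_rule = variance_rule),
            class = "coef_comparison")
}

#' @export
print.coef_comparison <- function(x, ...) {
  cat(sprintf("<coef_comparison (%s rule): diff = %.4f, z = %.3f, p = %.4g>\n",
              x$variance_rule, x$estimate_diff, x$z, x$p))
  invisible(x)
}
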