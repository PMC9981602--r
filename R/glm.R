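# GLM candidates of the regression suite: efficacy and life-history
# responses on treatment, stage and sex factors, with quasi-likelihood
# dispersion and AIC/qAIC.

ps_family <- function(family) {
  if (inherits(family, "family")) return(family)
  switch(match.arg(family, c("binomial", "quasibinomial", "gaussian",
                             "gamma-inverse", "Gamma")),
         binomial = binomial("logit"),
         quasibinomial = quasibinomial("logit"),
         gaussian = gaussian("identity"),
         `gamma-inverse` = Gamma("inverse"),
         Gamma = Gamma("inverse"))
}

# scale-parameter count entering log-likelihoods reconstructed from
# family$aic (gaussian and Gamma estimate a scale/shape; binomial none)
n_scale_params <- function(fam) {
  if (fam$family %in% c("gaussian", "Gamma", "inverse.gaussian")) 1L else 0L
}

# exact-likelihood twin of a quasi family, for qAIC's loglik
loglik_family <- function(fam) {
  switch(fam$family,
         quasibinomial = binomial(fam$link),
         quasipoisson = stats::poisson(fam$link),
         fam)
}

#' Fit a generalized linear model candidate
#'
#' Thin wrapper around [stats::glm()] (iteratively reweighted least
#' squares) returning the package's model-fit container with the
#' pieces the selection machinery needs: log-likelihood (for quasi
#' families, that of the exact-likelihood twin at the fitted
#' coefficients), Pearson dispersion, and parameter count. Treatment
#' coding with explicitly documented reference levels is used for
#' factors.
#'
#' @param formula Model formula (no smooth terms; see [gam_fit()]).
#' @param family `"binomial"`, `"quasibinomial"`, `"gaussian"`,
#'   `"gamma-inverse"`, or a [stats::family] object.
#' @param data Data frame.
#' @return Object of class `ps_glm`: list with `coefficients`, `vcov`,
#'   `loglik`, `dispersion`, `edf` (number of coefficients), `family`,
#'   `quasi`, `converged`, `n`, `fitted`, `glm` (the underlying fit).
#' @export
glm_fit <- function(formula, family, data) {
  fam <- ps_family(family)
  quasi <- grepl("^quasi", fam$family)
  fit <- glm(formula, family = fam, data = data,
             control = stats::glm.control(epsilon = 1e-10, maxit = 50L))
  if (!fit$converged) warning("IRLS did not converge for ",
                              deparse(formula))
  if (fit$rank < ncol(model.matrix(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("aliased term(s) in design matrix: ",
         paste(bad, collapse = ", "))
  }
  llfam <- loglik_family(fam)
  mu <- fitted(fit)
  y <- fit$y
  wt <- fit$prior.weights
  dev_exact <- sum(llfam$dev.resids(y, mu, wt))
  ll <- -llfam$aic(y, length(y), mu, wt, dev_exact) / 2 +
    n_scale_params(llfam)
  pearson <- sum(residuals(fit, type = "pearson")^2)
  disp <- if (df.residual(fit) > 0) pearson / df.residual(fit) else NA_real_
  structure(list(coefficients = coef(fit), vcov = vcov(fit),
                 loglik = ll, dispersion = disp,
                 pearson = pearson, df_residual = df.residual(fit),
                 edf = fit$rank, family = fam, quasi = quasi,
                 converged = fit$converged, n = length(y),
                 fitted = mu, formula = formula, glm = fit),
            class = "ps_glm")
}

#' @export
print.ps_glm <- function(x, ...) {
  cat("GLM fit: ", deparse(x$formula), " [", x$family$family, "(",
      x$family$link, ")]\n", sep = "")
  cat("  n =", x$n, " edf =", x$edf,
      " logLik =", format(x$loglik, digits = 6),
      " dispersion =", format(x$dispersion, digits = 4), "\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' Pearson overdispersion estimate
#'
#' `c_hat` = Pearson chi-square / residual degrees of freedom, the
#' scaling used by quasi-likelihood families and qAIC.
#'
#' @param fit A [glm_fit()] or [gam_fit()] object.
#' @return Scalar dispersion estimate.
#' @export
dispersion_estimate <- function(fit) {
  df <- fit$df_residual
  if (is.null(df) || df <= 0) stop("zero residual degrees of freedom")
  c_hat <- fit$pearson / df
  if (c_hat <= .Machine$double.eps^0.5)
    stop("degenerate fit: Pearson statistic is zero (saturated model)")
  c_hat
}

#' Information criteria for a fitted candidate
#'
#' `AIC = -2 loglik + 2 k` with `k` the (effective) number of
#' parameters; `qAIC = -2 loglik / c_hat + 2 k` with `k` counting one
#' extra parameter for `c_hat` itself.
#'
#' @param fit A [glm_fit()] or [gam_fit()] object.
#' @param c_hat Overdispersion estimate; required for `qaic`.
#' @return Named list with `aic` and (when `c_hat` is supplied) `qaic`.
#' @export
information_criteria <- function(fit, c_hat = NULL) {
  k <- fit$edf + n_scale_params(loglik_family(fit$family))
  out <- list(aic = -2 * fit$loglik + 2 * k)
  if (!is.null(c_hat)) {
    if (c_hat <= 0) stop("c_hat must be positive")
    out$qaic <- -2 * fit$loglik / c_hat + 2 * (k + 1)
  } else if (isTRUE(fit$quasi)) {
    stop("quasi-likelihood fit: qAIC requires a c_hat estimate")
  }
  out
}

#' Exclude superparasitized hosts from life-history data
#'
#' Hosts that received more than one parasitoid egg are removed from
#' parasitoid life-history analyses (their trait measurements are
#' confounded by larval competition); efficacy analyses keep all rows.
#'
#' @param records Exposure records.
#' @return The records minus rows from multi-egg hosts, with
#'   attributes `n_hosts_flagged` (superparasitized hosts) and
#'   `n_rows_removed`.
#' @export
filter_superparasitism <- function(records) {
  stopifnot("n_eggs" %in% names(records))
  flagged <- !is.na(records$n_eggs) & records$n_eggs > 1L
  out <- records[!flagged, , drop = FALSE]
  attr(out, "n_hosts_flagged") <- sum(flagged)
  attr(out, "n_rows_removed") <- sum(flagged)
  out
}

#' Wald post-hoc contrasts with Bonferroni adjustment
#'
#' General linear hypotheses `K beta = 0` on the linear-predictor
#' scale: estimates, standard errors from the coefficient covariance,
#' Wald z statistics and Bonferroni-adjusted p-values across the rows
#' of `K`.
#'
#' @param fit A [glm_fit()] or [gam_fit()] object.
#' @param K Contrast matrix, one row per hypothesis, columns matching
#'   the coefficient vector (by position; row names label output).
#' @return Data frame with `contrast`, `estimate`, `se`, `z`, `p`,
#'   `p_adjusted`.
#' @export
posthoc_contrasts <- function(fit, K) {
  K <- as.matrix(K)
  b <- fit$coefficients
  V <- fit$vcov
  if (ncol(K) != length(b))
    stop("contrast matrix has ", ncol(K), " columns; model has ",
         length(b), " coefficients")
  est <- drop(K %*% b)
  se <- sqrt(pmax(diag(K %*% V %*% t(K)), 0))
  z <- ifelse(se > 0, est / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  nm <- rownames(K)
  if (is.null(nm)) nm <- paste0("c", seq_len(nrow(K)))
  data.frame(contrast = nm, estimate = est, se = se, z = z, p = p,
             p_adjusted = bonferroni_adjust(pmax(p, .Machine$double.xmin)),
             row.names = NULL, stringsAsFactors = FALSE)
}
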