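# Penalized-spline additive models with factor-by smooths.
#
# Smooth terms s(A) and s(A, by = F) are cubic B-splines on equally
# spaced knots with a second-order difference penalty on the
# coefficients. With uniform knots the penalty null space is exactly
# the linear functions, so an infinitely penalized smooth collapses to
# the least-squares line. Each smooth block carries a sum-to-zero
# constraint for identifiability against the intercept / by-factor
# main effects; smoothing parameters are chosen by GCV on a log grid,
# one parameter per smooth term (shared across its by-levels).

#' Build a penalized B-spline basis
#'
#' Cubic B-spline basis on equally spaced knots spanning the covariate
#' range (extended `degree` knots beyond each end, so basis rows sum to
#' one everywhere on the range), with a second-order difference
#' penalty. The penalty is symmetric positive semidefinite and its
#' null space is the linear functions of the covariate.
#'
#' @param x Covariate values.
#' @param k Basis dimension (>= 4).
#' @param degree Spline degree (default cubic).
#' @param range Optional covariate range to build the knots on
#'   (defaults to `range(x)`).
#' @return List with `X` (basis matrix, `length(x)` x `k`), `S`
#'   (`k` x `k` penalty), `knots`, `k`, `degree`.
#' @export
build_smooth_basis <- function(x, k = 10L, degree = 3L, range = NULL) {
  k <- as.integer(k)
  if (k < 4L) stop("basis dimension k must be >= 4")
  if (length(unique(x)) < k)
    stop("fewer than k = ", k, " distinct covariate values; reduce k")
  if (is.null(range)) range <- base::range(x)
  xl <- range[1L]
  xu <- range[2L]
  dx <- (xu - xl) / (k - degree)
  knots <- seq(xl - degree * dx, xu + degree * dx, by = dx)
  X <- splines::splineDesign(knots, x, ord = degree + 1L,
                             outer.ok = TRUE)
  D <- diff(diag(k), differences = 2L)
  list(X = X, S = crossprod(D), knots = knots, k = k, degree = degree)
}

# --- smooth-term parsing ------------------------------------------------

# formula grammar: response ~ parametric terms + s(A) + s(A, by = Q, k = 10)
parse_smooth_terms <- function(formula) {
  tt <- terms(formula, specials = "s")
  labels <- attr(tt, "term.labels")
  is_smooth <- grepl("^s\\(", labels)
  smooths <- lapply(labels[is_smooth], function(lab) {
    cl <- str2lang(lab)
    args <- as.list(cl)[-1L]
    nm <- names(args)
    if (is.null(nm)) nm <- rep("", length(args))
    var <- deparse(args[[which(nm == "")[1L]]])
    by <- if ("by" %in% nm) deparse(args[[which(nm == "by")]]) else NULL
    kk <- if ("k" %in% nm) eval(args[[which(nm == "k")]]) else NULL
    list(label = lab, var = var, by = by, k = kk)
  })
  list(terms = tt, parametric = labels[!is_smooth], smooths = smooths,
       response = as.character(formula)[2L])
}

# assemble design: parametric columns + one constrained block per
# smooth (per by-level), returning everything prediction needs
build_gam_design <- function(formula, data, k_default = 10L) {
  ps <- parse_smooth_terms(formula)
  if (!length(ps$smooths))
    stop("no smooth terms; use glm_fit() for purely parametric models")
  pform <- if (length(ps$parametric)) {
    stats::reformulate(ps$parametric, response = ps$response)
  } else {
    as.formula(paste(ps$response, "~ 1"))
  }
  mf <- model.frame(pform, data = data)
  y <- model.response(mf)
  Xp <- model.matrix(pform, mf)
  xlev <- stats::.getXlevels(terms(pform), mf)

  blocks <- list()
  for (ti in seq_along(ps$smooths)) {
    sm <- ps$smooths[[ti]]
    xv <- data[[sm$var]]
    if (is.null(xv)) stop("smooth covariate '", sm$var, "' not in data")
    kk <- if (is.null(sm$k)) k_default else sm$k
    bb <- build_smooth_basis(xv, k = kk)
    levels_by <- if (is.null(sm$by)) NA_character_ else {
      byv <- data[[sm$by]]
      if (is.null(byv)) stop("by-factor '", sm$by, "' not in data")
      levels(factor(byv))
    }
    for (lv in levels_by) {
      B <- bb$X
      if (!is.na(lv)) {
        act <- as.numeric(factor(data[[sm$by]]) == lv)
        B <- B * act
      }
      cons <- colSums(B)
      Q <- qr.Q(qr(matrix(cons, ncol = 1L)), complete = TRUE)[, -1L,
                                                              drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        term = ti, label = sm$label, var = sm$var, by = sm$by,
        level = if (is.na(lv)) NULL else lv,
        X = B %*% Q, S = crossprod(Q, bb$S %*% Q),
        Q = Q, knots = bb$knots, k = bb$k, degree = bb$degree)
    }
  }
  list(y = y, Xp = Xp, blocks = blocks, n_terms = length(ps$smooths),
       pform = pform, xlev = xlev, parse = ps, mf = mf)
}

# penalized IRLS at fixed per-term smoothing parameters
pirls_fit <- function(y, X, S_list, block_cols, lambda_by_block, fam,
                      max_iter = 60L, tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  S <- matrix(0, p, p)
  for (i in seq_along(S_list)) {
    cols <- block_cols[[i]]
    S[cols, cols] <- S[cols, cols] + lambda_by_block[i] * S_list[[i]]
  }
  nobs <- n
  family <- fam   # family$initialize expressions reference `family`
  weights <- rep(1, n)
  etastart <- NULL
  start <- NULL
  mustart <- NULL
  eval(fam$initialize)
  y <- y  # initialize may rescale binomial matrix responses
  mu <- mustart
  eta <- fam$linkfun(mu)
  dev <- sum(fam$dev.resids(y, mu, weights))
  beta <- NULL
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    mev <- fam$mu.eta(eta)
    vv <- fam$variance(mu)
    good <- is.finite(mev) & is.finite(vv) & vv > 0 & mev != 0
    if (!all(good)) break
    w <- weights * mev^2 / vv
    z <- eta + (y - mu) / mev
    XtW <- t(X * w)
    A <- XtW %*% X + S
    beta_prop <- tryCatch(drop(solve(A, XtW %*% z)),
                          error = function(e) NULL)
    if (is.null(beta_prop)) break
    # step control: halve back toward the previous coefficients if the
    # proposal leaves the family's domain (e.g. Gamma inverse link
    # producing nonpositive means)
    h <- 1
    valid <- FALSE
    while (h >= 1e-6) {
      bc <- if (is.null(beta)) beta_prop else beta + h * (beta_prop - beta)
      eta_new <- drop(X %*% bc)
      mu_new <- fam$linkinv(eta_new)
      valid <- all(is.finite(mu_new)) && fam$validmu(mu_new) &&
        fam$valideta(eta_new)
      if (valid) break
      if (is.null(beta)) break  # no previous point to retreat toward
      h <- h / 2
    }
    if (!valid) break
    dev_new <- sum(fam$dev.resids(y, mu_new, weights))
    beta <- bc
    eta <- eta_new
    mu <- mu_new
    delta <- abs(dev_new - dev) / (abs(dev_new) + 0.1)
    dev <- dev_new
    if (delta < tol) {
      ok <- TRUE
      break
    }
  }
  if (is.null(beta)) return(NULL)
  mev <- fam$mu.eta(eta)
  vv <- fam$variance(mu)
  w <- weights * mev^2 / vv
  XtWX <- t(X * w) %*% X
  A <- XtWX + S
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(NULL)
  edf <- sum(diag(Ainv %*% XtWX))
  pearson <- sum((y - mu)^2 / vv)
  list(beta = drop(beta), eta = drop(eta), mu = drop(mu), dev = dev,
       edf = edf, Ainv = Ainv, XtWX = XtWX, pearson = pearson,
       converged = ok, weights = weights, y = y)
}

#' Fit a penalized-spline additive model
#'
#' Penalized iteratively reweighted least squares for models mixing
#' parametric terms and `s()` smooths, with smoothing parameters (one
#' per smooth term, shared across its by-levels) chosen by minimizing
#' the GCV score `n * deviance / (n - edf)^2` over a log-spaced grid,
#' or fixed via `sp`.
#'
#' @param formula Formula with `s(x)` / `s(x, by = f, k = ...)` terms.
#' @param family As in [glm_fit()].
#' @param data Data frame.
#' @param k Default basis dimension for smooths that do not set `k`.
#' @param sp Optional fixed smoothing parameter(s), one per smooth
#'   term (recycled); bypasses the GCV search.
#' @param sp_grid Candidate smoothing parameters for the GCV search.
#' @return Object of class `ps_gam`; shares the `ps_glm` fields
#'   (`coefficients`, `vcov`, `loglik`, `dispersion`, `edf`, ...) plus
#'   `sp`, `gcv`, and the design bookkeeping used by
#'   [compare_smooths()].
#' @export
gam_fit <- function(formula, family, data, k = 10L, sp = NULL,
                    sp_grid = 10^seq(-4, 9, length.out = 14L)) {
  fam <- ps_family(family)
  des <- build_gam_design(formula, data, k_default = k)
  y <- des$y
  X <- cbind(des$Xp, do.call(cbind, lapply(des$blocks, `[[`, "X")))
  np <- ncol(des$Xp)
  S_list <- lapply(des$blocks, `[[`, "S")
  off <- np
  block_cols <- lapply(des$blocks, function(b) {
    cols <- off + seq_len(ncol(b$X))
    off <<- off + ncol(b$X)
    cols
  })
  term_of_block <- vapply(des$blocks, `[[`, integer(1L), "term")
  nt <- des$n_terms

  fit_at <- function(sp_terms) {
    pirls_fit(y, X, S_list, block_cols, sp_terms[term_of_block], fam)
  }
  n <- length(y)
  if (!is.null(sp)) {
    sp_terms <- rep_len(sp, nt)
    best <- fit_at(sp_terms)
    if (is.null(best)) stop("penalized IRLS failed at the supplied sp")
    gcv <- n * best$dev / (n - best$edf)^2
  } else {
    grids <- if (nt == 1L) {
      matrix(sp_grid, ncol = 1L)
    } else if (nt == 2L) {
      as.matrix(expand.grid(10^seq(-3, 9, by = 1.5),
                            10^seq(-3, 9, by = 1.5)))
    } else {
      # shared smoothing parameter across terms beyond two
      matrix(rep(sp_grid, nt), ncol = nt)
    }
    best <- NULL
    gcv <- Inf
    sp_terms <- rep(1, nt)
    for (gi in seq_len(nrow(grids))) {
      cand <- fit_at(grids[gi, ])
      if (is.null(cand) || !cand$converged) next
      score <- n * cand$dev / (n - cand$edf)^2
      if (score < gcv) {
        gcv <- score
        best <- cand
        sp_terms <- grids[gi, ]
      }
    }
    if (is.null(best)) stop("penalized IRLS failed on the whole sp grid")
  }
  llfam <- loglik_family(fam)
  dev_exact <- sum(llfam$dev.resids(best$y, best$mu, best$weights))
  ll <- -llfam$aic(best$y, n, best$mu, best$weights, dev_exact) / 2 +
    n_scale_params(llfam)
  df_res <- n - best$edf
  phi <- if (fam$family %in% c("binomial", "poisson")) 1 else
    best$pearson / df_res
  Vp <- best$Ainv * phi
  cn <- c(colnames(des$Xp),
          unlist(lapply(seq_along(des$blocks), function(i) {
            b <- des$blocks[[i]]
            base <- if (is.null(b$level)) b$label else
              paste0(b$label, ":", b$level)
            paste0(base, ".", seq_len(ncol(b$X)))
          })))
  beta <- setNames(best$beta, cn)
  dimnames(Vp) <- list(cn, cn)
  structure(list(coefficients = beta, vcov = Vp, loglik = ll,
                 dispersion = phi, pearson = best$pearson,
                 df_residual = df_res, edf = best$edf,
                 edf_parametric = np, family = fam, quasi = FALSE,
                 converged = best$converged, n = n,
                 fitted = best$mu, linear_predictor = best$eta,
                 formula = formula, sp = sp_terms, gcv = gcv,
                 design = des, block_cols = block_cols,
                 deviance = best$dev),
            class = c("ps_gam"))
}

#' @export
print.ps_gam <- function(x, ...) {
  cat("Penalized-spline GAM: ", deparse(x$formula), " [",
      x$family$family, "(", x$family$link, ")]\n", sep = "")
  cat("  n =", x$n, " total edf =", format(x$edf, digits = 4),
      " sp =", paste(format(x$sp, digits = 3), collapse = ", "),
      " GCV =", format(x$gcv, digits = 6), "\n")
  invisible(x)
}

# linear-predictor matrix for new data (rows map new observations to
# the fitted coefficient vector)
gam_lpmatrix <- function(fit, newdata) {
  des <- fit$design
  tt <- stats::delete.response(terms(des$pform))
  mfp <- model.frame(tt, newdata, xlev = des$xlev)
  Xp <- model.matrix(tt, mfp)
  Xs <- lapply(des$blocks, function(b) {
    B <- splines::splineDesign(b$knots, newdata[[b$var]],
                               ord = b$degree + 1L, outer.ok = TRUE)
    if (!is.null(b$level)) {
      act <- as.numeric(as.character(newdata[[b$by]]) == b$level)
      B <- B * act
    }
    B %*% b$Q
  })
  cbind(Xp, do.call(cbind, Xs))
}

#' Predict from a penalized-spline GAM
#'
#' @param object A [gam_fit()] object.
#' @param newdata Data frame of covariates (defaults to fitted values).
#' @param type `"link"` or `"response"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ps_gam <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictor
  } else {
    eta <- drop(gam_lpmatrix(object, newdata) %*% object$coefficients)
  }
  if (type == "response") object$family$linkinv(eta) else eta
}

#' Pairwise comparison of by-level smooths
#'
#' Difference between the fitted curves of two by-factor levels on an
#' evaluation grid (including the levels' parametric offset, so a pure
#' level shift is part of the difference), with pointwise confidence
#' intervals from the joint coefficient covariance and flags for grid
#' points whose interval excludes zero. The interval level is
#' Bonferroni-adjusted for the number of level pairs compared.
#'
#' @param fit A [gam_fit()] with a by-factor smooth.
#' @param levelA,levelB Levels of the by-factor to compare.
#' @param grid Covariate values to evaluate on (default 100 points over
#'   the fitted range).
#' @param alpha Nominal error rate (default 0.05).
#' @param n_pairs Number of level pairs in the family of comparisons
#'   (Bonferroni divisor; default 1).
#' @return Data frame: `x`, `diff`, `se`, `lower`, `upper`,
#'   `significant`.
#' @export
compare_smooths <- function(fit, levelA, levelB, grid = NULL,
                            alpha = 0.05, n_pairs = 1L) {
  stopifnot(inherits(fit, "ps_gam"))
  des <- fit$design
  bys <- Filter(function(b) !is.null(b$level), des$blocks)
  if (!length(bys)) stop("model has no by-factor smooth")
  byvar <- bys[[1L]]$by
  var <- bys[[1L]]$var
  levs <- unique(vapply(bys, `[[`, character(1L), "level"))
  for (lv in c(levelA, levelB)) {
    if (!lv %in% levs) stop("level '", lv, "' has no fitted smooth")
  }
  if (is.null(grid)) {
    xv <- des$mf[[var]]
    if (is.null(xv)) xv <- range(fit$design$blocks[[1L]]$knots)
    grid <- seq(min(xv), max(xv), length.out = 100L)
  }
  base <- des$mf[rep(1L, length(grid)), , drop = FALSE]
  nd <- as.data.frame(base)
  nd[[var]] <- grid
  ndA <- nd
  ndA[[byvar]] <- factor(levelA, levels = levs)
  ndB <- nd
  ndB[[byvar]] <- factor(levelB, levels = levs)
  # the parametric frame may not contain the by factor (e.g. Y ~ s(A, by=Q)
  # without a Q main effect); gam_lpmatrix only needs columns it uses
  L <- gam_lpmatrix(fit, ndA) - gam_lpmatrix(fit, ndB)
  d <- drop(L %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((L %*% fit$vcov) * L), 0))
  crit <- qnorm(1 - alpha / (2 * max(1L, n_pairs)))
  lower <- d - crit * se
  upper <- d + crit * se
  data.frame(x = grid, diff = d, se = se, lower = lower, upper = upper,
             significant = lower > 0 | upper < 0)
}
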