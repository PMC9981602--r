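# Cox proportional hazards with tied event times.
#
# Each host contributes a single row: time is its age at the 24-h
# parasitoid exposure, event indicates parasitism, and unparasitized
# hosts are right-censored at that age.  Ages are integer days, so ties
# are pervasive and the tie approximation materially affects the
# estimate; Efron is the default, matching standard survival software.

# sort rows by time ascending; returns permutation
cox_order <- function(time) order(time)

cox_method_code <- function(tie_method) {
  tie_method <- match.arg(tie_method, c("efron", "breslow"))
  c(efron = 1L, breslow = 0L)[[tie_method]]
}

#' Cox partial log-likelihood with tie correction
#'
#' Evaluates the partial log-likelihood of a Cox proportional-hazards
#' model at a given coefficient vector, with tied event times handled by
#' the Efron or Breslow approximation. The two coincide when no event
#' times are tied.
#'
#' @param time Positive numeric vector of event/censoring times (here,
#'   host age in days at exposure).
#' @param event Binary vector (0/1 or logical): 1 if the host was
#'   parasitized at `time`, 0 if right-censored.
#' @param x Numeric covariate matrix (one column per coefficient), e.g.
#'   treatment dummy codes.
#' @param beta Numeric coefficient vector, `length(beta) == ncol(x)`.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @return The scalar partial log-likelihood.
#' @examples
#' # two subjects, distinct event times, beta = 0: one two-subject risk
#' # set and one singleton, so the value is -log(2)
#' cox_partial_loglik(c(1, 2), c(1, 1), matrix(c(0, 1)), beta = 0)
#' @export
cox_partial_loglik <- function(time, event, x, beta,
                               tie_method = c("efron", "breslow")) {
  x <- as.matrix(x)
  event <- as.integer(event)
  stopifnot(length(time) == length(event), nrow(x) == length(time),
            length(beta) == ncol(x))
  if (!any(event == 1L)) {
    stop("partial likelihood undefined: no events in the data")
  }
  ord <- cox_order(time)
  d <- .cox_derivs_cpp(as.numeric(time[ord]), event[ord],
                       x[ord, , drop = FALSE], as.numeric(beta),
                       cox_method_code(tie_method[[1L]]))
  d$loglik
}

# internal: full derivative bundle at beta (pre-sorted inputs)
cox_derivs <- function(time, event, x, beta, method_code) {
  .cox_derivs_cpp(time, event, x, beta, method_code)
}

#' Fit a Cox proportional-hazards model by Newton--Raphson
#'
#' Maximizes the tie-corrected partial likelihood with Newton--Raphson
#' and step-halving. Monotone likelihood (e.g. a treatment group with
#' all or no events) is detected by coefficient divergence and flagged.
#'
#' @inheritParams cox_partial_loglik
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient infinity norm.
#' @param coef_limit Absolute coefficient value beyond which monotone
#'   likelihood is declared.
#' @return An object of class `cox_fit`: list with `coef`, `se`,
#'   `vcov`, `loglik`, `loglik_null`, `tie_method`, `converged`,
#'   `monotone`, `iter`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, x, tie_method = c("efron", "breslow"),
                    max_iter = 25L, tol = 1e-8, coef_limit = 10) {
  tie_method <- match.arg(tie_method)
  x <- as.matrix(x)
  event <- as.integer(event)
  stopifnot(length(time) == length(event), nrow(x) == length(time))
  if (!any(event == 1L)) stop("no events: cannot fit hazard model")
  # a covariate column with a single value carries no information and
  # makes the information matrix singular
  degen <- apply(x, 2L, function(col) length(unique(col)) < 2L)
  if (ncol(x) == 0L || all(degen)) {
    stop("degenerate design: fewer than two groups represented")
  }
  mcode <- cox_method_code(tie_method)
  ord <- cox_order(time)
  tt <- as.numeric(time[ord])
  ee <- event[ord]
  xx <- x[ord, , drop = FALSE]

  p <- ncol(x)
  beta <- rep(0, p)
  dv <- cox_derivs(tt, ee, xx, beta, mcode)
  ll <- dv$loglik
  ll0 <- ll
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  # gradient tolerance scaled by the log-likelihood magnitude: at large
  # n the gradient cannot be accumulated below float noise of that scale
  gtol <- function(ll) tol * max(1, abs(ll))
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(dv$gradient)) < gtol(ll)) {
      converged <- TRUE
      break
    }
    info <- -dv$hessian
    step <- tryCatch(solve(info, dv$gradient), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: never accept a decrease in the partial likelihood
    h <- 1
    repeat {
      cand <- beta + h * step
      dc <- cox_derivs(tt, ee, xx, cand, mcode)
      if (dc$loglik >= ll - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    beta <- beta + h * step
    dv <- cox_derivs(tt, ee, xx, beta, mcode)
    ll <- dv$loglik
    if (any(abs(beta) > coef_limit)) {
      monotone <- TRUE
      break
    }
  }
  if (max(abs(dv$gradient)) < gtol(ll) && !monotone) converged <- TRUE
  vc <- tryCatch(solve(-dv$hessian), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(as.matrix(vc)), 0))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  names(beta) <- names(se) <- nm
  structure(list(coef = beta, se = se, vcov = vc, loglik = ll,
                 loglik_null = ll0, tie_method = tie_method,
                 converged = converged, monotone = monotone, iter = iter,
                 n = length(tt), n_events = sum(ee)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$tie_method, " ties)\n", sep = "")
  cat("  n =", x$n, " events =", x$n_events, "\n")
  tab <- data.frame(coef = x$coef, se = x$se)
  print(tab, ...)
  if (!x$converged) {
    cat("  WARNING: not converged",
        if (x$monotone) "(monotone likelihood)" else "", "\n")
  }
  invisible(x)
}

# treatment-dummy design matrix vs a reference level; column names
# "<level> vs <reference>"
quality_dummies <- function(quality, reference) {
  quality <- as.character(quality)
  lev <- unique(quality)
  if (!reference %in% lev) {
    stop("reference level '", reference, "' absent from data")
  }
  others <- sort(setdiff(lev, reference))
  m <- vapply(others, function(l) as.numeric(quality == l),
              numeric(length(quality)))
  m <- matrix(m, nrow = length(quality),
              dimnames = list(NULL, paste(others, "vs", reference)))
  m
}

#' Stage-specific Cox hazard fits for daily parasitism risk
#'
#' Subsets fully staged exposure records to each developmental stage and
#' fits the model `Surv(age, parasitized) ~ quality`, with the richest
#' diet (by default `"100"`) as the reference level. The first instar is
#' excluded by default: parasitism of L1 hosts is a rare, essentially
#' uninformative event. Stages whose subset cannot support a fit (no
#' events, or a single treatment present) are returned as skipped
#' markers rather than errors.
#'
#' @param records Exposure record data frame with columns
#'   `age_at_exposure`, `parasitized`, `quality`, and a complete
#'   `stage_at_parasitism` (see [impute_stages()]).
#' @param reference Reference treatment label (default `"100"`).
#' @param stages Stages to analyse; default all but `L1`.
#' @param tie_method Passed to [cox_fit()].
#' @return Object of class `stage_hazards`: a named list, one element
#'   per requested stage, each either a `cox_fit` (with `$stage`) or a
#'   `skipped_stage` marker carrying the reason.
#' @export
fit_stage_hazards <- function(records, reference = "100",
                              stages = setdiff(stage_levels(), "L1"),
                              tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  stopifnot(all(c("age_at_exposure", "parasitized", "quality",
                  "stage_at_parasitism") %in% names(records)))
  if (anyNA(records$stage_at_parasitism)) {
    stop("records contain unstaged hosts; run impute_stages() first")
  }
  stage <- as.character(records$stage_at_parasitism)
  out <- lapply(stages, function(s) {
    idx <- stage == s
    n <- sum(idx)
    sub <- records[idx, , drop = FALSE]
    if (n == 0L) {
      return(structure(list(stage = s, reason = "no records"),
                       class = "skipped_stage"))
    }
    if (!any(sub$parasitized == 1)) {
      return(structure(list(stage = s, reason = "no parasitism events"),
                       class = "skipped_stage"))
    }
    if (length(unique(sub$quality)) < 2L ||
        !reference %in% as.character(sub$quality)) {
      return(structure(list(stage = s,
                            reason = "fewer than two treatments present"),
                       class = "skipped_stage"))
    }
    xm <- quality_dummies(sub$quality, reference)
    keep <- colSums(xm) > 0 & colSums(xm) < nrow(xm)
    if (!any(keep)) {
      return(structure(list(stage = s, reason = "degenerate design"),
                       class = "skipped_stage"))
    }
    fit <- cox_fit(sub$age_at_exposure, sub$parasitized,
                   xm[, keep, drop = FALSE], tie_method = tie_method)
    fit$stage <- s
    fit$reference <- reference
    fit
  })
  names(out) <- stages
  structure(out, class = "stage_hazards", reference = reference)
}

#' Tabulate stage-specific hazard fits
#'
#' @param x A `stage_hazards` object from [fit_stage_hazards()].
#' @param ... Unused.
#' @return Data frame with one row per stage and contrast: `stage`,
#'   `contrast`, `lambda` (log hazard ratio), `se`, `n`, `n_events`,
#'   `converged`. Skipped stages appear with `NA` estimates and the
#'   skip reason.
#' @export
as.data.frame.stage_hazards <- function(x, ...) {
  rows <- lapply(x, function(f) {
    if (inherits(f, "skipped_stage")) {
      return(data.frame(stage = f$stage, contrast = NA_character_,
                        lambda = NA_real_, se = NA_real_,
                        n = 0L, n_events = 0L, converged = NA,
                        note = f$reason))
    }
    data.frame(stage = f$stage, contrast = names(f$coef),
               lambda = unname(f$coef), se = unname(f$se),
               n = f$n, n_events = f$n_events, converged = f$converged,
               note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.stage_hazards <- function(x, ...) {
  cat("Stage-specific daily parasitism hazard fits",
      "(reference ", attr(x, "reference"), "%)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
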