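# Candidate enumeration and AIC/qAIC ranking.

#' Candidate model specification
#'
#' @param formula Model formula; may contain `s()` smooth terms.
#' @param family As in [glm_fit()].
#' @param label Optional display label (defaults to the formula text).
#' @return A `model_spec` list.
#' @export
model_spec <- function(formula, family, label = NULL) {
  formula <- as.formula(formula)
  if (is.null(label)) label <- paste(deparse(formula), collapse = " ")
  structure(list(formula = formula, family = family, label = label),
            class = "model_spec")
}

spec_has_smooth <- function(spec) {
  any(grepl("^s\\(", attr(terms(spec$formula, specials = "s"),
                          "term.labels")))
}

spec_response <- function(spec) {
  as.character(spec$formula)[2L]
}

#' Expand main effects into an additive candidate set
#'
#' All subsets of the supplied main-effect terms (including the
#' intercept-only model), each as a [model_spec()] with the shared
#' response and family.
#'
#' @param response Response variable name.
#' @param effects Character vector of main-effect term labels.
#' @param family As in [glm_fit()].
#' @return List of `model_spec` objects (length `2^length(effects)`).
#' @export
additive_candidates <- function(response, effects, family) {
  subsets <- lapply(seq_len(2^length(effects)) - 1L, function(m) {
    effects[bitwAnd(m, 2^(seq_along(effects) - 1L)) > 0L]
  })
  lapply(subsets, function(tr) {
    f <- if (length(tr)) {
      stats::reformulate(tr, response = response)
    } else {
      as.formula(paste(response, "~ 1"))
    }
    model_spec(f, family)
  })
}

#' Fit candidates and rank by AIC or qAIC
#'
#' Fits every candidate (GLM or penalized-spline GAM as the formula
#' dictates) and ranks by AIC, or by qAIC when any candidate uses a
#' quasi-likelihood family; the overdispersion `c_hat` entering qAIC
#' is taken from the most complex candidate and applied to all of
#' them. Candidates within 2 criterion units of the top model are
#' flagged as near-ties. Equal criterion values keep insertion order.
#'
#' @param specs List of [model_spec()] objects sharing a response.
#' @param data Data frame.
#' @param k Default smooth basis dimension passed to [gam_fit()].
#' @return Object of class `selection_table`: data frame with `label`,
#'   `family`, `edf`, `loglik`, `criterion` (`"AIC"`/`"qAIC"`),
#'   `value`, `delta`, `near_tie`, ordered best-first; attributes
#'   `fits` (all fits, input order) and `top` (the selected fit).
#' @export
enumerate_and_select <- function(specs, data, k = 10L) {
  if (length(specs) < 2L) stop("need at least two candidate models")
  specs <- lapply(specs, function(s) {
    if (inherits(s, "model_spec")) s else stop("specs must be model_spec")
  })
  resp <- vapply(specs, spec_response, character(1L))
  if (length(unique(resp)) != 1L)
    stop("candidates mix response definitions: ",
         paste(unique(resp), collapse = " / "))
  fits <- lapply(specs, function(s) {
    if (spec_has_smooth(s)) {
      gam_fit(s$formula, s$family, data, k = k)
    } else {
      glm_fit(s$formula, s$family, data)
    }
  })
  quasi <- any(vapply(fits, function(f) isTRUE(f$quasi), logical(1L)))
  if (quasi) {
    most_complex <- which.max(vapply(fits, `[[`, numeric(1L), "edf"))
    c_hat <- dispersion_estimate(fits[[most_complex]])
    vals <- vapply(fits, function(f) {
      information_criteria(f, c_hat = c_hat)$qaic
    }, numeric(1L))
    criterion <- "qAIC"
  } else {
    c_hat <- NA_real_
    vals <- vapply(fits, function(f) information_criteria(f)$aic,
                   numeric(1L))
    criterion <- "AIC"
  }
  ord <- order(vals)  # stable: ties keep insertion order
  delta <- vals - min(vals)
  tab <- data.frame(
    label = vapply(specs, `[[`, character(1L), "label"),
    family = vapply(fits, function(f) f$family$family, character(1L)),
    edf = vapply(fits, `[[`, numeric(1L), "edf"),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    criterion = criterion, value = vals, delta = delta,
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  tab$near_tie <- tab$delta < 2 & seq_len(nrow(tab)) > 1L
  rownames(tab) <- NULL
  structure(tab, class = c("selection_table", "data.frame"),
            fits = fits, top = fits[[ord[1L]]], c_hat = c_hat)
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Model selection (", x$criterion[1L], ")\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
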