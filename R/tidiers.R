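#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`(Intercept)` plus one per
#'   feature) and its coefficient.
#' @method tidy lda_model
#' @export
tidy.lda_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("f", seq_along(x$normal))),
    estimate = c(x$intercept, unname(x$normal))
  )
}

#' Tidy a logistic regression model
#'
#' @param x An `lr_model`.
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @method tidy lr_model
#' @export
tidy.lr_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("f", seq_along(x$weights))),
    estimate = c(x$intercept, unname(x$weights))
  )
}

#' One-row fit summary of a logistic regression model
#'
#' @param x An `lr_model`.
#' @param ... Unused.
#' @return A tibble: `objective`, `iterations`, `converged`, `l2_penalty`.
#' @method glance lr_model
#' @export
glance.lr_model <- function(x, ...) {
  tibble::tibble(objective = x$objective, iterations = x$iterations,
                 converged = x$converged, l2_penalty = x$l2_penalty)
}

#' Tidy a CSP filter bank
#'
#' @param x A `csp_filters` object.
#' @param ... Unused.
#' @return A tibble with one row per filter: `filter`, `eigenvalue`,
#'   `side` (`"max"` for the variance-maximizing half, `"min"` for the
#'   minimizing half).
#' @method tidy csp_filters
#' @export
tidy.csp_filters <- function(x, ...) {
  tibble::tibble(
    filter = seq_len(2L * x$m),
    eigenvalue = x$eigenvalues,
    side = rep(c("max", "min"), each = x$m)
  )
}
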