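# broom-style tidiers for fitted objects.

#' Tidy an NB GLM fit
#'
#' @param x An `nbglm_fit` from [fit_nb_glm()].
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
#' @method tidy nbglm_fit
tidy.nbglm_fit <- function(x, ...) {
  wt <- wald_test(unname(x$coefficients), unname(x$se))
  if (is.null(names(x$coefficients))) {
    names(x$coefficients) <- paste0("b", seq_along(x$coefficients) - 1)
  }
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = wt$z, p.value = wt$p)
}

#' One-row summary of an NB GLM fit
#'
#' @param x An `nbglm_fit`.
#' @param ... Unused.
#' @return Tibble: `alpha`, `logLik`, `converged`, `iterations`, `nobs`.
#' @export
#' @method glance nbglm_fit
glance.nbglm_fit <- function(x, ...) {
  tibble(alpha = x$alpha, logLik = x$loglik, converged = x$converged,
         iterations = x$iterations, nobs = length(x$y))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
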