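#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conditional-logit fit
#'
#' @param x A `dce_clogit`.
#' @param ... Unused.
#' @return A tibble with `term`, `attribute`, `level`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.dce_clogit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients),
                        std.error = unname(x$std.error))
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  label_terms(out, x$schema)
}

#' Tidy a mixed-logit fit
#'
#' Returns one row per estimated parameter; `component` is `"mean"` for
#' the part-worth means and the opt-out constant and `"sd"` for the
#' random-coefficient standard deviations.
#'
#' @param x A `dce_mixlogit`.
#' @param ... Unused.
#' @return A tibble with `component`, `term`, `attribute`, `level`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.dce_mixlogit <- function(x, ...) {
  out <- tibble::tibble(
    component = c(rep("mean", length(x$coefficients)),
                  rep("sd", length(x$sd_coefficients))),
    term = c(names(x$coefficients), sub("^sd_", "", names(x$sd_coefficients))),
    estimate = c(unname(x$coefficients), unname(x$sd_coefficients)),
    std.error = c(unname(x$std.error), unname(x$sd_std.error)))
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  label_terms(out, x$schema)
}

label_terms <- function(out, schema) {
  if (is.null(schema)) return(out)
  terms <- schema_terms(schema)
  i <- match(out$term, terms$term)
  out$attribute <- ifelse(is.na(i), out$term, terms$attribute[i])
  out$level <- terms$level[i]
  front <- intersect(c("component", "term", "attribute", "level"), names(out))
  out[, c(front, setdiff(names(out), front))]
}

#' One-row model summary
#' @param x A `dce_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `AIC`, `BIC`, `k`, `nobs`,
#'   `n_respondents`, `converged` (plus `n_draws` for mixed logit).
#' @export
glance.dce_fit <- function(x, ...) {
  out <- tibble::tibble(logLik = x$log_likelihood, AIC = x$aic, BIC = x$bic,
                        k = x$k, nobs = x$n_obs,
                        n_respondents = x$n_respondents,
                        converged = x$converged)
  if (inherits(x, "dce_mixlogit")) out$n_draws <- x$n_draws
  out
}
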