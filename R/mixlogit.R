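#' Mixed-logit model specification
#'
#' Which design terms carry normally distributed random coefficients. The
#' default mirrors the information-criterion bookkeeping of the reference
#' analysis: the 12 categorical dummies are random, the cost coefficient
#' and the opt-out constant are fixed, giving k = 14 means + 12 standard
#' deviations = 26 parameters.
#'
#' @param random Character vector of design terms with random coefficients,
#'   or `"dummies"` (all categorical dummies, the default), `"all"` (every
#'   design term) or `"none"` (degenerates to conditional logit).
#' @param schema A [dce_schema()].
#' @return A `dce_model_spec` list with `random_terms` and `mixing`.
#' @export
model_spec <- function(random = "dummies", schema = orphan_drug_schema()) {
  terms <- schema_terms(schema)
  random_terms <- if (identical(random, "dummies")) {
    terms$term[terms$kind == "categorical"]
  } else if (identical(random, "all")) {
    terms$term
  } else if (identical(random, "none")) {
    character(0)
  } else {
    bad <- setdiff(random, terms$term)
    if (length(bad) > 0) stop("unknown design terms: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    random
  }
  structure(list(random_terms = random_terms, mixing = "normal"),
            class = "dce_model_spec")
}

#' Simulated log-likelihood of the panel mixed logit
#'
#' For respondent \eqn{i} with draws \eqn{z_{ir}}, the simulated panel
#' likelihood is \eqn{L_i = \frac1R \sum_r \prod_t P(\mathrm{choice}_{it}
#' \mid \beta_{ir})} with \eqn{\beta_{ir} = \mu + \sigma \odot z_{ir}} on
#' the random terms; the function returns \eqn{\sum_i \log L_i} with the
#' analytic score as attribute `"gradient"`. With all standard deviations
#' zero it equals [conditional_logit_loglik()] at the same means.
#'
#' @param par Parameter vector: K design-term means, the opt-out constant,
#'   then one standard deviation per random term.
#' @param data Long-format data from [build_long_format()].
#' @param draws A draws array (`n_resp` x `n_draws` x `n_random`), e.g.
#'   from the internal Halton generator used by [fit_mixed_logit()].
#' @param spec A [model_spec()].
#' @return Log-likelihood with `"gradient"` attribute.
#' @export
mixed_logit_loglik <- function(par, data, draws, spec = model_spec()) {
  idx <- if (is.list(data) && !is.data.frame(data) && !is.null(data$task)) data
         else long_index(data)
  K <- ncol(idx$X)
  rand_cols <- match(spec$random_terms, colnames(idx$X))
  n_rand <- length(rand_cols)
  if (length(par) != K + 1 + n_rand) {
    stop("par must have length ", K + 1 + n_rand, call. = FALSE)
  }
  if (dim(draws)[3] != n_rand) stop("draws do not match the random terms",
                                    call. = FALSE)
  if (n_rand > 0 && dim(draws)[2] < 1) stop("at least one draw required",
                                            call. = FALSE)
  n_alt <- unique(table(idx$task))
  if (length(n_alt) != 1) stop("tasks must share one alternative count",
                               call. = FALSE)
  res <- mixl_loglik_cpp(par[seq_len(K)], par[K + 1],
                         if (n_rand > 0) par[K + 1 + seq_len(n_rand)] else numeric(0),
                         idx$X, idx$opt_out, idx$resp - 1L,
                         idx$chosen - 1L, as.integer(n_alt),
                         max(idx$resp), draws, rand_cols - 1L, TRUE)
  ll <- res$loglik
  attr(ll, "gradient") <- as.vector(res$gradient)
  ll
}

#' Fit a panel mixed logit by maximum simulated likelihood
#'
#' Maximizes the simulated log-likelihood over the part-worth means, the
#' opt-out constant and the random-coefficient standard deviations, using
#' BFGS with the analytic score and scrambled-free Halton draws
#' (`n_draws` per respondent, first `burn` points dropped). Optimization
#' starts from the conditional-logit fit with small positive standard
#' deviations. Standard errors come from the inverse negative Hessian of
#' the simulated log-likelihood, obtained by central finite differences of
#' the analytic gradient; when that matrix cannot be inverted the standard
#' errors are reported as `NA`. Reported standard deviations are
#' sign-normalized to be non-negative. The same data, spec, draw settings
#' and seed reproduce the same fit exactly.
#'
#' @param data Long-format data from [build_long_format()].
#' @param spec A [model_spec()].
#' @param n_draws Halton draws per respondent (default 500).
#' @param seed Seed recorded with the fit (and used for draw scrambling if
#'   `scramble = TRUE`).
#' @param scramble Scramble the Halton digits.
#' @param burn Leading Halton points to drop.
#' @param start Optional full starting vector.
#' @param sd_start Starting value for the standard deviations.
#' @param hessian Compute standard errors (set `FALSE` to skip the
#'   finite-difference Hessian).
#' @param reltol,maxit BFGS control.
#' @return A `dce_mixlogit` fit: `coefficients` (means + `opt_out`),
#'   `sd_coefficients`, standard errors for both, vcov, log-likelihood,
#'   AIC/BIC (k = means + constant + sds), draw settings, seed and a
#'   convergence flag.
#' @export
fit_mixed_logit <- function(data, spec = model_spec(), n_draws = 500,
                            seed = 1L, scramble = FALSE, burn = 10,
                            start = NULL, sd_start = 0.1, hessian = TRUE,
                            reltol = 1e-8, maxit = 500) {
  idx <- long_index(data)
  K <- ncol(idx$X)
  n_rand <- length(spec$random_terms)
  n_resp <- max(idx$resp)
  draws <- draws_array(n_resp, n_draws, n_rand, burn = burn,
                       scramble = scramble, seed = seed)
  if (is.null(start)) {
    cl <- fit_conditional_logit(data, schema = NULL)
    start <- c(unname(cl$coefficients), rep(sd_start, n_rand))
  }
  fn <- function(p) -as.numeric(mixed_logit_loglik(p, idx, draws, spec))
  gr <- function(p) -attr(mixed_logit_loglik(p, idx, draws, spec), "gradient")
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  par <- opt$par
  par[K + 1 + seq_len(n_rand)] <- abs(par[K + 1 + seq_len(n_rand)])
  term_names <- c(colnames(idx$X), "opt_out")
  sd_names <- if (n_rand > 0) paste0("sd_", spec$random_terms) else character(0)
  names(par) <- c(term_names, sd_names)

  vc <- NULL
  se <- rep(NA_real_, length(par))
  if (hessian) {
    H <- fd_hessian(function(p) attr(mixed_logit_loglik(p, idx, draws, spec),
                                     "gradient"),
                    par)
    vc <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      se <- sqrt(diag(vc))
    } else {
      vc <- NULL
    }
  }
  names(se) <- names(par)
  ll <- -opt$value
  k <- length(par)
  n_obs <- nrow(idx$data)
  ic <- information_criteria(ll, k, n_obs)
  structure(list(
    coefficients = par[seq_len(K + 1)],
    sd_coefficients = par[K + 1 + seq_len(n_rand)],
    std.error = se[seq_len(K + 1)],
    sd_std.error = se[K + 1 + seq_len(n_rand)],
    all_coefficients = par, vcov = vc,
    log_likelihood = ll, k = k, n_obs = n_obs,
    n_respondents = n_resp,
    aic = ic$aic, bic = ic$bic,
    n_draws = n_draws, burn = burn, scramble = scramble, seed = seed,
    spec = spec,
    converged = opt$convergence == 0, iterations = opt$counts[["function"]],
    schema = orphan_drug_schema()
  ), class = c("dce_mixlogit", "dce_fit"))
}

## central finite differences of an analytic gradient -> symmetric Hessian
fd_hessian <- function(grad_fn, par, h = 1e-5) {
  n <- length(par)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    step <- h * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + step
    dn <- par; dn[j] <- dn[j] - step
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Serialize an estimation result as JSON
#'
#' @param fit A `dce_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    model = class(fit)[1],
    coefficients = as.list(fit$coefficients),
    std_error = as.list(fit$std.error),
    log_likelihood = fit$log_likelihood, k = fit$k, n_obs = fit$n_obs,
    n_respondents = fit$n_respondents, aic = fit$aic, bic = fit$bic,
    converged = fit$converged
  )
  if (inherits(fit, "dce_mixlogit")) {
    obj$sd_coefficients <- as.list(fit$sd_coefficients)
    obj$sd_std_error <- as.list(fit$sd_std.error)
    obj$n_draws <- fit$n_draws
    obj$seed <- fit$seed
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
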