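#' Reshape a survey into long-format estimation data
#'
#' Produces the standard three-rows-per-task choice table: one row per
#' alternative (drug 1, drug 2, opt-out) with the encoded design vector,
#' an opt-out indicator, and a chosen flag. The repeated consistency task
#' is excluded by default so each respondent contributes their scored
#' tasks only.
#'
#' @param survey A `dce_survey`.
#' @param schema A [dce_schema()]; defaults to the survey's own.
#' @param drop_consistency_repeat Exclude the repeated task (default TRUE).
#' @return A tibble with columns `respondent_id`, `group`, `task_id`,
#'   `alt_id` (1, 2, 3 = opt-out), `opt_out`, `chosen`, and one column per
#'   design term (e.g. `severity1` ... `cost`). Rows are ordered by
#'   respondent, task, alternative.
#' @export
build_long_format <- function(survey, schema = survey$schema,
                              drop_consistency_repeat = TRUE) {
  if (is.null(schema)) schema <- orphan_drug_schema()
  ch <- survey$choices
  if (drop_consistency_repeat) ch <- ch[!ch$is_repeat, ]
  ch <- ch[order(ch$respondent_id, ch$position), ]
  ch$task_id <- seq_len(nrow(ch))
  attrs <- schema_attributes(schema)
  sets <- survey$design_sets
  missing_sets <- setdiff(unique(ch$set_id), unique(sets$set_id))
  if (length(missing_sets) > 0) {
    stop("choices reference unknown choice sets: ",
         paste(missing_sets, collapse = ", "), call. = FALSE)
  }
  X_sets <- encode_profiles(sets[, attrs, drop = FALSE], schema)
  key <- paste(sets$set_id, sets$alt)
  terms <- colnames(X_sets)
  long <- ch[rep(seq_len(nrow(ch)), each = 3), ]
  long$alt_id <- rep(1:3, nrow(ch))
  long$opt_out <- as.numeric(long$alt_id == 3)
  long$chosen <- as.numeric(long$alt_id == long$choice)
  X <- matrix(0, nrow(long), length(terms), dimnames = list(NULL, terms))
  drug <- long$alt_id != 3
  X[drug, ] <- X_sets[match(paste(long$set_id[drug], long$alt_id[drug]), key), ]
  out <- dplyr::bind_cols(
    long[, c("respondent_id", "task_id", "alt_id", "opt_out", "chosen")],
    tibble::as_tibble(X))
  grp <- survey$respondents[, c("respondent_id", "group")]
  out <- dplyr::left_join(out, grp, by = "respondent_id")
  out <- out[, c("respondent_id", "group", "task_id", "alt_id", "opt_out",
                 "chosen", terms)]
  attr(out, "x_cols") <- terms
  out
}

long_x_cols <- function(data) {
  attr(data, "x_cols") %||%
    setdiff(names(data), c("respondent_id", "group", "task_id", "alt_id",
                           "opt_out", "chosen"))
}

## canonical ordering + index vectors shared by the likelihoods
long_index <- function(data) {
  data <- data[order(data$respondent_id, data$task_id, data$alt_id), ]
  x_cols <- long_x_cols(data)
  task <- match(data$task_id, unique(data$task_id))
  chosen_per_task <- tapply(data$chosen, task, sum)
  if (any(chosen_per_task != 1)) {
    stop("every task must have exactly one chosen row", call. = FALSE)
  }
  list(data = data,
       X = as.matrix(data[, x_cols, drop = FALSE]),
       opt_out = data$opt_out,
       task = task,
       resp = match(data$respondent_id, unique(data$respondent_id)),
       chosen = which(data$chosen == 1))
}

#' Conditional-logit log-likelihood
#'
#' The fixed-coefficient multinomial logit log-likelihood of long-format
#' choice data: the sum over tasks of the log softmax probability of the
#' chosen alternative, with utilities \eqn{V = X\beta + \alpha\,\mathrm{optout}}.
#'
#' @param par Numeric vector: the K design-term coefficients followed by
#'   the opt-out constant (length K + 1).
#' @param data Long-format data from [build_long_format()].
#' @return The log-likelihood, with the analytic score as attribute
#'   `"gradient"`.
#' @export
conditional_logit_loglik <- function(par, data) {
  idx <- if (is.list(data) && !is.data.frame(data) && !is.null(data$task)) data
         else long_index(data)
  K <- ncol(idx$X)
  if (length(par) != K + 1) {
    stop("par must have length ", K + 1, " (", K, " betas + opt-out constant)",
         call. = FALSE)
  }
  if (any(!is.finite(par))) stop("non-finite parameters", call. = FALSE)
  V <- as.vector(idx$X %*% par[seq_len(K)]) + par[K + 1] * idx$opt_out
  V <- V - ave(V, idx$task, FUN = max)
  e <- exp(V)
  p <- e / ave(e, idx$task, FUN = sum)
  ll <- sum(log(p[idx$chosen]))
  resid <- -p
  resid[idx$chosen] <- resid[idx$chosen] + 1
  grad <- c(as.vector(crossprod(idx$X, resid)), sum(resid * idx$opt_out))
  attr(ll, "gradient") <- grad
  ll
}

clogit_hessian <- function(par, idx) {
  K <- ncol(idx$X)
  V <- as.vector(idx$X %*% par[seq_len(K)]) + par[K + 1] * idx$opt_out
  V <- V - ave(V, idx$task, FUN = max)
  e <- exp(V)
  p <- e / ave(e, idx$task, FUN = sum)
  Xa <- cbind(idx$X, opt_out = idx$opt_out)
  xbar <- rowsum(p * Xa, idx$task)[idx$task, , drop = FALSE]
  Xc <- Xa - xbar
  -crossprod(Xc, p * Xc)
}

#' Fit a conditional (multinomial) logit model
#'
#' Maximizes [conditional_logit_loglik()] by BFGS with its analytic
#' gradient; standard errors come from the inverse observed information
#' (negative analytic Hessian) at the optimum. The fit is deterministic
#' given the data.
#'
#' @param data Long-format data from [build_long_format()].
#' @param start Optional starting values (zeros by default).
#' @param schema Schema used to label coefficients in [tidy()] output.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param maxit Iteration cap.
#' @return A `dce_clogit` fit: coefficients (named, `opt_out` last),
#'   standard errors, vcov, log-likelihood, AIC/BIC, data sizes and a
#'   convergence flag.
#' @export
fit_conditional_logit <- function(data, start = NULL,
                                  schema = orphan_drug_schema(),
                                  reltol = 1e-10, maxit = 500) {
  idx <- long_index(data)
  K <- ncol(idx$X)
  par0 <- start %||% rep(0, K + 1)
  fn <- function(p) -as.numeric(conditional_logit_loglik(p, idx))
  gr <- function(p) -attr(conditional_logit_loglik(p, idx), "gradient")
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  par <- opt$par
  names(par) <- c(colnames(idx$X), "opt_out")
  H <- clogit_hessian(par, idx)
  vc <- tryCatch(solve(-H), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(par)) else sqrt(diag(vc))
  names(se) <- names(par)
  ll <- -opt$value
  n_obs <- nrow(idx$data)
  k <- length(par)
  ic <- information_criteria(ll, k, n_obs)
  structure(list(
    coefficients = par, std.error = se, vcov = vc,
    log_likelihood = ll, k = k, n_obs = n_obs,
    n_respondents = length(unique(idx$data$respondent_id)),
    aic = ic$aic, bic = ic$bic,
    converged = opt$convergence == 0, iterations = opt$counts[["function"]],
    schema = schema
  ), class = c("dce_clogit", "dce_fit"))
}

#' Akaike and Bayesian information criteria
#'
#' `aic = 2k - 2 ll`; `bic = k log(n_obs) - 2 ll`, with `n_obs` the number
#' of long-format rows entering the likelihood (alternatives x scored
#' tasks x respondents).
#'
#' @param log_likelihood Fitted log-likelihood.
#' @param k Number of estimated parameters.
#' @param n_obs Number of observations for the BIC sample-size term.
#' @return A tibble with columns `aic` and `bic`.
#' @export
information_criteria <- function(log_likelihood, k, n_obs = 1L) {
  if (k < 0 || n_obs < 1) stop("k must be >= 0 and n_obs >= 1", call. = FALSE)
  tibble::tibble(aic = 2 * k - 2 * log_likelihood,
                 bic = k * log(n_obs) - 2 * log_likelihood)
}

#' @export
print.dce_fit <- function(x, ...) {
  cat("<", class(x)[1], "> ll = ", formatC(x$log_likelihood, format = "f", digits = 3),
      ", k = ", x$k, ", AIC = ", formatC(x$aic, format = "f", digits = 2),
      ", BIC = ", formatC(x$bic, format = "f", digits = 2),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Write long-format data or read it back
#'
#' Column layout: `respondent_id`, `task_id`, `alt_id`, `chosen`,
#' `opt_out`, then the design terms (written as `x1..x12` plus `cost_10k`
#' for the default schema), plus `group`.
#'
#' @param data Long-format tibble.
#' @param path CSV path.
#' @param schema A [dce_schema()].
#' @return `path` invisibly / the long-format tibble.
#' @export
write_long_csv <- function(data, path, schema = orphan_drug_schema()) {
  x_cols <- long_x_cols(data)
  out <- data
  dummies <- x_cols[x_cols != "cost"]
  names(out)[match(dummies, names(out))] <- paste0("x", seq_along(dummies))
  if ("cost" %in% x_cols) names(out)[match("cost", names(out))] <- "cost_10k"
  readr::write_csv(out, path)
  invisible(path)
}
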