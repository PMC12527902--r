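#' Preference population for survey simulation
#'
#' Describes the mixed-logit data-generating process a simulated panel of
#' respondents follows: normally distributed individual part-worth vectors
#' with the given means and standard deviations, an alternative-specific
#' constant on the opt-out, a fraction of careless respondents, completion
#' time behaviour, and SMART scoring noise.
#'
#' Defaults emulate the published decision-maker panel: part-worth means
#' are the pooled [reference_estimates()] column, between-respondent
#' standard deviations are half the absolute means, completion times are
#' lognormal with median 12 minutes for attentive respondents (truncated at
#' the 8-minute validity threshold) and median 5 minutes for careless ones
#' (truncated below it), and 15/84 of respondents are careless.
#'
#' @param mean_coefficients Named numeric vector of length [schema_k()]
#'   (part-worth means, design-term order).
#' @param sd_coefficients Non-negative vector of the same length
#'   (between-respondent standard deviations).
#' @param asc_opt_out Constant added to the opt-out alternative's utility.
#' @param asc_on `"opt_out"` (the constant enters the opt-out utility, the
#'   default) or `"drugs"` (it enters both drug alternatives instead; the
#'   two conventions differ only in sign of the implied contrast).
#' @param careless_fraction Proportion of respondents answering uniformly
#'   at random with sub-threshold completion times.
#' @param lapse Probability that an attentive respondent answers the
#'   repeated consistency task fresh instead of repeating their original
#'   choice.
#' @param time_meanlog,time_sdlog,careless_time_meanlog Lognormal
#'   completion-time parameters (minutes); attentive times are truncated to
#'   `>= time_threshold`, careless times to `< time_threshold`.
#' @param time_threshold The validity time threshold the truncation uses.
#' @param smart_noise_sd SD of the Gaussian noise added to SMART scores
#'   (0-100 scale).
#' @param he_fraction Probability a respondent is labelled a
#'   health-economics (rather than medical-insurance) expert.
#' @return A `dce_population` list.
#' @export
preference_population <- function(
    mean_coefficients = NULL,
    sd_coefficients = NULL,
    asc_opt_out = 2.454,
    asc_on = c("opt_out", "drugs"),
    careless_fraction = 15 / 84,
    lapse = 0,
    time_meanlog = log(12), time_sdlog = 0.3,
    careless_time_meanlog = log(5),
    time_threshold = 8,
    smart_noise_sd = 10,
    he_fraction = 37 / 69) {
  asc_on <- match.arg(asc_on)
  if (is.null(mean_coefficients)) {
    ref <- reference_estimates("all")
    mean_coefficients <- stats::setNames(
      ref$estimate[ref$term != "opt_out"], ref$term[ref$term != "opt_out"])
  }
  if (is.null(sd_coefficients)) {
    sd_coefficients <- 0.5 * abs(mean_coefficients)
  }
  if (length(sd_coefficients) != length(mean_coefficients)) {
    stop("mean and sd coefficient vectors must have equal length", call. = FALSE)
  }
  if (any(sd_coefficients < 0)) {
    stop("sd_coefficients must be non-negative", call. = FALSE)
  }
  if (careless_fraction < 0 || careless_fraction > 1) {
    stop("careless_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(mean_coefficients = mean_coefficients,
                 sd_coefficients = sd_coefficients,
                 asc_opt_out = asc_opt_out, asc_on = asc_on,
                 careless_fraction = careless_fraction, lapse = lapse,
                 time_meanlog = time_meanlog, time_sdlog = time_sdlog,
                 careless_time_meanlog = careless_time_meanlog,
                 time_threshold = time_threshold,
                 smart_noise_sd = smart_noise_sd,
                 he_fraction = he_fraction),
            class = "dce_population")
}

#' Draw individual part-worth vectors from a population
#'
#' Each coordinate is drawn independently from
#' Normal(mean_k, sd_k); the same seed reproduces the same draws.
#'
#' @param pop A [preference_population()].
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @return An `n` x K matrix with design-term column names.
#' @export
draw_individual_coefficients <- function(pop, n, seed = 1L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  set.seed(seed)
  K <- length(pop$mean_coefficients)
  z <- matrix(stats::rnorm(n * K), n, K)
  b <- sweep(sweep(z, 2, pop$sd_coefficients, `*`), 2,
             pop$mean_coefficients, `+`)
  colnames(b) <- names(pop$mean_coefficients)
  b
}

#' Choice probabilities for one task under a coefficient vector
#'
#' Multinomial-logit probabilities for (alternative 1, alternative 2,
#' opt-out): the softmax of the deterministic utilities
#' \eqn{V_1 = \beta^\top x_1}, \eqn{V_2 = \beta^\top x_2} and the opt-out
#' constant, as implied by i.i.d. Gumbel utility errors.
#'
#' @param task Two profile rows (a tibble with attribute ordinal columns,
#'   alternatives in rows), e.g. a single set from a design.
#' @param coefficients Numeric part-worth vector of length [schema_k()].
#' @param asc_opt_out The opt-out alternative-specific constant.
#' @param schema A [dce_schema()].
#' @param asc_on See [preference_population()].
#' @return Named numeric vector `c(alt1 = , alt2 = , opt_out = )`, summing
#'   to 1.
#' @export
choice_probabilities <- function(task, coefficients, asc_opt_out, schema,
                                 asc_on = c("opt_out", "drugs")) {
  asc_on <- match.arg(asc_on)
  attrs <- schema_attributes(schema)
  X <- encode_profiles(task[, attrs, drop = FALSE], schema)
  if (nrow(X) != 2) stop("task must contain exactly two alternatives", call. = FALSE)
  V <- c(as.vector(X %*% coefficients), 0)
  if (asc_on == "opt_out") V[3] <- V[3] + asc_opt_out else V[1:2] <- V[1:2] + asc_opt_out
  V <- V - max(V)
  p <- exp(V) / sum(exp(V))
  stats::setNames(p, c("alt1", "alt2", "opt_out"))
}

## deterministic truncated-lognormal sampler (resampling)
rlnorm_trunc <- function(n, meanlog, sdlog, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rlnorm(length(todo), meanlog, sdlog)
    ok <- draw >= lower & draw < upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a survey panel
#'
#' Generates respondent choice records, completion times, SMART rankings
#' and scores, and demographic labels from a mixed-logit data-generating
#' process over the supplied questionnaires.
#'
#' Respondents are assigned to questionnaire blocks round-robin. Attentive
#' respondents draw an individual part-worth vector from `pop` and sample
#' each choice from [choice_probabilities()]; the repeated consistency task
#' is answered identically to its original with probability `1 - lapse`.
#' Careless respondents (a `careless_fraction` share, rounded to a whole
#' count) choose uniformly at random and report completion times below the
#' validity threshold, so they fail screening by construction. SMART scores
#' are each respondent's own part-worth ranges rescaled so the largest is
#' 100, plus Gaussian noise clipped to \[0, 100\]; ranks are the descending
#' order of scores.
#'
#' @param questionnaires List of `dce_questionnaire` objects (see
#'   [build_questionnaires()]).
#' @param design The [dce_design] the questionnaires reference.
#' @param pop A [preference_population()].
#' @param n_respondents Number of respondents.
#' @param seed Integer seed; regeneration under the same seed and
#'   parameters is bit-identical.
#' @param schema A [dce_schema()].
#' @return A `dce_survey` list: `choices` (respondent_id, block_id,
#'   position, set_id, is_repeat, choice with 1/2 = drug alternatives and
#'   3 = opt-out), `respondents` (id, block, group, completion_minutes,
#'   careless flag recording the simulation's ground truth), `smart`
#'   (respondent_id, attribute, score, rank), plus the questionnaires,
#'   design sets, population and seed for provenance.
#' @export
simulate_responses <- function(questionnaires, design, pop, n_respondents,
                               seed = 1L, schema = orphan_drug_schema()) {
  if (length(questionnaires) == 0) stop("no questionnaires supplied", call. = FALSE)
  if (n_respondents < 1) stop("n_respondents must be at least 1", call. = FALSE)
  set.seed(seed)
  attrs <- schema_attributes(schema)
  n_blocks <- length(questionnaires)
  block_of <- rep(seq_len(n_blocks), length.out = n_respondents)
  n_careless <- round(pop$careless_fraction * n_respondents)
  careless <- rep(FALSE, n_respondents)
  if (n_careless > 0) careless[sample.int(n_respondents, n_careless)] <- TRUE
  betas <- draw_individual_coefficients(pop, n_respondents,
                                        seed = sample.int(.Machine$integer.max, 1))
  groups <- ifelse(stats::runif(n_respondents) < pop$he_fraction,
                   "health_economics", "medical_insurance")
  times <- numeric(n_respondents)
  att <- !careless
  times[att] <- rlnorm_trunc(sum(att), pop$time_meanlog, pop$time_sdlog,
                             lower = pop$time_threshold)
  times[careless] <- rlnorm_trunc(sum(careless), pop$careless_time_meanlog,
                                  pop$time_sdlog, upper = pop$time_threshold)

  ## choices are sampled block by block, vectorized across the block's
  ## respondents: utilities come from one matrix product per block and the
  ## categorical draw from one uniform per respondent-task
  sets <- design$sets
  X_sets <- encode_profiles(sets[, attrs, drop = FALSE], schema)
  key <- paste(sets$set_id, sets$alt)
  binfo <- lapply(questionnaires, function(q) {
    list(tasks = q$tasks,
         X1 = X_sets[match(paste(q$tasks$set_id, 1), key), , drop = FALSE],
         X2 = X_sets[match(paste(q$tasks$set_id, 2), key), , drop = FALSE],
         orig = q$consistency_pair[["original"]])
  })
  choices <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    if (length(idx) == 0) next
    nb <- length(idx)
    n_task <- nrow(binfo[[b]]$tasks)
    car <- careless[idx]
    V1 <- betas[idx, , drop = FALSE] %*% t(binfo[[b]]$X1)
    V2 <- betas[idx, , drop = FALSE] %*% t(binfo[[b]]$X2)
    ch <- matrix(0L, nb, n_task)
    for (t in seq_len(n_task)) {
      v1 <- V1[, t]; v2 <- V2[, t]; v3 <- rep(0, nb)
      if (pop$asc_on == "opt_out") v3 <- v3 + pop$asc_opt_out
      else { v1 <- v1 + pop$asc_opt_out; v2 <- v2 + pop$asc_opt_out }
      m <- pmax(v1, v2, v3)
      e1 <- exp(v1 - m); e2 <- exp(v2 - m); e3 <- exp(v3 - m)
      den <- e1 + e2 + e3
      u <- stats::runif(nb)
      fresh <- 1L + (u >= e1 / den) + (u >= (e1 + e2) / den)
      if (any(car)) fresh[car] <- sample.int(3L, sum(car), replace = TRUE)
      if (binfo[[b]]$tasks$is_repeat[t]) {
        keep <- !car & stats::runif(nb) >= pop$lapse
        fresh[keep] <- ch[keep, binfo[[b]]$orig]
      }
      ch[, t] <- fresh
    }
    choices[[b]] <- tibble::tibble(
      respondent_id = rep(idx, each = n_task),
      block_id = questionnaires[[b]]$block_id,
      position = rep(binfo[[b]]$tasks$position, nb),
      set_id = rep(binfo[[b]]$tasks$set_id, nb),
      is_repeat = rep(binfo[[b]]$tasks$is_repeat, nb),
      choice = as.integer(t(ch)))
  }
  choices <- dplyr::arrange(dplyr::bind_rows(choices),
                            .data$respondent_id, .data$position)

  ## SMART: scores from each respondent's own part-worth ranges
  rg <- part_worth_range_matrix(betas, schema)
  rmax <- do.call(pmax, as.data.frame(rg))
  score <- 100 * rg / ifelse(rmax > 0, rmax, 1)
  if (pop$smart_noise_sd > 0) {
    score <- score + matrix(stats::rnorm(length(score), 0, pop$smart_noise_sd),
                            nrow(score), ncol(score))
  }
  score <- pmin(pmax(score, 0), 100)
  if (any(careless)) {
    score[careless, ] <- matrix(stats::runif(sum(careless) * length(attrs),
                                             0, 100),
                                sum(careless), length(attrs))
  }
  ranks <- t(apply(-score, 1, rank, ties.method = "first"))
  smart <- tibble::tibble(
    respondent_id = rep(seq_len(n_respondents), each = length(attrs)),
    attribute = rep(attrs, n_respondents),
    score = as.numeric(t(score)),
    rank = as.integer(t(ranks)))

  structure(list(
    choices = choices,
    respondents = tibble::tibble(
      respondent_id = seq_len(n_respondents), block_id = block_of,
      group = groups, completion_minutes = times, careless = careless),
    smart = smart,
    questionnaires = questionnaires,
    design_sets = design$sets,
    population = pop, seed = seed, schema = schema
  ), class = "dce_survey")
}

#' @export
print.dce_survey <- function(x, ...) {
  cat("<dce_survey> ", nrow(x$respondents), " respondents, ",
      nrow(x$choices), " recorded choices",
      if (!is.null(attr(x, "filtered"))) " (validity-filtered)", "\n", sep = "")
  invisible(x)
}

#' Part-worth ranges of a coefficient vector
#'
#' The utility range each attribute spans: for a categorical attribute the
#' max minus min over the reference (0) and its level coefficients; for a
#' continuous attribute the absolute coefficient times the span of its
#' level values (42, in 10,000 RMB, for the default cost attribute).
#'
#' @param coefficients Named vector of design-term coefficients (length
#'   [schema_k()]).
#' @param schema A [dce_schema()].
#' @return Named numeric vector, one range per attribute.
#' @export
part_worth_ranges <- function(coefficients, schema) {
  terms <- schema_terms(schema)
  attrs <- schema_attributes(schema)
  parts <- schema_split(schema)
  vapply(attrs, function(a) {
    tm <- terms$term[terms$attribute == a]
    if (parts[[a]]$kind[1] == "continuous") {
      span <- diff(range(parts[[a]]$numeric_value))
      abs(coefficients[[tm]]) * span
    } else {
      v <- c(0, unname(coefficients[tm]))
      max(v) - min(v)
    }
  }, numeric(1))
}

## row-wise part_worth_ranges for a matrix of coefficient vectors
part_worth_range_matrix <- function(betas, schema) {
  terms <- schema_terms(schema)
  attrs <- schema_attributes(schema)
  parts <- schema_split(schema)
  out <- matrix(0, nrow(betas), length(attrs),
                dimnames = list(NULL, attrs))
  for (a in attrs) {
    tm <- terms$term[terms$attribute == a]
    if (parts[[a]]$kind[1] == "continuous") {
      span <- diff(range(parts[[a]]$numeric_value))
      out[, a] <- abs(betas[, tm]) * span
    } else {
      cols <- cbind(0, betas[, tm, drop = FALSE])
      out[, a] <- apply(cols, 1, max) - apply(cols, 1, min)
    }
  }
  out
}
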