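## coerce fits / tidy frames to a coefficient table (attribute, level, term,
## estimate) covering the design terms
coef_table <- function(x, schema) {
  if (inherits(x, "dce_fit")) {
    terms <- schema_terms(schema)
    est <- x$coefficients[terms$term]
    return(tibble::tibble(attribute = terms$attribute, level = terms$level,
                          term = terms$term, estimate = unname(est)))
  }
  x <- tibble::as_tibble(x)
  terms <- schema_terms(schema)
  if (!"term" %in% names(x)) {
    x <- dplyr::left_join(x, terms[, c("attribute", "level", "term")],
                          by = c("attribute", "level"))
  }
  x <- x[x$term %in% terms$term, c("attribute", "level", "term", "estimate")]
  missing <- setdiff(terms$term, x$term)
  if (length(missing) > 0) {
    stop("coefficients missing for terms: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[match(terms$term, x$term), ]
}

#' Relative importance of attributes from part-worth utilities
#'
#' Each attribute's share of the total utility range:
#' \deqn{RI_a = \frac{\beta_a^{max} - \beta_a^{min}}{\sum_c (\beta_c^{max} - \beta_c^{min})}.}
#' For a categorical attribute the range is taken over the reference level
#' (coefficient 0) and its level coefficients, so an attribute whose best
#' level is not its highest-coded one still contributes its full span. For
#' a continuous attribute the range is the absolute coefficient times the
#' span of its level values (42, in 10,000 RMB per year, for the default
#' cost attribute) — the utility difference between its extreme levels.
#'
#' @param x A `dce_fit`, or a coefficient table: a data frame with columns
#'   `attribute`, `level`, `estimate` (or `term`, `estimate`), e.g. a
#'   filtered [reference_estimates()].
#' @param schema A [dce_schema()].
#' @return A `dce_ri` tibble: `attribute`, `attribute_label`, `range`,
#'   `weight` (proportions summing to 1), `pct`, `rank`.
#' @examples
#' ref <- dplyr::filter(reference_estimates("all"), term != "opt_out")
#' relative_importance(ref, orphan_drug_schema())
#' @export
relative_importance <- function(x, schema = orphan_drug_schema()) {
  ct <- coef_table(x, schema)
  est <- stats::setNames(ct$estimate, ct$term)
  rng <- part_worth_ranges(est, schema)
  attrs <- schema_attributes(schema)
  labels <- vapply(schema_split(schema)[attrs],
                   function(a) a$attribute_label[1], character(1))
  w <- rng / sum(rng)
  out <- tibble::tibble(attribute = attrs, attribute_label = unname(labels),
                        range = unname(rng), weight = unname(w),
                        pct = 100 * unname(w),
                        rank = as.integer(rank(-w, ties.method = "min")))
  class(out) <- c("dce_ri", class(out))
  out
}

#' Willingness to pay for attribute levels
#'
#' The monetary value of moving an attribute from its reference level,
#' \eqn{WTP = -\beta_{level} / \beta_{cost}}, expressed in the cost
#' attribute's coding units (10,000 RMB per year for the default schema).
#' One entry is produced per non-reference categorical level; reference
#' levels have WTP 0 by convention and are omitted. When a coefficient
#' covariance matrix is available (from a fit), a delta-method standard
#' error is attached.
#'
#' @inheritParams relative_importance
#' @param vcov Optional coefficient covariance matrix with rows/columns
#'   named by design terms (taken from `x` when it is a fit).
#' @param tol Smallest usable `|cost coefficient|`.
#' @return A `dce_wtp` tibble: `attribute`, `attribute_label`, `level`,
#'   `estimate`, `wtp`, `std.error` (`NA` without a covariance).
#' @export
wtp_table <- function(x, schema = orphan_drug_schema(), vcov = NULL,
                      tol = 1e-8) {
  ct <- coef_table(x, schema)
  if (inherits(x, "dce_fit") && is.null(vcov)) {
    vcov <- x$vcov
    if (!is.null(vcov)) {
      dimnames(vcov) <- list(names(x$all_coefficients %||% x$coefficients),
                             names(x$all_coefficients %||% x$coefficients))
    }
  }
  terms <- schema_terms(schema)
  cont <- terms$term[terms$kind == "continuous"]
  if (length(cont) != 1) {
    stop("WTP needs exactly one continuous (cost) attribute", call. = FALSE)
  }
  b_cost <- ct$estimate[ct$term == cont]
  if (abs(b_cost) < tol) {
    stop("cost coefficient is numerically zero; WTP undefined", call. = FALSE)
  }
  lev <- ct[ct$term != cont, ]
  wtp <- -lev$estimate / b_cost
  se <- rep(NA_real_, nrow(lev))
  if (!is.null(vcov) && all(c(lev$term, cont) %in% rownames(vcov))) {
    for (i in seq_len(nrow(lev))) {
      g <- c(-1 / b_cost, lev$estimate[i] / b_cost^2)  # d wtp / d(beta, beta_cost)
      V <- vcov[c(lev$term[i], cont), c(lev$term[i], cont)]
      se[i] <- sqrt(as.numeric(t(g) %*% V %*% g))
    }
  }
  labels <- schema_terms(schema)
  out <- tibble::tibble(
    attribute = lev$attribute,
    attribute_label = labels$attribute_label[match(lev$term, labels$term)],
    level = lev$level, estimate = lev$estimate, wtp = wtp, std.error = se)
  class(out) <- c("dce_wtp", class(out))
  out
}

#' SMART direct weights from respondent rankings and scores
#'
#' Normalizes each respondent's 0-100 importance scores to individual
#' weights (score over score total), then averages across respondents.
#' Respondents with an all-zero score vector cannot be normalized and are
#' excluded from score averaging (with a message). The mean rank per
#' attribute is reported alongside, and overall orderings are derived both
#' from mean weights and from mean ranks, since the two need not agree.
#'
#' @param x A `dce_survey`, or a long SMART tibble with columns
#'   `respondent_id`, `attribute`, `score`, `rank`.
#' @return A `dce_smart` tibble: `attribute`, `mean_weight`, `mean_rank`,
#'   `rank_by_weight`, `rank_by_mean_rank`. Mean weights sum to 1.
#' @export
smart_weights <- function(x) {
  sm <- if (inherits(x, "dce_survey")) x$smart else tibble::as_tibble(x)
  if (nrow(sm) == 0) stop("no SMART responses", call. = FALSE)
  totals <- tapply(sm$score, sm$respondent_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    message("excluding ", length(zero),
            " respondent(s) with all-zero SMART scores from score averaging")
  }
  sc <- sm[!sm$respondent_id %in% zero, ]
  sc$weight <- sc$score / ave(sc$score, sc$respondent_id, FUN = sum)
  mean_w <- tapply(sc$weight, sc$attribute, mean)
  mean_r <- tapply(sm$rank, sm$attribute, mean)
  attrs <- unique(sm$attribute)
  out <- tibble::tibble(
    attribute = attrs,
    mean_weight = as.numeric(mean_w[attrs]),
    mean_rank = as.numeric(mean_r[attrs]),
    rank_by_weight = as.integer(rank(-mean_w[attrs], ties.method = "min")),
    rank_by_mean_rank = as.integer(rank(mean_r[attrs], ties.method = "min")))
  class(out) <- c("dce_smart", class(out))
  out
}

#' Concordance between choice-model and SMART weight orderings
#'
#' Spearman and Kendall rank correlations plus top-3 overlap between the
#' attribute ordering implied by relative-importance weights and the SMART
#' ordering, computed against both SMART bases (mean score weight and mean
#' rank).
#'
#' @param ri A [relative_importance()] result.
#' @param smart A [smart_weights()] result on the same attribute set.
#' @return A tibble with one row per SMART basis: `smart_basis`,
#'   `spearman`, `kendall`, `top3_overlap`.
#' @export
compare_weighting_methods <- function(ri, smart) {
  if (!setequal(ri$attribute, smart$attribute)) {
    stop("relative-importance and SMART results cover different attributes",
         call. = FALSE)
  }
  sm <- smart[match(ri$attribute, smart$attribute), ]
  one <- function(sm_rank, basis) {
    tibble::tibble(
      smart_basis = basis,
      spearman = stats::cor(ri$rank, sm_rank, method = "spearman"),
      kendall = stats::cor(ri$rank, sm_rank, method = "kendall"),
      top3_overlap = length(intersect(ri$attribute[ri$rank <= 3],
                                      sm$attribute[sm_rank <= 3])))
  }
  dplyr::bind_rows(one(sm$rank_by_weight, "score"),
                   one(sm$rank_by_mean_rank, "rank"))
}

#' Write a weight report as CSV
#' @param x A `dce_ri`, `dce_wtp` or `dce_smart` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
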