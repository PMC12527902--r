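test_that("relative importance reproduces all three published weight columns", {
  sch <- orphan_drug_schema()
  published <- list(
    all = c(hrqol = 23.44, severity = 18.65, cost = 17.34, safety = 13.10,
            efficacy = 11.92, evidence = 10.94, unmet_needs = 4.61),
    health_economics = c(hrqol = 23.26, severity = 22.57, cost = 16.27,
                         safety = 6.86, efficacy = 13.71, evidence = 6.18,
                         unmet_needs = 11.16),
    medical_insurance = c(hrqol = 20.12, severity = 11.81, cost = 18.27,
                          safety = 19.48, efficacy = 8.72, evidence = 13.18,
                          unmet_needs = 8.41))
  for (g in names(published)) {
    ri <- relative_importance(ref_coefs(g), sch)
    got <- stats::setNames(ri$pct, ri$attribute)
    expect_true(all(abs(got[names(published[[g]])] - published[[g]]) <= 0.15),
                label = paste("RI reproduction for group", g))
    expect_equal(sum(ri$weight), 1, tolerance = 1e-9)
  }
})

test_that("relative importance is scale invariant and handles edge schemas", {
  sch <- orphan_drug_schema()
  base <- ref_coefs("all")
  doubled <- base
  doubled$estimate <- 2 * doubled$estimate
  expect_equal(relative_importance(base, sch)$weight,
               relative_importance(doubled, sch)$weight, tolerance = 1e-12)

  # an attribute whose best level is its reference still contributes its span
  toyc <- tibble::tibble(attribute = c("eff", "eff", "price"),
                         level = c("some", "full", NA),
                         estimate = c(-0.5, -1.2, -0.1))
  ri_toy <- relative_importance(toyc, toy_schema())
  # eff range = 0 - (-1.2); price range = 0.1 * (10 - 1)
  expect_equal(ri_toy$range[ri_toy$attribute == "eff"], 1.2)
  expect_equal(ri_toy$range[ri_toy$attribute == "price"], 0.9)

  # single-attribute schema: weight 1
  one <- dce_schema(tibble::tibble(
    attribute = "a", kind = "categorical", level = c("l0", "l1", "l2"),
    ordinal = 0:2))
  ri1 <- relative_importance(
    tibble::tibble(attribute = "a", level = c("l1", "l2"),
                   estimate = c(0.3, 0.9)), one)
  expect_equal(ri1$weight, 1)

  expect_error(relative_importance(base[-1, ], sch), "missing")
})

test_that("WTP matches the published table within coefficient-rounding error", {
  sch <- orphan_drug_schema()
  published_wtp <- list(
    all = c(severity1 = 38.89, severity2 = 45.19, unmet_needs1 = -1.87,
            unmet_needs2 = 9.30, efficacy1 = 13.68, efficacy2 = 28.87,
            hrqol1 = 41.49, hrqol2 = 56.79, safety1 = 26.73,
            safety2 = 31.72, evidence1 = 26.50, evidence2 = 17.42),
    health_economics = c(severity1 = 44.12, severity2 = 58.26,
                         unmet_needs1 = 9.22, unmet_needs2 = 28.80,
                         efficacy1 = 13.35, efficacy2 = 35.38,
                         hrqol1 = 35.45, hrqol2 = 60.03, safety1 = 17.70,
                         safety2 = 15.20, evidence1 = 13.62,
                         evidence2 = 15.94))
  terms <- schema_terms(sch)
  cost_printed <- c(all = 0.039, health_economics = 0.067)
  for (g in names(published_wtp)) {
    w <- wtp_table(ref_coefs(g), sch)
    w$term <- terms$term[match(paste(w$attribute, w$level),
                               paste(terms$attribute, terms$level))]
    got <- stats::setNames(w$wtp, w$term)
    pub <- published_wtp[[g]]
    # worst-case propagation of the 3-decimal rounding of both printed
    # coefficients through the ratio -b/c
    tol <- (5e-4 + abs(pub) * 5e-4) / (cost_printed[[g]] - 5e-4)
    expect_true(all(abs(got[names(pub)] - pub) <= tol),
                label = paste("WTP reproduction for group", g))
  }
})

test_that("WTP edge cases: zero numerator, zero cost, currency-unit rescaling", {
  sch <- orphan_drug_schema()
  base <- ref_coefs("all")
  z <- base
  z$estimate[z$term == "severity1"] <- 0
  w <- wtp_table(z, sch)
  expect_equal(w$wtp[w$attribute == "severity" &
                       grepl("Moderate", w$level)], 0)

  bad <- base
  bad$estimate[bad$term == "cost"] <- 0
  expect_error(wtp_table(bad, sch), "cost coefficient")

  # recoding cost levels in RMB (x 1e4) with the correspondingly rescaled
  # coefficient multiplies WTP by exactly 1e4
  sch_rmb <- orphan_drug_schema()
  sch_rmb$numeric_value[sch_rmb$attribute == "cost"] <-
    sch_rmb$numeric_value[sch_rmb$attribute == "cost"] * 1e4
  resc <- base
  resc$estimate[resc$term == "cost"] <- resc$estimate[resc$term == "cost"] / 1e4
  w1 <- wtp_table(base, sch)
  w2 <- wtp_table(resc, sch_rmb)
  expect_equal(w2$wtp, w1$wtp * 1e4, tolerance = 1e-9)
})

test_that("SMART weights normalize per respondent and average as published", {
  # every respondent scores proportional to the published average column
  scores <- c(severity = 15.18, unmet_needs = 13.29, efficacy = 16.22,
              hrqol = 15.94, safety = 13.79, evidence = 12.40,
              cost = 13.18)
  sm <- purrr::map_dfr(1:10, function(i) {
    tibble::tibble(respondent_id = i, attribute = names(scores),
                   score = unname(scores) * i,  # scale varies, weights don't
                   rank = as.integer(rank(-scores, ties.method = "first")))
  })
  w <- smart_weights(sm)
  expect_equal(stats::setNames(w$mean_weight, w$attribute)[names(scores)],
               scores / 100, tolerance = 1e-9)
  expect_equal(sum(w$mean_weight), 1, tolerance = 1e-12)

  # single respondent with a degenerate score vector
  one <- tibble::tibble(respondent_id = 1, attribute = names(scores),
                        score = c(100, rep(0, 6)),
                        rank = 1:7)
  w1 <- smart_weights(one)
  expect_equal(sort(w1$mean_weight, decreasing = TRUE),
               c(1, rep(0, 6)))

  # all-zero respondents are excluded from score averaging
  zero <- tibble::tibble(respondent_id = 2, attribute = names(scores),
                         score = 0, rank = 1:7)
  expect_message(w2 <- smart_weights(dplyr::bind_rows(one, zero)),
                 "all-zero")
  expect_equal(w2$mean_weight, w1$mean_weight)
})

test_that("mean ranks on a 3-respondent fixture match hand-computed averages", {
  attrs <- c("a", "b", "c")
  sm <- dplyr::bind_rows(
    tibble::tibble(respondent_id = 1, attribute = attrs,
                   score = c(90, 50, 10), rank = c(1L, 2L, 3L)),
    tibble::tibble(respondent_id = 2, attribute = attrs,
                   score = c(40, 80, 20), rank = c(2L, 1L, 3L)),
    tibble::tibble(respondent_id = 3, attribute = attrs,
                   score = c(70, 30, 50), rank = c(1L, 3L, 2L)))
  w <- smart_weights(sm)
  expect_equal(stats::setNames(w$mean_rank, w$attribute),
               c(a = (1 + 2 + 1) / 3, b = (2 + 1 + 3) / 3,
                 c = (3 + 3 + 2) / 3))
  expect_equal(w$rank_by_mean_rank[w$attribute == "a"], 1L)
})

test_that("method concordance captures agreement, reversal and top-3 overlap", {
  ri <- relative_importance(ref_coefs("all"), orphan_drug_schema())

  # identical rankings -> Spearman 1
  sm_same <- tibble::tibble(
    attribute = ri$attribute, mean_weight = ri$weight,
    mean_rank = as.numeric(ri$rank), rank_by_weight = ri$rank,
    rank_by_mean_rank = ri$rank)
  class(sm_same) <- c("dce_smart", class(sm_same))
  cc <- compare_weighting_methods(ri, sm_same)
  expect_equal(cc$spearman, c(1, 1))
  expect_equal(cc$top3_overlap, c(3L, 3L))

  # exact reversal -> Spearman -1
  sm_rev <- sm_same
  sm_rev$rank_by_weight <- 8L - ri$rank
  sm_rev$rank_by_mean_rank <- 8L - ri$rank
  cc_rev <- compare_weighting_methods(ri, sm_rev)
  expect_equal(cc_rev$spearman, c(-1, -1))

  # DCE top-3 (hrqol, severity, cost) vs SMART top-3 (efficacy, hrqol,
  # severity): overlap 2
  smart_order <- c("efficacy", "hrqol", "severity", "cost", "safety",
                   "evidence", "unmet_needs")
  sm_fix <- sm_same
  sm_fix$rank_by_weight <- match(sm_fix$attribute, smart_order)
  cc_fix <- compare_weighting_methods(ri, sm_fix)
  expect_equal(cc_fix$top3_overlap[cc_fix$smart_basis == "score"], 2L)

  sm_bad <- sm_same[-1, ]
  expect_error(compare_weighting_methods(ri, sm_bad), "different attributes")
})

test_that("weight derivations accept fitted models directly", {
  sv <- small_survey(n = 40, seed = 59)
  long <- build_long_format(filter_survey(sv)$survey)
  fit <- fit_conditional_logit(long)
  ri <- relative_importance(fit)
  expect_s3_class(ri, "dce_ri")
  expect_equal(sum(ri$weight), 1, tolerance = 1e-9)
  w <- wtp_table(fit)
  expect_equal(nrow(w), 12)
  expect_true(all(is.finite(w$std.error)))  # delta-method SEs from the vcov
})
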