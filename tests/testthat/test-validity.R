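# build a minimal respondent record for rule-level tests
make_record <- function(choices, questionnaire) {
  tibble::tibble(position = questionnaire$tasks$position,
                 set_id = questionnaire$tasks$set_id,
                 is_repeat = questionnaire$tasks$is_repeat,
                 choice = choices)
}

test_that("consistency requires the identical alternative on the repeated task", {
  st <- small_study()
  q <- st$questionnaires[[1]]
  pair <- q$consistency_pair
  ch <- rep(1L, 11)
  expect_true(check_consistency(make_record(ch, q), q))
  ch2 <- ch
  ch2[pair[["repeated"]]] <- 3L  # switched to opt-out on the repeat
  expect_false(check_consistency(make_record(ch2, q), q))
  q_nopair <- q; q_nopair$consistency_pair <- NULL
  expect_error(check_consistency(make_record(ch, q), q_nopair),
               "consistency pair")
})

test_that("SMART alignment is weak-order concordance of scores and ranks", {
  expect_true(check_smart_alignment(c(90, 80, 70, 60, 50, 40, 30), 1:7))
  # top-ranked attribute has the lowest score
  expect_false(check_smart_alignment(c(10, 80, 70, 60, 50, 40, 30), 1:7))
  # ties impose no constraint
  expect_true(check_smart_alignment(rep(50, 7), sample(7)))
  expect_error(check_smart_alignment(rep(1, 7), c(1, 1, 2, 3, 4, 5, 6)),
               "permutation")
})

test_that("a planted 84-respondent panel filters to 69 valid with correct reasons", {
  # attentive, lapse-free panel: everyone starts valid
  pop <- preference_population(careless_fraction = 0, lapse = 0)
  sv <- small_survey(n = 84, seed = 61, pop = pop)

  # plant 15 violations: 6 slow-only, 5 inconsistent with misaligned SMART,
  # 4 slow and inconsistent
  slow <- 1:6
  inconsistent <- 7:11
  both <- 12:15
  sv$respondents$completion_minutes[c(slow, both)] <- 7.9
  q_by_block <- stats::setNames(sv$questionnaires,
                                vapply(sv$questionnaires,
                                       function(q) q$block_id, 1))
  for (id in c(inconsistent, both)) {
    b <- sv$respondents$block_id[sv$respondents$respondent_id == id]
    pair <- q_by_block[[as.character(b)]]$consistency_pair
    i <- which(sv$choices$respondent_id == id &
                 sv$choices$position == pair[["repeated"]])
    orig <- sv$choices$choice[sv$choices$respondent_id == id &
                                sv$choices$position == pair[["original"]]]
    sv$choices$choice[i] <- (orig %% 3L) + 1L  # guaranteed different
  }
  # break SMART alignment for the inconsistent-only group so the fallback
  # cannot rescue them
  for (id in inconsistent) {
    rows <- which(sv$smart$respondent_id == id)
    sc <- sv$smart$score[rows]
    rk <- sv$smart$rank[rows]
    sv$smart$score[rows][which.min(rk)] <- min(sc) - 1
  }

  flt <- filter_survey(sv)
  expect_equal(sum(flt$audit$valid), 69)
  expect_equal(nrow(flt$audit), 84)
  expect_equal(nrow(flt$survey$respondents), 69)

  a <- flt$audit
  expect_true(all(grepl("TIME_FAIL", a$reasons[a$respondent_id %in% slow])))
  expect_true(all(grepl("CONSISTENCY_FAIL",
                        a$reasons[a$respondent_id %in% inconsistent])))
  expect_true(all(grepl("SMART_ALIGN_FAIL",
                        a$reasons[a$respondent_id %in% inconsistent])))
  expect_true(all(!a$valid[a$respondent_id %in% both]))
})

test_that("time threshold is a sharp >= 8 minutes and SMART alignment rescues inconsistency", {
  pop <- preference_population(careless_fraction = 0, lapse = 0)
  sv <- small_survey(n = 6, seed = 71, pop = pop)

  # 7.9 minutes, consistent -> invalid with TIME_FAIL
  sv$respondents$completion_minutes[1] <- 7.9
  # 9 minutes, inconsistent, SMART aligned -> valid (fallback)
  sv$respondents$completion_minutes[2] <- 9
  q <- sv$questionnaires[[sv$respondents$block_id[2]]]
  pair <- q$consistency_pair
  i <- which(sv$choices$respondent_id == 2 &
               sv$choices$position == pair[["repeated"]])
  orig <- sv$choices$choice[sv$choices$respondent_id == 2 &
                              sv$choices$position == pair[["original"]]]
  sv$choices$choice[i] <- (orig %% 3L) + 1L
  # exactly 8.0 minutes passes
  sv$respondents$completion_minutes[3] <- 8.0

  flt <- filter_survey(sv)
  a <- flt$audit
  expect_false(a$valid[1]); expect_match(a$reasons[1], "TIME_FAIL")
  expect_true(a$valid[2]); expect_match(a$reasons[2], "SMART_ALIGN_PASS")
  expect_true(a$valid[3])
})

test_that("filtering is idempotent and respondent-order invariant", {
  sv <- small_survey(n = 50, seed = 81)
  flt1 <- filter_survey(sv)
  flt2 <- filter_survey(flt1$survey)
  expect_identical(flt1$survey$choices, flt2$survey$choices)
  expect_identical(flt1$survey$respondents, flt2$survey$respondents)
  expect_true(all(flt2$audit$valid))

  # permuting respondent order leaves each verdict unchanged
  perm <- sample(nrow(sv$respondents))
  sv_perm <- sv
  sv_perm$respondents <- sv$respondents[perm, ]
  flt3 <- filter_survey(sv_perm)
  merged <- merge(flt1$audit, flt3$audit, by = "respondent_id")
  expect_equal(merged$valid.x, merged$valid.y)
  expect_equal(merged$reasons.x, merged$reasons.y)
})
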