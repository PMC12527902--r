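# Shared fixtures, all built in code.

# a two-attribute toy schema (one categorical, one continuous)
toy_schema <- function() {
  dce_schema(tibble::tibble(
    attribute = c("eff", "eff", "eff", "price", "price", "price"),
    attribute_label = c(rep("Effectiveness", 3), rep("Price", 3)),
    domain = NA_character_,
    kind = c(rep("categorical", 3), rep("continuous", 3)),
    level = c("none", "some", "full", "high", "mid", "low"),
    ordinal = c(0L, 1L, 2L, 0L, 1L, 2L),
    numeric_value = c(NA, NA, NA, 10, 5, 1)
  ))
}

# small blocked design + questionnaires on the default schema, cached per
# test run (cheap but used by several files)
fixture_env <- new.env()

small_study <- function() {
  if (is.null(fixture_env$study)) {
    sch <- orphan_drug_schema()
    des <- generate_design(sch, 30, seed = 42, n_restarts = 1, max_passes = 4)
    blocked <- block_design(des, 3, seed = 1, schema = sch)
    qs <- build_questionnaires(blocked, seed = 7)
    fixture_env$study <- list(schema = sch, design = des, blocked = blocked,
                              questionnaires = qs)
  }
  fixture_env$study
}

# survey of n respondents under the default population, fixed seed
small_survey <- function(n = 84, seed = 11, pop = preference_population()) {
  st <- small_study()
  simulate_responses(st$questionnaires, st$design, pop, n, seed = seed,
                     schema = st$schema)
}

# reference coefficient table (design terms only, no opt-out constant)
ref_coefs <- function(group = "all") {
  x <- reference_estimates(group)
  x[x$term != "opt_out", ]
}
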