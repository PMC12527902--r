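#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run: design parameters,
#' simulation population (or paths to collected data), validity rules,
#' model specification and draw settings. All stage seeds derive
#' deterministically from the single `seed`, so a config fully determines
#' every output.
#'
#' @param schema A [dce_schema()].
#' @param n_sets,n_blocks Design size and blocking.
#' @param n_restarts Coordinate-exchange restarts.
#' @param n_respondents Simulated panel size.
#' @param population A [preference_population()].
#' @param rules A [validity_rules()].
#' @param spec A [model_spec()].
#' @param n_draws Halton draws for the mixed logit.
#' @param group_var Respondent column defining subgroup re-estimation
#'   (`NULL` to skip subgroups).
#' @param data_paths Optional `list(choices = , metadata = )` CSV paths;
#'   when given, ingestion replaces simulation.
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for report artifacts.
#' @return A `dce_pipeline_config` list.
#' @export
pipeline_config <- function(schema = orphan_drug_schema(),
                            n_sets = 30, n_blocks = 3, n_restarts = 2,
                            n_respondents = 84,
                            population = preference_population(),
                            rules = validity_rules(),
                            spec = model_spec(schema = schema),
                            n_draws = 500,
                            group_var = "group",
                            data_paths = NULL,
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "dce_pipeline_config")
}

stage_seed <- function(seed, offset) (seed * 7L + offset * 1009L) %% 2147483629L

#' Run the full design-to-weights pipeline
#'
#' Executes, in order: D-efficient design generation, blocking and
#' questionnaire assembly; survey simulation (or ingestion when
#' `data_paths` is configured); validity filtering; conditional and mixed
#' logit estimation on the valid respondents, re-estimated per subgroup
#' when `group_var` is set; and weight derivation (relative importance,
#' WTP, SMART, method concordance). When `out_dir` is set, artifacts are
#' written there (design JSON, audit CSV, per-group estimation JSON,
#' weight CSVs, run log).
#'
#' @param config A [pipeline_config()].
#' @return A `dce_report` list: `design`, `questionnaires`, `survey`
#'   (valid subset), `audit`, `fits` (per group), `weights` (per group:
#'   `ri`, `wtp`), `smart`, `comparison`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  design <- generate_design(cf$schema, n_sets = cf$n_sets,
                            seed = stage_seed(cf$seed, 1L),
                            n_restarts = cf$n_restarts)
  say("design: ", cf$n_sets, " sets, D-error ",
      formatC(design$d_error, digits = 6, format = "g"))
  blocked <- block_design(design, n_blocks = cf$n_blocks,
                          seed = stage_seed(cf$seed, 2L), schema = cf$schema)
  questionnaires <- build_questionnaires(blocked, seed = stage_seed(cf$seed, 3L))

  if (is.null(cf$data_paths)) {
    survey <- simulate_responses(questionnaires, design, cf$population,
                                 cf$n_respondents,
                                 seed = stage_seed(cf$seed, 4L),
                                 schema = cf$schema)
    say("simulated ", cf$n_respondents, " respondents")
  } else {
    survey <- ingest_survey(cf$data_paths$choices, cf$data_paths$metadata,
                            cf$schema)
    say("ingested ", nrow(survey$respondents), " respondents")
  }

  flt <- filter_survey(survey, cf$rules)
  say("validity: ", sum(flt$audit$valid), " of ", nrow(flt$audit),
      " respondents valid")

  groups <- list(all = flt$survey)
  if (!is.null(cf$group_var)) {
    gvals <- unique(flt$survey$respondents[[cf$group_var]])
    for (g in sort(gvals)) {
      sub <- flt$survey
      keep <- sub$respondents$respondent_id[sub$respondents[[cf$group_var]] == g]
      sub$choices <- sub$choices[sub$choices$respondent_id %in% keep, ]
      sub$respondents <- sub$respondents[sub$respondents$respondent_id %in% keep, ]
      sub$smart <- sub$smart[sub$smart$respondent_id %in% keep, ]
      groups[[g]] <- sub
    }
  }

  fits <- list()
  weights <- list()
  for (g in names(groups)) {
    fit <- tryCatch({
      long <- build_long_format(groups[[g]], cf$schema)
      fit_mixed_logit(long, cf$spec, n_draws = cf$n_draws,
                      seed = stage_seed(cf$seed, 5L))
    }, error = function(e) {
      say("estimation failed for group '", g, "': ", conditionMessage(e))
      NULL
    })
    fits[[g]] <- fit
    if (!is.null(fit)) {
      say("group ", g, ": ll = ",
          formatC(fit$log_likelihood, format = "f", digits = 3),
          ", AIC = ", formatC(fit$aic, format = "f", digits = 2),
          ", BIC = ", formatC(fit$bic, format = "f", digits = 2),
          if (!fit$converged) " [NOT CONVERGED]")
      weights[[g]] <- list(ri = relative_importance(fit, cf$schema),
                           wtp = wtp_table(fit, cf$schema))
    }
  }

  smart <- smart_weights(flt$survey)
  comparison <- if (!is.null(weights$all)) {
    compare_weighting_methods(weights$all$ri, smart)
  } else NULL

  report <- structure(list(
    design = design, questionnaires = questionnaires,
    survey = flt$survey, audit = flt$audit,
    fits = fits, weights = weights, smart = smart, comparison = comparison,
    config = cf, log = log_lines
  ), class = "dce_report")

  if (!is.null(cf$out_dir)) write_report(report, cf$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cf <- report$config
  write_design_json(report$design, file.path(out_dir, "design.json"),
                    report$questionnaires)
  write_audit_csv(report$audit, file.path(out_dir, "validity_audit.csv"))
  for (g in names(report$fits)) {
    if (is.null(report$fits[[g]])) next
    write_fit_json(report$fits[[g]],
                   file.path(out_dir, paste0("estimation_", g, ".json")))
    write_weights_csv(report$weights[[g]]$ri,
                      file.path(out_dir, paste0("ri_weights_", g, ".csv")))
    write_weights_csv(report$weights[[g]]$wtp,
                      file.path(out_dir, paste0("wtp_", g, ".csv")))
  }
  write_weights_csv(report$smart, file.path(out_dir, "smart_weights.csv"))
  if (!is.null(report$comparison)) {
    write_weights_csv(report$comparison,
                      file.path(out_dir, "method_concordance.csv"))
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.dce_report <- function(x, ...) {
  cat("<dce_report>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Export a simulated survey as CSV files
#'
#' Writes the long-format choice table (one row per task alternative,
#' columns `respondent_id`, `block_id`, `task_id`, `set_id`, `is_repeat`,
#' `alt_id`, `chosen`, `opt_out`, `x1..x12`, `cost_10k`) and the
#' respondent-metadata table (`respondent_id`, `block`,
#' `completion_minutes`, `group`, `rank_1..rank_7`, `score_1..score_7`).
#'
#' @param survey A `dce_survey`.
#' @param choices_path,metadata_path Output CSV paths.
#' @param schema A [dce_schema()].
#' @return Invisibly, the two paths.
#' @export
write_survey_csv <- function(survey, choices_path, metadata_path,
                             schema = survey$schema %||% orphan_drug_schema()) {
  attrs <- schema_attributes(schema)
  sets <- survey$design_sets
  X_sets <- encode_profiles(sets[, attrs, drop = FALSE], schema)
  key <- paste(sets$set_id, sets$alt)
  terms <- colnames(X_sets)

  ch <- survey$choices
  long <- ch[rep(seq_len(nrow(ch)), each = 3), ]
  long$alt_id <- rep(1:3, nrow(ch))
  long$opt_out <- as.numeric(long$alt_id == 3)
  long$chosen <- as.numeric(long$alt_id == long$choice)
  X <- matrix(0, nrow(long), length(terms), dimnames = list(NULL, terms))
  drug <- long$alt_id != 3
  X[drug, ] <- X_sets[match(paste(long$set_id[drug], long$alt_id[drug]), key), ]
  out <- dplyr::bind_cols(
    long[, c("respondent_id", "block_id", "position", "set_id", "is_repeat",
             "alt_id", "chosen", "opt_out")],
    tibble::as_tibble(X))
  names(out)[match("position", names(out))] <- "task_id"
  dummies <- terms[terms != "cost"]
  names(out)[match(dummies, names(out))] <- paste0("x", seq_along(dummies))
  if ("cost" %in% terms) names(out)[match("cost", names(out))] <- "cost_10k"
  readr::write_csv(out, choices_path)

  sm <- survey$smart
  attrs_order <- unique(sm$attribute)
  wide_r <- tidyr::pivot_wider(sm[, c("respondent_id", "attribute", "rank")],
                               names_from = "attribute", values_from = "rank")
  names(wide_r)[-1] <- paste0("rank_", seq_along(attrs_order))
  wide_s <- tidyr::pivot_wider(sm[, c("respondent_id", "attribute", "score")],
                               names_from = "attribute", values_from = "score")
  names(wide_s)[-1] <- paste0("score_", seq_along(attrs_order))
  meta <- survey$respondents[, c("respondent_id", "block_id",
                                 "completion_minutes", "group")]
  names(meta)[2] <- "block"
  meta <- dplyr::left_join(meta, wide_r, by = "respondent_id")
  meta <- dplyr::left_join(meta, wide_s, by = "respondent_id")
  readr::write_csv(meta, metadata_path)
  invisible(c(choices = choices_path, metadata = metadata_path))
}

decode_x_row <- function(xrow, schema) {
  ## map a design vector back to level ordinals (dummy coding)
  attrs <- schema_attributes(schema)
  parts <- schema_split(schema)
  terms <- schema_terms(schema)
  out <- stats::setNames(integer(length(attrs)), attrs)
  for (a in attrs) {
    if (parts[[a]]$kind[1] == "continuous") {
      i <- match(xrow[[a]], parts[[a]]$numeric_value)
      if (is.na(i)) stop("cost value ", xrow[[a]],
                         " matches no schema level", call. = FALSE)
      out[a] <- parts[[a]]$ordinal[i]
    } else {
      tms <- terms[terms$attribute == a, ]
      on <- which(unlist(xrow[tms$term]) == 1)
      if (length(on) > 1) stop("multiple dummies set for ", a, call. = FALSE)
      out[a] <- if (length(on) == 0) {
        parts[[a]]$ordinal[parts[[a]]$reference]
      } else tms$ordinal[on]
    }
  }
  out
}

#' Ingest a survey from CSV files
#'
#' Reads the choice and metadata CSV dialects written by
#' [write_survey_csv()], validates them (exactly one chosen alternative
#' per task, SMART ranks a permutation, metadata covering every
#' respondent), reconstructs the choice-set profiles from the design
#' vectors, and returns a `dce_survey` equivalent to the one exported.
#'
#' @param choices_path,metadata_path Input CSV paths.
#' @param schema A [dce_schema()].
#' @return A `dce_survey`.
#' @export
ingest_survey <- function(choices_path, metadata_path,
                          schema = orphan_drug_schema()) {
  ch <- readr::read_csv(choices_path, show_col_types = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  terms <- schema_terms(schema)$term
  dummies <- terms[terms != "cost"]
  x_names <- c(paste0("x", seq_along(dummies)), if ("cost" %in% terms) "cost_10k")
  need <- c("respondent_id", "block_id", "task_id", "set_id", "is_repeat",
            "alt_id", "chosen", x_names)
  missing <- setdiff(need, names(ch))
  if (length(missing) > 0) {
    stop("choice CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  names(ch)[match(x_names, names(ch))] <- terms

  dup <- duplicated(ch[, c("respondent_id", "task_id", "alt_id")])
  if (any(dup)) {
    stop("duplicate respondent-task rows at line(s) ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  }
  n_chosen <- tapply(ch$chosen, paste(ch$respondent_id, ch$task_id), sum)
  bad <- names(n_chosen)[n_chosen != 1]
  if (length(bad) > 0) {
    stop("tasks without exactly one chosen alternative (respondent task): ",
         paste(utils::head(bad, 5), collapse = "; "), call. = FALSE)
  }
  missing_meta <- setdiff(unique(ch$respondent_id), meta$respondent_id)
  if (length(missing_meta) > 0) {
    stop("metadata missing respondent(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }

  ## reconstruct per-set profiles from the drug alternatives' design vectors
  drug <- ch[ch$alt_id != 3, ]
  sets_raw <- drug[!duplicated(paste(drug$set_id, drug$alt_id)),
                   c("set_id", "alt_id", terms)]
  prof <- purrr::map_dfr(seq_len(nrow(sets_raw)), function(i) {
    tibble::as_tibble(as.list(decode_x_row(sets_raw[i, terms], schema)))
  })
  sets <- dplyr::bind_cols(tibble::tibble(set_id = sets_raw$set_id,
                                          alt = sets_raw$alt_id), prof)
  sets <- sets[order(sets$set_id, sets$alt), ]

  chosen <- ch[ch$chosen == 1, ]
  choices <- tibble::tibble(
    respondent_id = chosen$respondent_id, block_id = chosen$block_id,
    position = chosen$task_id, set_id = chosen$set_id,
    is_repeat = as.logical(chosen$is_repeat), choice = chosen$alt_id)
  choices <- choices[order(choices$respondent_id, choices$position), ]

  n_attr <- length(schema_attributes(schema))
  rank_cols <- paste0("rank_", seq_len(n_attr))
  score_cols <- paste0("score_", seq_len(n_attr))
  smart <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    ranks <- as.integer(unlist(meta[i, rank_cols]))
    if (!setequal(ranks, seq_len(n_attr))) {
      stop("SMART ranks for respondent ", meta$respondent_id[i],
           " are not a permutation of 1..", n_attr, call. = FALSE)
    }
    tibble::tibble(respondent_id = meta$respondent_id[i],
                   attribute = schema_attributes(schema),
                   score = as.numeric(unlist(meta[i, score_cols])),
                   rank = ranks)
  })

  structure(list(
    choices = choices,
    respondents = tibble::tibble(
      respondent_id = meta$respondent_id, block_id = meta$block,
      group = meta$group, completion_minutes = meta$completion_minutes),
    smart = smart,
    questionnaires = NULL,
    design_sets = sets,
    population = NULL, seed = NULL, schema = schema
  ), class = "dce_survey")
}
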