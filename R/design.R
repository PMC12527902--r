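#' Choice designs
#'
#' A `dce_design` bundles a set of paired choice tasks with the settings
#' used to construct it: `sets` is a tibble with columns `set_id`, `alt`
#' (1 or 2) and one column per schema attribute holding level ordinals;
#' `d_error` is the design's D-error under `prior`; `seed` records the
#' search seed. The opt-out alternative is not part of the design: it is
#' appended when questionnaires are assembled.
#'
#' @name dce_design
NULL

new_dce_design <- function(sets, d_error, prior, seed) {
  structure(list(sets = tibble::as_tibble(sets), d_error = d_error,
                 prior = prior, seed = seed),
            class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  n_sets <- length(unique(x$sets$set_id))
  cat("<dce_design> ", n_sets, " paired choice sets, D-error ",
      formatC(x$d_error, digits = 5, format = "g"), "\n", sep = "")
  invisible(x)
}

design_profiles <- function(design) {
  design$sets[, setdiff(names(design$sets), c("set_id", "alt")), drop = FALSE]
}

#' Expected (MNL) information matrix of a choice design
#'
#' Under a multinomial-logit response model with coefficient vector
#' `prior`, the Fisher information contributed by a choice set with
#' alternatives \eqn{x_j} and choice probabilities \eqn{P_j} is
#' \eqn{\sum_j P_j (x_j - \bar x)(x_j - \bar x)^\top} with
#' \eqn{\bar x = \sum_j P_j x_j}; the design's information is the sum over
#' sets. The zero prior (utility-neutral case) gives equal probabilities.
#'
#' @param design A [dce_design] or a sets tibble (`set_id`, `alt`,
#'   attribute ordinals).
#' @param prior Numeric coefficient vector of length [schema_k()].
#' @param schema A [dce_schema()].
#' @return A symmetric positive semidefinite K x K matrix.
#' @export
mnl_info_matrix <- function(design, prior, schema) {
  sets <- if (inherits(design, "dce_design")) design$sets else tibble::as_tibble(design)
  X <- encode_profiles(sets[, setdiff(names(sets), c("set_id", "alt")), drop = FALSE],
                       schema)
  if (length(prior) != ncol(X)) {
    stop("prior length ", length(prior), " does not match design-vector length ",
         ncol(X), call. = FALSE)
  }
  info_matrix_encoded(X, sets$set_id, prior)
}

## core computation on an already-encoded design matrix
info_matrix_encoded <- function(X, set_id, prior) {
  V <- as.vector(X %*% prior)
  g <- match(set_id, unique(set_id))
  V <- V - ave(V, g, FUN = max)
  e <- exp(V)
  P <- e / ave(e, g, FUN = sum)
  xbar <- rowsum(P * X, g)[g, , drop = FALSE]
  Xc <- X - xbar
  crossprod(Xc, P * Xc)
}

#' D-error of a choice design
#'
#' \eqn{\det(I)^{-1/K}} where \eqn{I} is the MNL information matrix under
#' `prior` and \eqn{K} the design-vector length. Lower is better; a design
#' whose information matrix is singular has D-error `Inf`.
#'
#' @inheritParams mnl_info_matrix
#' @return A non-negative number, possibly `Inf`.
#' @export
d_error <- function(design, prior, schema) {
  I <- mnl_info_matrix(design, prior, schema)
  d_error_from_info(I)
}

d_error_from_info <- function(I) {
  ld <- determinant(I, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(Inf)
  exp(-as.numeric(ld$modulus) / ncol(I))
}

## log-det objective used by the search (maximize); -Inf when singular
logdet_info <- function(X, set_id, prior) {
  I <- info_matrix_encoded(X, set_id, prior)
  ld <- determinant(I, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(-Inf)
  as.numeric(ld$modulus)
}

## fast log-det objective for two-alternative designs whose rows come in
## contiguous (alt 1, alt 2) pairs; avoids the general grouping machinery
## inside the coordinate-exchange hot loop
logdet_pairs <- function(X, prior) {
  V <- as.vector(X %*% prior)
  i1 <- seq(1, nrow(X), 2L)
  i2 <- i1 + 1L
  m <- pmax(V[i1], V[i2])
  e1 <- exp(V[i1] - m)
  e2 <- exp(V[i2] - m)
  p1 <- e1 / (e1 + e2)
  p2 <- 1 - p1
  X1 <- X[i1, , drop = FALSE]
  X2 <- X[i2, , drop = FALSE]
  B <- p1 * X1 + p2 * X2
  X1 <- X1 - B
  X2 <- X2 - B
  I <- crossprod(X1, p1 * X1) + crossprod(X2, p2 * X2)
  ld <- determinant(I, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(-Inf)
  as.numeric(ld$modulus)
}

## encode a single profile (named integer vector of ordinals) without the
## data-frame overhead of encode_profiles()
encode_one <- function(ord, enc) {
  x <- numeric(enc$K)
  for (a in seq_along(enc$attrs)) {
    e <- enc$by_attr[[a]]
    if (e$continuous) {
      x[e$cols] <- e$values[ord[a] + 1L]
    } else {
      hit <- e$col_of_ordinal[ord[a] + 1L]
      if (!is.na(hit)) x[hit] <- 1
    }
  }
  x
}

## precomputed encoding tables for encode_one()
encoder_tables <- function(schema) {
  terms <- schema_terms(schema)
  attrs <- schema_attributes(schema)
  parts <- schema_split(schema)
  by_attr <- lapply(attrs, function(a) {
    lv <- parts[[a]]
    cols <- which(terms$attribute == a)
    if (lv$kind[1] == "continuous") {
      list(continuous = TRUE, cols = cols,
           values = lv$numeric_value[order(lv$ordinal)])
    } else {
      col_of <- rep(NA_integer_, nrow(lv))
      for (j in cols) col_of[terms$ordinal[j] + 1L] <- j
      list(continuous = FALSE, col_of_ordinal = col_of)
    }
  })
  list(K = nrow(terms), attrs = attrs, by_attr = by_attr,
       n_lev = vapply(parts[attrs], nrow, integer(1)))
}

random_paired_sets <- function(schema, n_sets) {
  attrs <- schema_attributes(schema)
  parts <- schema_split(schema)
  n_lev <- vapply(parts[attrs], nrow, integer(1))
  draw <- function(n) {
    m <- vapply(seq_along(attrs),
                function(j) sample.int(n_lev[j], n, replace = TRUE) - 1L,
                integer(n))
    if (n == 1L) m <- matrix(m, nrow = 1)
    colnames(m) <- attrs
    m
  }
  a1 <- draw(n_sets)
  a2 <- draw(n_sets)
  for (s in seq_len(n_sets)) {  # forbid identical pairs
    while (all(a1[s, ] == a2[s, ])) a2[s, ] <- draw(1L)
  }
  sets <- tibble::as_tibble(rbind(a1, a2))
  sets$set_id <- rep(seq_len(n_sets), 2L)
  sets$alt <- rep(1:2, each = n_sets)
  sets <- sets[order(sets$set_id, sets$alt), c("set_id", "alt", attrs)]
  sets
}

#' Generate a random paired choice design
#'
#' Uniformly sampled alternatives (identical pairs redrawn). Used as the
#' starting point of the D-efficient search and as the comparison baseline
#' when benchmarking design efficiency.
#'
#' @param schema A [dce_schema()].
#' @param n_sets Number of paired choice sets.
#' @param prior Coefficient vector used to evaluate the reported D-error.
#' @param seed Integer seed.
#' @return A [dce_design].
#' @export
random_design <- function(schema, n_sets = 30, prior = rep(0, schema_k(schema)),
                          seed = 1L) {
  set.seed(seed)
  sets <- random_paired_sets(schema, n_sets)
  new_dce_design(sets, d_error(sets, prior, schema), prior, seed)
}

#' D-efficient paired choice design by coordinate exchange
#'
#' Searches for a design of `n_sets` paired choice sets minimizing the
#' D-error under `prior` (zero by default, the utility-neutral case).
#' Starting from a random design, the algorithm sweeps over every (set,
#' alternative, attribute) position, tries each alternative level, and
#' accepts a swap whenever it increases the information determinant;
#' sweeps repeat until a full pass makes no change. The best design over
#' `n_restarts` random starts is returned, so the result's D-error never
#' exceeds that of its own random start.
#'
#' @param schema A [dce_schema()].
#' @param n_sets Number of paired choice sets (default 30).
#' @param prior Coefficient vector (length [schema_k()]) of assumed
#'   utilities; zero by default.
#' @param seed Integer seed; the same seed reproduces the same design.
#' @param n_restarts Number of random starts.
#' @param max_passes Cap on coordinate-exchange sweeps per start.
#' @return A [dce_design] with 2 `n_sets` rows in `$sets`.
#' @export
generate_design <- function(schema, n_sets = 30,
                            prior = rep(0, schema_k(schema)),
                            seed = 1L, n_restarts = 3, max_passes = 25) {
  K <- schema_k(schema)
  if (length(prior) != K) stop("prior must have length ", K, call. = FALSE)
  if (2 * n_sets < K) {
    stop("n_sets = ", n_sets, " cannot identify ", K, " parameters",
         call. = FALSE)
  }
  attrs <- schema_attributes(schema)
  enc <- encoder_tables(schema)
  set.seed(seed)
  best <- NULL
  best_ld <- -Inf
  for (r in seq_len(n_restarts)) {
    sets <- random_paired_sets(schema, n_sets)
    prof <- as.matrix(sets[, attrs, drop = FALSE])
    X <- encode_profiles(sets[, attrs, drop = FALSE], schema)
    ld <- logdet_pairs(X, prior)
    improved <- TRUE
    pass <- 0
    while (improved && pass < max_passes) {
      improved <- FALSE
      pass <- pass + 1
      for (row in seq_len(nrow(prof))) {
        other <- if (sets$alt[row] == 1) row + 1L else row - 1L
        for (a in seq_along(attrs)) {
          cur <- prof[row, a]
          for (cand in seq_len(enc$n_lev[a]) - 1L) {
            if (cand == cur) next
            trial <- prof[row, ]
            trial[a] <- cand
            if (all(trial == prof[other, ])) next  # keep pairs distinct
            x_old <- X[row, ]
            X[row, ] <- encode_one(trial, enc)
            ld_try <- logdet_pairs(X, prior)
            if (ld_try > ld + 1e-12) {
              prof[row, a] <- cand
              ld <- ld_try
              improved <- TRUE
            } else {
              X[row, ] <- x_old
            }
          }
        }
      }
    }
    if (ld > best_ld) {
      best_ld <- ld
      out <- sets
      out[, attrs] <- tibble::as_tibble(as.data.frame(prof))
      best <- out
    }
  }
  new_dce_design(best, if (is.finite(best_ld)) exp(-best_ld / K) else Inf,
                 prior, seed)
}

block_score <- function(counts_by_block) {
  ## counts_by_block: n_blocks x n_levelcols matrix of level frequencies
  dev <- sweep(counts_by_block, 2, colMeans(counts_by_block))
  sum(dev^2)
}

block_level_counts <- function(prof, set_id, assignment, n_blocks, n_lev) {
  ## frequency of each (attribute, level) per block, over both alternatives
  n_cols <- sum(n_lev)
  counts <- matrix(0, n_blocks, n_cols)
  offs <- c(0, cumsum(n_lev))[seq_along(n_lev)]
  blk <- assignment[match(set_id, sort(unique(set_id)))]
  for (a in seq_along(n_lev)) {
    tab <- table(factor(blk, levels = seq_len(n_blocks)),
                 factor(prof[, a], levels = 0:(n_lev[a] - 1)))
    counts[, offs[a] + seq_len(n_lev[a])] <- tab
  }
  counts
}

#' Split a design into blocks of equal size
#'
#' Partitions the choice sets into `n_blocks` disjoint blocks of equal
#' size. Starting from a random equal split, a greedy pairwise-swap pass
#' reduces the imbalance of attribute-level frequencies across blocks
#' (sum of squared deviations from the per-block expected frequency) until
#' no swap improves it.
#'
#' @param design A [dce_design].
#' @param n_blocks Number of blocks; must divide the number of sets.
#' @param seed Integer seed.
#' @param schema A [dce_schema()].
#' @return A tibble like `design$sets` with an added `block_id` column.
#' @export
block_design <- function(design, n_blocks = 3, seed = 1L,
                         schema = orphan_drug_schema()) {
  sets <- design$sets
  ids <- sort(unique(sets$set_id))
  n_sets <- length(ids)
  if (n_sets %% n_blocks != 0) {
    stop(n_sets, " sets cannot be divided equally into ", n_blocks,
         " blocks", call. = FALSE)
  }
  per <- n_sets / n_blocks
  attrs <- schema_attributes(schema)
  parts <- schema_split(schema)
  n_lev <- vapply(parts[attrs], nrow, integer(1))
  prof <- as.matrix(sets[, attrs, drop = FALSE])
  set.seed(seed)
  assignment <- sample(rep(seq_len(n_blocks), each = per))
  counts <- block_level_counts(prof, sets$set_id, assignment, n_blocks, n_lev)
  score <- block_score(counts)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n_sets - 1)) {
      for (j in seq(i + 1, n_sets)) {
        if (assignment[i] == assignment[j]) next
        trial <- assignment
        trial[c(i, j)] <- trial[c(j, i)]
        sc <- block_score(block_level_counts(prof, sets$set_id, trial,
                                             n_blocks, n_lev))
        if (sc < score - 1e-12) {
          assignment <- trial
          score <- sc
          improved <- TRUE
        }
      }
    }
  }
  out <- sets
  out$block_id <- assignment[match(out$set_id, ids)]
  out[order(out$block_id, out$set_id, out$alt),
      c("block_id", setdiff(names(out), "block_id"))]
}

#' Assemble a questionnaire from one block of choice sets
#'
#' Orders the block's sets into tasks, then duplicates the task holding the
#' set at `repeat_index` as a consistency check, inserted at least two
#' positions after its original. Every task implicitly offers three
#' choices: alternative 1, alternative 2, and the opt-out.
#'
#' @param block A tibble of sets for one block (as one element of
#'   [block_design()] output), or a [dce_design]'s `sets` subset.
#' @param repeat_index Which of the block's sets (1-based, in block order)
#'   to repeat.
#' @param seed Integer seed controlling task order and repeat placement.
#' @param block_id Block identifier stored on the questionnaire.
#' @return A `dce_questionnaire`: list with `block_id`, `tasks` (tibble of
#'   `position`, `set_id`, `is_repeat`) and `consistency_pair` (positions
#'   of the original and repeated task).
#' @export
build_questionnaire <- function(block, repeat_index, seed = 1L,
                                block_id = block$block_id[1] %||% 1L) {
  ids <- unique(block$set_id)
  n <- length(ids)
  if (n == 0) stop("block is empty", call. = FALSE)
  if (repeat_index < 1 || repeat_index > n) {
    stop("repeat_index ", repeat_index, " out of range 1..", n, call. = FALSE)
  }
  set.seed(seed)
  order_ids <- sample(ids)
  rep_set <- ids[repeat_index]
  p_orig <- match(rep_set, order_ids)
  if (p_orig > n - 1) {  # need room for the repeat >= 2 positions later
    swap_to <- sample.int(n - 1, 1)
    order_ids[c(p_orig, swap_to)] <- order_ids[c(swap_to, p_orig)]
    p_orig <- swap_to
  }
  cands <- seq(p_orig + 2, n + 1)
  p_rep <- cands[sample.int(length(cands), 1)]
  tasks <- tibble::tibble(set_id = append(order_ids, rep_set, after = p_rep - 1),
                          is_repeat = FALSE)
  tasks$is_repeat[p_rep] <- TRUE
  tasks$position <- seq_len(nrow(tasks))
  structure(list(block_id = block_id,
                 tasks = tasks[, c("position", "set_id", "is_repeat")],
                 consistency_pair = c(original = p_orig, repeated = p_rep),
                 n_alternatives = 3L),
            class = "dce_questionnaire")
}

#' @export
print.dce_questionnaire <- function(x, ...) {
  cat("<dce_questionnaire> block ", x$block_id, ": ", nrow(x$tasks),
      " tasks (consistency pair ", x$consistency_pair[1], "/",
      x$consistency_pair[2], "), opt-out on every task\n", sep = "")
  invisible(x)
}

#' Build one questionnaire per block of a blocked design
#'
#' @param blocked Output of [block_design()].
#' @param seed Integer seed; per-block seeds and repeat indices derive
#'   from it.
#' @return A list of `dce_questionnaire` objects, one per block.
#' @export
build_questionnaires <- function(blocked, seed = 1L) {
  blocks <- split(blocked, blocked$block_id)
  set.seed(seed)
  reps <- vapply(blocks, function(b) sample.int(length(unique(b$set_id)), 1),
                 integer(1))
  sub_seeds <- sample.int(.Machine$integer.max, length(blocks))
  purrr::imap(blocks, function(b, nm) {
    i <- match(nm, names(blocks))
    build_questionnaire(b, reps[i], seed = sub_seeds[i],
                        block_id = as.integer(nm))
  })
}

#' Export questionnaires as a human-readable CSV
#'
#' One row per task x alternative with level wording, mirroring how a
#' choice task is presented to a respondent (opt-out row included).
#'
#' @param questionnaires List of `dce_questionnaire` objects.
#' @param design The [dce_design] the questionnaires reference.
#' @param schema A [dce_schema()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_questionnaire_csv <- function(questionnaires, design, schema, path) {
  attrs <- schema_attributes(schema)
  rows <- purrr::map_dfr(questionnaires, function(q) {
    purrr::map_dfr(seq_len(nrow(q$tasks)), function(i) {
      task <- q$tasks[i, ]
      alts <- design$sets[design$sets$set_id == task$set_id, ]
      lab <- profile_labels(alts[, attrs, drop = FALSE], schema)
      opt <- tibble::as_tibble(stats::setNames(
        as.list(rep("(opt out)", length(attrs))), attrs))
      out <- dplyr::bind_rows(lab, opt)
      dplyr::bind_cols(
        tibble::tibble(block_id = q$block_id, position = task$position,
                       set_id = task$set_id, is_repeat = task$is_repeat,
                       alternative = c("Orphan Drug 1", "Orphan Drug 2",
                                       "Neither")),
        out)
    })
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' Write / read a blocked design and questionnaires as JSON
#'
#' @param design A [dce_design].
#' @param questionnaires Optional list of questionnaires.
#' @param path File path.
#' @return `path` invisibly for the writer; a list with `design` (tibble of
#'   sets plus settings) and `questionnaires` for the reader.
#' @export
write_design_json <- function(design, path, questionnaires = NULL) {
  obj <- list(
    d_error = design$d_error, prior = design$prior, seed = design$seed,
    sets = design$sets
  )
  if (!is.null(questionnaires)) {
    obj$questionnaires <- purrr::map(questionnaires, function(q) {
      list(block_id = q$block_id, tasks = q$tasks,
           consistency_pair = as.list(q$consistency_pair))
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
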