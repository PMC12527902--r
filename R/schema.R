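#' Attribute schema for a discrete choice experiment
#'
#' A `dce_schema` is a tibble with one row per attribute level and columns
#' `attribute` (short key), `attribute_label` (full wording), `domain`
#' (`"disease-related"`, `"drug/treatment-related"` or `"cost-related"`),
#' `kind` (`"categorical"` or `"continuous"`), `level` (level wording),
#' `ordinal` (0-based position within the attribute; 0 is the reference
#' level), `numeric_value` (the level's value on the attribute's natural
#' scale, `NA` for categorical attributes) and `reference` (logical).
#'
#' Attributes appear in the order in which their coefficients enter the
#' utility function; within an attribute, levels are ordered worst to best
#' so that the reference level is the least attractive one.
#'
#' @param attributes A data frame with the columns listed above (minus
#'   `reference`, which is derived from `ordinal == reference_ordinal`).
#' @return A `dce_schema` tibble.
#' @seealso [orphan_drug_schema()] for the packaged default.
#' @export
dce_schema <- function(attributes) {
  x <- tibble::as_tibble(attributes)
  required <- c("attribute", "kind", "level", "ordinal")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("schema is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"attribute_label" %in% names(x)) x$attribute_label <- x$attribute
  if (!"domain" %in% names(x)) x$domain <- NA_character_
  if (!"numeric_value" %in% names(x)) x$numeric_value <- NA_real_
  if (!"reference" %in% names(x)) x$reference <- x$ordinal == 0L
  x$ordinal <- as.integer(x$ordinal)

  by_attr <- split(x, factor(x$attribute, levels = unique(x$attribute)))
  for (a in by_attr) {
    if (anyDuplicated(a$ordinal) > 0) {
      stop("duplicate level ordinals in attribute '", a$attribute[1], "'",
           call. = FALSE)
    }
    if (sum(a$reference) != 1L) {
      stop("attribute '", a$attribute[1], "' must have exactly one reference level",
           call. = FALSE)
    }
    kind <- unique(a$kind)
    if (length(kind) != 1L || !kind %in% c("categorical", "continuous")) {
      stop("attribute '", a$attribute[1],
           "' must have a single kind, 'categorical' or 'continuous'",
           call. = FALSE)
    }
    if (kind == "continuous") {
      v <- a$numeric_value[order(a$ordinal)]
      if (anyNA(v)) {
        stop("continuous attribute '", a$attribute[1],
             "' needs a numeric_value for every level", call. = FALSE)
      }
      if (any(diff(v) == 0) || !(all(diff(v) > 0) || all(diff(v) < 0))) {
        stop("continuous attribute '", a$attribute[1],
             "' must have strictly monotone numeric values", call. = FALSE)
      }
    } else if (!all(is.na(a$numeric_value))) {
      stop("categorical attribute '", a$attribute[1],
           "' must not carry numeric values", call. = FALSE)
    }
  }
  class(x) <- c("dce_schema", class(x))
  x
}

#' The packaged seven-attribute orphan-drug value schema
#'
#' The default attribute set for orphan-drug value assessment from the
#' perspective of basic medical insurance access: seven attributes in three
#' domains, three levels each. Six attributes are categorical and dummy
#' coded against their least attractive (reference) level; annual treatment
#' cost is continuous with levels 500,000 / 200,000 / 80,000 RMB per year,
#' coded in units of 10,000 RMB so the level values are 50, 20 and 8.
#'
#' The design vector implied by this schema has length 13: two dummies for
#' each of the six categorical attributes plus the continuous cost term.
#'
#' @return A `dce_schema` tibble with 21 rows (7 attributes x 3 levels).
#' @examples
#' sch <- orphan_drug_schema()
#' dplyr::count(sch, attribute)
#' @export
orphan_drug_schema <- function() {
  lvl <- function(attribute, attribute_label, domain, kind, levels,
                  numeric_value = rep(NA_real_, length(levels))) {
    tibble::tibble(
      attribute = attribute, attribute_label = attribute_label,
      domain = domain, kind = kind, level = levels,
      ordinal = seq_along(levels) - 1L, numeric_value = numeric_value
    )
  }
  x <- dplyr::bind_rows(
    lvl("severity", "Disease severity", "disease-related", "categorical",
        c("Low", "Moderate", "High")),
    lvl("unmet_needs", "Unmet needs", "drug/treatment-related", "categorical",
        c("Mature treatments available with good clinical outcomes",
          "Controllable treatments available to manage disease progression",
          "No specific treatment available, only symptomatic/supportive treatment")),
    lvl("efficacy", "Drug efficacy", "drug/treatment-related", "categorical",
        c("Stabilizes disease",
          "Partially improves or alleviates",
          "Significantly improves or alleviates")),
    lvl("hrqol", "Improvement in health-related quality of life",
        "drug/treatment-related", "categorical",
        c("No improvement in usual activity",
          "Partial improvement in usual activity",
          "Significant improvement in usual activity")),
    lvl("safety", "Drug safety", "drug/treatment-related", "categorical",
        c("May cause severe adverse reactions",
          "May cause moderate adverse reactions",
          "No or mild adverse reactions")),
    lvl("evidence", "Quality of drug evidence", "drug/treatment-related",
        "categorical", c("Low", "Moderate", "High")),
    lvl("cost",
        "Annual treatment cost per patient reimbursed by basic medical insurance",
        "cost-related", "continuous",
        c("500,000 RMB", "200,000 RMB", "80,000 RMB"),
        numeric_value = c(50, 20, 8))
  )
  dce_schema(x)
}

#' Attribute names of a schema, in utility-function order
#' @param schema A [dce_schema()].
#' @return Character vector of attribute keys.
#' @export
schema_attributes <- function(schema) unique(schema$attribute)

#' Design-vector terms implied by a schema
#'
#' One row per design-vector entry: each non-reference level of a
#' categorical attribute contributes a dummy named `<attribute><ordinal>`
#' (e.g. `severity1`, `severity2`), and each continuous attribute
#' contributes a single term named after the attribute.
#'
#' @param schema A [dce_schema()].
#' @return A tibble with columns `term`, `attribute`, `attribute_label`,
#'   `level`, `ordinal`, `kind`.
#' @export
schema_terms <- function(schema) {
  rows <- dplyr::filter(schema,
                        (.data$kind == "categorical" & !.data$reference) |
                          (.data$kind == "continuous" & .data$ordinal == 0L))
  rows <- rows[order(match(rows$attribute, schema_attributes(schema)), rows$ordinal), ]
  tibble::tibble(
    term = ifelse(rows$kind == "categorical",
                  paste0(rows$attribute, rows$ordinal), rows$attribute),
    attribute = rows$attribute,
    attribute_label = rows$attribute_label,
    level = ifelse(rows$kind == "categorical", rows$level, NA_character_),
    ordinal = ifelse(rows$kind == "categorical", rows$ordinal, NA_integer_),
    kind = rows$kind
  )
}

#' Number of design-vector entries implied by a schema
#' @param schema A [dce_schema()].
#' @return Integer: sum over categorical attributes of (levels - 1) plus the
#'   number of continuous attributes (13 for [orphan_drug_schema()]).
#' @export
schema_k <- function(schema) nrow(schema_terms(schema))

## per-attribute lookup used by the encoders: list of per-attribute tibbles
schema_split <- function(schema) {
  split(as.data.frame(schema),
        factor(schema$attribute, levels = schema_attributes(schema)))
}

#' Encode profiles into design vectors
#'
#' Converts attribute-level profiles into the numeric design matrix that
#' enters the utility function. Categorical attributes are dummy coded
#' against their reference level by default (a profile at the reference
#' level contributes zeros); continuous attributes contribute the level's
#' `numeric_value`. With `coding = "effects"`, the reference level instead
#' contributes -1 on each of the attribute's indicator columns.
#'
#' @param profiles A data frame with one column per schema attribute holding
#'   level ordinals (0-based), one row per profile.
#' @param schema A [dce_schema()].
#' @param coding `"dummy"` (default) or `"effects"`.
#' @return A numeric matrix, `nrow(profiles)` rows by [schema_k()] columns,
#'   with design-term column names.
#' @examples
#' sch <- orphan_drug_schema()
#' ref <- profile_tibble(sch)           # all-reference profile
#' encode_profiles(ref, sch)
#' @export
encode_profiles <- function(profiles, schema, coding = c("dummy", "effects")) {
  coding <- match.arg(coding)
  profiles <- as.data.frame(profiles)
  attrs <- schema_attributes(schema)
  if (!setequal(names(profiles), attrs)) {
    stop("profile columns must be exactly the schema attributes; got: ",
         paste(names(profiles), collapse = ", "), call. = FALSE)
  }
  terms <- schema_terms(schema)
  n <- nrow(profiles)
  X <- matrix(0, n, nrow(terms), dimnames = list(NULL, terms$term))
  parts <- schema_split(schema)
  for (a in attrs) {
    levs <- parts[[a]]
    ord <- profiles[[a]]
    if (any(is.na(ord)) || !all(ord %in% levs$ordinal)) {
      stop("unknown level ordinal for attribute '", a, "'", call. = FALSE)
    }
    if (levs$kind[1] == "continuous") {
      X[, a] <- levs$numeric_value[match(ord, levs$ordinal)]
    } else {
      ref <- levs$ordinal[levs$reference]
      cols <- terms$term[terms$attribute == a]
      col_ord <- terms$ordinal[terms$attribute == a]
      for (j in seq_along(cols)) {
        X[, cols[j]] <- as.numeric(ord == col_ord[j])
        if (coding == "effects") X[ord == ref, cols[j]] <- -1
      }
    }
  }
  X
}

#' Build a profile tibble, defaulting every attribute to its reference level
#'
#' @param schema A [dce_schema()].
#' @param ... Named attribute ordinals overriding the reference (0) default,
#'   e.g. `profile_tibble(sch, severity = 2, cost = 2)`.
#' @return A one-row tibble with one column per attribute.
#' @export
profile_tibble <- function(schema, ...) {
  attrs <- schema_attributes(schema)
  p <- stats::setNames(as.list(rep(0L, length(attrs))), attrs)
  dots <- list(...)
  bad <- setdiff(names(dots), attrs)
  if (length(bad) > 0) {
    stop("unknown attributes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p[names(dots)] <- lapply(dots, as.integer)
  tibble::as_tibble(p)
}

#' Enumerate the full factorial of a schema
#'
#' All distinct combinations of attribute levels; for the default orphan
#' drug schema this is 3^7 = 2187 profiles.
#'
#' @param schema A [dce_schema()].
#' @return A tibble with one column per attribute (level ordinals) and one
#'   row per distinct profile.
#' @export
enumerate_profiles <- function(schema) {
  attrs <- schema_attributes(schema)
  if (length(attrs) == 0) stop("schema has no attributes", call. = FALSE)
  parts <- schema_split(schema)
  grid <- expand.grid(lapply(parts[attrs], function(a) sort(a$ordinal)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- attrs
  tibble::as_tibble(lapply(grid, as.integer))
}

#' Translate profile ordinals to level wording
#' @param profiles A profile tibble (ordinals).
#' @param schema A [dce_schema()].
#' @return A tibble of the same shape with level labels instead of ordinals.
#' @export
profile_labels <- function(profiles, schema) {
  parts <- schema_split(schema)
  out <- profiles
  for (a in names(profiles)) {
    levs <- parts[[a]]
    out[[a]] <- levs$level[match(profiles[[a]], levs$ordinal)]
  }
  tibble::as_tibble(out)
}

#' Write / read a schema as JSON
#'
#' The JSON layout is an object with a `coding` descriptor and an
#' `attributes` array; each attribute records its name, label, domain, kind,
#' reference ordinal and level array (label, ordinal, numeric value). Labels
#' and numeric values round-trip exactly.
#'
#' @param schema A [dce_schema()].
#' @param path File path.
#' @return `write_schema_json()` returns `path` invisibly;
#'   `read_schema_json()` returns a [dce_schema()].
#' @export
write_schema_json <- function(schema, path) {
  attrs <- lapply(schema_split(schema), function(a) {
    a <- a[order(a$ordinal), ]
    list(
      name = a$attribute[1], label = a$attribute_label[1],
      domain = a$domain[1], kind = a$kind[1],
      reference_ordinal = a$ordinal[a$reference],
      levels = lapply(seq_len(nrow(a)), function(i) {
        lv <- list(label = a$level[i], ordinal = a$ordinal[i])
        if (!is.na(a$numeric_value[i])) lv$numeric_value <- a$numeric_value[i]
        lv
      })
    )
  })
  jsonlite::write_json(list(coding = "dummy", attributes = unname(attrs)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(obj$attributes, function(a) {
    purrr::map_dfr(a$levels, function(lv) {
      tibble::tibble(
        attribute = a$name, attribute_label = a$label,
        domain = a$domain %||% NA_character_, kind = a$kind,
        level = lv$label, ordinal = as.integer(lv$ordinal),
        numeric_value = if (is.null(lv$numeric_value)) NA_real_ else as.numeric(lv$numeric_value),
        reference = as.integer(lv$ordinal) == as.integer(a$reference_ordinal)
      )
    })
  })
  dce_schema(rows)
}

#' @importFrom rlang %||% .data
NULL
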