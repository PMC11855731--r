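#' @importFrom stats aggregate anova lm pf prcomp qtukey rbinom rlnorm rmultinom
#'   rnorm sd setNames t.test
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Treatment vocabulary -------------------------------------------------------

#' Treatment-level constants
#'
#' Factor levels of the factorial priming x heat-wave design: priming UP
#' (unprimed) / HP (hydroprimed); stress NT (8 h imbibition at 25 C, no heat
#' wave; "US" is accepted as an input alias) / HW (4 h at 25 C then 4 h at
#' 40 C). Expression sampling adds the stages DS (dry seed) and DB
#' (post-priming dry-back), which are mutually exclusive with a priming x
#' stress combination.
#'
#' @name treatment-levels
#' @keywords internal
NULL

priming_levels <- function() c("UP", "HP")
stress_levels  <- function() c("NT", "HW")
stage_levels   <- function() c("DS", "DB")

#' Expression sampling groups
#'
#' The six groups at which qPCR expression is sampled: the two stages DS and
#' DB plus the four priming x stress combinations.
#'
#' @return Character vector of group labels.
#' @export
expression_groups <- function() {
  c("DS", "DB", "UP-NT", "UP-HW", "HP-NT", "HP-HW")
}

#' The four factorial treatment groups
#'
#' @return Character vector `c("UP-NT", "UP-HW", "HP-NT", "HP-HW")`.
#' @export
treatment_groups <- function() {
  as.vector(outer(priming_levels(), stress_levels(), paste, sep = "-"))[c(1, 3, 2, 4)]
}

# "US" is the unstressed label used in some figures; canonical form is "NT"
normalize_stress <- function(x) {
  x <- as.character(x)
  x[x == "US"] <- "NT"
  x
}

group_label <- function(priming, stress) paste(priming, stress, sep = "-")

split_group <- function(group) {
  parts <- strsplit(as.character(group), "-", fixed = TRUE)
  data.frame(
    priming = vapply(parts, `[`, "", 1L),
    stress  = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

# Schemas --------------------------------------------------------------------

schema_defs <- function() {
  list(
    germination = c(
      accession = "character", priming = "character", stress = "character",
      replicate = "integer", total_seeds = "integer",
      time_h = "numeric", n_new_germinated = "integer"
    ),
    biometry = c(
      accession = "character", priming = "character", stress = "character",
      replicate = "integer", seedling_id = "integer", category = "character",
      shoot_len_cm = "numeric", root_len_cm = "numeric"
    ),
    comet = c(
      accession = "character", priming = "character", stress = "character",
      replicate = "integer", slide = "integer",
      class_0 = "integer", class_1 = "integer", class_2 = "integer",
      class_3 = "integer", class_4 = "integer"
    ),
    ct = c(
      accession = "character", group = "character", gene = "character",
      tech_rep = "integer", ct = "numeric"
    )
  )
}

#' Names of the supported table schemas
#'
#' @return `c("germination", "biometry", "comet", "ct")`.
#' @export
schema_names <- function() names(schema_defs())

coerce_column <- function(x, type, col) {
  if (type == "character") return(as.character(x))
  raw <- as.character(x)
  num <- suppressWarnings(as.numeric(raw))
  bad <- is.na(num) & !is.na(raw) & trimws(raw) != "" & toupper(raw) != "NA"
  if (any(bad)) {
    stop(sprintf("column '%s': unparseable value(s): %s",
                 col, paste(unique(raw[bad]), collapse = ", ")), call. = FALSE)
  }
  if (type == "integer") {
    frac <- !is.na(num) & num != round(num)
    if (any(frac)) {
      stop(sprintf("column '%s': non-integer value(s): %s",
                   col, paste(unique(raw[frac]), collapse = ", ")), call. = FALSE)
    }
    return(as.integer(round(num)))
  }
  num
}

validate_labels <- function(df, schema) {
  check <- function(col, allowed) {
    vals <- unique(df[[col]])
    bad <- setdiff(vals[!is.na(vals)], allowed)
    if (length(bad)) {
      stop(sprintf("column '%s': unknown label(s) %s; allowed: %s",
                   col, paste(bad, collapse = ", "),
                   paste(allowed, collapse = ", ")), call. = FALSE)
    }
  }
  if ("priming" %in% names(df)) check("priming", priming_levels())
  if ("stress" %in% names(df)) check("stress", stress_levels())
  if (schema == "biometry") {
    check("category", c("normal", "aberrant", "non_germinating"))
  }
  if (schema == "ct") check("group", expression_groups())
  invisible(df)
}

#' Construct a validated study table
#'
#' Coerces a data frame to one of the package's tabular schemas
#' ([schema_names()]), validating column presence, cell parseability and
#' treatment labels. The unstressed alias "US" is canonicalised to "NT".
#'
#' @param df A data frame.
#' @param schema Schema name, one of [schema_names()].
#' @return A `study_table` data frame carrying a `schema` attribute.
#' @export
as_study_table <- function(df, schema) {
  schema <- match.arg(schema, schema_names())
  cols <- schema_defs()[[schema]]
  missing <- setdiff(names(cols), names(df))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing column(s): %s",
                 schema, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- df[names(cols)]
  for (col in names(cols)) {
    out[[col]] <- coerce_column(out[[col]], cols[[col]], col)
  }
  if ("stress" %in% names(out)) out$stress <- normalize_stress(out$stress)
  if ("group" %in% names(out)) {
    out$group[out$group == "UP-US"] <- "UP-NT"
    out$group[out$group == "HP-US"] <- "HP-NT"
  }
  validate_labels(out, schema)
  rownames(out) <- NULL
  structure(out, schema = schema, class = c("study_table", "data.frame"))
}

#' Read a study table from CSV
#'
#' @param path Path to a CSV file whose header matches the named schema.
#' @param schema Schema name, one of [schema_names()].
#' @return A validated `study_table` (see [as_study_table()]).
#' @export
load_table <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = TRUE)
  as_study_table(df, schema)
}

#' Write a study table to CSV
#'
#' Inverse of [load_table()]: a table written and re-read compares equal in
#' values and row order.
#'
#' @param x A `study_table` (or a data frame matching a schema).
#' @param path Output CSV path.
#' @param schema Schema name; defaults to the table's `schema` attribute.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema = attr(x, "schema")) {
  if (is.null(schema)) stop("no schema attribute; supply `schema`", call. = FALSE)
  x <- as_study_table(as.data.frame(x), schema)
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Study design ---------------------------------------------------------------

#' Declare the expected factorial design
#'
#' Describes the design a study table is validated against: which accessions
#' and treatment groups are expected, how many replicate trays per cell, and
#' how many seeds per replicate. The main factorial design of the study is
#' 4 treatment groups x 3 replicates x 20 seeds; the preliminary temperature
#' screening used 10 seeds per replicate, so the seed count is declared
#' metadata rather than a package constant.
#'
#' @param accessions Character vector of accession labels.
#' @param groups Character vector of treatment-group labels
#'   (default [treatment_groups()]).
#' @param replicates Expected replicates (trays) per accession x group cell.
#' @param seeds_per_replicate Expected seeds per replicate tray.
#' @return A `study_design` list.
#' @export
study_design <- function(accessions, groups = treatment_groups(),
                         replicates = 3L, seeds_per_replicate = 20L) {
  accessions <- as.character(accessions)
  if (!length(accessions) || any(!nzchar(accessions))) {
    stop("accession labels must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(accessions)) stop("accession labels must be unique", call. = FALSE)
  structure(list(
    accessions = accessions,
    groups = as.character(groups),
    replicates = as.integer(replicates),
    seeds_per_replicate = as.integer(seeds_per_replicate)
  ), class = "study_design")
}

#' Validate a study table against a declared design
#'
#' Report-only check: lists accession x treatment-group cells missing from
#' the table, replicate counts deviating from the declared number, and (for
#' germination tables) seed counts deviating from the declared seeds per
#' replicate. Seed-count deviations are warnings, never errors. The input
#' table is not modified.
#'
#' @param table A `study_table`.
#' @param expected A [study_design()].
#' @return A `design_report` data frame with columns `severity`, `type`,
#'   `cell`, `detail`; zero rows when the table matches the design.
#' @export
validate_design <- function(table, expected) {
  stopifnot(inherits(expected, "study_design"))
  schema <- attr(table, "schema")
  df <- as.data.frame(table)
  if (identical(schema, "ct")) {
    df$cell_group <- df$group
  } else {
    df$cell_group <- group_label(df$priming, df$stress)
  }
  report <- list()
  add <- function(severity, type, cell, detail) {
    report[[length(report) + 1L]] <<- data.frame(
      severity = severity, type = type, cell = cell, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (acc in expected$accessions) {
    for (grp in expected$groups) {
      sub <- df[df$accession == acc & df$cell_group == grp, , drop = FALSE]
      cell <- paste(acc, grp, sep = " / ")
      if (!nrow(sub)) {
        add("error", "missing_cell", cell, "no records for this cell")
        next
      }
      if (identical(schema, "ct")) next  # ct tables have tech reps, not trays
      reps <- sort(unique(sub$replicate))
      if (length(reps) != expected$replicates ||
          !identical(as.integer(reps), seq_len(expected$replicates))) {
        add("error", "replicate_count", cell,
            sprintf("found replicates {%s}, expected 1..%d",
                    paste(reps, collapse = ","), expected$replicates))
      }
      if (identical(schema, "germination")) {
        for (r in reps) {
          tot <- unique(sub$total_seeds[sub$replicate == r])
          if (length(tot) > 1) {
            add("error", "seed_count", paste0(cell, " / rep ", r),
                "total_seeds not constant within replicate")
          } else if (tot != expected$seeds_per_replicate) {
            add("warning", "seed_count", paste0(cell, " / rep ", r),
                sprintf("total_seeds = %d, declared design has %d",
                        tot, expected$seeds_per_replicate))
          }
        }
      }
    }
  }
  out <- if (length(report)) do.call(rbind, report) else
    data.frame(severity = character(), type = character(),
               cell = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(out, class = c("design_report", "data.frame"))
}

#' @export
print.design_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("design report: no deviations\n")
  } else {
    cat(sprintf("design report: %d deviation(s)\n", nrow(x)))
    print.data.frame(x, ...)
  }
  invisible(x)
}

# Grouped summaries ----------------------------------------------------------

#' Mean, sample SD and n by group
#'
#' Summarises one value column of a long data frame by grouping columns,
#' using the arithmetic mean and the sample (n-1 denominator) standard
#' deviation. `NA` values are dropped with their count recorded.
#'
#' @param df A data frame.
#' @param value Name of the numeric value column.
#' @param by Character vector of grouping column names.
#' @return Data frame with the grouping columns plus `mean`, `sd`, `n`,
#'   `n_missing`. `sd` is `NA` when n < 2.
#' @export
summarize_groups <- function(df, value, by) {
  stopifnot(value %in% names(df), all(by %in% names(df)))
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    v <- df[[value]][idx]
    ok <- !is.na(v)
    head <- df[idx[1], by, drop = FALSE]
    cbind(head,
          data.frame(mean = if (any(ok)) mean(v[ok]) else NA_real_,
                     sd = if (sum(ok) >= 2) sd(v[ok]) else NA_real_,
                     n = sum(ok), n_missing = sum(!ok)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
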