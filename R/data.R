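#' Nested survey dataset with three binary outcomes
#'
#' Validates and wraps individual-level records nested in households nested
#' in clusters.  Outcome columns must be 0/1/NA; a record with any missing
#' outcome is kept but flagged and excluded from fits and tabulations
#' (listwise deletion).  Categorical covariates are dummy-encoded against
#' their declared reference level.
#'
#' @param df data frame with columns `cluster_id`, `household_id`,
#'   `person_id`, `y1`, `y2`, `y3` and any covariate columns.
#' @param covariates list of covariate descriptors as in
#'   [simulation_config()] (only `name`, `type`, and for categoricals
#'   `levels`/`ref` are used here); `NULL` means no covariates.
#' @return an object of class `survey_dataset` with elements `df` (the raw
#'   records), `X` (the encoded model matrix, intercept first),
#'   `covariate_names`, `encoding` (categorical level maps) and `complete`
#'   (logical: all three outcomes observed).
#' @export
survey_dataset <- function(df, covariates = NULL) {
  need <- c("cluster_id", "household_id", "person_id", "y1", "y2", "y3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$cluster_id <- as.character(df$cluster_id)
  df$household_id <- as.character(df$household_id)
  df$person_id <- as.character(df$person_id)
  if (nrow(df) < 1) stop("dataset has no records", call. = FALSE)

  for (v in c("y1", "y2", "y3")) {
    y <- df[[v]]
    bad <- !is.na(y) & !(y %in% c(0, 1))
    if (any(bad))
      stop(sprintf("outcome %s takes values outside {0, 1, NA}: %s", v,
                   paste(unique(y[bad]), collapse = ", ")), call. = FALSE)
    df[[v]] <- as.integer(y)
  }

  # nesting invariant: a household belongs to exactly one cluster
  map <- unique(df[, c("cluster_id", "household_id")])
  dup <- map$household_id[duplicated(map$household_id)]
  if (length(dup))
    stop("household(s) appear under more than one cluster: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  X <- .encode_covariates(df, covariates)
  enc <- .encoding_map(covariates)
  complete <- !is.na(df$y1) & !is.na(df$y2) & !is.na(df$y3)
  structure(list(df = df, X = X,
                 covariate_names = colnames(X)[-1],
                 encoding = enc, complete = complete),
            class = "survey_dataset")
}

.encoding_map <- function(covariates) {
  enc <- list()
  for (cv in covariates) {
    if (identical(cv$type, "categorical")) {
      ref <- cv$ref %||% cv$levels[1]
      enc[[cv$name]] <- list(levels = cv$levels, ref = ref)
    }
  }
  enc
}

.encode_covariates <- function(df, covariates) {
  n <- nrow(df)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in covariates) {
    v <- df[[cv$name]]
    if (is.null(v))
      stop(sprintf("covariate column '%s' not found", cv$name),
           call. = FALSE)
    if (identical(cv$type, "categorical")) {
      ref <- cv$ref %||% cv$levels[1]
      if (!ref %in% cv$levels)
        stop(sprintf("reference '%s' is not a level of '%s'", ref, cv$name),
             call. = FALSE)
      unknown <- setdiff(unique(as.character(v)), cv$levels)
      if (length(unknown))
        stop(sprintf("unknown level(s) in '%s': %s", cv$name,
                     paste(unknown, collapse = ", ")), call. = FALSE)
      for (lev in setdiff(cv$levels, ref))
        cols[[paste0(cv$name, ":", lev)]] <- as.numeric(v == lev)
    } else {
      cols[[cv$name]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf(
    "survey_dataset: %d records (%d complete), %d households, %d clusters\n",
    nrow(x$df), sum(x$complete), length(unique(x$df$household_id)),
    length(unique(x$df$cluster_id))))
  if (length(x$covariate_names))
    cat("covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a survey dataset from CSV
#'
#' Reads RFC-4180 CSV with a header row and validates it against a schema
#' mapping columns to roles.  IDs are treated as opaque strings.  Values
#' listed in `schema$missing_codes` (e.g. `"don't know"`) are mapped to
#' `NA` in the outcome columns before validation; any other non-0/1
#' outcome value is a domain error.
#'
#' @param path CSV path.
#' @param schema a list (or path to a YAML file) with entries `cluster`,
#'   `household`, `person` (optional; a row index is synthesized when
#'   absent), `outcomes` (three column names, in outcome order), and
#'   optionally `covariates` (named list: `"continuous"`, `"binary"`, or a
#'   list with `type = "categorical"`, `levels`, `ref`) and
#'   `missing_codes`.
#' @return a [survey_dataset].
#' @export
read_survey_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1)
    schema <- yaml::read_yaml(schema)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)

  need <- c(schema$cluster, schema$household, schema$person,
            unlist(schema$outcomes), names(schema$covariates))
  unknown <- setdiff(need, names(raw))
  if (length(unknown))
    stop("schema names column(s) absent from the file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(schema$outcomes) != 3)
    stop("schema must name exactly three outcome columns", call. = FALSE)

  df <- data.frame(cluster_id = raw[[schema$cluster]],
                   household_id = raw[[schema$household]],
                   stringsAsFactors = FALSE)
  df$person_id <- if (!is.null(schema$person)) raw[[schema$person]] else
    sprintf("row%d", seq_len(nrow(raw)))
  for (k in 1:3) {
    v <- raw[[schema$outcomes[[k]]]]
    v[v %in% c(schema$missing_codes, "", "NA")] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num)))
      stop(sprintf("outcome column '%s' has non-numeric values not listed in missing_codes",
                   schema$outcomes[[k]]), call. = FALSE)
    df[[paste0("y", k)]] <- num
  }

  covs <- list()
  for (nm in names(schema$covariates)) {
    decl <- schema$covariates[[nm]]
    if (is.character(decl)) decl <- list(type = decl)
    cv <- list(name = nm, type = decl$type, level = decl$level %||% "individual")
    if (identical(decl$type, "categorical")) {
      cv$levels <- decl$levels %||% sort(unique(raw[[nm]]))
      if (is.null(decl$ref))
        stop(sprintf("categorical covariate '%s' must declare a reference level",
                     nm), call. = FALSE)
      cv$ref <- decl$ref
      df[[nm]] <- raw[[nm]]
    } else {
      df[[nm]] <- as.numeric(raw[[nm]])
    }
    covs[[length(covs) + 1L]] <- cv
  }
  survey_dataset(df, covariates = covs)
}

#' Write a survey dataset (and optionally the true random effects) to CSV
#'
#' @param dataset a [survey_dataset].
#' @param path output CSV path.
#' @param effects optional `effects` list from [simulate_survey()]; written
#'   to `effects_path` as a sidecar CSV.
#' @param effects_path sidecar path (default: `path` with `_effects` suffix).
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(dataset, path, effects = NULL,
                             effects_path = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  write.csv(dataset$df, path, row.names = FALSE, quote = TRUE, na = "")
  if (!is.null(effects)) {
    if (is.null(effects_path))
      effects_path <- sub("(\\.csv)?$", "_effects.csv", path)
    ec <- data.frame(level = "cluster", unit = rownames(effects$u_c),
                     u1 = effects$u_c[, 1], u2 = effects$u_c[, 2],
                     u3 = effects$u_c[, 3])
    eh <- data.frame(level = "household", unit = rownames(effects$u_h),
                     u1 = effects$u_h[, 1], u2 = effects$u_h[, 2],
                     u3 = effects$u_h[, 3])
    write.csv(rbind(ec, eh), effects_path, row.names = FALSE)
  }
  invisible(path)
}

# ---- outcome-pattern tabulation -------------------------------------------

.pattern_keys <- function() {
  g <- expand.grid(y3 = 0:1, y2 = 0:1, y1 = 0:1)
  paste0(g$y1, g$y2, g$y3)[order(paste0(g$y1, g$y2, g$y3))]
}

#' Construct a 2^3 outcome-pattern table from counts
#'
#' Keys are strings `"000"`..`"111"` in outcome order (outcome 1, outcome
#' 2, outcome 3).  Patterns absent from `counts` get count zero; all eight
#' keys are always present.
#'
#' @param counts named nonnegative integer vector keyed by pattern.
#' @return an object of class `pattern_table` with `counts`, `total` and
#'   `percentages` (rounded to 2 decimal places).
#' @export
pattern_table <- function(counts) {
  keys <- .pattern_keys()
  bad <- setdiff(names(counts), keys)
  if (length(bad))
    stop("invalid pattern key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  full <- stats::setNames(numeric(8), keys)
  full[names(counts)] <- counts
  total <- sum(full)
  if (total == 0) stop("pattern table is empty", call. = FALSE)
  structure(list(counts = full, total = total,
                 percentages = round(100 * full / total, 2)),
            class = "pattern_table")
}

#' Tabulate the eight joint outcome patterns
#'
#' Counts complete-outcome records over the 2^3 ordered patterns
#' (outcome 1, outcome 2, outcome 3); records with any missing outcome are
#' excluded and reported via the `n_missing` attribute.
#'
#' @param dataset a [survey_dataset].
#' @return a [pattern_table()] with attribute `n_missing`.
#' @export
tabulate_patterns <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  df <- dataset$df[dataset$complete, , drop = FALSE]
  if (nrow(df) == 0)
    stop("no complete-outcome records to tabulate", call. = FALSE)
  key <- paste0(df$y1, df$y2, df$y3)
  tab <- table(factor(key, levels = .pattern_keys()))
  out <- pattern_table(stats::setNames(as.numeric(tab), names(tab)))
  attr(out, "n_missing") <- sum(!dataset$complete)
  out
}

#' Marginal count and percentage of one outcome from a pattern table
#'
#' @param table a [pattern_table()].
#' @param outcome outcome index 1..3.
#' @return numeric vector `c(count, percent)`, the percentage of records
#'   with that outcome equal to 1, rounded to 1 decimal place.
#' @export
marginal_counts <- function(table, outcome) {
  stopifnot(inherits(table, "pattern_table"))
  if (!outcome %in% 1:3) stop("outcome must be 1, 2 or 3", call. = FALSE)
  if (table$total == 0) stop("empty pattern table", call. = FALSE)
  sel <- substr(names(table$counts), outcome, outcome) == "1"
  count <- sum(table$counts[sel])
  c(count = count, percent = round(100 * count / table$total, 1))
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("outcome patterns (outcome1 outcome2 outcome3):\n")
  out <- data.frame(pattern = names(x$counts), count = x$counts,
                    percent = sprintf("%.2f", x$percentages),
                    row.names = NULL)
  print(out, row.names = FALSE)
  cat(sprintf("total: %d complete records\n", as.integer(x$total)))
  nm <- attr(x, "n_missing")
  if (!is.null(nm)) cat(sprintf("excluded (missing outcomes): %d\n", nm))
  invisible(x)
}

#' Export a pattern table as CSV
#'
#' @param table a [pattern_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(table, path) {
  stopifnot(inherits(table, "pattern_table"))
  df <- data.frame(pattern = names(table$counts),
                   count = as.integer(table$counts),
                   percent = table$percentages)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
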