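# Table schemas shared by readers, writers and the pipeline. All interchange
# is UTF-8 CSV with a header row; dates are ISO-8601; region identifiers are
# opaque strings matched exactly ("NATIONAL" marks national trend rows).

table_schemas <- function() {
  list(
    corpus = list(columns = c(id = "character", platform = "character",
                              date = "date", text = "character"),
                  key = "id"),
    trends = list(columns = c(region = "character", word = "character",
                              date = "date", value = "numeric"),
                  key = c("region", "word", "date")),
    population = list(columns = c(region = "character", year = "integer",
                                  population = "numeric"),
                      key = c("region", "year")),
    penetration = list(columns = c(year = "integer", penetration = "numeric"),
                       key = "year"),
    covariates = list(columns = c(region = "character", year = "integer",
                                  setNames(rep("numeric", 8), covariate_names()),
                                  gdp_pc = "numeric"),
                      key = c("region", "year")),
    survey = list(columns = c(region = "character", weight = "numeric",
                              disorder = "integer"),
                  key = character()),
    pod = list(columns = c(word = "character", alpha = "numeric",
                           frequency = "integer"),
               key = "word"),
    cadi = list(columns = c(region = "character", year = "integer",
                            cadi = "numeric", cadi_adjusted = "numeric"),
                key = c("region", "year"))
  )
}

coerce_column <- function(x, type, name) {
  out <- suppressWarnings(switch(type,
                character = as.character(x),
                integer = as.integer(x),
                numeric = as.numeric(x),
                date = as.Date(x),
                stop("unknown schema type ", type)))
  out
}

#' Read and validate a typed CSV table
#'
#' Checks the header against the schema (error listing expected vs found
#' columns), coerces column types, and reports duplicate-key and
#' missing-value violations with file line numbers (header = line 1).
#'
#' @param path Path to a CSV file.
#' @param schema One of `"corpus"`, `"trends"`, `"population"`,
#'   `"penetration"`, `"covariates"`, `"survey"`, `"pod"`, `"cadi"`, or a
#'   schema list with elements `columns` (named character vector of types)
#'   and `key`.
#' @param allow_na Columns in which missing values are tolerated.
#' @return Validated data frame with columns in schema order.
#' @export
read_table <- function(path, schema, allow_na = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema)) {
    schema <- table_schemas()[[match.arg(schema, names(table_schemas()))]]
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  want <- names(schema$columns)
  if (!setequal(names(raw), want)) {
    stop("schema mismatch in ", path, ": expected columns {",
         paste(want, collapse = ", "), "}, found {",
         paste(names(raw), collapse = ", "), "}")
  }
  raw <- raw[, want, drop = FALSE]
  for (col in want) {
    raw[[col]] <- coerce_column(raw[[col]], schema$columns[[col]], col)
    if (!col %in% allow_na && anyNA(raw[[col]])) {
      lines <- which(is.na(raw[[col]])) + 1L
      stop("missing/unparseable values in column '", col, "' of ", path,
           " at line(s) ", paste(head(lines, 5L), collapse = ", "))
    }
  }
  if (length(schema$key)) {
    dup <- duplicated(raw[, schema$key, drop = FALSE])
    if (any(dup)) {
      i <- which(dup)[1L]
      keyval <- paste(unlist(raw[i, schema$key]), collapse = ", ")
      stop("duplicate key (", paste(schema$key, collapse = ", "), ") = (",
           keyval, ") in ", path, " at line ", i + 1L)
    }
  }
  raw
}

#' @rdname read_table
#' @export
read_corpus_csv <- function(path) read_table(path, "corpus")

#' @rdname read_table
#' @export
read_trends_csv <- function(path) read_table(path, "trends")

#' @rdname read_table
#' @export
read_population_csv <- function(path) read_table(path, "population")

#' @rdname read_table
#' @export
read_penetration_csv <- function(path) read_table(path, "penetration")

#' @rdname read_table
#' @export
read_covariates_csv <- function(path) read_table(path, "covariates")

#' @rdname read_table
#' @export
read_survey_csv <- function(path) read_table(path, "survey")

#' @rdname read_table
#' @export
read_pod_csv <- function(path) read_table(path, "pod")

#' @rdname read_table
#' @export
read_cadi_csv <- function(path) read_table(path, "cadi", allow_na = "cadi_adjusted")

#' Write a table as UTF-8 CSV
#'
#' Plain CSV with a header row; numeric columns keep full double precision
#' (15 significant digits), so a write-read round trip preserves values to
#' well under 1e-12 relative error.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
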