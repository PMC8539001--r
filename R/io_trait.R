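#' Trait column names used throughout the package
#'
#' FS = fruit set (%), TNF = total number of fruit per plant, FW = fruit
#' weight (g), YP = yield per plant (kg), TSSC = total soluble solid
#' content (degrees Brix), TA = titratable acidity (g citric acid / 100 g).
#'
#' @export
TRAIT_COLUMNS <- c("FS", "TNF", "FW", "YP", "TSSC", "TA")

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a genotype-by-replicate trait table
#'
#' Reads a delimited text file of phenotype records, one row per genotype x
#' environment x replicate, and validates each row: fruit set must lie in
#' \[0, 100\] and all quantitative traits must be non-negative where present.
#' Missing trait cells stay `NA` (flagged, never silently zeroed).
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param sep Field separator; sniffed from the first line when `NULL`.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`genotype_id`, `environment`, `year`, `replicate`, and
#'   the six traits in [TRAIT_COLUMNS]) to the header names actually used
#'   in the file, e.g. `c(FS = "fruit_set_pct")`.
#' @param required Columns that must be present after mapping. Defaults to
#'   `genotype_id` plus the six trait columns.
#'
#' @return A `data.frame` of class `trait_table` with canonical column
#'   names; row order is preserved.
#' @export
read_trait_table <- function(path, sep = NULL, col_map = NULL,
                             required = c("genotype_id", TRAIT_COLUMNS)) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  if (is.null(sep)) sep <- .sniff_sep(path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop("column '", src, "' (mapped to '", canon, "') missing from ", path)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trait table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in c("environment", "year", "replicate")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  validate_trait_table(df)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Validate trait-table invariants
#'
#' @param df A data.frame with trait columns.
#' @return Invisibly, `df`. Errors name the offending row.
#' @export
validate_trait_table <- function(df) {
  present <- intersect(TRAIT_COLUMNS, names(df))
  if ("FS" %in% present) {
    bad <- which(!is.na(df$FS) & (df$FS < 0 | df$FS > 100))
    if (length(bad)) {
      stop("FS outside [0, 100] at row(s): ", paste(bad, collapse = ", "))
    }
  }
  for (tr in setdiff(present, "FS")) {
    bad <- which(!is.na(df[[tr]]) & df[[tr]] < 0)
    if (length(bad)) {
      stop(tr, " negative at row(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(df)
}

#' Read a cross-design table (hybrid and its two parents)
#'
#' @param path Delimited file with columns `hybrid_id`, `parent1_id`,
#'   `parent2_id`. Lines starting with `#` are ignored.
#' @param sep Field separator; sniffed when `NULL`.
#' @return A `data.frame` of class `cross_design`.
#' @export
read_cross_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cross table not found: ", path)
  if (is.null(sep)) {
    lines <- readLines(path)
    first <- lines[!startsWith(lines, "#")][1]
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  need <- c("hybrid_id", "parent1_id", "parent2_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cross table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  selfed <- which(df$parent1_id == df$parent2_id)
  if (length(selfed)) {
    stop("parent1_id equals parent2_id at row(s): ",
         paste(selfed, collapse = ", "))
  }
  class(df) <- c("cross_design", "data.frame")
  df
}
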