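#' Fruit-record table schema
#'
#' Column names and roles for per-fruit measurement tables. One row is one
#' measured fruit, tied to its treatment (cultivar, substrate volume in L per
#' slab, plants per slab) and replicate block.
#'
#' @return A tibble with columns `column`, `type` and `description`.
#' @export
fruit_table_schema <- function() {
  tibble(
    column = c(
      "cultivar", "substrate_volume", "plants_per_slab", "block",
      "weight", "length", "diameter", "flesh_thickness", "brix", "net_score"
    ),
    type = c(
      "character", "numeric", "integer", "integer",
      "numeric", "numeric", "numeric", "numeric", "numeric", "numeric"
    ),
    description = c(
      "cultivar label",
      "substrate volume per slab (L), > 0",
      "plants per slab, >= 1",
      "replicate block id, >= 1",
      "fruit weight (kg), > 0",
      "fruit length (cm), > 0",
      "fruit diameter (cm), > 0",
      "flesh thickness (mm), > 0",
      "soluble solids (degrees Brix), > 0",
      "panel netting score, 1 (excellent) to 5 (bad)"
    )
  )
}

validate_fruit_table <- function(x, call_label = "fruit table") {
  schema <- fruit_table_schema()
  missing <- setdiff(schema$column, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      call_label, ": missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  bad <- function(cond) which(!is.na(cond) & cond)
  checks <- list(
    "substrate_volume must be > 0" = x$substrate_volume <= 0,
    "plants_per_slab must be >= 1" = x$plants_per_slab < 1,
    "block must be >= 1"           = x$block < 1,
    "weight must be > 0"           = x$weight <= 0,
    "length must be > 0"           = x$length <= 0,
    "diameter must be > 0"         = x$diameter <= 0,
    "flesh_thickness must be > 0"  = x$flesh_thickness <= 0,
    "brix must be > 0"             = x$brix <= 0,
    "net_score must be in [1, 5]"  = x$net_score < 1 | x$net_score > 5
  )
  nas <- which(rowSums(is.na(x[schema$column])) > 0)
  if (length(nas) > 0) {
    abort(paste0(
      call_label, ": missing values at row(s) ",
      paste(head(nas, 10), collapse = ", ")
    ))
  }
  msgs <- purrr::imap_chr(checks, function(cond, msg) {
    rows <- bad(cond)
    if (length(rows) == 0) return(NA_character_)
    paste0(msg, " (row ", paste(head(rows, 10), collapse = ", "), ")")
  })
  msgs <- msgs[!is.na(msgs)]
  if (length(msgs) > 0) {
    abort(paste0(call_label, ": invalid values.\n  ",
                 paste(msgs, collapse = "\n  ")))
  }
  x
}

#' Read a per-fruit measurement table
#'
#' Reads and validates a fruit table from CSV or JSON (an array of row
#' objects). All schema invariants are enforced; violations are reported with
#' row numbers. The derived fruit shape index (length/diameter) is appended as
#' `fruit_shape_index`.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the file extension.
#' @return A validated tibble of fruit records.
#' @seealso [fruit_table_schema()], [write_fruit_table()]
#' @export
read_fruit_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- switch(format,
    csv  = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    json = as_tibble(jsonlite::fromJSON(path))
  )
  x <- validate_fruit_table(x, call_label = basename(path))
  mutate(x, fruit_shape_index = .data$length / .data$diameter)
}

#' Write a per-fruit measurement table
#'
#' Writes the schema columns of a validated fruit table to CSV or JSON.
#' Numeric values are written at 15 significant digits, so a write/read
#' round-trip reproduces every field to that documented precision.
#'
#' @param x Fruit table (tibble).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_fruit_table <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  x <- validate_fruit_table(x)
  x <- select(x, dplyr::all_of(fruit_table_schema()$column))
  switch(format,
    csv  = readr::write_csv(x, path),
    json = jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  )
  invisible(path)
}
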