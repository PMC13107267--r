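# Record and node tables: schema, validation, season classification, CSV IO.

#' Closed vocabularies used throughout the package
#'
#' Interaction layers are two-letter codes: `Pr` predation, `Sc` scavenging,
#' `He` herbivory, `Po` pollination, `Kl` kleptoparasitism, `Co` coprophagy,
#' `De` detritus flow. Realms place each node in the marine, terrestrial or
#' coastal compartment. Seasons are `summer`, `winter` or `unclassified`.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
layer_codes <- function() c("Pr", "Sc", "He", "Po", "Kl", "Co", "De")

#' @rdname vocabularies
#' @export
realm_codes <- function() c("marine", "terrestrial", "coastal")

#' @rdname vocabularies
#' @export
season_codes <- function() c("summer", "winter", "unclassified")

WINTER_MONTHS <- c(11L, 12L, 1L, 2L, 3L)
SUMMER_MONTHS <- 5L:9L

RECORD_COLS <- c("study_id", "pub_year", "consumer", "resource", "layer",
                 "metric_type", "raw_value", "study_months", "study_type",
                 "excluded_review")
NODE_COLS <- c("node_id", "label", "guild", "realm", "n_species", "flagship")

#' Parse a study-month field
#'
#' Months may be given as integers 1-12 or three-letter English abbreviations
#' (case-insensitive), separated by `;`, `,` or `|`. Duplicates are dropped.
#'
#' @param x character scalar (one CSV field) or a vector of month
#'   numbers/abbreviations.
#' @return Sorted integer vector of months (possibly empty).
#' @export
parse_months <- function(x) {
  if (length(x) == 0L) return(integer(0))
  if (length(x) == 1L && is.character(x)) {
    x <- strsplit(x, "[;,|]")[[1]]
    x <- trimws(x)
    x <- x[nzchar(x)]
  }
  if (length(x) == 0L) return(integer(0))
  if (is.numeric(x)) {
    m <- as.integer(x)
  } else {
    m <- suppressWarnings(as.integer(x))
    abb <- match(tolower(x), tolower(month.abb))
    full <- match(tolower(x), tolower(month.name))
    abb[is.na(abb)] <- full[is.na(abb)]
    m[is.na(m)] <- abb[is.na(m)]
  }
  if (anyNA(m) || any(m < 1L | m > 12L))
    stop("unparseable month(s): ", paste(x[is.na(m) | m < 1L | m > 12L],
                                         collapse = ", "))
  sort(unique(m))
}

format_months <- function(m) paste(month.abb[parse_months(m)], collapse = ";")

#' Classify a study period into a season
#'
#' A study is a winter study when the strict majority of its covered months
#' fall in the winter block (November-March) and a summer study when the
#' strict majority fall in the summer block (May-September). April and
#' October belong to neither block. Ties and periods covering neither block
#' are `"unclassified"`.
#'
#' @param study_months months of the study period; anything [parse_months()]
#'   accepts.
#' @return One of `"summer"`, `"winter"`, `"unclassified"`.
#' @examples
#' classify_season(c("Jun", "Jul", "Aug"))   # "summer"
#' classify_season(c(11, 12, 1, 2))          # "winter"
#' classify_season("Apr")                    # "unclassified"
#' classify_season(c(1, 2, 6, 7))            # tie -> "unclassified"
#' @export
classify_season <- function(study_months) {
  m <- parse_months(study_months)
  if (length(m) == 0L) stop("study_months must be non-empty")
  n_w <- sum(m %in% WINTER_MONTHS)
  n_s <- sum(m %in% SUMMER_MONTHS)
  half <- length(m) / 2
  if (n_w > half) "winter" else if (n_s > half) "summer" else "unclassified"
}

# Vectorized over a character column of month-set fields; "" -> "unclassified".
classify_season_vec <- function(month_fields) {
  u <- unique(month_fields)
  cls <- vapply(u, function(f) {
    if (is.na(f) || !nzchar(trimws(f))) "unclassified" else classify_season(f)
  }, character(1))
  unname(cls[match(month_fields, u)])
}

#' Read and validate the node table
#'
#' Expected columns: `node_id`, `label`, `guild`, `realm`, `n_species`,
#' `flagship`.
#'
#' @param path CSV file path.
#' @return A validated `data.frame` of nodes.
#' @export
read_nodes <- function(path) {
  if (!file.exists(path)) stop("node table not found: ", path)
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  validate_nodes(nodes)
}

#' @rdname read_nodes
#' @param nodes a node `data.frame` to validate in place.
#' @export
validate_nodes <- function(nodes) {
  missing <- setdiff(NODE_COLS, names(nodes))
  if (length(missing))
    stop("node table is missing column(s): ", paste(missing, collapse = ", "))
  errs <- character(0)
  if (anyDuplicated(nodes$node_id))
    errs <- c(errs, paste0("duplicated node_id: ",
      paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", ")))
  bad_realm <- which(!nodes$realm %in% realm_codes())
  if (length(bad_realm))
    errs <- c(errs, paste0("row ", bad_realm, ": unknown realm '",
                           nodes$realm[bad_realm], "'"))
  nodes$n_species <- as.integer(nodes$n_species)
  bad_n <- which(is.na(nodes$n_species) | nodes$n_species < 1L)
  if (length(bad_n))
    errs <- c(errs, paste0("row ", bad_n, ": n_species must be a positive integer"))
  nodes$flagship <- as.logical(nodes$flagship)
  if (length(errs))
    stop("invalid node table:\n  ", paste(errs, collapse = "\n  "))
  nodes
}

#' Read and validate literature interaction records
#'
#' One row per study x consumer x resource observation. Expected columns:
#' `study_id`, `pub_year`, `consumer`, `resource`, `layer`, `metric_type`,
#' `raw_value`, `study_months`, `study_type`, `excluded_review`; an optional
#' `species` column names the studied species within the consumer node (used
#' for knowledge scoring). Every `consumer`/`resource` must resolve to a
#' `node_id` in the node table. Malformed rows are reported with their row
#' numbers.
#'
#' @param path records CSV file path.
#' @param nodes node table: a `data.frame` from [read_nodes()] or a CSV path.
#' @param allow_self_loops permit `consumer == resource` rows (off by
#'   default; cannibalism is rarely book-kept in metawebs).
#' @return A list with elements `records` and `nodes`, both validated
#'   `data.frame`s. The records gain a `season` column from
#'   [classify_season()].
#' @export
read_records <- function(path, nodes, allow_self_loops = FALSE) {
  if (!file.exists(path)) stop("records file not found: ", path)
  if (is.character(nodes)) nodes <- read_nodes(nodes)
  recs <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c(study_months = "character"))
  recs <- validate_records(recs, nodes, allow_self_loops = allow_self_loops)
  list(records = recs, nodes = validate_nodes(nodes))
}

#' @rdname read_records
#' @param records an in-memory record `data.frame` to validate.
#' @export
validate_records <- function(records, nodes, allow_self_loops = FALSE) {
  missing <- setdiff(RECORD_COLS, names(records))
  if (length(missing))
    stop("record table is missing column(s): ", paste(missing, collapse = ", "))
  nodes <- validate_nodes(nodes)
  errs <- character(0)
  row_err <- function(rows, msg, vals = NULL) {
    if (!length(rows)) return(character(0))
    if (is.null(vals)) paste0("row ", rows, ": ", msg)
    else paste0("row ", rows, ": ", msg, " '", vals, "'")
  }
  bad <- which(!records$layer %in% layer_codes())
  errs <- c(errs, row_err(bad, "unknown layer code", records$layer[bad]))
  bad <- which(!records$consumer %in% nodes$node_id)
  errs <- c(errs, row_err(bad, "consumer not in node table",
                          records$consumer[bad]))
  bad <- which(!records$resource %in% nodes$node_id)
  errs <- c(errs, row_err(bad, "resource not in node table",
                          records$resource[bad]))
  bad <- which(!records$study_type %in% c("quantitative", "case_study"))
  errs <- c(errs, row_err(bad, "study_type must be 'quantitative' or 'case_study', got",
                          records$study_type[bad]))
  records$raw_value <- as.numeric(records$raw_value)
  bad <- which(!is.na(records$raw_value) & records$raw_value < 0)
  errs <- c(errs, row_err(bad, "negative raw_value"))
  is_quant <- records$study_type == "quantitative"
  bad <- which(is_quant & is.na(records$raw_value))
  errs <- c(errs, row_err(bad, "quantitative record without raw_value"))
  if (!allow_self_loops) {
    bad <- which(records$consumer == records$resource)
    errs <- c(errs, row_err(bad, "self-loop (consumer == resource); set allow_self_loops = TRUE to keep"))
  }
  records$study_months <- as.character(records$study_months)
  records$study_months[is.na(records$study_months)] <- ""
  months_ok <- vapply(records$study_months, function(f) {
    tryCatch({ parse_months(f); TRUE }, error = function(e) FALSE)
  }, logical(1))
  errs <- c(errs, row_err(which(!months_ok), "unparseable study_months",
                          records$study_months[!months_ok]))
  empty_m <- !vapply(records$study_months, function(f) nzchar(trimws(f)),
                     logical(1))
  bad <- which(is_quant & empty_m)
  errs <- c(errs, row_err(bad, "quantitative record without study_months"))
  records$pub_year <- as.integer(records$pub_year)
  errs <- c(errs, row_err(which(is.na(records$pub_year)),
                          "pub_year must be an integer year"))
  records$excluded_review <- as.logical(records$excluded_review)
  if (length(errs))
    stop("invalid record table (", length(errs), " problem(s)):\n  ",
         paste(errs, collapse = "\n  "))
  # canonical month encoding + season, computed once
  records$study_months <- vapply(records$study_months, function(f)
    if (nzchar(trimws(f))) format_months(f) else "", character(1),
    USE.NAMES = FALSE)
  records$season <- classify_season_vec(records$study_months)
  records
}

#' Write record and node tables back to CSV
#'
#' Inverse of [read_records()]: months are serialized as `;`-separated
#' three-letter abbreviations, so a read/write cycle reproduces the table
#' field-for-field.
#'
#' @param records validated record `data.frame`.
#' @param path output CSV path.
#' @export
write_records <- function(records, path) {
  out <- records[, intersect(c(RECORD_COLS, "species"), names(records)),
                 drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @param nodes validated node `data.frame`.
#' @export
write_nodes <- function(nodes, path) {
  utils::write.csv(nodes[, NODE_COLS, drop = FALSE], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
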