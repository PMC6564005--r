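#' Construct a multi-rater, multi-round annotation dataset
#'
#' Bundles annotation records (one per rater, unit and round) with unit
#' metadata (gesture and the intended ground-truth variation) and validates
#' everything against the active decision graph.
#'
#' @param records data frame with columns `rater_id`, `unit_id`, `round`
#'   (1 or 2), `answer_path` (answer tokens joined by `"|"`) and `views`
#'   (non-negative viewing counts joined by `"|"`, one per answered question).
#' @param units data frame with columns `unit_id`, `gesture` (`"knocking"` or
#'   `"direction"`), `intended_category` (`Effort`, `Space`, `Shape`,
#'   `Phrasing` or `Neutral`) and `intended_leaf` (a leaf of `graph`;
#'   `NoChange` if and only if the category is `Neutral`). Extra columns
#'   (e.g. `variation_label`) are carried along.
#' @param graph the `decision_graph` the answer paths must be legal in.
#' @return an object of class `annotation_dataset` with elements `records`,
#'   `units` and `raters`.
#' @export
annotation_dataset <- function(records, units, graph) {
  req_rec <- c("rater_id", "unit_id", "round", "answer_path", "views")
  req_unit <- c("unit_id", "gesture", "intended_category", "intended_leaf")
  if (!all(req_rec %in% names(records))) {
    stop("records need columns: ", paste(req_rec, collapse = ", "))
  }
  if (!all(req_unit %in% names(units))) {
    stop("units need columns: ", paste(req_unit, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  records$rater_id <- as.character(records$rater_id)
  records$unit_id <- as.character(records$unit_id)
  records$round <- as.integer(records$round)
  records$answer_path <- as.character(records$answer_path)
  records$views <- as.character(records$views)
  units$unit_id <- as.character(units$unit_id)

  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id in unit metadata")
  bad_gesture <- !units$gesture %in% c("knocking", "direction")
  if (any(bad_gesture)) {
    stop("unknown gesture '", units$gesture[bad_gesture][1], "'")
  }
  cats <- c("Effort", "Space", "Shape", "Phrasing", "Neutral")
  bad_cat <- !units$intended_category %in% cats
  if (any(bad_cat)) {
    stop("unknown intended_category '", units$intended_category[bad_cat][1], "'")
  }
  leaf_info <- enumerate_paths(graph)
  leaf_cat <- setNames(leaf_info$category, leaf_info$leaf)
  for (i in seq_len(nrow(units))) {
    lf <- units$intended_leaf[[i]]
    if (!lf %in% names(leaf_cat)) {
      stop("unit '", units$unit_id[[i]], "': intended_leaf '", lf,
           "' is not a leaf of graph '", graph$id, "'")
    }
    want <- if (units$intended_category[[i]] == "Neutral") "NoChange" else units$intended_category[[i]]
    if (leaf_cat[[lf]] != want) {
      stop("unit '", units$unit_id[[i]], "': leaf '", lf,
           "' belongs to branch '", leaf_cat[[lf]],
           "', not '", units$intended_category[[i]], "'")
    }
  }

  if (nrow(records)) {
    if (!all(records$round %in% c(1L, 2L))) stop("round must be 1 or 2")
    key <- paste(records$rater_id, records$unit_id, records$round, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1]
      stop("duplicate record for rater '", records$rater_id[[dup]],
           "', unit '", records$unit_id[[dup]], "', round ",
           records$round[[dup]])
    }
    missing_unit <- !records$unit_id %in% units$unit_id
    if (any(missing_unit)) {
      stop("record row ", which(missing_unit)[1], " cites unknown unit '",
           records$unit_id[missing_unit][1], "'")
    }
    for (i in seq_len(nrow(records))) {
      res <- tryCatch(validate_sequence(graph, records$answer_path[[i]]),
                      error = function(e) {
                        stop("record row ", i, ": ", conditionMessage(e),
                             call. = FALSE)
                      })
      v <- suppressWarnings(as.integer(split_path(records$views[[i]])))
      npos <- length(split_path(records$answer_path[[i]]))
      if (anyNA(v) || any(v < 0L) || length(v) != npos) {
        stop("record row ", i, ": views must be ", npos,
             " non-negative integer counts joined by '|'")
      }
    }
  }

  structure(
    list(records = records, units = units,
         raters = sort(unique(records$rater_id), method = "radix")),
    class = "annotation_dataset"
  )
}

#' Read an annotation dataset from a CSV table
#'
#' The table has one row per (rater, unit, round) with columns `rater_id`,
#' `unit_id`, `gesture`, `intended_category`, `intended_leaf`, `round`,
#' `answer_path` (answers joined by `"|"`) and `views` (counts joined by
#' `"|"`). Unit metadata is taken from the distinct unit rows and checked for
#' consistency.
#'
#' @param file path to a CSV file (UTF-8, header row) or a data frame in the
#'   same layout.
#' @param graph the `decision_graph` to validate against.
#' @return an `annotation_dataset`.
#' @export
read_dataset <- function(file, graph) {
  tab <- if (is.data.frame(file)) file else {
    read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  }
  req <- c("rater_id", "unit_id", "gesture", "intended_category",
           "intended_leaf", "round", "answer_path", "views")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("table lacks columns: ", paste(miss, collapse = ", "))
  meta_cols <- setdiff(names(tab), c("rater_id", "round", "answer_path", "views"))
  units <- unique(tab[meta_cols])
  if (anyDuplicated(units$unit_id)) {
    stop("inconsistent unit metadata across rows for unit '",
         units$unit_id[duplicated(units$unit_id)][1], "'")
  }
  rownames(units) <- NULL
  annotation_dataset(
    records = tab[c("rater_id", "unit_id", "round", "answer_path", "views")],
    units = units,
    graph = graph
  )
}

#' Write an annotation dataset to a CSV table
#'
#' Rows are emitted in a deterministic order (unit, rater, round) with unit
#' metadata repeated per row, so that write/read round trips are the identity
#' and identically simulated datasets serialize byte-for-byte identically.
#'
#' @param ds an `annotation_dataset`.
#' @param file path to write; `NULL` (default) returns the data frame instead.
#' @return the flat data frame, invisibly when `file` is given.
#' @export
write_dataset <- function(ds, file = NULL) {
  stopifnot(inherits(ds, "annotation_dataset"))
  meta_cols <- setdiff(names(ds$units), "unit_id")
  tab <- merge(ds$records, ds$units, by = "unit_id", sort = FALSE)
  tab <- tab[c("rater_id", "unit_id", "gesture", "intended_category",
               "intended_leaf",
               setdiff(meta_cols, c("gesture", "intended_category", "intended_leaf")),
               "round", "answer_path", "views")]
  if (nrow(tab)) {
    ord <- order(tab$unit_id, tab$rater_id, tab$round, method = "radix")
    tab <- tab[ord, , drop = FALSE]
  }
  rownames(tab) <- NULL
  if (is.null(file)) return(tab)
  has_sep <- vapply(tab, function(col) any(grepl("[,\"\n]", col)), logical(1))
  if (any(has_sep)) stop("cell values may not contain commas, quotes or newlines")
  write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Restrict a dataset to a subset of units
#'
#' @param ds an `annotation_dataset`.
#' @param unit_ids character vector of unit ids to keep.
#' @return an `annotation_dataset` containing exactly the records and unit
#'   metadata of the selected units.
#' @export
filter_dataset <- function(ds, unit_ids) {
  stopifnot(inherits(ds, "annotation_dataset"))
  keep_u <- ds$units$unit_id %in% unit_ids
  keep_r <- ds$records$unit_id %in% unit_ids
  structure(
    list(records = ds$records[keep_r, , drop = FALSE],
         units = ds$units[keep_u, , drop = FALSE],
         raters = sort(unique(ds$records$rater_id[keep_r]), method = "radix")),
    class = "annotation_dataset"
  )
}

#' @export
print.annotation_dataset <- function(x, ...) {
  cat("<annotation_dataset>\n")
  cat("  raters: ", length(x$raters),
      "   units: ", nrow(x$units),
      "   records: ", nrow(x$records), "\n", sep = "")
  if (nrow(x$units)) {
    cat("  gestures: ",
        paste(sprintf("%s (%d)", names(table(x$units$gesture)),
                      as.integer(table(x$units$gesture))), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
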