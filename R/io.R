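# Reading, labeling, cleaning and writing GlycReSoft-style match tables.

# Required column roles and their default (case-insensitive) header names.
.required_roles <- c(compound_key_raw = "compound key",
                     score = "score",
                     total_volume = "total volume")

# Resolve header names to the three required roles.  column_map is a named
# character vector role -> header name overriding the defaults.
.resolve_columns <- function(headers, column_map = NULL) {
  wanted <- .required_roles
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(wanted))
    if (length(bad))
      stop("unknown column_map role(s): ", paste(bad, collapse = ", "))
    wanted[names(column_map)] <- unlist(column_map)
  }
  idx <- match(tolower(wanted), tolower(trimws(headers)))
  if (anyNA(idx)) {
    missing <- names(wanted)[is.na(idx)]
    stop("input table is missing required column(s) for role(s): ",
         paste(missing, collapse = ", "),
         " (headers seen: ", paste(headers, collapse = ", "), ")")
  }
  stats::setNames(idx, names(wanted))
}

.parse_numeric <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(is.na(x) | trimws(x) == "")
  if (any(bad))
    stop("unparseable ", what, " value(s) in ", path, ": ",
         paste(sQuote(utils::head(x[bad], 5)), collapse = ", "))
  if (any(out < 0, na.rm = TRUE))
    stop("negative ", what, " value(s) in ", path)
  out
}

#' Read a GlycReSoft-style match table
#'
#' Reads one tab-delimited text table as exported per sample/replicate: a
#' header row followed by one candidate match per row, carrying at least a
#' compound key, a score and a total ion volume.  Header names are matched
#' case-insensitively against `"Compound Key"`, `"Score"` and
#' `"Total Volume"`; exports using other names are accommodated with
#' `column_map`.  All remaining columns are kept as passthrough text.
#'
#' @param path Path to the table file.
#' @param label Sample label; defaults to the file name without extension
#'   (each table is identified by its source file).
#' @param column_map Optional named character vector mapping the roles
#'   `compound_key_raw`, `score`, `total_volume` to nonstandard header names.
#' @param delim Field delimiter (default tab; `","` for comma-separated
#'   exports).
#' @return A `sample_table`: a data.frame with columns `sample_label`,
#'   `compound_key_raw`, `score`, `total_volume` and then any passthrough
#'   columns in original order, with attributes `label` and `source_path`.
#'   An empty file (header only) yields a zero-row table.  If the file
#'   carries its own `"Sample Label"` column (as written by
#'   [write_match_table()]) and no `label` is given, per-row labels are
#'   taken from it.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("Compound Key\tScore\tTotal Volume",
#'              "[1,4,5,2,7] 2NH3\t0.5\t1200"), f)
#' read_sample_table(f)
#' @export
read_sample_table <- function(path, label = NULL, column_map = NULL,
                              delim = "\t") {
  if (!file.exists(path))
    stop("no such file: ", path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  idx <- .resolve_columns(names(raw), column_map)
  lab_col <- match("sample label", tolower(trimws(names(raw))))
  if (is.null(label)) {
    if (!is.na(lab_col)) {
      row_labels <- raw[[lab_col]]
      label <- if (nrow(raw)) row_labels[1] else
        tools::file_path_sans_ext(basename(path))
    } else {
      label <- tools::file_path_sans_ext(basename(path))
      row_labels <- rep(label, nrow(raw))
    }
  } else {
    row_labels <- rep(as.character(label), nrow(raw))
  }
  drop_cols <- c(idx, if (!is.na(lab_col)) lab_col)
  extras <- raw[, setdiff(seq_along(raw), drop_cols), drop = FALSE]
  tab <- data.frame(
    sample_label = as.character(row_labels),
    compound_key_raw = as.character(raw[[idx[["compound_key_raw"]]]]),
    score = .parse_numeric(raw[[idx[["score"]]]], "score", path),
    total_volume = .parse_numeric(raw[[idx[["total_volume"]]]],
                                  "total volume", path),
    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, extras)
  rownames(tab) <- NULL
  structure(tab, class = c("sample_table", "data.frame"),
            label = label, source_path = path)
}

#' Drop noise rows with an empty compound key
#'
#' Rows whose compound key is empty (or whitespace-only) are deconvolution
#' noise, not glycan matches, and are always removed before pooling; this
#' also keeps the downstream comparison fast.  Input order is preserved and
#' the operation is idempotent.
#'
#' @param tab A `sample_table` (or any data.frame with a `compound_key_raw`
#'   column).
#' @return The table restricted to rows with a non-empty key.
#' @export
drop_empty_keys <- function(tab) {
  key <- tab$compound_key_raw
  keep <- !is.na(key) & nzchar(trimws(key))
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool several sample tables into one record set
#'
#' Concatenates the tables row-wise into a single record sequence; every
#' record keeps its `sample_label`, so provenance survives pooling (the
#' equivalent of copying all sheets into one total sheet with a label
#' column).  Labels must be pairwise distinct or provenance would be
#' ambiguous.
#'
#' @param tables List of `sample_table` objects (at least 2).
#' @return A data.frame of pooled records, with attribute `labels` giving
#'   the input labels in order.
#' @export
pool_tables <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("pool_tables needs at least 2 tables")
  labels <- vapply(tables, function(t) attr(t, "label") %||%
                     unique(t$sample_label)[1], character(1))
  if (anyDuplicated(labels))
    stop("duplicate sample labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  cols <- unique(unlist(lapply(tables, names)))
  filled <- lapply(tables, function(t) {
    for (cn in setdiff(cols, names(t))) t[[cn]] <- rep("", nrow(t))
    as.data.frame(t)[, cols, drop = FALSE]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write match records or comparison results as tab-delimited text
#'
#' Writes a deterministic, round-trippable TSV: header row first, columns in
#' the fixed order `Sample Label`, `Compound Key`, `Score`, `Total Volume`,
#' then passthrough columns in first-seen order.  Numeric columns are
#' formatted with up to 10 significant digits so that
#' `read_sample_table(write_match_table(x))` reproduces `x` field-for-field
#' at that declared precision.
#'
#' @param x A data.frame of match records, or a `comparison_result` (written
#'   via its own wide layout, see [comparison_wide()]).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_match_table <- function(x, path, delim = "\t") {
  if (inherits(x, "comparison_result"))
    x <- comparison_wide(x)
  lead <- intersect(c("sample_label", "compound_key_raw", "score",
                      "total_volume"), names(x))
  x <- as.data.frame(x)[, c(lead, setdiff(names(x), lead)), drop = FALSE]
  canonical <- c(sample_label = "Sample Label",
                 compound_key_raw = "Compound Key",
                 score = "Score", total_volume = "Total Volume")
  hit <- names(x) %in% names(canonical)
  names(x)[hit] <- canonical[names(x)[hit]]
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 10,
                                               format = "g", flag = ""))
  utils::write.table(x, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
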