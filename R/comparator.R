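# The core comparison: all-presence screening across samples and per-sample
# merging of ammonium-adduct variants.

#' All-presence filter across samples
#'
#' Implements the "all-presence principle": a composition is retained only if
#' it is observed in every one of the K samples (replicates or lots) being
#' compared; compositions missing from any sample are deleted as likely
#' false-positive matches.  Multiple rows per key (adduct variants) count
#' through their distinct sample labels, so a key with four rows spread over
#' all three samples is retained, while a key with many rows confined to two
#' samples is not.
#'
#' @param records Pooled match records (see [pool_tables()]) with non-empty
#'   compound keys.
#' @param labels Character vector of all K sample labels (K >= 2); defaults
#'   to the `labels` attribute of `records`.
#' @return The retained records, relative order preserved, with canonical
#'   keys in a `key` column.
#' @export
all_presence_filter <- function(records, labels = attr(records, "labels")) {
  if (is.null(labels) || length(labels) < 2L)
    stop("all_presence_filter needs the full set of >= 2 sample labels")
  if (!all(records$sample_label %in% labels))
    stop("record(s) labeled outside the declared label set: ",
         paste(unique(setdiff(records$sample_label, labels)), collapse = ", "))
  if (nrow(records) == 0L) {
    records$key <- character(0)
    attr(records, "labels") <- labels
    return(records)
  }
  key <- extract_key(records$compound_key_raw)
  n_labels <- vapply(split(records$sample_label, key),
                     function(l) length(unique(l)), integer(1))
  keep <- key %in% names(n_labels)[n_labels == length(labels)]
  out <- records[keep, , drop = FALSE]
  out$key <- key[keep]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

# Compensated (Kahan) summation: byte-stable totals over a deterministically
# ordered group regardless of later refactoring of the grouping.
kahan_sum <- function(x) {
  s <- 0; comp <- 0
  for (v in x) {
    y <- v - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  s
}

#' Merge adduct-variant rows per composition and sample
#'
#' Within each (key, sample) group of filtered records, the surviving score
#' is the group maximum and the surviving total volume is the group sum:
#' the adduct variants of one composition are collapsed into a single entry
#' whose abundance aggregates all its adduct states.  Passthrough columns
#' are taken from the maximum-score row (the first such row in pooled order
#' on exact score ties).  Volume sums use compensated addition in the fixed
#' pooled order, so outputs are byte-stable.
#'
#' @param records Output of [all_presence_filter()] (records with a `key`
#'   column and a `labels` attribute covering every key).
#' @param profile Key field-order profile (see [parse_composition()]); used
#'   to sort results by (dp, tuple).
#' @return A `comparison_result`: a long-format data.frame with columns
#'   `key`, `dp`, `sample_label`, `score`, `total_volume` plus passthrough
#'   columns, one row per (key, sample), sorted by (dp, key tuple, sample
#'   order); attributes `labels` and `profile`.
#' @export
merge_adduct_groups <- function(records, profile = "enoxaparin") {
  labels <- attr(records, "labels")
  if (is.null(labels))
    stop("records must carry a `labels` attribute (run all_presence_filter)")
  if (is.null(records$key))
    stop("records must carry extracted keys (run all_presence_filter)")
  if (nrow(records) == 0L) {
    out <- data.frame(key = character(0), dp = integer(0),
                      sample_label = character(0), score = numeric(0),
                      total_volume = numeric(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("comparison_result", "data.frame"),
                     labels = labels, profile = profile))
  }
  grp <- split(seq_len(nrow(records)),
               list(key = records$key, label = records$sample_label),
               drop = TRUE)
  merged <- lapply(grp, function(ix) {
    sc <- records$score[ix]
    best <- ix[which.max(sc)]   # first max in pooled order on ties
    row <- records[best, , drop = FALSE]
    row$score <- max(sc)
    row$total_volume <- kahan_sum(records$total_volume[ix])
    row
  })
  out <- do.call(rbind, merged)
  # every retained key must appear under every label
  tab <- table(out$key)
  if (any(tab != length(labels)))
    stop("internal error: merged keys not present under every label; ",
         "all_presence_filter contract violated")
  out$dp <- key_dp(out$key, profile = profile)
  out$compound_key_raw <- NULL
  lead <- c("key", "dp", "sample_label", "score", "total_volume")
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  ord <- order(match(out$key, unique(out$key)[key_order(unique(out$key),
                                                        profile = profile)]),
               match(out$sample_label, labels))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("comparison_result", "data.frame"),
            labels = labels, profile = profile)
}

#' Compare replicate/batch match tables end to end
#'
#' The full pipeline: read each table, drop empty-key noise rows, pool the
#' tables with provenance labels, optionally apply a minimum-score
#' pre-filter, extract canonical keys, apply the all-presence filter, and
#' merge adduct groups.  One log line per stage reports the row counts
#' (raw, non-empty key, retained, merged).
#'
#' @param paths Character vector of >= 2 table files.
#' @param labels Optional sample labels (default: file name stems).
#' @param min_score Optional minimum score applied before the all-presence
#'   filter (disabled by default; a 0.1 threshold is the conventional
#'   pre-screen for low-abundance enoxaparin components).
#' @param column_map,delim Passed to [read_sample_table()].
#' @param profile Key field-order profile (see [parse_composition()]).
#' @param quiet Suppress per-stage log messages.
#' @return A `comparison_result` (see [merge_adduct_groups()]).
#' @export
compare_tables <- function(paths, labels = NULL, min_score = NULL,
                           column_map = NULL, delim = "\t",
                           profile = "enoxaparin", quiet = FALSE) {
  if (length(paths) < 2L)
    stop("compare_tables needs at least 2 input tables")
  if (!is.null(labels) && length(labels) != length(paths))
    stop("labels must match paths in length")
  say <- function(...) if (!quiet) message(...)
  tabs <- lapply(seq_along(paths), function(i) {
    read_sample_table(paths[i], label = labels[i], column_map = column_map,
                      delim = delim)
  })
  say("stage=raw rows=", sum(vapply(tabs, nrow, integer(1))))
  tabs <- lapply(tabs, drop_empty_keys)
  say("stage=nonempty_key rows=", sum(vapply(tabs, nrow, integer(1))))
  pooled <- pool_tables(tabs)
  if (!is.null(min_score)) {
    lab <- attr(pooled, "labels")
    pooled <- pooled[pooled$score >= min_score, , drop = FALSE]
    attr(pooled, "labels") <- lab
    say("stage=min_score rows=", nrow(pooled))
  }
  kept <- all_presence_filter(pooled)
  say("stage=all_presence rows=", nrow(kept),
      " keys=", length(unique(kept$key)))
  res <- merge_adduct_groups(kept, profile = profile)
  say("stage=merged rows=", nrow(res),
      " keys=", length(unique(res$key)))
  res
}

#' Wide layout of a comparison result
#'
#' One row per retained composition, with per-sample `score.<label>` and
#' `total_volume.<label>` columns; used for TSV output.
#'
#' @param res A `comparison_result`.
#' @return Data.frame with columns `key`, `dp`, `anhydro` (if present in the
#'   source), then the per-sample column pairs.
#' @export
comparison_wide <- function(res) {
  stopifnot(inherits(res, "comparison_result"))
  .comparison_wide_impl(res)
}

.comparison_wide_impl <- function(res) {
  stopifnot(inherits(res, "comparison_result"))
  labels <- attr(res, "labels")
  keys <- unique(res$key)
  out <- data.frame(key = keys,
                    dp = res$dp[match(keys, res$key)],
                    stringsAsFactors = FALSE)
  for (lab in labels) {
    sub <- res[res$sample_label == lab, , drop = FALSE]
    i <- match(keys, sub$key)
    out[[paste0("score.", lab)]] <- sub$score[i]
    out[[paste0("total_volume.", lab)]] <- sub$total_volume[i]
  }
  out
}

#' Read a comparison result back from its wide TSV
#'
#' Inverse of [write_match_table()] applied to a `comparison_result`:
#' reconstructs the long format from the `score.<label>` /
#' `total_volume.<label>` column pairs.
#'
#' @param path TSV written from a `comparison_result`.
#' @param profile Key field-order profile.
#' @return A `comparison_result`.
#' @export
read_comparison <- function(path, profile = "enoxaparin") {
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
  sc <- grep("^score\\.", names(wide), value = TRUE)
  labels <- sub("^score\\.", "", sc)
  if (!length(labels) || !"key" %in% names(wide))
    stop("not a comparison-result table: ", path)
  long <- do.call(rbind, lapply(labels, function(lab) {
    data.frame(key = wide$key, dp = as.integer(wide$dp), sample_label = lab,
               score = as.numeric(wide[[paste0("score.", lab)]]),
               total_volume = as.numeric(wide[[paste0("total_volume.", lab)]]),
               stringsAsFactors = FALSE)
  }))
  ord <- order(match(long$key, wide$key), match(long$sample_label, labels))
  long <- long[ord, , drop = FALSE]
  rownames(long) <- NULL
  structure(long, class = c("comparison_result", "data.frame"),
            labels = labels, profile = profile)
}
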