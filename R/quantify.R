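# Relative quantification (top-10 normalization), false-positive-rate
# evaluation and dp-grouped reporting.

#' Normalize abundances to the top-n most abundant components
#'
#' Per sample, components are ranked by merged total volume (descending,
#' ties broken by canonical key order) and the sum of the top `n` volumes is
#' used as the denominator; every component's normalized abundance is its
#' volume divided by that denominator.  When ties straddle rank `n`, all
#' keys tied with the rank-n volume are included in the denominator, so the
#' denominator is deterministic.  With fewer than `n` components, all
#' volumes enter the denominator and the abundances sum to 1.
#'
#' @param res A `comparison_result` (see [merge_adduct_groups()]).
#' @param n Number of most-abundant components defining the denominator
#'   (default 10).
#' @return `res` with an extra `normalized` column (abundance relative to
#'   the per-sample top-n volume sum, reported for all keys).
#' @export
top_n_normalize <- function(res, n = 10L) {
  stopifnot(inherits(res, "comparison_result"), n >= 1L)
  if (nrow(res) == 0L)
    stop("cannot normalize an empty comparison result")
  profile <- attr(res, "profile") %||% "enoxaparin"
  res$normalized <- NA_real_
  for (lab in unique(res$sample_label)) {
    ix <- which(res$sample_label == lab)
    vol <- res$total_volume[ix]
    if (all(vol == 0))
      stop("all volumes are zero for sample ", sQuote(lab),
           "; normalization denominator undefined")
    ko <- key_order(res$key[ix], profile = profile)
    ord <- ix[ko][order(-vol[ko])]          # stable: volume desc, key order
    topvol <- res$total_volume[ord][seq_len(min(n, length(ord)))]
    thr <- min(topvol)
    denom <- kahan_sum(res$total_volume[ix][vol >= thr])
    res$normalized[ix] <- res$total_volume[ix] / denom
  }
  res
}

#' Read a truth annotation file
#'
#' One canonical key per line; `#` starts a comment; blank lines ignored.
#' Keys are canonicalized via [extract_key()] and validated as compositions.
#'
#' @param path Truth file path.
#' @param profile Key field-order profile for validation.
#' @return Character vector of canonical true keys.
#' @export
read_truth <- function(path, profile = "enoxaparin") {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("truth file is empty: ", path)
  keys <- extract_key(lines)
  for (k in keys) parse_composition(k, profile = profile)
  unique(keys)
}

#' Evaluate the false-positive rate against a truth set
#'
#' Compares the retained composition keys with a manually confirmed truth
#' set.  Because the all-presence filter forces identical key sets across
#' replicates, one rate describes the whole run.
#'
#' @param res A `comparison_result`, or a character vector of retained keys.
#' @param truth Character vector of true keys (see [read_truth()]).
#' @return List with `retained` (number of distinct retained keys),
#'   `false_positive_rate` (`(retained - true positives) / retained`; `NA`
#'   with a message when nothing was retained), and `false_negatives`
#'   (true keys not retained).
#' @examples
#' fdr_evaluate(c("[1,2,3,0,4]", "[1,2,3,0,5]"), "[1,2,3,0,4]")
#' @export
fdr_evaluate <- function(res, truth) {
  keys <- if (inherits(res, "comparison_result")) unique(res$key)
          else unique(as.character(res))
  truth <- unique(as.character(truth))
  if (!length(truth)) stop("truth set is empty")
  retained <- length(keys)
  if (retained == 0L) {
    message("no components retained; false-positive rate undefined")
    return(list(retained = 0L, false_positive_rate = NA_real_,
                false_negatives = length(truth)))
  }
  tp <- length(intersect(keys, truth))
  list(retained = retained,
       false_positive_rate = (retained - tp) / retained,
       false_negatives = length(setdiff(truth, keys)))
}

#' Report normalized abundances grouped by dp and anhydro status
#'
#' A wide table suitable for bar-chart plotting: rows ordered by (anhydro,
#' dp, key tuple), one normalized-abundance column per sample.
#'
#' @param res A `comparison_result` carrying a `normalized` column (see
#'   [top_n_normalize()]).
#' @param anhydro Logical flag recorded for these results (which hypothesis
#'   variant the tables were matched against); a single value or one per
#'   key.
#' @return Data.frame with columns `anhydro`, `dp`, `key`, then one column
#'   `<label>` of normalized abundance per sample.
#' @export
grouped_report <- function(res, anhydro = FALSE) {
  stopifnot(inherits(res, "comparison_result"))
  if (is.null(res$normalized))
    stop("run top_n_normalize() first")
  labels <- attr(res, "labels")
  profile <- attr(res, "profile") %||% "enoxaparin"
  keys <- unique(res$key)
  if (length(anhydro) == 1L) anhydro <- rep(anhydro, length(keys))
  if (length(anhydro) != length(keys))
    stop("anhydro must be length 1 or one value per key")
  out <- data.frame(anhydro = anhydro, dp = res$dp[match(keys, res$key)],
                    key = keys, stringsAsFactors = FALSE)
  for (lab in labels) {
    sub <- res[res$sample_label == lab, , drop = FALSE]
    out[[lab]] <- sub$normalized[match(keys, sub$key)]
  }
  key_rank <- match(seq_along(keys), key_order(keys, profile = profile))
  ord <- order(out$anhydro, key_rank)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
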