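# Synthetic replicate-table generator with planted ground truth, so the
# whole pipeline is testable without any instrument data.

#' Specification of a synthetic replicate data set
#'
#' Describes K replicate match tables with planted ground truth emulating
#' the structure of real exports: true components present in every
#' replicate and split across several ammonium-adduct rows, decoy
#' components (false-positive matches) present in a strict subset of the
#' replicates, and noise rows with an empty compound key.  Row volumes are
#' drawn log-normal (ion volumes are heavy-tailed) and scores uniform on
#' (0, 1).
#'
#' The noise fraction is the fraction of each file's rows that are
#' empty-key noise: a file with P planted rows gets
#' `round(P * noise_fraction / (1 - noise_fraction))` noise rows, so at
#' `noise_fraction = 0.5` noise doubles the file.
#'
#' @param k_samples Number of replicates/lots (>= 2; default 3, the
#'   conventional comparison width).
#' @param n_true Number of true components planted in every replicate.
#' @param n_decoy Number of decoy components, each planted in a uniformly
#'   chosen strict subset of replicates (never all of them).
#' @param adduct_rows Integer range `c(lo, hi)`: rows per component per
#'   replicate, each row carrying a distinct NH3 adduct annotation.
#' @param noise_fraction Fraction of rows that are empty-key noise, in
#'   `[0, 1)`.
#' @param vol_meanlog,vol_sdlog Log-normal volume parameters (defaults
#'   `log(1e4)` and 1: volumes centered on 1e4 arbitrary units spanning
#'   roughly two orders of magnitude, like deconvoluted ion volumes).
#' @param discretize Round volumes to 2 decimals (integer cents) so that
#'   merged sums are exactly reproducible; on by default.
#' @param seed Integer seed; the whole data set is a deterministic function
#'   of the spec (R's default Mersenne-Twister generator).
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(k_samples = 3L, n_true = 10L, n_decoy = 15L,
                           adduct_rows = c(1L, 3L), noise_fraction = 0.3,
                           vol_meanlog = log(1e4), vol_sdlog = 1,
                           discretize = TRUE, seed = 1L) {
  if (k_samples < 2L) stop("k_samples must be >= 2")
  if (n_true < 0L || n_decoy < 0L) stop("n_true and n_decoy must be >= 0")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must be in [0, 1)")
  if (length(adduct_rows) != 2L || adduct_rows[1] < 1L ||
      adduct_rows[2] < adduct_rows[1] || adduct_rows[2] > 15L)
    stop("adduct_rows must be c(lo, hi) with 1 <= lo <= hi <= 15")
  structure(list(k_samples = as.integer(k_samples),
                 n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
                 adduct_rows = as.integer(adduct_rows),
                 noise_fraction = noise_fraction,
                 vol_meanlog = vol_meanlog, vol_sdlog = vol_sdlog,
                 discretize = isTRUE(discretize), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample distinct compositions from the hypothesis space
#'
#' Draws `n` distinct compositions uniformly without replacement from the
#' composition set of [enumerate_hypothesis()] (adduct states collapsed).
#'
#' @param n Number of compositions.
#' @param p A [hypothesis_params()] object.
#' @param seed Optional integer seed.
#' @return Character vector of `n` canonical keys.
#' @export
sample_compositions <- function(n, p = hypothesis_params(), seed = NULL) {
  space <- unique(enumerate_hypothesis(
    hypothesis_params(dHexA_choices = p$dHexA_choices,
                      hexA_max = p$hexA_max, ac_max = p$ac_max,
                      nh3_max = 0L, mw_min = p$mw_min, mw_max = p$mw_max,
                      dp_max = p$dp_max, anhydro = p$anhydro,
                      mw_on = p$mw_on))$key)
  if (length(space) == 0L) stop("hypothesis space is empty")
  if (n > length(space))
    stop("requested ", n, " compositions from a space of ", length(space))
  draw <- function() space[sample.int(length(space), n)]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# One file's planted rows for a set of (key, n-adduct-rows) assignments.
.plant_rows <- function(keys, n_rows_each, spec) {
  rows <- lapply(seq_along(keys), function(i) {
    nr <- n_rows_each[i]
    adducts <- sort(sample.int(15L, nr) - 1L)     # distinct n_nh3 in 0..14
    vol <- stats::rlnorm(nr, spec$vol_meanlog, spec$vol_sdlog)
    if (spec$discretize) vol <- round(vol, 2)
    data.frame(
      compound_key_raw = ifelse(adducts == 0L, keys[i],
                                sprintf("%s %dNH3", keys[i], adducts)),
      score = round(stats::runif(nr), 4),
      total_volume = vol, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic replicate data set on disk
#'
#' Writes `k_samples` tab-delimited match tables in the reader's dialect
#' (header `Compound Key`, `Score`, `Total Volume`) plus planted ground
#' truth: every true component appears in every file (split across several
#' adduct rows), every decoy in a strict subset of files, and empty-key
#' noise rows are interleaved.  Fully reproducible from the seed: the same
#' spec always yields byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @param params Hypothesis parameters defining the composition space the
#'   components are drawn from.
#' @return List with `paths` (the K file paths), `labels`, `truth`
#'   (character vector of true keys), `decoys`, and `ledger` (data.frame
#'   with one row per planted (key, label): `key`, `sample_label`,
#'   `n_rows`, `expected_volume` — the exact merged volume — and
#'   `expected_score` — the expected maximum score).
#' @examples
#' d <- generate_dataset(synthetic_spec(n_true = 3, n_decoy = 2, seed = 7),
#'                       tempfile("synthdata"))
#' length(d$truth)
#' @export
generate_dataset <- function(spec, out_dir, params = hypothesis_params()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_true + spec$n_decoy < 1L)
    stop("nothing to plant: n_true + n_decoy must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- sprintf("rep%d", seq_len(spec$k_samples))
  withr::with_seed(spec$seed, {
    keys <- sample_compositions(spec$n_true + spec$n_decoy, params)
    truth <- keys[seq_len(spec$n_true)]
    decoys <- setdiff(keys, truth)
    # decoy presence: uniformly chosen strict subset of samples
    decoy_sets <- lapply(decoys, function(k) {
      sz <- sample.int(spec$k_samples - 1L, 1L)
      sort(sample.int(spec$k_samples, sz))
    })
    files <- vector("list", spec$k_samples)
    ledger <- list()
    for (s in seq_len(spec$k_samples)) {
      here <- c(truth,
                decoys[vapply(decoy_sets, function(ix) s %in% ix,
                              logical(1))])
      nr <- sample(seq(spec$adduct_rows[1], spec$adduct_rows[2]),
                   length(here), replace = TRUE)
      planted <- .plant_rows(here, nr, spec)
      n_noise <- round(nrow(planted) * spec$noise_fraction /
                         (1 - spec$noise_fraction))
      if (n_noise > 0) {
        vol <- stats::rlnorm(n_noise, spec$vol_meanlog, spec$vol_sdlog)
        if (spec$discretize) vol <- round(vol, 2)
        noise <- data.frame(compound_key_raw = rep("", n_noise),
                            score = round(stats::runif(n_noise), 4),
                            total_volume = vol, stringsAsFactors = FALSE)
        planted <- rbind(planted, noise)
      }
      planted <- planted[sample.int(nrow(planted)), , drop = FALSE]
      files[[s]] <- planted
      key_of <- rep(NA_character_, nrow(planted))
      nz <- nzchar(planted$compound_key_raw)
      key_of[nz] <- extract_key(planted$compound_key_raw[nz])
      for (k in here) {
        ix <- which(!is.na(key_of) & key_of == k)
        ledger[[length(ledger) + 1L]] <- data.frame(
          key = k, sample_label = labels[s], n_rows = length(ix),
          expected_volume = kahan_sum(planted$total_volume[ix]),
          expected_score = max(planted$score[ix]),
          stringsAsFactors = FALSE)
      }
    }
  })
  paths <- file.path(out_dir, paste0(labels, ".txt"))
  for (s in seq_along(paths)) {
    df <- files[[s]]
    df$score <- formatC(df$score, digits = 4, format = "f")
    df$total_volume <- formatC(df$total_volume, digits = 2, format = "f")
    names(df) <- c("Compound Key", "Score", "Total Volume")
    utils::write.table(df, paths[s], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL
  list(paths = paths, labels = labels, truth = truth, decoys = decoys,
       ledger = ledger)
}
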