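# Independent oracles used across the suite.  Each is deliberately written
# along a different computational path from the implementation it checks.

# --- element-sum mass oracle: assemble the full molecular formula of a
# composition and sum atomic monoisotopic masses (own atomic table).
oracle_atomic <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)

oracle_mass <- function(dHexA, hexA, glcN, ac, so3, anhydro = FALSE) {
  el <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  add <- function(el, n, C = 0, H = 0, N = 0, O = 0, S = 0)
    el + n * c(C = C, H = H, N = N, O = O, S = S)
  el <- if (anhydro) add(el, dHexA, C = 6, H = 4, O = 4)
        else add(el, dHexA, C = 6, H = 6, O = 5)
  el <- add(el, hexA, C = 6, H = 8, O = 6)
  el <- add(el, glcN, C = 6, H = 11, N = 1, O = 4)
  el <- add(el, ac, C = 2, H = 2, O = 1)
  el <- add(el, so3, S = 1, O = 3)
  el <- add(el, 1, H = 2, O = 1)          # terminal water
  sum(el * oracle_atomic[names(el)])
}

# --- brute-force hypothesis oracle: full grid then filter (no nested
# constraint-aware loops).
oracle_hypothesis <- function(p) {
  g <- expand.grid(A = 0:1, B = 0:p$hexA_max, C = 0:(p$hexA_max + 2L),
                   D = 0:p$ac_max, E = 0:(2L * (p$hexA_max + 2L) + 12L),
                   n = 0:p$nh3_max)
  keep <- g$A %in% p$dHexA_choices &
    g$C >= pmax(0L, g$A + g$B - 1L) & g$C <= g$A + g$B + 1L &
    g$D <= g$C &
    g$E >= g$B & g$E <= g$A + g$B + 2L * g$C + 1L - g$D &
    g$A + g$B + g$C >= 1L & g$A + g$B + g$C <= p$dp_max
  g <- g[keep, , drop = FALSE]
  m0 <- mapply(function(A, B, C, D, E)
    oracle_mass(A, B, C, D, E, anhydro = p$anhydro),
    g$A, g$B, g$C, g$D, g$E)
  m <- m0 + g$n * (oracle_atomic[["N"]] + 3 * oracle_atomic[["H"]])
  mw <- if (p$mw_on == "adducted") m else m0
  keep <- mw >= p$mw_min & mw <= p$mw_max
  data.frame(key = sprintf("[%d,%d,%d,%d,%d]", g$A, g$B, g$C, g$D, g$E),
             n_nh3 = g$n, mass = m, stringsAsFactors = FALSE)[keep, ]
}

# --- naive comparison oracle: per-label key sets -> intersection -> group
# by (key, label) with max/sum.
oracle_compare <- function(records, labels) {
  keys <- extract_key(records$compound_key_raw)
  shared <- Reduce(intersect, lapply(labels, function(l)
    unique(keys[records$sample_label == l])))
  kept <- records[keys %in% shared, , drop = FALSE]
  kept$key <- keys[keys %in% shared]
  if (nrow(kept) == 0L)
    return(data.frame(key = character(0), sample_label = character(0),
                      score = numeric(0), total_volume = numeric(0)))
  agg <- do.call(rbind, lapply(split(kept, list(kept$key,
                                                kept$sample_label),
                                     drop = TRUE), function(g)
    data.frame(key = g$key[1], sample_label = g$sample_label[1],
               score = max(g$score), total_volume = sum(g$total_volume),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$key, agg$sample_label), ]
}

# --- literal simulator of the merging pseudocode: stable sort by key, then
# walk adjacent rows bottom-up, folding volume into the higher-scoring row
# (ties keep the earlier-sorted row).
oracle_merge_simulator <- function(records) {
  df <- records[order(records$key), , drop = FALSE]   # stable radix sort
  rownames(df) <- NULL
  I <- nrow(df)
  while (I >= 2L) {
    J <- I - 1L
    if (df$key[I] == df$key[J] &&
        df$sample_label[I] == df$sample_label[J]) {
      if (df$score[I] <= df$score[J]) {
        df$total_volume[J] <- df$total_volume[J] + df$total_volume[I]
        df <- df[-I, , drop = FALSE]
        I <- J
      } else {
        df$total_volume[I] <- df$total_volume[I] + df$total_volume[J]
        df <- df[-J, , drop = FALSE]
        I <- I - 1L
      }
    } else {
      I <- J
    }
  }
  rownames(df) <- NULL
  df
}

# --- random pooled record sets (per-label contiguous, like real pooling).
# Integer volumes so all sums are exact in double arithmetic.
random_records <- function(seed, k = 3L, max_keys = 8L, max_rows = 20L) {
  withr::with_seed(seed, {
    labels <- sprintf("lot%d", seq_len(k))
    pool <- sprintf("[%d,%d,%d,%d,%d]", sample(0:1, max_keys, TRUE),
                    sample(0:5, max_keys, TRUE), sample(1:6, max_keys, TRUE),
                    sample(0:3, max_keys, TRUE), sample(0:9, max_keys, TRUE))
    pool <- unique(pool)
    tabs <- lapply(labels, function(lab) {
      n <- sample.int(max_rows, 1L)
      keys <- sample(pool, n, replace = TRUE)
      adduct <- sample(0:5, n, replace = TRUE)
      data.frame(
        sample_label = lab,
        compound_key_raw = ifelse(adduct == 0L, keys,
                                  sprintf("%s %dNH3", keys, adduct)),
        score = round(stats::runif(n), 3),
        total_volume = as.numeric(sample.int(100000L, n, replace = TRUE)),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    attr(out, "labels") <- labels
    out
  })
}

# write a small sample table file; returns path
write_fixture <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

fdr_fixture_dir <- function() {
  system.file("extdata", "fdr_synthetic", package = "heparcomp")
}
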