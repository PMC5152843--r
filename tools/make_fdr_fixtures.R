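#!/usr/bin/env Rscript
# Builds the SYNTHETIC stand-in fixtures under inst/extdata/fdr_synthetic/.
#
# The original false-discovery-rate investigation used LC-MS match tables of
# four chemoenzymatically synthesized heparin oligosaccharides (A-D), three
# replicates each, distributed only as a supplementary spreadsheet that is
# not available in this repository.  These files are a synthetic stand-in
# built to the published summary structure, NOT the original data:
#   A: 23/18/19 match records per replicate, 5 components present in all
#      three replicates, 3 of them true          -> FP rate 40%
#   B: 8 retained, 3 true                        -> FP rate 62.5%
#   C: 6 retained, 3 true                        -> FP rate 50%
#   D: 5 retained, 3 true                        -> FP rate 40%
# Keys use the synthesized-standard dialect [HexA, GlcN, PNP = 1, SO3, Ac].
# Deterministic: fixed seed, fixed formatting.  Run from the package root:
#   Rscript tools/make_fdr_fixtures.R

set.seed(20161212L)
out_dir <- "inst/extdata/fdr_synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rand_key <- function(n) {
  sprintf("[%d,%d,1,%d,%d]", sample(1:6, n, TRUE), sample(1:6, n, TRUE),
          sample(0:12, n, TRUE), sample(0:2, n, TRUE))
}

row_block <- function(keys, adducts) {
  raw <- ifelse(adducts == 0L, keys, sprintf("%s %dNH3", keys, adducts))
  data.frame(`Compound Key` = raw,
             Score = formatC(round(runif(length(keys)), 4), digits = 4,
                             format = "f"),
             `Total Volume` = formatC(round(rlnorm(length(keys),
                                                   log(1e4), 1), 2),
                                      digits = 2, format = "f"),
             check.names = FALSE, stringsAsFactors = FALSE)
}

make_oligo <- function(name, shared_keys, true_keys, rep_totals,
                       shared_rows_per_rep) {
  stopifnot(all(true_keys %in% shared_keys))
  used <- shared_keys
  for (r in seq_along(rep_totals)) {
    ns <- shared_rows_per_rep[r]
    skeys <- rep(shared_keys, each = ns)
    adducts <- unlist(lapply(seq_along(shared_keys), function(i)
      sample(0:6, ns)))
    n_decoy <- rep_totals[r] - length(skeys)
    stopifnot(n_decoy >= 0)
    repeat {
      dkeys <- unique(rand_key(n_decoy * 2))
      dkeys <- setdiff(dkeys, used)
      if (length(dkeys) >= n_decoy) break
    }
    dkeys <- dkeys[seq_len(n_decoy)]
    used <- c(used, dkeys)     # decoys unique across reps -> never shared
    block <- rbind(row_block(skeys, adducts),
                   row_block(dkeys, sample(0:6, n_decoy, TRUE)))
    block <- block[sample.int(nrow(block)), , drop = FALSE]
    f <- file.path(out_dir, sprintf("oligo%s_rep%d_synthetic.txt", name, r))
    write.table(block, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c("# SYNTHETIC truth annotation (stand-in, not original data)",
               true_keys),
             file.path(out_dir, sprintf("oligo%s_truth_synthetic.txt", name)))
}

shared <- list(
  A = c("[3,3,1,6,0]", "[3,3,1,5,0]", "[3,3,1,7,0]",   # true
        "[2,4,1,6,1]", "[4,2,1,8,0]"),
  B = c("[3,3,1,8,0]", "[3,3,1,9,0]", "[3,3,1,10,0]",
        "[2,3,1,7,1]", "[4,3,1,9,0]", "[3,4,1,8,1]",
        "[2,2,1,5,0]", "[4,4,1,11,0]"),
  C = c("[2,2,1,4,0]", "[2,2,1,5,0]", "[2,2,1,3,0]",
        "[3,1,1,4,1]", "[1,3,1,5,0]", "[2,3,1,6,0]"),
  D = c("[4,4,1,10,0]", "[4,4,1,11,0]", "[4,4,1,12,0]",
        "[3,5,1,10,1]", "[5,3,1,9,0]"))

# rep_totals: match records per replicate; shared_rows_per_rep: adduct rows
# per shared component per replicate (shared * rows + decoys = total).
make_oligo("A", shared$A, shared$A[1:3], c(23L, 18L, 19L), c(2L, 1L, 1L))
make_oligo("B", shared$B, shared$B[1:3], c(20L, 22L, 21L), c(1L, 1L, 1L))
make_oligo("C", shared$C, shared$C[1:3], c(15L, 16L, 17L), c(1L, 1L, 1L))
make_oligo("D", shared$D, shared$D[1:3], c(14L, 13L, 15L), c(1L, 1L, 1L))
cat("wrote fixtures to", out_dir, "\n")
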