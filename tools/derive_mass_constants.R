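#!/usr/bin/env Rscript
# Derivation of the hard-coded residue masses in R/composition.R from
# standard atomic monoisotopic masses (CODATA/IUPAC values).
atomic <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
            O = 15.9949146196, S = 31.97207100)
f <- function(C = 0, H = 0, N = 0, O = 0, S = 0)
  sum(atomic * c(C, H, N, O, S))
consts <- c(
  m_dHexA         = f(C = 6, H = 6, O = 5),   # 4,5-unsaturated uronic acid
  m_dHexA_anhydro = f(C = 6, H = 4, O = 4),   # with 1,6-anhydro RE chain
  m_hexA          = f(C = 6, H = 8, O = 6),   # hexuronic acid residue
  m_glcN          = f(C = 6, H = 11, N = 1, O = 4),  # hexosamine residue
  m_ac            = f(C = 2, H = 2, O = 1),   # N-acetyl increment
  m_so3           = f(S = 1, O = 3),          # sulfo increment
  m_h2o           = f(H = 2, O = 1),
  m_nh3           = f(N = 1, H = 3)
)
cat(sprintf("%-16s = %.10f\n", names(consts), consts))
stopifnot(abs(consts["m_dHexA"] - consts["m_dHexA_anhydro"] -
                consts["m_h2o"]) < 1e-9)
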