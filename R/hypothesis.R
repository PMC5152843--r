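# Enoxaparin intact-chain composition hypothesis: enumeration and ppm
# matching of deconvoluted masses.

#' Parameters of the intact-chain composition hypothesis
#'
#' Encodes the constraint box that defines plausible enoxaparin intact-chain
#' compositions.  Writing A = dHexA, B = HexA, C = GlcN, D = Ac, E = SO3,
#' the defaults enumerate:
#' \itemize{
#'   \item A in \{0, 1\} (non-reducing end unsaturated or saturated);
#'   \item 0 <= B <= 9;
#'   \item max(0, A + B - 1) <= C <= A + B + 1 (backbone alternation allows
#'     the hexosamine count to differ from the uronic acid count by at most
#'     one; the lower bound is clamped at 0 when A = B = 0);
#'   \item 0 <= D <= min(3, C) (no more N-acetyl groups than hexosamines);
#'   \item B <= E <= A + B + 2C + 1 - D (available sulfation positions);
#'   \item dp = A + B + C <= 18;
#'   \item 0 to 14 ammonium adducts;
#'   \item unadducted monoisotopic mass between 500 and 6000 Da.
#' }
#'
#' @param dHexA_choices Integer subset of `c(0, 1)` allowed for A.
#' @param hexA_max Maximum B.
#' @param ac_max Maximum D (additionally capped at C).
#' @param nh3_max Maximum ammonium adduct count.
#' @param mw_min,mw_max Molecular weight window in Da.
#' @param dp_max Maximum degree of polymerization (A + B + C).
#' @param match_error_ppm Default ppm tolerance for [match_mass()].
#' @param anhydro Logical; enumerate the 1,6-anhydro reducing-end variant
#'   (forces A = 1 and uses the anhydro residue mass).
#' @param mw_on One of `"unadducted"` (default: the MW window describes the
#'   bare chain; adducts are a mass shift on top) or `"adducted"`.
#' @return Object of class `"hypothesis_params"` (a named list).
#' @export
hypothesis_params <- function(dHexA_choices = c(0L, 1L), hexA_max = 9L,
                              ac_max = 3L, nh3_max = 14L,
                              mw_min = 500, mw_max = 6000, dp_max = 18L,
                              match_error_ppm = 5.0, anhydro = FALSE,
                              mw_on = c("unadducted", "adducted")) {
  mw_on <- match.arg(mw_on)
  dHexA_choices <- sort(unique(as.integer(dHexA_choices)))
  if (!all(dHexA_choices %in% c(0L, 1L)))
    stop("dHexA_choices must be a subset of {0, 1}")
  if (isTRUE(anhydro)) dHexA_choices <- 1L
  if (mw_min >= mw_max) stop("mw_min must be < mw_max")
  if (min(hexA_max, ac_max, nh3_max, dp_max, mw_min) < 0)
    stop("all bounds must be >= 0")
  structure(list(dHexA_choices = dHexA_choices,
                 hexA_max = as.integer(hexA_max),
                 ac_max = as.integer(ac_max), nh3_max = as.integer(nh3_max),
                 mw_min = mw_min, mw_max = mw_max,
                 dp_max = as.integer(dp_max),
                 match_error_ppm = match_error_ppm,
                 anhydro = isTRUE(anhydro), mw_on = mw_on),
            class = "hypothesis_params")
}

#' Enumerate the composition hypothesis
#'
#' Produces every (composition, adduct count) pair satisfying the constraint
#' box in [hypothesis_params()], with its theoretical monoisotopic mass.
#' Rows are emitted in lexicographic order of (dHexA, hexA, glcN, ac, so3,
#' n_nh3), with no duplicates; the molecular-weight window is applied to the
#' unadducted chain mass by default.
#'
#' @param p A [hypothesis_params()] object.
#' @param consts Mass constants, see [mass_constants()].
#' @return Data.frame with columns `key` (canonical text), `dHexA`, `hexA`,
#'   `glcN`, `ac`, `so3`, `anhydro`, `n_nh3`, `base_mass` (unadducted Da)
#'   and `theoretical_mass` (adducted Da).
#' @examples
#' h <- enumerate_hypothesis(hypothesis_params(nh3_max = 0, mw_max = 1000))
#' head(h)
#' @export
enumerate_hypothesis <- function(p = hypothesis_params(),
                                 consts = mass_constants()) {
  stopifnot(inherits(p, "hypothesis_params"))
  rows <- vector("list", 2048L); nrows <- 0L
  for (A in p$dHexA_choices) {
    for (B in 0:p$hexA_max) {
      c_lo <- max(0L, A + B - 1L)
      for (C in c_lo:(A + B + 1L)) {
        if (A + B + C > p$dp_max || A + B + C < 1L) next
        for (D in 0:min(p$ac_max, C)) {
          e_hi <- A + B + 2L * C + 1L - D
          if (e_hi < B) next
          for (E in B:e_hi) {
            cmp <- composition(A, B, C, D, E, anhydro = p$anhydro)
            m0 <- composition_mass(cmp, consts)
            for (n in 0:p$nh3_max) {
              m <- adducted_mass(m0, n, max_nh3 = p$nh3_max, consts = consts)
              mw <- if (p$mw_on == "adducted") m else m0
              if (mw < p$mw_min || mw > p$mw_max) next
              nrows <- nrows + 1L
              if (nrows > length(rows))
                rows <- c(rows, vector("list", length(rows)))
              rows[[nrows]] <- c(A, B, C, D, E, n, m0, m)
            }
          }
        }
      }
    }
  }
  if (nrows == 0L) {
    return(data.frame(key = character(0), dHexA = integer(0),
                      hexA = integer(0), glcN = integer(0), ac = integer(0),
                      so3 = integer(0), anhydro = logical(0),
                      n_nh3 = integer(0), base_mass = numeric(0),
                      theoretical_mass = numeric(0)))
  }
  m <- do.call(rbind, rows[seq_len(nrows)])
  out <- data.frame(
    key = sprintf("[%d,%d,%d,%d,%d]", m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]),
    dHexA = as.integer(m[, 1]), hexA = as.integer(m[, 2]),
    glcN = as.integer(m[, 3]), ac = as.integer(m[, 4]),
    so3 = as.integer(m[, 5]), anhydro = p$anhydro,
    n_nh3 = as.integer(m[, 6]), base_mass = m[, 7],
    theoretical_mass = m[, 8], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Match an observed deconvoluted mass against hypothesis entries
#'
#' Returns the hypothesis entries whose theoretical (adducted) mass lies
#' within `ppm` parts per million of the observed mass, sorted by ascending
#' absolute ppm error.  Matching is against (composition, adduct) entries,
#' not compositions: one observed mass can hit several adduct states of
#' different compositions, which is exactly the ambiguity that all-presence
#' filtering across replicates is designed to resolve.
#'
#' @param observed Observed monoisotopic mass (Da, > 0).
#' @param entries Data.frame from [enumerate_hypothesis()].
#' @param ppm Match tolerance in ppm (default 5, the standard match error).
#' @return The matching subset of `entries` with an extra `ppm_error`
#'   column, ordered by `abs(ppm_error)`; zero rows when nothing matches.
#' @export
match_mass <- function(observed, entries, ppm = 5.0) {
  stopifnot(length(observed) == 1L, observed > 0, ppm > 0)
  err <- (observed - entries$theoretical_mass) /
    entries$theoretical_mass * 1e6
  hit <- abs(err) <= ppm
  out <- entries[hit, , drop = FALSE]
  out$ppm_error <- err[hit]
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
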