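# Compound-key parsing, canonical compositions and monoisotopic masses.

#' Monoisotopic mass constants for heparin oligosaccharide residues
#'
#' Returns the residue and increment monoisotopic masses (Da) used throughout
#' the package.  Values are hard-coded from standard atomic monoisotopic
#' masses (C 12, H 1.00782503207, N 14.0030740048, O 15.9949146196,
#' S 31.97207100); the derivation script is kept at
#' `tools/derive_mass_constants.R` in the package sources.
#'
#' The residues are: `m_dHexA`, the 4,5-unsaturated uronic acid residue
#' (C6H6O5) produced at the non-reducing end by beta-eliminative cleavage;
#' `m_dHexA_anhydro`, its variant used when the chain carries a 1,6-anhydro
#' reducing end (C6H4O4, one further H2O loss, so
#' `m_dHexA - m_dHexA_anhydro == m_h2o`); `m_hexA`, a hexuronic acid residue
#' (C6H8O6); `m_glcN`, a free-amine hexosamine residue (C6H11NO4); the
#' substituent increments `m_ac` (N-acetyl, C2H2O) and `m_so3` (sulfo, SO3);
#' and the terminal `m_h2o` plus the ammonium-adduct increment `m_nh3`.
#'
#' @return Named list of masses in Da.
#' @examples
#' mass_constants()$m_h2o
#' @export
mass_constants <- function() {
  list(
    m_dHexA         = 158.0215232904,
    m_dHexA_anhydro = 140.0109586067,
    m_hexA          = 176.0320879742,
    m_glcN          = 161.0688078360,
    m_ac            = 42.0105646837,
    m_so3           = 79.9568148588,
    m_h2o           = 18.0105646837,
    m_nh3           = 17.0265491010
  )
}

#' Construct a canonical oligosaccharide composition
#'
#' A composition is the 5-tuple of counts `[dHexA, HexA, GlcN, Ac, SO3]`
#' identifying an intact heparin chain at the compositional (not sequence)
#' level, plus a flag marking the 1,6-anhydro reducing-end variant.  The
#' anhydro flag is metadata carried alongside the tuple: the bracketed key
#' text is identical for both variants and the flag records which hypothesis
#' (normal or anhydro reducing end) a table was matched against.
#'
#' @param dHexA Count of 4,5-unsaturated uronic acid residues (0 or 1).
#' @param hexA Count of saturated hexuronic acid residues.
#' @param glcN Count of hexosamine residues.
#' @param ac Count of N-acetyl substituents.
#' @param so3 Count of sulfo substituents.
#' @param anhydro Logical; 1,6-anhydro reducing-end variant.  Requires
#'   `dHexA == 1`.
#' @return Object of class `"composition"`: a named list with integer fields
#'   `dHexA`, `hexA`, `glcN`, `ac`, `so3` and logical `anhydro`.
#' @examples
#' cmp <- composition(1, 4, 5, 2, 7)
#' composition_dp(cmp)   # 10
#' @export
composition <- function(dHexA, hexA, glcN, ac, so3, anhydro = FALSE) {
  counts <- c(dHexA = dHexA, hexA = hexA, glcN = glcN, ac = ac, so3 = so3)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("composition counts must be non-negative integers, got [",
         paste(counts, collapse = ","), "]")
  if (dHexA > 1L)
    stop("dHexA must be 0 or 1, got ", dHexA)
  if (dHexA + hexA + glcN < 1L)
    stop("degree of polymerization must be >= 1")
  if (isTRUE(anhydro) && dHexA != 1L)
    stop("the 1,6-anhydro variant requires dHexA == 1")
  structure(list(dHexA = as.integer(dHexA), hexA = as.integer(hexA),
                 glcN = as.integer(glcN), ac = as.integer(ac),
                 so3 = as.integer(so3), anhydro = isTRUE(anhydro)),
            class = "composition")
}

#' @export
format.composition <- function(x, ...) {
  paste0("[", x$dHexA, ",", x$hexA, ",", x$glcN, ",", x$ac, ",", x$so3, "]",
         if (x$anhydro) " (1,6-anhydro RE)" else "")
}

#' @export
print.composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Degree of polymerization of a composition
#'
#' dp counts monosaccharide residues: `dHexA + hexA + glcN`.
#'
#' @param x A `composition`.
#' @return Integer dp.
#' @export
composition_dp <- function(x) {
  stopifnot(inherits(x, "composition"))
  x$dHexA + x$hexA + x$glcN
}

#' Extract the bracketed compound key from a raw table cell
#'
#' GlycReSoft-style tables carry the composition as a square-bracketed tuple,
#' optionally followed by adduct annotation (e.g. `"[1,4,5,2,7] 2NH3"`).  The
#' first bracketed span is isolated by lazy (shortest-match) regular
#' expression matching -- from the first `[` to the next `]` -- and internal
#' whitespace is removed, so the result is canonical key text.  Anything
#' outside the first bracketed span (adduct annotations, further bracketed
#' groups) is treated as opaque and discarded.
#'
#' @param cells Character vector of raw cells (non-empty after trimming).
#' @return Character vector of canonical keys `"[a,b,c,d,e]"`.
#' @examples
#' extract_key("[1,4,5,2,7] 2NH3")
#' @export
extract_key <- function(cells) {
  cells <- as.character(cells)
  m <- regmatches(cells, regexpr("\\[.*?\\]", cells, perl = TRUE))
  hit <- grepl("\\[.*?\\]", cells, perl = TRUE)
  if (!all(hit)) {
    bad <- cells[!hit]
    stop("no bracketed compound key in cell(s): ",
         paste(sQuote(utils::head(bad, 5)), collapse = ", "))
  }
  gsub("[[:space:]]+", "", m)
}

# Field-order profiles mapping bracket positions to composition fields.
# "enoxaparin": [dHexA, HexA, GlcN, Ac, SO3] (the default display order).
# "pnp": the synthesized-standard dialect [HexA, GlcN, PNP = 1, SO3, Ac];
# position 3 is the para-nitrophenyl aglycone flag (carried through but not a
# residue count here) and dHexA is 0 for these saturated standards.
.key_profiles <- list(
  enoxaparin = c(dHexA = 1L, hexA = 2L, glcN = 3L, ac = 4L, so3 = 5L),
  pnp        = c(hexA = 1L, glcN = 2L, so3 = 4L, ac = 5L)
)

#' Parse a canonical key into a composition
#'
#' @param key Canonical key text `"[i,i,i,i,i]"` with five non-negative
#'   integers (as produced by [extract_key()]).
#' @param anhydro Logical; flag the 1,6-anhydro reducing-end variant (table
#'   metadata, not inferred from the key).
#' @param profile Field-order profile: `"enoxaparin"` (default) reads the
#'   tuple as `[dHexA, HexA, GlcN, Ac, SO3]`; `"pnp"` reads the
#'   synthesized-standard dialect `[HexA, GlcN, PNP, SO3, Ac]` (dHexA = 0).
#' @return A [composition()].
#' @examples
#' parse_composition("[1,4,5,2,7]")
#' @export
parse_composition <- function(key, anhydro = FALSE,
                              profile = c("enoxaparin", "pnp")) {
  profile <- match.arg(profile)
  key <- gsub("[[:space:]]+", "", as.character(key))
  if (length(key) != 1L)
    stop("parse_composition expects a single key")
  body <- sub("^\\[(.*)\\]$", "\\1", key)
  if (identical(body, key))
    stop("malformed key (missing brackets): ", sQuote(key))
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (length(parts) != 5L)
    stop("key must have 5 fields, got ", length(parts), " in ", sQuote(key))
  if (!all(grepl("^[0-9]+$", parts)))
    stop("key fields must be non-negative integers in ", sQuote(key))
  v <- as.integer(parts)
  idx <- .key_profiles[[profile]]
  get <- function(field) if (field %in% names(idx)) v[idx[[field]]] else 0L
  composition(get("dHexA"), get("hexA"), get("glcN"), get("ac"), get("so3"),
              anhydro = anhydro)
}

#' Monoisotopic mass of a composition
#'
#' Sums residue masses plus one terminal water:
#' `M = dHexA * m_dHexA(+/- anhydro) + hexA * m_hexA + glcN * m_glcN +
#'  ac * m_ac + so3 * m_so3 + m_h2o`.
#' When the composition carries the 1,6-anhydro flag the unsaturated uronic
#' residue mass is replaced by its anhydro variant, one H2O lighter.
#'
#' @param x A [composition()].
#' @param consts Mass constants, see [mass_constants()].
#' @return Monoisotopic mass in Da.
#' @examples
#' composition_mass(composition(1, 4, 5, 2, 7))
#' @export
composition_mass <- function(x, consts = mass_constants()) {
  stopifnot(inherits(x, "composition"))
  m_d <- if (x$anhydro) consts$m_dHexA_anhydro else consts$m_dHexA
  x$dHexA * m_d + x$hexA * consts$m_hexA + x$glcN * consts$m_glcN +
    x$ac * consts$m_ac + x$so3 * consts$m_so3 + consts$m_h2o
}

#' Mass of an ammonium-adducted chain
#'
#' @param mass Unadducted monoisotopic mass (Da).
#' @param n_nh3 Number of NH3 adducts (integer, `0 <= n_nh3 <= max_nh3`).
#' @param max_nh3 Upper bound on the adduct count (default 14, the standard
#'   ammonium adduct range for enoxaparin intact chains).
#' @param consts Mass constants, see [mass_constants()].
#' @return `mass + n_nh3 * m_nh3` (vectorized over `mass`/`n_nh3`).
#' @export
adducted_mass <- function(mass, n_nh3, max_nh3 = 14L,
                          consts = mass_constants()) {
  if (any(n_nh3 < 0L) || any(n_nh3 > max_nh3) || any(n_nh3 != floor(n_nh3)))
    stop("n_nh3 must be an integer in [0, ", max_nh3, "]")
  mass + n_nh3 * consts$m_nh3
}

# dp for a vector of canonical keys under a profile (used for report sorting).
key_dp <- function(keys, profile = "enoxaparin") {
  vapply(keys, function(k) {
    composition_dp(parse_composition(k, profile = profile))
  }, integer(1), USE.NAMES = FALSE)
}

# Deterministic ordering of canonical keys: by dp, then lexicographically by
# the integer tuple.  Returns an ordering permutation.
key_order <- function(keys, profile = "enoxaparin") {
  mat <- t(vapply(keys, function(k) {
    as.integer(strsplit(sub("^\\[(.*)\\]$", "\\1", k), ",")[[1]])
  }, integer(5), USE.NAMES = FALSE))
  do.call(order, c(list(key_dp(keys, profile)), as.data.frame(mat)))
}
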