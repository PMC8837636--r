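#' @include AllClasses.R
NULL

## Monoisotopic atomic masses (Da). The protonated-adduct constant is the
## proton mass (electron-corrected), not the H-atom mass: accurate [M+H]+
## values in the bundled marker table match M + 1.00727646 to 4 dp.
ATOMIC_MASSES <- c(C = 12.000000, H = 1.00782503, N = 14.00307401,
                   O = 15.99491462, P = 30.97376200, S = 31.97207117)

#' Proton mass used for [M+H]+ adducts
#'
#' Electron-corrected proton mass, 1.00727646 Da. Positive-mode DESI of milk
#' lipids yields singly protonated ions, so every adduct computation in the
#' package is `monoisotopicMass(f) + protonMass()`.
#'
#' @return the proton mass in Da.
#' @export
#' @examples
#' protonMass()
protonMass <- function() 1.00727646

#' Parse an elemental formula
#'
#' Parses formulas of the style printed for lipid ions ("C27H53O8P"):
#' element symbols from C, H, N, O, P, S, each optionally followed by an
#' integer count (absent count means 1). No parentheses, charges or isotope
#' labels. Repeated symbols accumulate.
#'
#' @param text formula string.
#' @return named integer vector of element counts, in Hill order (C, H, then
#'   alphabetical), with class `"ElementalFormula"`.
#' @seealso [formulaToString()] for the canonical serialisation,
#'   [monoisotopicMass()], [protonatedMass()].
#' @export
#' @examples
#' parseFormula("C27H53O8P")
parseFormula <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(text))
        stop("formula must be a single non-empty string")
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
    parts <- regmatches(text, list(tokens))[[1]]
    if (sum(attr(tokens, "match.length")) != nchar(text))
        stop(sprintf("formula '%s' contains unparseable characters", text))
    counts <- integer()
    for (part in parts) {
        sym <- sub("[0-9]*$", "", part)
        num <- sub("^[A-Za-z]+", "", part)
        if (!sym %in% names(ATOMIC_MASSES))
            stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
        n <- if (nzchar(num)) as.integer(num) else 1L
        if (n == 0L)
            stop(sprintf("zero count for element '%s' in formula '%s'", sym, text))
        counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    }
    structure(hillOrder(counts), class = "ElementalFormula")
}

hillOrder <- function(counts) {
    syms <- names(counts)
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c(intersect(c("C", "H"), syms), rest)
    counts[ord]
}

#' Serialise an elemental formula in Hill order
#'
#' @param f named count vector as returned by [parseFormula()].
#' @return the canonical formula string (C first, H second, remaining
#'   elements alphabetical; unit counts omitted). `parseFormula()` of the
#'   result reproduces `f`.
#' @export
#' @examples
#' formulaToString(parseFormula("H2O"))
formulaToString <- function(f) {
    f <- hillOrder(unclass(f))
    paste0(names(f), ifelse(f == 1L, "", as.character(f)), collapse = "")
}

asFormula <- function(f) {
    if (is.character(f)) parseFormula(f) else {
        if (is.null(names(f)) || !all(names(f) %in% names(ATOMIC_MASSES)))
            stop("formula counts must be named with known element symbols")
        if (any(f < 1)) stop("element counts must be >= 1")
        f
    }
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times monoisotopic atomic mass over the elements present,
#' using fixed constants (C 12, H 1.00782503, N 14.00307401, O 15.99491462,
#' P 30.97376200, S 31.97207117 Da).
#'
#' @param f a formula string or a named count vector from [parseFormula()].
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopicMass("C27H53O8P")
monoisotopicMass <- function(f) {
    f <- asFormula(f)
    sum(ATOMIC_MASSES[names(f)] * as.numeric(f))
}

#' Protonated-adduct m/z of a formula
#'
#' Theoretical m/z of the singly protonated ion `[M+H]+`:
#' `monoisotopicMass(f) + protonMass()`.
#'
#' @inheritParams monoisotopicMass
#' @return m/z of `[M+H]+`.
#' @export
#' @examples
#' protonatedMass("C27H53O8P")  # 537.3551
protonatedMass <- function(f) monoisotopicMass(f) + protonMass()

#' Parts-per-million mass error
#'
#' @param observed observed m/z (vectorised).
#' @param theoretical theoretical m/z, strictly positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
#' @examples
#' ppmError(600.0006, 600.0)
ppmError <- function(observed, theoretical) {
    if (any(theoretical <= 0)) stop("theoretical mass must be positive")
    1e6 * (observed - theoretical) / theoretical
}
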