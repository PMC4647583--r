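# Molecular-formula parsing, monoisotopic masses, adduct m/z with
# electron-mass correction, and ion matching at mmu tolerance.

#' Parse a molecular formula
#'
#' Hill-style tokenization: a capital letter, an optional lowercase letter,
#' then an optional integer count (default 1). Underscores and other
#' subscript markup (as in `"C_54_H_84_O_19_N"`) are stripped before
#' parsing. Repeated element tokens accumulate.
#'
#' @param text Formula string, e.g. `"C54H83NO19"`.
#' @return Named integer vector of element counts (an element-counts map).
#'   Unknown element symbols and zero counts are rejected.
#' @export
#' @examples
#' parseFormula("C54H84O19N")
#' parseFormula("C_54_H_87_O_19_N_2_")
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("[_{}\\s]", "", text, perl = TRUE)
  if (!nzchar(clean)) stop("empty formula")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", clean)[[1]]
  parts <- regmatches(clean, gregexpr("[A-Z][a-z]?[0-9]*", clean))[[1]]
  if (sum(nchar(parts)) != nchar(clean))
    stop("malformed formula '", text, "'")
  counts <- integer()
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.ATOMIC_MASSES))
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    if (cnt == 0L)
      stop("zero count for element '", sym, "' in formula '", text, "'")
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
  }
  counts
}

#' Serialize element counts back to a formula string (Hill order)
#'
#' @param counts Named integer vector of element counts.
#' @return Character string: C first, H second, remaining elements
#'   alphabetical.
#' @export
formatFormula <- function(counts) {
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the packaged monoisotopic atomic mass.
#' Additive: `monoisotopicMass(a) + monoisotopicMass(b)` equals the mass of
#' the merged counts.
#'
#' @param counts Named integer vector of element counts, or a formula
#'   string.
#' @return Mass in u (numeric scalar).
#' @export
#' @examples
#' monoisotopicMass("C")       # 12, exactly
#' monoisotopicMass("H2O")     # 18.0105646...
monoisotopicMass <- function(counts) {
  if (is.character(counts)) counts <- parseFormula(counts)
  missing <- setdiff(names(counts), names(.ATOMIC_MASSES))
  if (length(missing))
    stop("element(s) missing from the atomic-mass table: ",
         paste(missing, collapse = ", "))
  sum(.ATOMIC_MASSES[names(counts)] * as.numeric(counts))
}

# Merge two element-count maps.
.mergeCounts <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    sum(c(a[s], b[s]), na.rm = TRUE)
  }, numeric(1))
  out
}

#' Theoretical m/z of an adduct ion
#'
#' Adds the adduct atoms to the neutral formula, subtracts one electron mass
#' per positive charge (the ion is a cation, so the electron deficit is part
#' of the exact mass — omitting this correction biases m/z upward by
#' ~0.55 mmu per charge) and divides by the charge.
#'
#' @param neutral Neutral molecule: named element-count vector or formula
#'   string.
#' @param adduct Adduct spec: list with `atoms` (named counts added) and
#'   `charge`, e.g. an entry of [defaultAdducts()], or one of the names
#'   `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"`.
#' @return m/z (numeric scalar, full precision).
#' @export
#' @examples
#' round(adductMz("C54H83NO19", "[M+H]+"), 4)   # 1050.5632
#' round(adductMz("C54H83NO19", "[M+NH4]+"), 4) # 1067.5898
#' round(adductMz("C54H83NO19", "[M+Na]+"), 4)  # 1072.5452
adductMz <- function(neutral, adduct) {
  if (is.character(neutral)) neutral <- parseFormula(neutral)
  if (is.character(adduct)) {
    spec <- defaultAdducts()[[adduct]]
    if (is.null(spec)) stop("unknown adduct '", adduct, "'")
    adduct <- spec
  }
  stopifnot(is.list(adduct), adduct$charge >= 1L)
  ion <- .mergeCounts(neutral, adduct$atoms)
  (monoisotopicMass(ion) - adduct$charge * .ELECTRON_MASS) / adduct$charge
}

#' Match observed ions to theoretical adduct m/z values
#'
#' Compares every observed m/z against every (candidate, adduct) theoretical
#' m/z and reports pairs within `toleranceMmu` milli-mass-units, sorted by
#' absolute delta. An observed ion may match several candidates; ambiguity
#' is preserved. The result is invariant under permutation of the observed
#' and candidate lists.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param candidates Named list or character vector of neutral formulas
#'   (names are compound labels), or a data.frame with columns `name` and
#'   `formula`.
#' @param adducts List of adduct specs (default [defaultAdducts()]).
#' @param toleranceMmu Matching tolerance in mmu (default 3.0, about 3x the
#'   mass error of a modern orbitrap at m/z 1000); must be positive.
#' @return data.frame with columns `observed_mz`, `candidate`,
#'   `adduct_name`, `theoretical_mz`, `delta_mmu`
#'   (`(observed - theoretical) * 1000`), `formula` (ion formula).
#' @export
matchIons <- function(observed, candidates, adducts = defaultAdducts(),
                      toleranceMmu = 3.0) {
  stopifnot(toleranceMmu > 0)
  if (is.data.frame(candidates)) {
    stopifnot(all(c("name", "formula") %in% names(candidates)))
    cand <- as.character(candidates$formula)
    names(cand) <- as.character(candidates$name)
    candidates <- cand
  }
  if (is.character(candidates) && is.null(names(candidates)))
    names(candidates) <- candidates
  empty <- data.frame(observed_mz = numeric(), candidate = character(),
                      adduct_name = character(), theoretical_mz = numeric(),
                      delta_mmu = numeric(), formula = character(),
                      stringsAsFactors = FALSE)
  if (!length(observed)) return(empty)
  rows <- list()
  for (ci in seq_along(candidates)) {
    neutral <- parseFormula(candidates[[ci]])
    for (ad in adducts) {
      theo <- adductMz(neutral, ad)
      ionFormula <- formatFormula(.mergeCounts(neutral, ad$atoms))
      delta <- (observed - theo) * 1000
      hit <- which(abs(delta) <= toleranceMmu)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          observed_mz = observed[hit], candidate = names(candidates)[ci],
          adduct_name = ad$name, theoretical_mz = theo,
          delta_mmu = delta[hit], formula = ionFormula,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$delta_mmu), out$candidate, out$adduct_name,
                   out$observed_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen observed ions against a table of known compounds
#'
#' Direct m/z-to-m/z lookup (no formulas involved), used to test whether
#' observed polyhydroxy ions correspond to already-reported compounds.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param compoundTable data.frame with columns `name` and `reported_mz`.
#' @param tolerance Tolerance value (default 10).
#' @param unit `"mmu"` (default) or `"ppm"`.
#' @return data.frame with columns `observed_mz`, `compound`,
#'   `reported_mz`, `delta` (in the chosen unit).
#' @export
screenCompoundTable <- function(observed, compoundTable, tolerance = 10,
                                unit = c("mmu", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(all(c("name", "reported_mz") %in% names(compoundTable)))
  rows <- list()
  for (i in seq_len(nrow(compoundTable))) {
    ref <- compoundTable$reported_mz[i]
    delta <- if (unit == "mmu") (observed - ref) * 1000
             else (observed - ref) / ref * 1e6
    hit <- which(abs(delta) <= tolerance)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        observed_mz = observed[hit], compound = compoundTable$name[i],
        reported_mz = ref, delta = delta[hit], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(observed_mz = numeric(), compound = character(),
                      reported_mz = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Table-style adduct report for one neutral formula
#'
#' Computes the theoretical m/z of each adduct of a neutral formula,
#' rounded half away from zero at 4 decimal places for printing.
#'
#' @param formula Neutral formula string.
#' @param adducts Adduct list (default [defaultAdducts()]).
#' @return data.frame with `adduct`, `theoretical_mz` (4 dp), `ion_formula`.
#' @export
#' @examples
#' adductReport("C54H83NO19")
adductReport <- function(formula, adducts = defaultAdducts()) {
  neutral <- parseFormula(formula)
  data.frame(
    adduct = vapply(adducts, `[[`, "", "name"),
    theoretical_mz = vapply(adducts, function(ad)
      roundHalfUp(adductMz(neutral, ad), 4L), numeric(1)),
    ion_formula = vapply(adducts, function(ad)
      formatFormula(.mergeCounts(neutral, ad$atoms)), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Printed-value comparisons in mass tables use commercial rounding, not
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
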