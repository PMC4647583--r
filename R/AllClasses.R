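#' CompiledMotif class
#'
#' A compiled degenerate signature motif. Each position is one of: a literal
#' residue (mismatches there count against the substitution budget), a strict
#' alternative set (bracket sets such as `[DEG]`, or IUPAC-degenerate
#' nucleotide letters, which must be satisfied and never consume
#' substitutions) or a wildcard `x` (matches anything, never counts).
#'
#' @slot name short label for the motif.
#' @slot pattern the source pattern string.
#' @slot alphabet `"protein"` or `"nucleotide"`.
#' @slot elements list, one entry per motif position, each a list with
#'   `kind` (`"literal"`, `"set"` or `"wild"`) and `letters`.
#' @export
setClass("CompiledMotif",
  representation(name = "character", pattern = "character",
                 alphabet = "character", elements = "list"),
  validity = function(object) {
    if (length(object@pattern) != 1L || !nzchar(object@pattern))
      return("pattern must be a single non-empty string")
    if (!object@alphabet %in% c("protein", "nucleotide"))
      return("alphabet must be 'protein' or 'nucleotide'")
    if (length(object@elements) < 1L)
      return("compiled motif must have at least one position")
    for (el in object@elements) {
      if (!el$kind %in% c("literal", "set", "wild"))
        return("element kind must be literal, set or wild")
      if (el$kind != "wild" && length(el$letters) < 1L)
        return("alternative sets must contain at least one letter")
    }
    TRUE
  })

setMethod("show", "CompiledMotif", function(object) {
  cat("CompiledMotif '", object@name, "' (", object@alphabet, "): ",
      object@pattern, " [", length(object@elements), " positions, ",
      sum(vapply(object@elements, function(e) e$kind == "literal", TRUE)),
      " literal]\n", sep = "")
})

#' Length of a compiled motif (number of positions)
#' @param x A [CompiledMotif-class] object.
#' @export
setMethod("length", "CompiledMotif", function(x) length(x@elements))

#' Architecture class
#'
#' The ordered list of assembly-line domain codes carried by one gene, the
#' unit of PKS gene classification. Optional per-domain amino-acid
#' coordinates (1-based inclusive) may be attached.
#'
#' @slot geneId gene identifier.
#' @slot domains character vector of domain codes (closed vocabulary:
#'   KS, AT, PP, KR, DH, ER, AM, C, A, MT, TE, HXXPF).
#' @slot totalAA protein length in residues (NA if unknown).
#' @slot coords optional data.frame with columns `start_aa`, `end_aa`
#'   parallel to `domains`; zero-row when absent.
#' @export
setClass("Architecture",
  representation(geneId = "character", domains = "character",
                 totalAA = "numeric", coords = "data.frame"),
  prototype(totalAA = NA_real_,
            coords = data.frame(start_aa = integer(), end_aa = integer())),
  validity = function(object) {
    if (length(object@geneId) != 1L)
      return("geneId must be a single string")
    bad <- setdiff(unique(object@domains), .DOMAIN_CODES)
    if (length(bad))
      return(paste0("unknown domain code(s): ", paste(bad, collapse = ", ")))
    if (nrow(object@coords)) {
      if (nrow(object@coords) != length(object@domains))
        return("coords must have one row per domain")
      s <- object@coords$start_aa; e <- object@coords$end_aa
      if (any(e < s)) return("coords: end_aa < start_aa")
      if (any(diff(s) <= 0) || any(s[-1] <= e[-length(e)]))
        return("coords must be ascending and non-overlapping")
    }
    TRUE
  })

setMethod("show", "Architecture", function(object) {
  cat("Architecture ", object@geneId, ": ",
      paste(object@domains, collapse = "-"),
      if (!is.na(object@totalAA)) paste0(" (", object@totalAA, " aa)"),
      "\n", sep = "")
})

#' @describeIn Architecture-class number of domains.
#' @param x An `Architecture`.
#' @export
setMethod("length", "Architecture", function(x) length(x@domains))

#' Accessors for Architecture objects
#'
#' @param x An [Architecture-class] object.
#' @return `geneId()` the gene identifier; `domains()` the ordered character
#'   vector of domain codes.
#' @export
geneId <- function(x) x@geneId

#' @rdname geneId
#' @export
domains <- function(x) x@domains

#' CladeAlignment class
#'
#' An aligned, equal-width set of (gapped) protein sequences with a clade
#' label per row; query rows carry the label `"QUERY"`. This is the container
#' for the trimmed ketosynthase-domain alignment used in distance-based clade
#' assignment.
#'
#' @slot sequences an [Biostrings::AAStringSet] of equal-width gapped rows.
#' @slot labels character vector of clade tags, parallel to `sequences`.
#' @export
setClass("CladeAlignment",
  representation(sequences = "AAStringSet", labels = "character"),
  validity = function(object) {
    if (length(object@sequences) < 2L)
      return("alignment needs at least 2 rows")
    if (length(unique(width(object@sequences))) != 1L)
      return("alignment rows must all have the same width")
    if (length(object@labels) != length(object@sequences))
      return("labels must be parallel to sequences")
    TRUE
  })

setMethod("show", "CladeAlignment", function(object) {
  tab <- table(object@labels)
  cat("CladeAlignment: ", length(object@sequences), " rows x ",
      width(object@sequences)[1], " columns; labels: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})

#' Construct a CladeAlignment
#'
#' @param sequences An `AAStringSet` (or named character vector) of
#'   equal-width gapped rows.
#' @param labels Character vector of clade labels, one per row. Rows whose
#'   clade is unknown (queries) should be labelled `"QUERY"`.
#' @return A [CladeAlignment-class] object.
#' @export
CladeAlignment <- function(sequences, labels) {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  new("CladeAlignment", sequences = sequences, labels = as.character(labels))
}

#' @rdname CladeAlignment
#' @param x A `CladeAlignment`.
#' @export
cladeLabels <- function(x) x@labels

#' @rdname CladeAlignment
#' @export
alignedSequences <- function(x) x@sequences
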