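# Adenylation-domain specificity-code (Stachelhaus-type) extraction by
# global alignment of a query A-domain to an annotated reference.

#' Packaged A-domain reference
#'
#' Loads the reference adenylation domain shipped with the package together
#' with its eight annotated substrate-binding-pocket positions (reference
#' coordinates, 1-based). The shipped reference is a synthetic GrsA-type
#' stand-in (see `inst/extdata/adomain_reference_synthetic.fasta`): a fixed
#' A-domain-sized sequence whose eight pocket positions are annotated and
#' whose own specificity code is `DAWTIAAI`.
#'
#' @param fastaFile,positionsFile Paths to the reference FASTA and the
#'   pocket-position TSV (`position` column); defaults to the packaged
#'   files.
#' @return List with `sequence` (character), `pocket_positions` (integer,
#'   length 8) and `id`.
#' @export
aDomainReference <- function(
    fastaFile = system.file("extdata", "adomain_reference_synthetic.fasta",
                            package = "dinoPKS"),
    positionsFile = system.file("extdata",
                                "adomain_reference_synthetic_positions.tsv",
                                package = "dinoPKS")) {
  ref <- readAAStringSet(fastaFile)
  pos <- read.delim(positionsFile, comment.char = "#")
  stopifnot(length(ref) == 1L, "position" %in% names(pos),
            nrow(pos) == 8L)
  list(sequence = as.character(ref[[1]]), id = names(ref)[1],
       pocket_positions = sort(as.integer(pos$position)))
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Extract an adenylation-domain specificity code
#'
#' Globally aligns the reference A-domain to the query (affine gaps; the
#' query may carry flanking sequence, which is absorbed by local alignment
#' on the query side) and reads off the query residues aligned to the eight
#' annotated binding-pocket positions of the reference. A pocket position
#' aligned to a gap yields `'x'`. These eight residues are the
#' Stachelhaus-type substrate-specificity code of the domain.
#'
#' @param aDomainSeq Query protein sequence (an A-domain region, typically
#'   several hundred residues).
#' @param reference Reference as returned by [aDomainReference()].
#' @param gapOpening,gapExtension Affine gap penalties (defaults 10 and 1).
#' @param minCoverage Minimum fraction of reference positions aligned to
#'   query residues for the code to be trusted (default 0.5); below it the
#'   code is refused and a diagnostic returned.
#' @return List with `code` (8-character string, or `NA` when refused),
#'   `coverage` (fraction of reference residues aligned to non-gap),
#'   `score` and `refused` (logical with a `reason` attribute when TRUE).
#' @export
#' @examples
#' ref <- aDomainReference()
#' extractADomainCode(ref$sequence)$code  # the reference's own pocket code
extractADomainCode <- function(aDomainSeq, reference = aDomainReference(),
                               gapOpening = 10, gapExtension = 1,
                               minCoverage = 0.5) {
  aDomainSeq <- .normalizeSeq(aDomainSeq)
  aln <- pairwiseAlignment(
    pattern = AAString(reference$sequence),
    subject = AAString(aDomainSeq),
    type = "global-local",
    substitutionMatrix = .blosum62(),
    gapOpening = gapOpening, gapExtension = gapExtension)
  refRow <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  qryRow <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  refPos <- cumsum(refRow != "-")
  aligned <- refRow != "-" & qryRow != "-"
  coverage <- sum(aligned) / nchar(reference$sequence)
  if (coverage < minCoverage) {
    refused <- TRUE
    attr(refused, "reason") <- sprintf(
      "alignment covers only %.0f%% of the reference (minimum %.0f%%)",
      100 * coverage, 100 * minCoverage)
    return(list(code = NA_character_, coverage = coverage,
                score = BiocGenerics::score(aln), refused = refused))
  }
  code <- vapply(reference$pocket_positions, function(p) {
    col <- which(refPos == p & refRow != "-")[1]
    ch <- qryRow[col]
    if (is.na(ch) || ch == "-") "x" else ch
  }, "")
  list(code = paste(code, collapse = ""), coverage = coverage,
       score = BiocGenerics::score(aln), refused = FALSE)
}
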