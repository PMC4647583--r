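# Degenerate signature-motif compilation, scanning and active-site checks.
#
# Pattern grammar: uppercase residue letters are literals (mismatches there
# consume the substitution budget); 'x' is a wildcard; '[...]' encloses a
# strict alternative set. For the nucleotide alphabet, IUPAC degeneracy
# letters (e.g. D = A/G/T) compile to strict sets. The ambiguity residue 'X'
# in a *scanned sequence* never matches a literal or a set, and always
# matches 'x'.

#' Compile a degenerate signature motif
#'
#' @param pattern Motif string, e.g. `"DTACSS"`, `"HxxxGxxxx"` or
#'   `"GxG[AG]"`.
#' @param alphabet `"protein"` (default) or `"nucleotide"`. Nucleotide
#'   patterns accept IUPAC degeneracy letters, which compile to strict
#'   alternative sets.
#' @param name Optional label stored with the motif (defaults to the pattern
#'   itself).
#' @return A [CompiledMotif-class] object usable with [scanMotif()].
#'   Malformed patterns (unbalanced bracket, illegal character) are rejected
#'   with the 1-based position of the offending character.
#' @export
#' @examples
#' compileMotif("GHSLG")
#' compileMotif("GxG[AG]")
compileMotif <- function(pattern, alphabet = c("protein", "nucleotide"),
                         name = pattern) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!nzchar(pattern)) stop("empty motif pattern")
  chars <- strsplit(pattern, "")[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close))
        stop("unbalanced '[' at position ", i, " in pattern '", pattern, "'")
      close <- close[1]
      set <- chars[seq(i + 1L, length.out = close - i - 1L)]
      if (!length(set))
        stop("empty bracket set at position ", i, " in pattern '", pattern, "'")
      bad <- which(!set %in% .alphabetLetters(alphabet))
      if (length(bad))
        stop("illegal character '", set[bad[1]], "' at position ",
             i + bad[1], " in pattern '", pattern, "'")
      elements[[length(elements) + 1L]] <- list(kind = "set", letters = set)
      i <- close + 1L
    } else if (ch == "x") {
      elements[[length(elements) + 1L]] <-
        list(kind = "wild", letters = character())
      i <- i + 1L
    } else if (alphabet == "nucleotide" && ch %in% names(.IUPAC_NT)) {
      exp <- .IUPAC_NT[[ch]]
      kind <- if (length(exp) == 1L) "literal" else "set"
      elements[[length(elements) + 1L]] <- list(kind = kind, letters = exp)
      i <- i + 1L
    } else if (alphabet == "protein" && ch %in% .PROTEIN_LETTERS) {
      elements[[length(elements) + 1L]] <- list(kind = "literal", letters = ch)
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' at position ", i,
           " in pattern '", pattern, "'")
    }
  }
  new("CompiledMotif", name = name, pattern = pattern,
      alphabet = alphabet, elements = elements)
}

.alphabetLetters <- function(alphabet) {
  if (alphabet == "protein") .PROTEIN_LETTERS else names(.IUPAC_NT)
}

#' Scan a sequence for a compiled motif
#'
#' Slides the motif along the sequence and reports every window whose strict
#' positions (alternative sets) are satisfied and whose literal-position
#' mismatch count is at most `maxSubstitutions`. Wildcard positions never
#' count. Overlapping hits are all reported, in ascending start order.
#'
#' @param seq A single protein (or nucleotide) string. Lowercase input is
#'   uppercased with a warning. An empty sequence yields zero hits.
#' @param motif A [CompiledMotif-class], or a pattern string that will be
#'   compiled with the protein alphabet.
#' @param maxSubstitutions Mismatches allowed at literal positions
#'   (default 0).
#' @return A data.frame with columns `pattern_name`, `start` (1-based),
#'   `end`, `matched_span` and `substitutions`.
#' @export
#' @examples
#' scanMotif("AAGHSLGAA", compileMotif("GHSLG"))          # hit at 3
#' scanMotif("AAGHSAGAA", compileMotif("GHSLG"), maxSubstitutions = 1)
scanMotif <- function(seq, motif, maxSubstitutions = 0L) {
  if (is.character(motif)) motif <- compileMotif(motif)
  stopifnot(is(motif, "CompiledMotif"), maxSubstitutions >= 0)
  seq <- .normalizeSeq(seq)
  m <- length(motif@elements)
  n <- nchar(seq)
  empty <- data.frame(pattern_name = character(), start = integer(),
                      end = integer(), matched_span = character(),
                      substitutions = integer(),
                      stringsAsFactors = FALSE)
  if (n < m || n == 0L) return(empty)
  chars <- strsplit(seq, "")[[1]]
  starts <- seq_len(n - m + 1L)
  subs <- integer(length(starts))
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m)) {
    el <- motif@elements[[j]]
    if (el$kind == "wild") next
    cj <- chars[starts + j - 1L]
    if (el$kind == "literal") {
      subs <- subs + (cj != el$letters)       # 'X' never matches a literal
    } else {
      ok <- ok & (cj %in% el$letters)
    }
  }
  keep <- which(ok & subs <= maxSubstitutions)
  if (!length(keep)) return(empty)
  data.frame(pattern_name = motif@name,
             start = starts[keep],
             end = starts[keep] + m - 1L,
             matched_span = substring(seq, starts[keep], starts[keep] + m - 1L),
             substitutions = subs[keep],
             stringsAsFactors = FALSE)
}

.normalizeSeq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[a-z]", seq)) {
    warning("lowercase residues in input sequence; normalizing to uppercase")
    seq <- toupper(seq)
  }
  seq
}

#' Packaged PKS signature-motif set
#'
#' Reads the plain-text motif configuration shipped with the package
#' (`name<TAB>pattern<TAB>alphabet`) and compiles each entry. The defaults
#' are the Type I PKS signature motifs: KS `DTACSS`, DH `HxxxGxxxx`,
#' ER `LxHxxxGGVG`, KR `GxGxxGxxxA`, AT `GHSLG` and the N-terminal
#' `ExExGYLG`.
#'
#' @param file Path to a motif configuration file; defaults to the packaged
#'   set, which users can copy and extend.
#' @return Named list of [CompiledMotif-class] objects.
#' @export
pksMotifs <- function(file = system.file("extdata", "pks_motifs.tsv",
                                         package = "dinoPKS")) {
  tab <- read.delim(file, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern", "alphabet") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i)
    compileMotif(tab$pattern[i], tab$alphabet[i], name = tab$name[i]))
  names(out) <- tab$name
  out
}

#' Verify the ketosynthase active site
#'
#' Locates the KS catalytic-motif `DTACSS` (allowing substitutions) and
#' checks the three residues required for condensation activity: the
#' catalytic cysteine at motif position 4 (which must be a literal `C`
#' regardless of the substitution budget), a histidine within `hisWindow`
#' residues downstream of the motif end, and a lysine within `lysWindow`
#' residues downstream. When several motif hits exist the one with fewest
#' substitutions (then leftmost) is assessed.
#'
#' @param seq Protein sequence (single string).
#' @param maxSubstitutions Substitution budget for the DTACSS match
#'   (default 2, matching observed near-variants of the motif).
#' @param hisWindow,lysWindow Downstream search windows (residues) for the
#'   catalytic His and Lys; defaults 200 and 250.
#' @return A list with elements `motif_hit` (one-row data.frame or `NULL`),
#'   `cys_ok`, `his_ok`, `lys_ok` and `overall` (all three residues present
#'   and a motif hit found).
#' @export
#' @examples
#' s <- paste0(strrep("A", 10), "DTACSS", strrep("G", 20), "H",
#'             strrep("G", 30), "K", strrep("A", 10))
#' verifyKSActiveSite(s)$overall
verifyKSActiveSite <- function(seq, maxSubstitutions = 2L,
                               hisWindow = 200L, lysWindow = 250L) {
  seq <- .normalizeSeq(seq)
  motif <- compileMotif("DTACSS", name = "KS_DTACSS")
  hits <- scanMotif(seq, motif, maxSubstitutions)
  if (!nrow(hits)) {
    return(list(motif_hit = NULL, cys_ok = FALSE, his_ok = FALSE,
                lys_ok = FALSE, overall = FALSE))
  }
  hits <- hits[order(hits$substitutions, hits$start), , drop = FALSE]
  hit <- hits[1L, , drop = FALSE]
  cysPos <- hit$start + 3L                      # position 4 of DTACSS
  cys_ok <- substring(seq, cysPos, cysPos) == "C"
  down <- function(windowLen) {
    from <- hit$end + 1L
    to <- min(nchar(seq), hit$end + windowLen)
    if (from > to) "" else substring(seq, from, to)
  }
  his_ok <- grepl("H", down(hisWindow), fixed = TRUE)
  lys_ok <- grepl("K", down(lysWindow), fixed = TRUE)
  list(motif_hit = hit, cys_ok = cys_ok, his_ok = his_ok, lys_ok = lys_ok,
       overall = cys_ok && his_ok && lys_ok)
}

#' Survey the dehydratase active-site motif
#'
#' Locates the DH signature `HxxxGxxxx` and reports whether the catalytic
#' histidine is present at motif position 1, plus a heuristic flag for a
#' proline within `proWindow` residues downstream of the motif (the second
#' active residue has no fixed position within the signature).
#'
#' @param seq Protein sequence.
#' @param maxSubstitutions Substitution budget for the motif literals.
#' @param proWindow Downstream window (residues) searched for proline;
#'   default 30.
#' @return List with `motif_hit`, `his_ok` and `pro_downstream`.
#' @export
verifyDHSite <- function(seq, maxSubstitutions = 0L, proWindow = 30L) {
  seq <- .normalizeSeq(seq)
  hits <- scanMotif(seq, compileMotif("HxxxGxxxx", name = "DH_motif"),
                    maxSubstitutions)
  if (!nrow(hits))
    return(list(motif_hit = NULL, his_ok = FALSE, pro_downstream = FALSE))
  hits <- hits[order(hits$substitutions, hits$start), , drop = FALSE]
  hit <- hits[1L, , drop = FALSE]
  his_ok <- substring(seq, hit$start, hit$start) == "H"
  to <- min(nchar(seq), hit$end + proWindow)
  pro <- hit$end < to &&
    grepl("P", substring(seq, hit$end + 1L, to), fixed = TRUE)
  list(motif_hit = hit, his_ok = his_ok, pro_downstream = pro)
}

# Known N-terminal core tetrapeptide variants.
.NTERM_VARIANTS <- c("GYLG", "DYLG", "EYLG", "GYMG")

#' Classify the conserved N-terminal signature of a KS protein
#'
#' Scores every 8-residue window in the first `searchLimit` residues against
#' the template `ExExGYLG` (+1 for each matching literal: E at template
#' positions 1 and 3, and G, Y, L, G at positions 5-8). The best-scoring
#' window (ties broken by smallest position) supplies the core tetrapeptide
#' at template positions 5-8, labelled `GYLG`, or one of the variants
#' `DYLG`, `EYLG`, `GYMG`, or `OTHER(<tetrapeptide>)`.
#'
#' @param seq Protein sequence.
#' @param searchLimit Only the first `searchLimit` residues are searched
#'   (default 150; the signature is N-terminal).
#' @param minScore Minimum template score to accept a window (default 4 of a
#'   maximum 6); below it the label is `OTHER(----)` with `position = NA`.
#' @return List with `core_tetrapeptide`, `variant_label`, `position`
#'   (1-based start of the 8-residue window, NA if none accepted) and
#'   `score`.
#' @export
#' @examples
#' classifyNTermSignature("MAEAELGYLGKKAAAA")$variant_label  # "GYLG"
classifyNTermSignature <- function(seq, searchLimit = 150L, minScore = 4L) {
  seq <- .normalizeSeq(seq)
  n <- min(nchar(seq), searchLimit)
  none <- list(core_tetrapeptide = "----",
               variant_label = "OTHER(----)", position = NA_integer_,
               score = 0L)
  if (n < 8L) return(none)
  chars <- strsplit(substring(seq, 1L, n), "")[[1]]
  starts <- seq_len(n - 7L)
  score <- (chars[starts] == "E") + (chars[starts + 2L] == "E") +
    (chars[starts + 4L] == "G") + (chars[starts + 5L] == "Y") +
    (chars[starts + 6L] == "L") + (chars[starts + 7L] == "G")
  best <- which.max(score)                       # ties -> smallest position
  if (score[best] < minScore) return(none)
  at <- starts[best]
  core <- substring(seq, at + 4L, at + 7L)
  label <- if (core %in% .NTERM_VARIANTS) core else paste0("OTHER(", core, ")")
  list(core_tetrapeptide = core, variant_label = label,
       position = at, score = as.integer(score[best]))
}

#' Motif-scan a set of proteins with the packaged motif set
#'
#' Convenience wrapper producing the per-protein motif report used by
#' [runSurvey()].
#'
#' @param proteins An `AAStringSet` (or named character vector).
#' @param motifs List of [CompiledMotif-class] (default [pksMotifs()]).
#' @param maxSubstitutions Substitution budget applied to every motif.
#' @return data.frame with columns `protein_id`, `motif_name`,
#'   `start_1based`, `matched_span`, `substitutions`.
#' @export
scanProteinSet <- function(proteins, motifs = pksMotifs(),
                           maxSubstitutions = 0L) {
  if (is.character(proteins)) proteins <- AAStringSet(proteins)
  rows <- list()
  for (i in seq_along(proteins)) {
    s <- as.character(proteins[[i]])
    id <- names(proteins)[i]
    for (mo in motifs) {
      h <- scanMotif(s, mo, maxSubstitutions)
      if (nrow(h))
        rows[[length(rows) + 1L]] <-
          data.frame(protein_id = id, motif_name = h$pattern_name,
                     start_1based = h$start, matched_span = h$matched_span,
                     substitutions = h$substitutions,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), motif_name = character(),
                      start_1based = integer(), matched_span = character(),
                      substitutions = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
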