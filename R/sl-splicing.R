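# Spliced-leader (SL) read trimming, exact placement on scaffolds and
# transcription-start-site (TSS) clustering.
#
# Dinoflagellate mRNAs acquire a 22-nt spliced leader at their 5' end by
# trans-splicing; a TSS read beginning with the SL therefore marks a genuine
# transcript start. Trimming the leader from 99-nt TSS reads leaves 77-nt
# residues that place the start on the genome.

#' Match the spliced-leader prefix of reads
#'
#' Tests whether each read begins with the SL consensus. Degenerate
#' consensus positions (e.g. the leading `D` = A/G/T) must be satisfied by
#' one of their expansion bases and never consume mismatch budget;
#' non-degenerate positions tolerate at most `maxMismatch` violations in
#' total. Reads shorter than the consensus never match.
#'
#' @param reads Character vector or `DNAStringSet` of read sequences.
#' @param consensus SL consensus with IUPAC degeneracy
#'   (default [slConsensus()]).
#' @param maxMismatch Mismatches allowed at non-degenerate positions
#'   (default 0: exact SL removal).
#' @return data.frame with columns `read_id`, `match` (logical),
#'   `mismatches` (NA for too-short reads), `sl_first_base` (the realized
#'   base at the degenerate first position; NA when unmatched).
#' @export
#' @examples
#' matchSLPrefix(paste0("TCCGTAGCCATTTTGGCTCAAG", strrep("A", 77)))$match
matchSLPrefix <- function(reads, consensus = slConsensus(),
                          maxMismatch = 0L) {
  if (is(reads, "DNAStringSet")) {
    ids <- names(reads)
    reads <- as.character(reads)
  } else {
    ids <- names(reads)
  }
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  reads <- toupper(reads)
  motif <- compileMotif(consensus, alphabet = "nucleotide", name = "SL")
  m <- length(motif@elements)
  n <- length(reads)
  longEnough <- nchar(reads) >= m
  mism <- rep(NA_integer_, n)
  ok <- rep(FALSE, n)
  if (any(longEnough)) {
    idx <- which(longEnough)
    subs <- integer(length(idx))
    strictOk <- rep(TRUE, length(idx))
    for (j in seq_len(m)) {
      cj <- substring(reads[idx], j, j)
      el <- motif@elements[[j]]
      if (el$kind == "literal") {
        subs <- subs + (cj != el$letters)
      } else if (el$kind == "set") {
        strictOk <- strictOk & (cj %in% el$letters)
      }
    }
    mism[idx] <- subs
    ok[idx] <- strictOk & subs <= maxMismatch
  }
  first <- substring(reads, 1L, 1L)
  data.frame(read_id = ids, match = ok, mismatches = mism,
             sl_first_base = ifelse(ok, first, NA_character_),
             stringsAsFactors = FALSE)
}

#' Trim the spliced leader from TSS reads
#'
#' Removes the leading SL consensus from every read whose prefix matches
#' (see [matchSLPrefix()]); 99-nt inputs yield 77-nt residuals. Non-matching
#' reads are routed unchanged to the untrimmed stream, reads shorter than
#' the consensus to the too-short stream, and matching reads whose residual
#' would be empty are discarded with a flag. The three stream counts plus
#' discards always sum to the input count.
#'
#' @param reads `DNAStringSet` (or named character vector) of reads.
#' @param consensus SL consensus (default [slConsensus()]).
#' @param maxMismatch Mismatch budget at non-degenerate positions
#'   (default 0).
#' @return List with `trimmed` (`DNAStringSet` of residuals),
#'   `untrimmed`, `tooShort` (`DNAStringSet`s), `slFirstBase` (named
#'   character vector, one entry per trimmed read) and `counts` (list:
#'   `input`, `trimmed`, `untrimmed`, `too_short`, `empty_discarded`).
#' @export
trimSLReads <- function(reads, consensus = slConsensus(), maxMismatch = 0L) {
  if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
    reads <- DNAStringSet(reads)
  }
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  pref <- matchSLPrefix(reads, consensus, maxMismatch)
  sl <- nchar(consensus)
  tooShort <- width(reads) < sl
  matched <- pref$match & !tooShort
  emptyResidual <- matched & width(reads) == sl
  trimSel <- matched & !emptyResidual
  trimmed <- DNAStringSet(substring(as.character(reads[trimSel]), sl + 1L))
  names(trimmed) <- names(reads)[trimSel]
  sfb <- pref$sl_first_base[trimSel]
  names(sfb) <- names(reads)[trimSel]
  list(trimmed = trimmed,
       untrimmed = reads[!matched & !tooShort],
       tooShort = reads[tooShort],
       slFirstBase = sfb,
       counts = list(input = length(reads),
                     trimmed = sum(trimSel),
                     untrimmed = sum(!matched & !tooShort),
                     too_short = sum(tooShort),
                     empty_discarded = sum(emptyResidual)))
}

#' Place reads on scaffolds by exact full-length match
#'
#' Deterministic micro-mapper: every exact, full-length occurrence of each
#' read on either strand of the scaffolds is reported (minus-strand
#' occurrences are found via the reverse complement and reported at their
#' leftmost genomic coordinate). A read is `unique` when it has exactly one
#' occurrence genome-wide. Spliced or mismatch-tolerant alignment is out of
#' scope; precomputed placements may be supplied to
#' [detectTransSpliceSites()] instead.
#'
#' @param reads `DNAStringSet` (or named character vector) of (trimmed)
#'   reads.
#' @param scaffolds `DNAStringSet` of scaffold sequences.
#' @return List with `placements` (data.frame: `read_id`, `scaffold`,
#'   `start` 1-based, `end` inclusive, `strand`, `unique`), ordered by
#'   scaffold, start, strand, and `unmapped` (character vector of read ids
#'   with zero occurrences).
#' @export
mapReadsExact <- function(reads, scaffolds) {
  if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
    reads <- DNAStringSet(reads)
  }
  if (is.null(names(scaffolds)))
    names(scaffolds) <- paste0("scaffold_", seq_along(scaffolds))
  rows <- list()
  unmapped <- character()
  for (i in seq_along(reads)) {
    rid <- names(reads)[i]
    fw <- reads[[i]]
    rc <- reverseComplement(fw)
    found <- 0L
    for (k in seq_along(scaffolds)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") fw else rc
        mt <- matchPattern(pat, scaffolds[[k]])
        if (length(mt)) {
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = rid, scaffold = names(scaffolds)[k],
            start = start(mt), end = end(mt), strand = strand,
            stringsAsFactors = FALSE)
          found <- found + length(mt)
        }
      }
    }
    if (found == 0L) unmapped <- c(unmapped, rid)
  }
  if (!length(rows)) {
    pl <- data.frame(read_id = character(), scaffold = character(),
                     start = integer(), end = integer(), strand = character(),
                     unique = logical(), stringsAsFactors = FALSE)
    return(list(placements = pl, unmapped = unmapped))
  }
  pl <- do.call(rbind, rows)
  hitCount <- table(pl$read_id)
  pl$unique <- as.vector(hitCount[pl$read_id]) == 1L
  pl <- pl[order(pl$scaffold, pl$start, pl$strand, pl$read_id), ,
           drop = FALSE]
  rownames(pl) <- NULL
  list(placements = pl, unmapped = unmapped)
}

# Single-linkage clustering of sorted 1-D positions: break where the gap to
# the previous member exceeds clusterGap.
.clusterPositions <- function(positions, clusterGap) {
  positions <- sort(positions)
  breaks <- c(0L, which(diff(positions) > clusterGap), length(positions))
  lapply(seq_len(length(breaks) - 1L), function(i)
    positions[(breaks[i] + 1L):breaks[i + 1L]])
}

#' Detect trans-splice-supported transcription start sites per gene
#'
#' For each gene model, takes the uniquely placed, sense-strand SL-trimmed
#' reads whose 5' ends fall within the gene interval extended upstream by
#' `upstreamMargin`, single-linkage clusters those 5' positions with maximum
#' within-cluster gap `clusterGap`, and reports clusters supported by at
#' least `minSupport` reads. The number of reported clusters is the
#' predicted transcript count for the gene: two well-separated SL read
#' pileups mean two transcripts generated by trans-splicing.
#'
#' @param placements data.frame as produced by [mapReadsExact()] (columns
#'   `read_id`, `scaffold`, `start`, `end`, `strand`, `unique`).
#' @param geneModels data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end` (1-based inclusive), `strand`.
#' @param clusterGap Maximum gap (nt) joining 5' positions into one cluster
#'   (default 50).
#' @param minSupport Minimum reads per reported cluster (default 2).
#' @param upstreamMargin Upstream extension (nt) of the gene interval
#'   searched for SL sites (default 500).
#' @return List with `clusters` (data.frame: `gene_id`,
#'   `representative_position` — the most supported position, ties to the
#'   smallest —, `support`, `positions` semicolon-joined) and `transcripts`
#'   (data.frame: `gene_id`, `n_unique_reads`, `n_clusters`,
#'   `transcript_count`). Genes with no qualifying placements report
#'   transcript count 0.
#' @export
detectTransSpliceSites <- function(placements, geneModels,
                                   clusterGap = 50L, minSupport = 2L,
                                   upstreamMargin = 500L) {
  stopifnot(all(c("gene_id", "scaffold", "start", "end", "strand") %in%
                  names(geneModels)))
  clRows <- list(); txRows <- list()
  for (g in seq_len(nrow(geneModels))) {
    gm <- geneModels[g, ]
    sel <- placements$unique &
      placements$scaffold == gm$scaffold &
      placements$strand == gm$strand
    p <- placements[sel, , drop = FALSE]
    fivePrime <- ifelse(p$strand == "+", p$start, p$end)
    lo <- if (gm$strand == "+") gm$start - upstreamMargin else gm$start
    hi <- if (gm$strand == "+") gm$end else gm$end + upstreamMargin
    inGene <- fivePrime >= lo & fivePrime <= hi
    pos <- fivePrime[inGene]
    nClusters <- 0L
    if (length(pos)) {
      for (cl in .clusterPositions(pos, clusterGap)) {
        if (length(cl) < minSupport) next
        nClusters <- nClusters + 1L
        counts <- table(cl)
        rep_pos <- as.integer(names(counts)[which.max(counts)])
        clRows[[length(clRows) + 1L]] <- data.frame(
          gene_id = gm$gene_id, representative_position = rep_pos,
          support = length(cl),
          positions = paste(sort(unique(cl)), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    txRows[[length(txRows) + 1L]] <- data.frame(
      gene_id = gm$gene_id, n_unique_reads = length(pos),
      n_clusters = nClusters, transcript_count = nClusters,
      stringsAsFactors = FALSE)
  }
  clusters <- if (length(clRows)) do.call(rbind, clRows) else
    data.frame(gene_id = character(), representative_position = integer(),
               support = integer(), positions = character(),
               stringsAsFactors = FALSE)
  list(clusters = clusters, transcripts = do.call(rbind, txRows))
}

#' Write placements as BED
#'
#' @param placements Placement data.frame (see [mapReadsExact()]).
#' @param file Output path. BED is 0-based half-open, so `start - 1` is
#'   written.
#' @export
writePlacementsBED <- function(placements, file) {
  bed <- data.frame(chrom = placements$scaffold,
                    chromStart = placements$start - 1L,
                    chromEnd = placements$end,
                    name = placements$read_id,
                    score = ifelse(placements$unique, 1L, 0L),
                    strand = placements$strand)
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read gene models from a GFF-like TSV or BED file
#'
#' @param file Path. A BED file (no header, 0-based half-open) is converted
#'   to 1-based inclusive; a GFF-like TSV must carry a header with columns
#'   `gene_id`, `scaffold`, `start`, `end`, `strand` (1-based inclusive).
#' @param format `"tsv"` (default) or `"bed"`.
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`.
#' @export
readGeneModels <- function(file, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- read.delim(file, header = FALSE, comment.char = "#")
    stopifnot(ncol(bed) >= 6L)
    return(data.frame(gene_id = as.character(bed[[4]]),
                      scaffold = as.character(bed[[1]]),
                      start = as.integer(bed[[2]]) + 1L,
                      end = as.integer(bed[[3]]),
                      strand = as.character(bed[[6]]),
                      stringsAsFactors = FALSE))
  }
  tab <- read.delim(file, comment.char = "#")
  stopifnot(all(c("gene_id", "scaffold", "start", "end", "strand") %in%
                  names(tab)))
  tab[, c("gene_id", "scaffold", "start", "end", "strand")]
}
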