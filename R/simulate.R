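# Synthetic-fixture generators. Each generator is deterministic given
# (parameters, seed) and returns the fixture together with a machine-readable
# `truth` record of what was planted, so round-trip tests read only the
# truth and never re-derive it.

# Evaluate expr with a locally seeded RNG, restoring global RNG state.
.withSeed <- function(seed, expr) {
  force(seed)  # evaluate caller expressions before snapshotting RNG state
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.randomResidues <- function(n) {
  paste(sample(.PROTEIN_LETTERS, n, replace = TRUE), collapse = "")
}

.randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Concrete instance of a compiled motif: literals kept, sets/wildcards drawn
# at random (an instance always scans with substitutions = 0).
.instantiateMotif <- function(motif) {
  paste(vapply(motif@elements, function(el) {
    switch(el$kind,
           literal = el$letters,
           set = sample(el$letters, 1L),
           wild = if (motif@alphabet == "protein")
             sample(.PROTEIN_LETTERS, 1L) else sample(c("A","C","G","T"), 1L))
  }, ""), collapse = "")
}

# Motif planted for each domain code, plus extra residues required downstream.
.DOMAIN_MOTIFS <- list(
  KS = "DTACSS", AT = "GHSLG", KR = "GxGxxGxxxA",
  DH = "HxxxGxxxx", ER = "LxHxxxGGVG", HXXPF = "HxxPF"
)
# KS additionally needs the catalytic His (+20 aa) and Lys (+45 aa)
# downstream of the motif end for the active-site check to succeed.
.KS_HIS_OFFSET <- 20L
.KS_LYS_OFFSET <- 45L

#' Simulate a PKS protein with a planted domain architecture
#'
#' Builds a protein of `lengthAA` residues with i.i.d. uniform background
#' composition, splits it into one equal slot per domain of the requested
#' architecture, and plants each domain's signature motif at a recorded
#' position inside its slot (KS gets `DTACSS` plus a histidine 20 aa and a
#' lysine 45 aa downstream of the motif; AT gets `GHSLG`; KR, DH, ER and
#' HXXPF their respective signatures; domains without a signature occupy a
#' slot with background only). Optionally each planted motif position is
#' mutated with probability `mutationRate`.
#'
#' @param architecture An [Architecture-class] or architecture string.
#' @param lengthAA Protein length; rejected (naming the minimum) when too
#'   small to host all motifs.
#' @param mutationRate Per-motif-position mutation probability (default 0).
#' @param seed Integer seed; identical (parameters, seed) give identical
#'   output.
#' @param ntermVariant Optional core tetrapeptide (e.g. `"GYLG"`) planting
#'   an `E-x-E-x-<tetra>` signature at residue 3.
#' @return List with `protein` (named character scalar), `truth`
#'   (data.frame: `domain`, `motif_name`, `start`, `end`, `instance`,
#'   `mutated`), and `geneId`.
#' @export
#' @examples
#' sim <- simulatePKSProtein("KS", 200, seed = 1)
#' sim$truth
simulatePKSProtein <- function(architecture, lengthAA = 600L,
                               mutationRate = 0, seed = 1L,
                               ntermVariant = NULL) {
  if (is.character(architecture)) architecture <- parseArchitecture(architecture)
  d <- architecture@domains
  needs <- vapply(d, function(code) {
    pat <- .DOMAIN_MOTIFS[[code]]
    if (is.null(pat)) 2L
    else if (code == "KS") nchar(pat) + .KS_LYS_OFFSET + 2L
    else nchar(pat) + 2L
  }, integer(1))
  ntermNeed <- if (is.null(ntermVariant)) 0L else 12L
  # every equal-width slot must host its domain's motif (plus the KS
  # downstream residues), so the binding need is the largest one
  minLen <- length(d) * max(needs) + ntermNeed
  if (lengthAA < minLen)
    stop("lengthAA too small to host all motifs; minimum is ", minLen)
  .withSeed(seed, {
    chars <- strsplit(.randomResidues(lengthAA), "")[[1]]
    slot <- floor((lengthAA - ntermNeed) / length(d))
    truth <- list()
    offset <- ntermNeed
    if (!is.null(ntermVariant)) {
      stopifnot(nchar(ntermVariant) == 4L)
      sig <- strsplit(paste0("E", sample(.PROTEIN_LETTERS, 1L),
                             "E", sample(.PROTEIN_LETTERS, 1L),
                             ntermVariant), "")[[1]]
      chars[3:10] <- sig
    }
    for (k in seq_along(d)) {
      code <- d[k]
      pat <- .DOMAIN_MOTIFS[[code]]
      if (is.null(pat)) next
      motif <- compileMotif(pat, name = code)
      inst <- .instantiateMotif(motif)
      at <- offset + (k - 1L) * slot + 1L
      instChars <- strsplit(inst, "")[[1]]
      mutated <- rep(FALSE, length(instChars))
      if (mutationRate > 0) {
        hit <- runif(length(instChars)) < mutationRate
        for (p in which(hit)) {
          instChars[p] <- sample(setdiff(.PROTEIN_LETTERS, instChars[p]), 1L)
        }
        mutated <- hit
      }
      chars[at:(at + length(instChars) - 1L)] <- instChars
      if (code == "KS") {
        mEnd <- at + length(instChars) - 1L
        chars[mEnd + .KS_HIS_OFFSET] <- "H"
        chars[mEnd + .KS_LYS_OFFSET] <- "K"
      }
      truth[[length(truth) + 1L]] <- data.frame(
        domain = code, motif_name = code, start = at,
        end = at + length(instChars) - 1L,
        instance = paste(instChars, collapse = ""),
        mutated = any(mutated), stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(domain = character(), motif_name = character(),
                 start = integer(), end = integer(), instance = character(),
                 mutated = logical(), stringsAsFactors = FALSE)
    protein <- paste(chars, collapse = "")
    names(protein) <- architecture@geneId
    list(protein = protein, truth = truth, geneId = architecture@geneId)
  })
}

#' Simulate a spliced-leader TSS read set
#'
#' Generates a random scaffold, a plus-strand gene model spanning the
#' requested transcription start sites, and `readsPerTSS` reads per TSS.
#' With probability `slFraction` a read is trans-spliced: the 22-nt SL
#' consensus (degenerate first base drawn uniformly from T/A/G) is prepended
#' to the genomic residue starting at the TSS, giving a `readLength`-nt read
#' whose residual after trimming is `readLength - 22` nt. Non-SL reads are
#' plain genomic `readLength`-mers from the TSS.
#'
#' @param tssPositions Integer vector of TSS coordinates (1-based) on the
#'   scaffold; must fit inside the scaffold.
#' @param readsPerTSS Reads generated per TSS (recycled).
#' @param slFraction Fraction of reads carrying the SL (default 1).
#' @param readLength Read length in nt (default 99, the TSS library read
#'   length).
#' @param scaffoldLength Scaffold length (default: large enough for the
#'   rightmost TSS plus read plus margin).
#' @param seed Integer seed.
#' @return List with `reads` (`DNAStringSet`), `scaffold` (`DNAStringSet`
#'   of 1), `geneModel` (data.frame), and `truth` (data.frame: `read_id`,
#'   `tss`, `sl` logical, `sl_first_base`).
#' @export
simulateSLReadSet <- function(tssPositions, readsPerTSS = 5L,
                              slFraction = 1, readLength = 99L,
                              scaffoldLength = NULL, seed = 1L) {
  sl <- slConsensus()
  slLen <- nchar(sl)
  resLen <- readLength - slLen
  stopifnot(resLen > 0L, all(tssPositions >= 1L))
  if (is.null(scaffoldLength))
    scaffoldLength <- max(tssPositions) + readLength + 200L
  if (max(tssPositions) + readLength - 1L > scaffoldLength)
    stop("TSS outside scaffold: need scaffoldLength >= ",
         max(tssPositions) + readLength - 1L)
  .withSeed(seed, {
    scaffold <- .randomBases(scaffoldLength)
    nPer <- rep_len(readsPerTSS, length(tssPositions))
    ids <- character(); seqs <- character()
    tss <- integer(); isSL <- logical(); firstBase <- character()
    ri <- 0L
    for (t in seq_along(tssPositions)) {
      for (k in seq_len(nPer[t])) {
        ri <- ri + 1L
        p <- tssPositions[t]
        withSL <- runif(1) < slFraction
        if (withSL) {
          fb <- sample(c("T", "A", "G"), 1L)
          leader <- paste0(fb, substring(sl, 2L))
          sq <- paste0(leader, substring(scaffold, p, p + resLen - 1L))
        } else {
          fb <- NA_character_
          sq <- substring(scaffold, p, p + readLength - 1L)
        }
        ids <- c(ids, sprintf("read_%04d", ri))
        seqs <- c(seqs, sq)
        tss <- c(tss, p); isSL <- c(isSL, withSL)
        firstBase <- c(firstBase, fb)
      }
    }
    reads <- DNAStringSet(seqs); names(reads) <- ids
    scaff <- DNAStringSet(scaffold); names(scaff) <- "scaffold_1"
    geneModel <- data.frame(
      gene_id = "gene_1", scaffold = "scaffold_1",
      start = min(tssPositions),
      end = min(max(tssPositions) + readLength + 100L, scaffoldLength),
      strand = "+", stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids, tss = tss, sl = isSL,
                        sl_first_base = firstBase, stringsAsFactors = FALSE)
    list(reads = reads, scaffold = scaff, geneModel = geneModel,
         truth = truth)
  })
}

#' Simulate an observed-ion list from a neutral formula
#'
#' Theoretical adduct m/z values receive Gaussian mass error of standard
#' deviation `noiseSdMmu` milli-mass-units (the error model of a
#' high-resolution orbitrap at the few-mmu scale); decoy ions are drawn
#' uniformly over the instrument scan range m/z 400-2000.
#'
#' @param formula Neutral formula string.
#' @param adducts Adduct list (default [defaultAdducts()]).
#' @param noiseSdMmu Mass-error standard deviation in mmu (>= 0).
#' @param nDecoys Number of uniform decoy ions (default 0).
#' @param scanRange Numeric length-2 scan range for decoys
#'   (default `c(400, 2000)`).
#' @param seed Integer seed.
#' @return List with `observed` (data.frame: `mz`, shuffled) and `truth`
#'   (data.frame: `mz`, `source` — adduct name or `"decoy"`,
#'   `theoretical_mz`).
#' @export
simulateIonList <- function(formula, adducts = defaultAdducts(),
                            noiseSdMmu = 1.0, nDecoys = 0L,
                            scanRange = c(400, 2000), seed = 1L) {
  if (noiseSdMmu < 0) stop("noiseSdMmu must be >= 0")
  neutral <- parseFormula(formula)
  .withSeed(seed, {
    theo <- vapply(adducts, function(ad) adductMz(neutral, ad), numeric(1))
    obs <- theo + rnorm(length(theo), 0, noiseSdMmu) / 1000
    src <- vapply(adducts, `[[`, "", "name")
    if (nDecoys > 0L) {
      dec <- runif(nDecoys, scanRange[1], scanRange[2])
      obs <- c(obs, dec)
      theo <- c(theo, rep(NA_real_, nDecoys))
      src <- c(src, rep("decoy", nDecoys))
    }
    ord <- sample(seq_along(obs))
    truth <- data.frame(mz = obs[ord], source = src[ord],
                        theoretical_mz = theo[ord], stringsAsFactors = FALSE)
    list(observed = data.frame(mz = truth$mz), truth = truth)
  })
}

#' Simulate a clade-structured protein alignment
#'
#' A common root sequence is mutated into one ancestor per clade at
#' `betweenDiv` substitutions per site, and each ancestor into
#' `seqsPerClade` leaves (plus optional queries) at `withinDiv` per site.
#' No indels are introduced, so the rows are aligned by construction.
#'
#' @param nClades Number of clades (default 3: the dinoflagellate
#'   single-domain, protist multi-domain and bacterial groups of a KS
#'   survey).
#' @param seqsPerClade Reference rows per clade (default 5).
#' @param length Alignment columns (default 235, a trimmed KS domain).
#' @param withinDiv,betweenDiv Per-site substitution probabilities within
#'   and between clades; both must lie in `[0, 1]`.
#' @param queriesPerClade Extra rows per clade labelled `"QUERY"`
#'   (default 0); their generating clade is recorded in the truth.
#' @param seed Integer seed.
#' @return List with `alignment` (a [CladeAlignment-class]) and `truth`
#'   (data.frame: `id`, `label`, `true_clade`).
#' @export
simulateCladeAlignment <- function(nClades = 3L, seqsPerClade = 5L,
                                   length = 235L, withinDiv = 0.1,
                                   betweenDiv = 0.4, queriesPerClade = 0L,
                                   seed = 1L) {
  if (withinDiv < 0 || withinDiv > 1 || betweenDiv < 0 || betweenDiv > 1)
    stop("divergences must lie in [0, 1]")
  mutate <- function(chars, rate) {
    hit <- which(runif(base::length(chars)) < rate)
    for (p in hit)
      chars[p] <- sample(setdiff(.PROTEIN_LETTERS, chars[p]), 1L)
    chars
  }
  .withSeed(seed, {
    root <- strsplit(.randomResidues(length), "")[[1]]
    seqs <- character(); labels <- character(); trueClade <- character()
    ids <- character()
    for (c_i in seq_len(nClades)) {
      cladeName <- paste0("clade", LETTERS[c_i])
      anc <- mutate(root, betweenDiv)
      for (s_i in seq_len(seqsPerClade)) {
        leaf <- mutate(anc, withinDiv)
        ids <- c(ids, paste0(cladeName, "_ref", s_i))
        seqs <- c(seqs, paste(leaf, collapse = ""))
        labels <- c(labels, cladeName)
        trueClade <- c(trueClade, cladeName)
      }
      if (queriesPerClade > 0L) {
        for (q_i in seq_len(queriesPerClade)) {
          leaf <- mutate(anc, withinDiv)
          ids <- c(ids, paste0(cladeName, "_query", q_i))
          seqs <- c(seqs, paste(leaf, collapse = ""))
          labels <- c(labels, "QUERY")
          trueClade <- c(trueClade, cladeName)
        }
      }
    }
    names(seqs) <- ids
    list(alignment = CladeAlignment(seqs, labels),
         truth = data.frame(id = ids, label = labels,
                            true_clade = trueClade, stringsAsFactors = FALSE))
  })
}
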