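# Survey orchestration: motif verification -> architecture classification ->
# tandem clustering -> SL analysis -> clade assignment -> metabolite
# matching, with a Table-1-style per-gene report and machine-readable counts.

#' Packaged KS gene survey table
#'
#' The 25 KS-domain-containing gene models of the *S. minutum* genome survey
#' with protein length, domain-architecture string and scaffold. The hybrid
#' NRPS-PKS gene (symbB1.v1.2.012436.t1) has no printed architecture string;
#' its entry is a reconstruction of the published 8-module schematic
#' (3 NRPS modules — one of them the C-HxxPF-A NRPS-like assembly — and
#' 5 PKS modules, thioesterase terminal).
#'
#' @param file Path to a survey TSV (`gene_id`, `total_aa`, `domain_string`,
#'   `scaffold`); defaults to the packaged table.
#' @return data.frame.
#' @export
ksGeneSurvey <- function(file = system.file("extdata", "ks_gene_survey.tsv",
                                            package = "dinoPKS")) {
  read.delim(file, comment.char = "#", colClasses = c(
    gene_id = "character", total_aa = "integer",
    domain_string = "character", scaffold = "character"))
}

#' Packaged Symbiodinium compound table
#'
#' Known secondary metabolites isolated from *Symbiodinium* spp. with their
#' reported m/z values, used to screen observed polyhydroxy ions against
#' already-described molecules.
#'
#' @param file Path to a compound TSV (`name`, `reported_mz`); defaults to
#'   the packaged table.
#' @return data.frame.
#' @export
symbiodiniumCompounds <- function(
    file = system.file("extdata", "symbiodinium_compounds.tsv",
                       package = "dinoPKS")) {
  read.delim(file, comment.char = "#")
}

#' Packaged observed high-resolution ions for zooxanthellamide D
#'
#' The three positive-mode ions observed for ZAD-D (neutral formula
#' C54H83NO19): protonated, ammoniated and sodiated, printed at 4 decimal
#' places.
#'
#' @param file Path to an ion TSV (`ion`, `mz`); defaults to the packaged
#'   table.
#' @return data.frame.
#' @export
zadObservedIons <- function(file = system.file("extdata", "zad_observed_ions.tsv",
                                               package = "dinoPKS")) {
  read.delim(file, comment.char = "#")
}

#' Read an architecture table
#'
#' @param file TSV with columns `gene_id`, `domain_string` and optionally
#'   `total_aa`, `scaffold`. Rows whose `domain_string` is not a parseable
#'   code list (e.g. figure references) are returned in the `unparsed`
#'   component rather than silently dropped.
#' @return List with `architectures` (list of [Architecture-class]),
#'   `table` (the input rows that parsed) and `unparsed` (rows that did
#'   not).
#' @export
readArchitectureTable <- function(file) {
  tab <- read.delim(file, comment.char = "#",
                    colClasses = list(gene_id = "character",
                                      domain_string = "character"))
  stopifnot(all(c("gene_id", "domain_string") %in% names(tab)))
  archs <- list(); okRows <- integer()
  for (i in seq_len(nrow(tab))) {
    a <- tryCatch(
      parseArchitecture(tab$domain_string[i], tab$gene_id[i],
                        if ("total_aa" %in% names(tab)) tab$total_aa[i]
                        else NA_real_),
      error = function(e) NULL)
    if (!is.null(a)) {
      archs[[length(archs) + 1L]] <- a
      okRows <- c(okRows, i)
    }
  }
  list(architectures = archs,
       table = tab[okRows, , drop = FALSE],
       unparsed = tab[setdiff(seq_len(nrow(tab)), okRows), , drop = FALSE])
}

#' Run the full PKS gene survey
#'
#' Orchestrates every characterization stage for which inputs are supplied;
#' absent stages are skipped and their report columns left empty (never
#' fabricated). Outputs are deterministic given fixed inputs: rows are
#' sorted by gene id and floats written with fixed formatting, so reruns on
#' identical inputs reproduce identical report bytes.
#'
#' @param proteins Protein FASTA path or `AAStringSet` (motif/active-site
#'   stage).
#' @param archTable Architecture TSV path or data.frame with `gene_id`,
#'   `domain_string`, optional `total_aa`, `scaffold` (classification +
#'   tandem stage).
#' @param reads Read FASTA/FASTQ path or `DNAStringSet` (SL stage; needs
#'   `scaffolds` and `geneModels`).
#' @param scaffolds Scaffold FASTA path or `DNAStringSet`.
#' @param geneModels Gene-model data.frame or TSV/BED path (see
#'   [readGeneModels()]).
#' @param ions Observed-ion TSV path (column `mz`) or numeric vector
#'   (metabolite stage; needs `candidates`).
#' @param candidates Candidate TSV path (columns `name`, `formula`) or
#'   data.frame.
#' @param refAlignment Clade-labelled aligned FASTA path or
#'   [CladeAlignment-class] (clade stage; query rows labelled `QUERY`).
#' @param outDir Output directory (created if missing); when `NULL` nothing
#'   is written and the report objects are only returned.
#' @param params Named list of stage parameters overriding
#'   [surveyDefaults()].
#' @return (Invisibly) a list with `report` (one row per gene:
#'   `gene_id`, `total_aa`, `domain_string`, `gene_class`,
#'   `ks_active_site_overall`, `nterm_variant`, `scaffold`,
#'   `tandem_cluster_id`, `transcript_count`, `clade`), `modules`,
#'   `motifs`, `tandem`, `ionMatches`, `cladeAssignments`, `counts`.
#' @export
runSurvey <- function(proteins = NULL, archTable = NULL, reads = NULL,
                      scaffolds = NULL, geneModels = NULL, ions = NULL,
                      candidates = NULL, refAlignment = NULL,
                      outDir = NULL, params = list()) {
  p <- surveyDefaults()
  p[names(params)] <- params
  if (is.null(proteins) && is.null(archTable))
    stop("mandatory input missing: supply a protein FASTA and/or an ",
         "architecture table")
  counts <- list()

  # --- architecture stage ------------------------------------------------
  archRows <- NULL; modules <- NULL; tandem <- NULL
  if (!is.null(archTable)) {
    if (is.character(archTable)) {
      parsed <- readArchitectureTable(archTable)
    } else {
      tmp <- archTable
      stopifnot(all(c("gene_id", "domain_string") %in% names(tmp)))
      parsed <- list(architectures = lapply(seq_len(nrow(tmp)), function(i)
        parseArchitecture(tmp$domain_string[i], tmp$gene_id[i],
                          if ("total_aa" %in% names(tmp)) tmp$total_aa[i]
                          else NA_real_)),
        table = tmp,
        unparsed = tmp[0, , drop = FALSE])
    }
    counts$architectures_parsed <- length(parsed$architectures)
    counts$architectures_unparsed <- nrow(parsed$unparsed)
    tab <- parsed$table
    cls <- vapply(parsed$architectures, classifyGene, "")
    archRows <- data.frame(
      gene_id = tab$gene_id,
      total_aa = if ("total_aa" %in% names(tab)) tab$total_aa else NA_integer_,
      domain_string = tab$domain_string,
      gene_class = cls,
      scaffold = if ("scaffold" %in% names(tab)) as.character(tab$scaffold)
                 else NA_character_,
      stringsAsFactors = FALSE)
    counts$gene_class <- as.list(table(cls))
    modRows <- lapply(parsed$architectures, function(a) {
      m <- decomposeModules(a)
      cbind(gene_id = a@geneId, m, stringsAsFactors = FALSE)
    })
    modules <- do.call(rbind, modRows)
    tandem <- findTandemClusters(archRows)
    counts$tandem_clusters <- nrow(tandem)
  }

  # --- protein motif stage ----------------------------------------------
  motifReport <- NULL; ksReport <- NULL
  if (!is.null(proteins)) {
    if (is.character(proteins) && length(proteins) == 1L &&
        file.exists(proteins)) {
      proteins <- if (file.size(proteins) > 0) readAAStringSet(proteins)
                  else AAStringSet()
    } else if (is.character(proteins)) {
      proteins <- AAStringSet(proteins)
    }
    counts$proteins <- length(proteins)
    motifReport <- scanProteinSet(proteins,
                                  maxSubstitutions = p$motif_max_substitutions)
    ksRows <- lapply(seq_along(proteins), function(i) {
      s <- as.character(proteins[[i]])
      ks <- verifyKSActiveSite(s, p$ks_max_substitutions,
                               p$his_window, p$lys_window)
      nt <- classifyNTermSignature(s, p$nterm_search_limit, p$nterm_min_score)
      data.frame(gene_id = names(proteins)[i],
                 motif_found = !is.null(ks$motif_hit),
                 cys_ok = ks$cys_ok, his_ok = ks$his_ok, lys_ok = ks$lys_ok,
                 ks_active_site_overall = ks$overall,
                 nterm_variant = nt$variant_label,
                 stringsAsFactors = FALSE)
    })
    ksReport <- if (length(ksRows)) do.call(rbind, ksRows) else
      data.frame(gene_id = character(), motif_found = logical(),
                 cys_ok = logical(), his_ok = logical(), lys_ok = logical(),
                 ks_active_site_overall = logical(),
                 nterm_variant = character(), stringsAsFactors = FALSE)
    counts$ks_active_sites_ok <- sum(ksReport$ks_active_site_overall)
  }

  # --- SL / transcript stage ---------------------------------------------
  transcripts <- NULL
  if (!is.null(reads) && !is.null(scaffolds) && !is.null(geneModels)) {
    if (is.character(reads)) {
      fmt <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE))
        "fastq" else "fasta"
      reads <- readDNAStringSet(reads, format = fmt)
    }
    if (is.character(scaffolds)) scaffolds <- readDNAStringSet(scaffolds)
    if (is.character(geneModels)) geneModels <- readGeneModels(geneModels)
    tr <- trimSLReads(reads, maxMismatch = p$sl_max_mismatch)
    counts$reads <- tr$counts
    mp <- mapReadsExact(tr$trimmed, scaffolds)
    counts$reads_unmapped <- length(mp$unmapped)
    counts$placements_multi <- sum(!mp$placements$unique)
    det <- detectTransSpliceSites(mp$placements, geneModels,
                                  p$cluster_gap, p$min_support,
                                  p$upstream_margin)
    transcripts <- det$transcripts
    counts$tss_clusters <- nrow(det$clusters)
  }

  # --- metabolite stage ----------------------------------------------------
  ionMatches <- NULL
  if (!is.null(ions) && !is.null(candidates)) {
    if (is.character(ions) && length(ions) == 1L && file.exists(ions))
      ions <- read.delim(ions, comment.char = "#")$mz
    if (is.character(candidates) && length(candidates) == 1L &&
        file.exists(candidates))
      candidates <- read.delim(candidates, comment.char = "#")
    ionMatches <- matchIons(ions, candidates,
                            toleranceMmu = p$tolerance_mmu)
    counts$ions_observed <- length(ions)
    counts$ions_matched <- nrow(ionMatches)
  }

  # --- clade stage ---------------------------------------------------------
  cladeAssignments <- NULL
  if (!is.null(refAlignment)) {
    if (is.character(refAlignment))
      refAlignment <- readCladeAlignment(refAlignment)
    cladeAssignments <- assignCladeSet(refAlignment, p$min_overlap)
    counts$clade_queries <- nrow(cladeAssignments)
  }

  # --- merge the per-gene report -------------------------------------------
  geneIds <- sort(unique(c(
    if (!is.null(archRows)) archRows$gene_id,
    if (!is.null(ksReport)) ksReport$gene_id)))
  report <- data.frame(gene_id = geneIds, stringsAsFactors = FALSE)
  pull <- function(tab, col) {
    if (is.null(tab) || !nrow(tab)) return(rep(NA, length(geneIds)))
    tab[[col]][match(geneIds, tab$gene_id)]
  }
  report$total_aa <- pull(archRows, "total_aa")
  report$domain_string <- pull(archRows, "domain_string")
  report$gene_class <- pull(archRows, "gene_class")
  report$ks_active_site_overall <- pull(ksReport, "ks_active_site_overall")
  report$nterm_variant <- pull(ksReport, "nterm_variant")
  report$scaffold <- pull(archRows, "scaffold")
  if (!is.null(tandem) && nrow(tandem)) {
    scaf2cluster <- setNames(tandem$cluster_id, tandem$scaffold)
    report$tandem_cluster_id <- unname(scaf2cluster[as.character(report$scaffold)])
  } else {
    report$tandem_cluster_id <- rep(NA_character_, nrow(report))
  }
  report$transcript_count <- pull(transcripts, "transcript_count")
  report$clade <- if (!is.null(cladeAssignments) && nrow(cladeAssignments))
    cladeAssignments$clade[match(geneIds, cladeAssignments$query_id)]
  else rep(NA_character_, nrow(report))

  out <- list(report = report, modules = modules, motifs = motifReport,
              ksReport = ksReport, tandem = tandem,
              transcripts = transcripts, ionMatches = ionMatches,
              cladeAssignments = cladeAssignments, counts = counts)
  if (!is.null(outDir)) .writeSurveyOutputs(out, outDir)
  invisible(out)
}

.writeSurveyOutputs <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    if (is.null(x)) return()
    write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(out$report, "survey.tsv")
  wt(out$modules, "modules.tsv")
  wt(out$motifs, "motifs.tsv")
  wt(out$ksReport, "ks_active_sites.tsv")
  wt(out$tandem, "tandem_clusters.tsv")
  wt(out$transcripts, "transcripts.tsv")
  if (!is.null(out$ionMatches)) {
    im <- out$ionMatches
    im$theoretical_mz <- sprintf("%.4f", im$theoretical_mz)
    im$delta_mmu <- sprintf("%.2f", im$delta_mmu)
    wt(im, "ion_matches.tsv")
  }
  wt(out$cladeAssignments, "clade_assignments.tsv")
  write_json(out$counts, file.path(outDir, "counts.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Default survey parameters
#'
#' One flat namespace holding every tunable stage parameter with its
#' default: motif substitution budgets, KS active-site windows, N-terminal
#' signature search settings, SL mismatch budget, TSS clustering gap /
#' support / upstream margin, ion tolerance and clade overlap threshold.
#'
#' @return Named list.
#' @export
surveyDefaults <- function() {
  list(
    motif_max_substitutions = 0L,
    ks_max_substitutions = 2L,
    his_window = 200L,
    lys_window = 250L,
    nterm_search_limit = 150L,
    nterm_min_score = 4L,
    sl_max_mismatch = 0L,
    cluster_gap = 50L,
    min_support = 2L,
    upstream_margin = 500L,
    tolerance_mmu = 3.0,
    min_overlap = 0.5
  )
}
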