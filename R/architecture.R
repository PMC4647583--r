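# Domain-architecture parsing, gene classification, module decomposition and
# tandem-cluster detection.

#' Parse a hyphen-separated domain-architecture string
#'
#' @param archString e.g. `"AM-KS-KR-PP-KS-DH-KR-PP-KS"`. Tokens are
#'   case-insensitive and whitespace around hyphens is tolerated;
#'   `HxxPF` is accepted for the HXXPF condensation-like domain.
#' @param geneId Gene identifier attached to the result.
#' @param totalAA Optional protein length (residues).
#' @return An [Architecture-class] object preserving token order. Unknown
#'   tokens are rejected naming the token and its ordinal.
#' @export
#' @examples
#' parseArchitecture("AM-PP-KS-AT", "gene1")
parseArchitecture <- function(archString, geneId = "gene",
                              totalAA = NA_real_) {
  stopifnot(is.character(archString), length(archString) == 1L)
  toks <- trimws(strsplit(archString, "-", fixed = TRUE)[[1]])
  toks <- toupper(toks)
  if (!length(toks) || any(!nzchar(toks)))
    stop("empty domain token in architecture string '", archString, "'")
  bad <- which(!toks %in% .DOMAIN_CODES)
  if (length(bad))
    stop("unknown domain code '", toks[bad[1]], "' at token ", bad[1],
         " in architecture '", archString, "'")
  new("Architecture", geneId = geneId, domains = toks,
      totalAA = as.numeric(totalAA))
}

#' Build an Architecture from per-domain coordinate annotations
#'
#' @param coordTable data.frame with columns `domain_code`, `start_aa`,
#'   `end_aa` (1-based inclusive); rows are sorted by `start_aa`.
#' @param geneId Gene identifier.
#' @param totalAA Optional protein length.
#' @return An [Architecture-class] with `coords` attached. A coordinate
#'   input and an architecture string yielding the same ordered code list
#'   classify identically.
#' @export
architectureFromCoords <- function(coordTable, geneId = "gene",
                                   totalAA = NA_real_) {
  stopifnot(all(c("domain_code", "start_aa", "end_aa") %in% names(coordTable)))
  coordTable <- coordTable[order(coordTable$start_aa), , drop = FALSE]
  toks <- toupper(as.character(coordTable$domain_code))
  bad <- which(!toks %in% .DOMAIN_CODES)
  if (length(bad))
    stop("unknown domain code '", toks[bad[1]], "' at row ", bad[1])
  new("Architecture", geneId = geneId, domains = toks,
      totalAA = as.numeric(totalAA),
      coords = data.frame(start_aa = as.integer(coordTable$start_aa),
                          end_aa = as.integer(coordTable$end_aa)))
}

# Non-KS codes whose presence alongside KS marks a multifunctional PKS.
.PKS_COMPANIONS <- c("AT", "PP", "KR", "DH", "ER", "AM", "MT", "TE")

#' Classify a gene from its domain architecture
#'
#' Total classification rule: `HYBRID_NRPS_PKS` if the architecture carries
#' at least one KS and at least one NRPS domain (C or A); else `MULTI_PKS`
#' if KS occurs together with at least one companion PKS code
#' (AT, PP, KR, DH, ER, AM, MT, TE); else `SINGLE_KS` if the architecture is
#' exactly one KS; else `NON_PKS`.
#'
#' @param arch An [Architecture-class] (or an architecture string, parsed on
#'   the fly).
#' @return One of `"SINGLE_KS"`, `"MULTI_PKS"`, `"HYBRID_NRPS_PKS"`,
#'   `"NON_PKS"`.
#' @export
#' @examples
#' classifyGene("KS")                 # SINGLE_KS
#' classifyGene("AM-PP-KS-AT")        # MULTI_PKS
#' classifyGene("C-A-PP-KS-AT-PP")    # HYBRID_NRPS_PKS
classifyGene <- function(arch) {
  if (is.character(arch)) arch <- parseArchitecture(arch)
  d <- arch@domains
  hasKS <- "KS" %in% d
  if (hasKS && any(c("C", "A") %in% d)) return("HYBRID_NRPS_PKS")
  if (hasKS && any(.PKS_COMPANIONS %in% d)) return("MULTI_PKS")
  if (identical(d, "KS")) return("SINGLE_KS")
  "NON_PKS"
}

#' Decompose an architecture into assembly-line modules
#'
#' Greedy left-to-right segmentation following standard assembly-line
#' convention: each condensation (C) domain opens an NRPS module and each
#' ketosynthase (KS) opens a PKS module. Domains preceding the first anchor
#' form a loading module whose kind follows the first anchor. An NRPS module
#' containing HXXPF is relabelled `NRPS_LIKE`. Trailing domains (e.g. the
#' thioesterase) remain in the final module. Concatenating module members in
#' order reproduces the architecture.
#'
#' @param arch An [Architecture-class] or architecture string.
#' @return data.frame with one row per module: `index` (1-based), `kind`
#'   (`NRPS`, `PKS`, `NRPS_LIKE` or `LOADING_ONLY` when no anchor exists),
#'   `members` (hyphen-joined domain codes), `n_domains`, `loading`
#'   (logical).
#' @export
#' @examples
#' decomposeModules("C-A-PP-KS-AT-PP-KS-KR-PP-C-A-PP-TE")
decomposeModules <- function(arch) {
  if (is.character(arch)) arch <- parseArchitecture(arch)
  d <- arch@domains
  anchor <- d %in% c("C", "KS")
  if (!any(anchor)) {
    return(data.frame(index = 1L, kind = "LOADING_ONLY",
                      members = paste(d, collapse = "-"),
                      n_domains = length(d), loading = TRUE,
                      stringsAsFactors = FALSE))
  }
  firstAnchor <- which(anchor)[1]
  # module id: 0 for the loading region, then cumulative anchor count
  modId <- cumsum(anchor)
  kinds <- character(); members <- list(); loading <- logical()
  if (firstAnchor > 1L) {
    kinds <- if (d[firstAnchor] == "C") "NRPS" else "PKS"
    members <- list(d[seq_len(firstAnchor - 1L)])
    loading <- TRUE
  }
  for (k in seq_len(max(modId))) {
    mem <- d[modId == k]
    kind <- if (mem[1] == "C") "NRPS" else "PKS"
    if (kind == "NRPS" && "HXXPF" %in% mem) kind <- "NRPS_LIKE"
    kinds <- c(kinds, kind)
    members <- c(members, list(mem))
    loading <- c(loading, FALSE)
  }
  data.frame(index = seq_along(kinds), kind = kinds,
             members = vapply(members, paste, "", collapse = "-"),
             n_domains = lengths(members), loading = loading,
             stringsAsFactors = FALSE)
}

#' Count occurrences of a domain code in an architecture
#'
#' @param arch An [Architecture-class] or architecture string.
#' @param code A domain code, e.g. `"KS"`.
#' @return Integer count.
#' @export
#' @examples
#' countDomains("AM-KS-KR-PP-KS-DH-KR-PP-KS", "KS")  # 3
countDomains <- function(arch, code) {
  if (is.character(arch)) arch <- parseArchitecture(arch)
  code <- toupper(code)
  if (!code %in% .DOMAIN_CODES) stop("unknown domain code '", code, "'")
  sum(arch@domains == code)
}

#' Find tandemly arranged KS genes sharing a scaffold
#'
#' Groups KS-domain-containing genes by scaffold and reports every scaffold
#' carrying two or more of them, the pattern interpreted as tandem gene
#' expansion by duplication.
#'
#' @param geneTable data.frame with columns `gene_id`, `scaffold` and
#'   optionally `gene_class`; when `gene_class` is present, `NON_PKS` rows
#'   are excluded from clustering.
#' @return data.frame with columns `cluster_id`, `scaffold`, `n_genes`,
#'   `gene_ids` (semicolon-joined, input order preserved), ordered by
#'   scaffold. Zero rows when every gene sits on its own scaffold.
#' @export
findTandemClusters <- function(geneTable) {
  stopifnot(all(c("gene_id", "scaffold") %in% names(geneTable)))
  tab <- geneTable
  if ("gene_class" %in% names(tab))
    tab <- tab[tab$gene_class != "NON_PKS", , drop = FALSE]
  tab <- tab[!is.na(tab$scaffold) & nzchar(as.character(tab$scaffold)), ,
             drop = FALSE]
  if (!nrow(tab))
    return(data.frame(cluster_id = character(), scaffold = character(),
                      n_genes = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  groups <- split(as.character(tab$gene_id), as.character(tab$scaffold))
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups))
    return(data.frame(cluster_id = character(), scaffold = character(),
                      n_genes = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  groups <- groups[order(names(groups))]
  data.frame(cluster_id = paste0("tandem_", seq_along(groups)),
             scaffold = names(groups),
             n_genes = lengths(groups),
             gene_ids = vapply(groups, paste, "", collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}
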