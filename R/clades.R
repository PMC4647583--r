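# Distance-based ketosynthase clade assignment: p-distances over a trimmed
# KS alignment, Saitou-Nei neighbor joining, and nearest-clade labelling.
# A desk-scale, distance-based classifier: it assigns sequences to reference
# clades but does not estimate model-based phylogenies or support values.

#' Pairwise p-distance matrix over an alignment
#'
#' For each pair of rows, columns where either row carries a gap are
#' excluded and the distance is the fraction of mismatching compared
#' columns. Pairs with zero comparable columns receive distance 1 and are
#' flagged. An optional Poisson correction `-log(1 - p)` is available for
#' multiple hits.
#'
#' @param aln A [CladeAlignment-class], `AAStringSet` or character vector of
#'   equal-length gapped rows.
#' @param correction `"p"` (default, raw proportion) or `"poisson"`.
#' @return Square symmetric numeric matrix with zero diagonal; attribute
#'   `no_overlap` holds a two-column matrix of flagged index pairs (if any).
#'   Ragged input is rejected.
#' @export
#' @examples
#' pDistanceMatrix(c(a = "ACDE", b = "ACDF"))[1, 2]  # 0.25
pDistanceMatrix <- function(aln, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  rows <- .alignmentRows(aln)
  n <- length(rows)
  if (n < 2L) stop("alignment needs at least 2 rows")
  wid <- unique(nchar(rows))
  if (length(wid) != 1L) stop("ragged alignment: unequal row lengths")
  mat <- matrix(unlist(strsplit(rows, "")), nrow = n, byrow = TRUE)
  gap <- mat == "-"
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  flagged <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        p <- 1
        flagged <- rbind(flagged, c(i, j))
      } else {
        p <- sum(mat[i, comp] != mat[j, comp]) / nc
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  if (correction == "poisson") {
    off <- row(d) != col(d)
    d[off] <- -log(pmax(1 - d[off], .Machine$double.eps))
  }
  if (!is.null(flagged)) attr(d, "no_overlap") <- flagged
  d
}

.alignmentRows <- function(aln) {
  if (is(aln, "CladeAlignment")) {
    rows <- as.character(aln@sequences)
    if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
    return(rows)
  }
  if (is(aln, "AAStringSet")) aln <- as.character(aln)
  stopifnot(is.character(aln))
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  aln
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q(i,j) = (r - 2) d(i,j) - R(i) - R(j)`. Ties in Q are broken by the
#' smallest (i, j) index pair in the current working order (deterministic).
#' Negative branch lengths are clamped to zero with the remainder
#' transferred to the sibling branch, so each joined pair still spans
#' `d(i,j)`. NJ reconstructs the generating topology exactly whenever the
#' input matrix is additive.
#'
#' @param dm Square symmetric distance matrix with row/column names (taxon
#'   labels); unnamed matrices get `t1..tn`.
#' @return A newick string (rooted arbitrarily at the final 3-way join;
#'   topologically an unrooted tree). For n = 2 a trivial two-leaf tree; for
#'   n = 1 a single-leaf tree.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 0.5, 2, 0, 2, 0.5, 2, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' njTree(d)
njTree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  stopifnot(n == ncol(dm))
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 1L) return(paste0(labs[1], ";"))
  if (n == 2L)
    return(sprintf("(%s:%g,%s:%g);", labs[1], dm[1, 2] / 2,
                   labs[2], dm[1, 2] / 2))
  nodes <- labs              # newick fragment per active node
  D <- dm
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minimal Q
    minQ <- min(Q)
    best <- NULL
    for (i in seq_len(r - 1L)) {
      js <- which(Q[i, (i + 1L):r] <= minQ + 1e-12) + i
      if (length(js)) { best <- c(i, js[1]); break }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    newNode <- sprintf("(%s:%g,%s:%g)", nodes[i], li, nodes[j], lj)
    others <- setdiff(seq_len(r), c(i, j))
    newDist <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newDist),
               c(newDist, 0))
    nodes <- c(nodes[others], newNode)
  }
  # terminal 3-way join
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  sprintf("(%s:%g,%s:%g,%s:%g);", nodes[1], l1, nodes[2], l2, nodes[3], l3)
}

#' Assign a query sequence to its nearest reference clade
#'
#' Computes the mean p-distance from the query (a gapped row in the
#' reference alignment's coordinate system) to each labelled clade of the
#' reference and returns the clade with the smallest mean. The margin over
#' the runner-up quantifies confidence; exact ties are broken alphabetically
#' and flagged. Queries overlapping fewer than `minOverlap` of the non-gap
#' columns of every reference row are returned `UNASSIGNED`.
#'
#' @param queryRow Gapped query sequence (character scalar) with the same
#'   width as the reference alignment.
#' @param reference A [CladeAlignment-class]; rows labelled `"QUERY"` are
#'   ignored as references.
#' @param minOverlap Minimum fraction of a reference row's non-gap columns
#'   that must be comparable with the query (default 0.5).
#' @param queryId Identifier carried into the result.
#' @return data.frame row: `query_id`, `clade`, `mean_distance`, `margin`,
#'   `tie` (logical). `clade` is `"UNASSIGNED"` (with NA distances) when
#'   overlap is insufficient.
#' @export
assignClade <- function(queryRow, reference, minOverlap = 0.5,
                        queryId = "query") {
  stopifnot(is(reference, "CladeAlignment"))
  refSel <- reference@labels != "QUERY"
  refRows <- as.character(reference@sequences)[refSel]
  refLabels <- reference@labels[refSel]
  if (!length(refRows)) stop("reference has no labelled rows")
  wid <- width(reference@sequences)[1]
  if (nchar(queryRow) != wid)
    stop("query width (", nchar(queryRow), ") != alignment width (", wid, ")")
  q <- strsplit(toupper(queryRow), "")[[1]]
  qGap <- q == "-"
  dist <- overlapOK <- numeric(length(refRows))
  for (k in seq_along(refRows)) {
    s <- strsplit(refRows[k], "")[[1]]
    sGap <- s == "-"
    comp <- !qGap & !sGap
    nc <- sum(comp)
    overlapOK[k] <- nc / max(sum(!sGap), 1L)
    dist[k] <- if (nc == 0L) 1 else sum(q[comp] != s[comp]) / nc
  }
  if (all(overlapOK < minOverlap)) {
    return(data.frame(query_id = queryId, clade = "UNASSIGNED",
                      mean_distance = NA_real_, margin = NA_real_,
                      tie = FALSE, stringsAsFactors = FALSE))
  }
  means <- tapply(dist, refLabels, mean)
  means <- means[order(names(means))]     # alphabetical tie-break
  ord <- order(means)
  winner <- names(means)[ord[1]]
  margin <- if (length(means) > 1L) means[ord[2]] - means[ord[1]] else NA_real_
  tie <- isTRUE(length(means) > 1L && margin == 0)
  data.frame(query_id = queryId, clade = winner,
             mean_distance = unname(means[ord[1]]),
             margin = unname(margin), tie = tie, stringsAsFactors = FALSE)
}

#' Assign every QUERY row of a clade alignment
#'
#' @param aln A [CladeAlignment-class] containing reference rows (labelled
#'   by clade) and query rows (labelled `"QUERY"`).
#' @param minOverlap Passed to [assignClade()].
#' @return data.frame with one row per query (see [assignClade()]).
#' @export
assignCladeSet <- function(aln, minOverlap = 0.5) {
  stopifnot(is(aln, "CladeAlignment"))
  qSel <- which(aln@labels == "QUERY")
  if (!length(qSel))
    return(data.frame(query_id = character(), clade = character(),
                      mean_distance = numeric(), margin = numeric(),
                      tie = logical(), stringsAsFactors = FALSE))
  rows <- lapply(qSel, function(i)
    assignClade(as.character(aln@sequences[[i]]), aln, minOverlap,
                queryId = names(aln@sequences)[i]))
  do.call(rbind, rows)
}

#' Read a clade-labelled alignment from aligned FASTA
#'
#' Clade labels are parsed from `clade=<label>` tokens in the FASTA
#' description lines; rows without a token are labelled `"QUERY"`.
#'
#' @param file Path to an aligned FASTA file.
#' @return A [CladeAlignment-class].
#' @export
readCladeAlignment <- function(file) {
  seqs <- readAAStringSet(file)
  desc <- names(seqs)
  labels <- ifelse(grepl("clade=", desc),
                   sub(".*clade=([^ ]+).*", "\\1", desc), "QUERY")
  names(seqs) <- vapply(strsplit(desc, "[ \t]"), `[[`, "", 1L)
  CladeAlignment(seqs, labels)
}
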