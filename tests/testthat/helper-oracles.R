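suppressPackageStartupMessages({
  library(Biostrings)
  library(ape)
})

# Independent oracles and random-case generators for property tests.
# These deliberately re-derive results by brute force, without calling the
# package's scanning/clustering/tree code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# --- naive motif scan ------------------------------------------------------
# Independent parser (regex tokenization) + double-loop comparator.
naiveParsePattern <- function(pattern) {
  toks <- regmatches(pattern,
                     gregexpr("\\[[A-Z]+\\]|x|[A-Z]", pattern))[[1]]
  lapply(toks, function(t) {
    if (t == "x") list(kind = "wild")
    else if (startsWith(t, "[")) list(kind = "set",
                                      letters = strsplit(gsub("\\[|\\]", "", t),
                                                         "")[[1]])
    else list(kind = "literal", letters = t)
  })
}

naiveMotifScan <- function(seq, pattern, maxSub) {
  els <- naiveParsePattern(pattern)
  m <- length(els)
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  if (length(chars) < m) return(data.frame(start = integer(),
                                           substitutions = integer()))
  for (s in 1:(length(chars) - m + 1)) {
    subs <- 0L; ok <- TRUE
    for (j in 1:m) {
      el <- els[[j]]; ch <- chars[s + j - 1]
      if (el$kind == "wild") next
      if (el$kind == "set") {
        if (!(ch %in% el$letters)) { ok <- FALSE; break }
      } else if (ch != el$letters) subs <- subs + 1L
    }
    if (ok && subs <= maxSub)
      hits[[length(hits) + 1L]] <- c(start = s, substitutions = subs)
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       substitutions = integer()))
  as.data.frame(do.call(rbind, hits))
}

# --- brute-force single-linkage 1-D clustering -----------------------------
# All-pairs union-find: link every pair closer than the gap, then read off
# the components.
naiveSingleLinkage <- function(positions, gap) {
  n <- length(positions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(positions[i] - positions[j]) <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(lapply(split(positions, roots), sort))
}

# --- exhaustive unrooted-topology enumeration + least-squares fit ----------
# Trees are edge matrices over nodes 1..n (leaves) and n+1.. (internal).
enumTopologies <- function(n) {
  stopifnot(n >= 3)
  base <- list(list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                    nextNode = n + 2))
  trees <- base
  if (n == 3) return(lapply(trees, `[[`, "edges"))
  for (leaf in 4:n) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        a <- ed[e, 1]; b <- ed[e, 2]
        mid <- tr$nextNode
        ed2 <- rbind(ed[-e, , drop = FALSE],
                     c(a, mid), c(mid, b), c(mid, leaf))
        nxt[[length(nxt) + 1L]] <- list(edges = ed2, nextNode = mid + 1L)
      }
    }
    trees <- nxt
  }
  lapply(trees, `[[`, "edges")
}

treePaths <- function(edges, n) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  pathEdges <- function(from, to) {
    # DFS with predecessor tracking
    prev <- rep(NA_integer_, nodes); prevEdge <- rep(NA_integer_, nodes)
    stack <- from; seen <- rep(FALSE, nodes); seen[from] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v == to) break
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        w <- nb[k, 1]
        if (!seen[w]) {
          seen[w] <- TRUE; prev[w] <- v; prevEdge[w] <- nb[k, 2]
          stack <- c(stack, w)
        }
      }
    }
    out <- integer(); v <- to
    while (v != from) { out <- c(out, prevEdge[v]); v <- prev[v] }
    out
  }
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs)))
    A[p, pathEdges(pairs[p, 1], pairs[p, 2])] <- 1
  list(pairs = pairs, A = A)
}

# Least-squares SSE of fitting D's pairwise distances on a topology.
lsFitSSE <- function(edges, D) {
  n <- nrow(D)
  tp <- treePaths(edges, n)
  d <- D[tp$pairs]
  fit <- qr.solve(tp$A, d)
  sum((tp$A %*% fit - d)^2)
}

edgesToNewick <- function(edges, labels) {
  n <- length(labels)
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  recurse <- function(v, from) {
    if (v <= n) return(labels[v])
    kids <- setdiff(adj[[v]], from)
    paste0("(", paste(vapply(kids, recurse, "", from = v),
                      collapse = ","), ")")
  }
  paste0(recurse(n + 1, NA), ";")
}

# Random additive distance matrix from a random topology with random
# positive branch lengths; returns the matrix and the generating newick.
randomAdditiveMatrix <- function(n, labels = paste0("t", seq_len(n))) {
  topos <- enumTopologies(n)
  edges <- topos[[sample(length(topos), 1)]]
  len <- runif(nrow(edges), 0.2, 1)
  tp <- treePaths(edges, n)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  d <- as.vector(tp$A %*% len)
  for (p in seq_len(nrow(tp$pairs)))
    D[tp$pairs[p, 1], tp$pairs[p, 2]] <- D[tp$pairs[p, 2], tp$pairs[p, 1]] <- d[p]
  list(D = D, newick = edgesToNewick(edges, labels), edges = edges)
}

# Topology equality through ape's Robinson-Foulds distance.
sameTopology <- function(nw1, nw2) {
  t1 <- ape::unroot(ape::read.tree(text = nw1))
  t2 <- ape::unroot(ape::read.tree(text = nw2))
  isTRUE(all.equal(as.numeric(ape::dist.topo(t1, t2)), 0))
}

# Random valid architecture string (always at least one anchor).
randomArchitecture <- function(maxLen = 10) {
  codes <- c("KS", "AT", "PP", "KR", "DH", "ER", "AM", "C", "A", "MT",
             "TE", "HXXPF")
  len <- sample(2:maxLen, 1)
  toks <- sample(codes, len, replace = TRUE)
  if (!any(toks %in% c("C", "KS")))
    toks[sample(len, 1)] <- sample(c("C", "KS"), 1)
  paste(toks, collapse = "-")
}
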