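## Independent brute-force oracles and fixture generators.  These stay
## deliberately naive (plain loops, definitions rather than update
## formulas) so they exercise a different route than the implementation.

## --- alignment fixtures ---------------------------------------------------

writeFastaText <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(text, path)
  path
}

toyAln <- function() {
  CpGAlignment(c(s1 = "ACGTACGT", s2 = "ACGTATGT", s3 = "ACGTACGT"))
}

## Random alignment as a named character vector; CpG-enriched so dinucleotide
## scans have material to find, optionally salted with gaps and Ns.
randomRows <- function(nTaxa, nCol, pGap = 0, pCpG = 0.15) {
  anc <- character(nCol)
  i <- 1L
  while (i <= nCol) {
    if (i < nCol && runif(1) < pCpG) {
      anc[i] <- "C"; anc[i + 1L] <- "G"; i <- i + 2L
    } else {
      anc[i] <- sample(c("A", "C", "G", "T"), 1L); i <- i + 1L
    }
  }
  rows <- vapply(seq_len(nTaxa), function(k) {
    r <- anc
    nm <- rbinom(1L, nCol, 0.08)
    if (nm > 0) {
      at <- sample.int(nCol, nm)
      r[at] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
    }
    if (pGap > 0) {
      ng <- rbinom(1L, nCol, pGap)
      if (ng > 0) r[sample.int(nCol, ng)] <- sample(c("-", "N"), ng, replace = TRUE)
    }
    paste(r, collapse = "")
  }, character(1))
  names(rows) <- paste0("t", seq_len(nTaxa))
  rows
}

## --- dinucleotide scan oracle ---------------------------------------------

bruteScanDinuc <- function(rows, type, rule = "majority", refTaxon = NULL) {
  N <- length(rows); L <- nchar(rows[[1]])
  out <- list()
  for (i in seq_len(L - 1L)) {
    states <- vapply(rows, substr, character(1), i, i + 1L)
    hits <- states == type
    keep <- switch(rule,
                   majority = sum(hits) > N / 2,
                   any = sum(hits) >= 1L,
                   reference = hits[[refTaxon]])
    if (!keep) next
    gap <- any(grepl("[N-]", states))
    cls <- if (gap) "gapped"
      else if (all(hits)) "conserved_all"
      else if (sum(hits) > N / 2) "preserved_variable"
      else "not_preserved"
    out[[length(out) + 1L]] <- list(column = i, states = states, class = cls)
  }
  out
}

brutePolymorphicFraction <- function(rows) {
  L <- nchar(rows[[1]])
  npoly <- 0L
  for (i in seq_len(L)) {
    st <- unique(vapply(rows, substr, character(1), i, i))
    st <- st[st %in% c("A", "C", "G", "T")]
    if (length(st) >= 2L) npoly <- npoly + 1L
  }
  npoly / L
}

## Manual application of the A/T recoding rule, per taxon per site.
bruteRecode <- function(rows, siteColumns, type = "CG", includeConstant = TRUE) {
  m <- sapply(siteColumns, function(i)
    ifelse(vapply(rows, substr, character(1), i, i + 1L) == type, "A", "T"))
  m <- matrix(m, nrow = length(rows),
              dimnames = list(names(rows), as.character(siteColumns)))
  if (!includeConstant) m <- m[, colSums(m == "T") > 0L, drop = FALSE]
  m
}

## --- UPGMA oracle ----------------------------------------------------------

## Definition-based agglomeration: cluster distance recomputed every round
## as the plain mean over all original leaf pairs (no Lance-Williams
## update).  Ties broken by smallest pair of creation-order indices.
bruteUpgma <- function(dm) {
  labels <- rownames(dm)
  n <- nrow(dm)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  clades <- list(); heights <- numeric(0)
  while (length(active) > 1L) {
    best <- NULL; bestd <- Inf
    for (a in seq_len(length(active) - 1L)) for (b in seq.int(a + 1L, length(active))) {
      i <- active[a]; j <- active[b]
      dd <- mean(dm[members[[i]], members[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    id <- length(members) + 1L
    members[[id]] <- c(members[[best[1L]]], members[[best[2L]]])
    active <- c(setdiff(active, best), id)
    clades[[length(clades) + 1L]] <- sort(labels[members[[id]]])
    heights <- c(heights, bestd / 2)
  }
  list(clades = clades, heights = heights)
}

## Same agglomeration, but emitting Newick directly with the package's
## child-ordering convention (taller child first, ties by creation order).
bruteUpgmaNewick <- function(dm, digits = 6) {
  labels <- rownames(dm)
  n <- nrow(dm)
  members <- as.list(seq_len(n))
  nwk <- as.list(labels)
  h <- rep(0, n)
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL; bestd <- Inf
    for (a in seq_len(length(active) - 1L)) for (b in seq.int(a + 1L, length(active))) {
      i <- active[a]; j <- active[b]
      dd <- mean(dm[members[[i]], members[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    id <- length(members) + 1L
    members[[id]] <- c(members[[best[1L]]], members[[best[2L]]])
    kids <- best[order(-h[best], best)]
    hh <- bestd / 2
    nwk[[id]] <- paste0("(",
      paste(vapply(kids, function(k)
        paste0(nwk[[k]], ":", sprintf("%.*f", digits, hh - h[k])), character(1)),
        collapse = ","), ")")
    h[id] <- hh
    active <- c(setdiff(active, best), id)
  }
  paste0(nwk[[length(members)]], ";")
}

## Ordered clade list of a fitted UPGMA tree, from its merge matrix.
cladeSeqFromMerge <- function(merge, labels) {
  members <- vector("list", nrow(merge))
  lapply(seq_len(nrow(merge)), function(k) {
    get1 <- function(x) if (x < 0L) labels[-x] else members[[x]]
    members[[k]] <<- c(get1(merge[k, 1L]), get1(merge[k, 2L]))
    sort(members[[k]])
  })
}

randomDistanceMatrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}

## Random ultrametric matrix built from explicit random merges at strictly
## increasing heights; returns the matrix plus the generating clades/heights.
randomUltrametric <- function(n) {
  labels <- letters[seq_len(n)]
  groups <- as.list(labels)
  hts <- sort(runif(n - 1L, 0.05, 1))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  clades <- list()
  for (k in seq_len(n - 1L)) {
    pick <- sample.int(length(groups), 2L)
    g1 <- groups[[pick[1L]]]; g2 <- groups[[pick[2L]]]
    D[g1, g2] <- 2 * hts[k]; D[g2, g1] <- 2 * hts[k]
    groups[[min(pick)]] <- c(g1, g2)
    groups[[max(pick)]] <- NULL
    clades[[k]] <- sort(c(g1, g2))
  }
  list(d = D, clades = clades, heights = hts)
}

## Replay a mutation log down the tree: every leaf must equal the root
## sequence with its branch-path events applied in order.
replayLeaves <- function(sim) {
  tree <- trueTree(sim)
  log <- mutationLog(sim)
  nTip <- length(tree$tip.label)
  parent <- integer(nTip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  out <- vapply(seq_len(nTip), function(tip) {
    path <- tip
    while (path[1L] != nTip + 1L) path <- c(parent[path[1L]], path)
    sq <- strsplit(rootSequence(sim), "")[[1]]
    for (node in path[-1L]) {
      ev <- log[log$node == node, , drop = FALSE]
      ev <- ev[order(ev$time), , drop = FALSE]
      for (r in seq_len(nrow(ev))) {
        stopifnot(sq[ev$pos[r]] == ev$from[r])
        sq[ev$pos[r]] <- ev$to[r]
      }
    }
    paste(sq, collapse = "")
  }, character(1))
  names(out) <- tree$tip.label
  out
}
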