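#' Pairwise p-distance matrix
#'
#' The p-distance between two equal-length rows is the proportion of
#' mismatching positions among compared positions.  With `ignoreGaps`
#' (default), positions where either row carries `-` or `N` are excluded
#' from both numerator and denominator; without it, characters are compared
#' literally.  No multiple-hit correction is applied.
#'
#' @param x A [CpGAlignment-class], an [EpiMatrix-class], a named character
#'   vector of equal-length strings, or a character matrix (taxa x
#'   positions).
#' @param ignoreGaps Exclude gap/ambiguous positions pairwise?
#' @return A symmetric numeric matrix in `[0, 1]` with taxon labels as
#'   dimnames.
#' @examples
#' pDistanceMatrix(c(a = "ACGT", b = "ACGA"))  # 0.25 off-diagonal
#' @export
setGeneric("pDistanceMatrix",
           function(x, ignoreGaps = TRUE) standardGeneric("pDistanceMatrix"))

#' @rdname pDistanceMatrix
#' @export
setMethod("pDistanceMatrix", "CpGAlignment", function(x, ignoreGaps = TRUE) {
  .pdist(as.matrix(x), ignoreGaps)
})

#' @rdname pDistanceMatrix
#' @export
setMethod("pDistanceMatrix", "EpiMatrix", function(x, ignoreGaps = TRUE) {
  if (length(x) == 0L)
    stop("cannot compute distances on an empty epigenetic matrix")
  .pdist(as.matrix(x), ignoreGaps)
})

#' @rdname pDistanceMatrix
#' @export
setMethod("pDistanceMatrix", "character", function(x, ignoreGaps = TRUE) {
  stopifnot(length(x) >= 2L, !is.null(names(x)))
  if (length(unique(nchar(x))) != 1L) stop("rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  .pdist(m, ignoreGaps)
})

#' @rdname pDistanceMatrix
#' @export
setMethod("pDistanceMatrix", "matrix", function(x, ignoreGaps = TRUE) {
  .pdist(x, ignoreGaps)
})

.pdist <- function(m, ignoreGaps) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  if (ncol(m) < 1L) stop("need at least 1 position")
  ok <- !(m %in% .GAPLIKE)
  dim(ok) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    use <- if (ignoreGaps) ok[i, ] & ok[j, ] else rep(TRUE, ncol(m))
    nc <- sum(use)
    if (nc == 0L)
      stop("no comparable positions between '", rownames(m)[i], "' and '",
           rownames(m)[j], "'; distance undefined")
    d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use]) / nc
  }
  d
}

#' Build a rooted UPGMA tree from a distance matrix
#'
#' Classical (unweighted, i.e. cluster-size weighted average) UPGMA:
#' repeatedly merges the closest pair of clusters; the distance from the
#' merged cluster to any other is the arithmetic mean of all between-leaf
#' distances, maintained by size-weighted averaging.  The merge height of a
#' pair at distance `d` is `d/2`, so the result is a rooted ultrametric
#' binary tree — the molecular-clock assumption implies the root sits at
#' the last merge.  Ties in the closest-pair search are broken by the
#' smallest pair of cluster indices in creation order (leaves first, in
#' label order), so runs are reproducible.
#'
#' @param dm Symmetric nonnegative numeric matrix with taxon labels as
#'   dimnames (as from [pDistanceMatrix()]), or a [stats::dist] object.
#' @return An [ape::phylo] tree (rooted, with branch lengths) carrying
#'   attributes `merge` (hclust-style merge matrix), `mergeHeights` (the
#'   merge distances `d`) and `nodeHeights` (heights `d/2` of the internal
#'   nodes, named by ape node number).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' toNewick(upgmaTree(d), 1)  # "((A:1.0,B:1.0):1.0,C:2.0);"
#' @export
upgmaTree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), is.numeric(dm))
  n <- nrow(dm)
  if (n < 2L || ncol(dm) != n) stop("distance matrix must be square with >= 2 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- colnames(dm)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique taxon labels as dimnames")
  if (any(!is.finite(dm))) stop("distances must be finite (no NA/NaN/Inf)")
  if (any(dm < 0)) stop("distances must be nonnegative")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")

  # working matrix over cluster ids; leaves 1..n, merges n+1..2n-1
  M <- 2L * n - 1L
  D <- matrix(NA_real_, M, M)
  D[1:n, 1:n] <- dm
  size <- c(rep(1L, n), integer(n - 1L))
  height <- numeric(M)
  merge <- matrix(0L, n - 1L, 2L)         # hclust convention: -leaf, +merge
  mergeHeights <- numeric(n - 1L)
  active <- seq_len(n)

  for (k in seq_len(n - 1L)) {
    # closest active pair; ties -> smallest (i, j) in id order
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (a in seq_along(active)[-length(active)]) {
      i <- active[a]
      for (b in seq.int(a + 1L, length(active))) {
        j <- active[b]
        if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    id <- n + k
    size[id] <- size[i] + size[j]
    height[id] <- bestd / 2
    merge[k, ] <- ifelse(best <= n, -best, best - n)
    mergeHeights[k] <- bestd
    rest <- setdiff(active, best)
    if (length(rest)) {
      newd <- (size[i] * D[i, rest] + size[j] * D[j, rest]) / size[id]
      D[id, rest] <- D[rest, id] <- newd
    }
    active <- c(rest, id)
  }

  tr <- .mergeToPhylo(merge, height, labels, n)
  attr(tr, "merge") <- merge
  attr(tr, "mergeHeights") <- mergeHeights
  nh <- height[(n + 1L):M]
  names(nh) <- as.character(3L * n - ((n + 1L):M))   # ape node numbers
  attr(tr, "nodeHeights") <- nh[order(as.integer(names(nh)))]
  tr
}

## merge matrix + per-id heights -> ape phylo.  ape numbers tips 1..n and
## the root n+1; merge k becomes node 2n - k, so the last merge is the root.
.mergeToPhylo <- function(merge, height, labels, n) {
  nodeOf <- function(id) if (id <= n) id else 3L * n - id
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  r <- 0L
  for (k in seq_len(n - 1L)) {
    parent_id <- n + k
    kids_id <- ifelse(merge[k, ] < 0L, -merge[k, ], n + merge[k, ])
    # taller (more recently merged) child first; ties by creation order
    kids_id <- kids_id[order(-height[kids_id], kids_id)]
    for (child_id in kids_id) {
      r <- r + 1L
      edge[r, ] <- c(nodeOf(parent_id), nodeOf(child_id))
      elen[r] <- height[parent_id] - height[child_id]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen, tip.label = labels,
                       Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Serialize a rooted tree to Newick
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param digits Number of decimals printed for branch lengths.
#' @return A single Newick string terminated by `;`, parseable by standard
#'   readers (round-trip preserves topology and lengths to the stated
#'   precision).
#' @export
toNewick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) sprintf("%.*f", digits, x)
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r)
      paste0(rec(tree$edge[r, 2L]), ":", fmt(tree$edge.length[r])), character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}

#' Compare rooted tree topologies
#'
#' Two rooted trees are topologically equal when their clade sets (the sets
#' of tip labels under each internal node) are identical; branch lengths
#' are ignored.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return `TRUE` or `FALSE`.
#' @export
topologyEqual <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets; topologies are not comparable")
  setequal(.cladeSet(t1), .cladeSet(t2))
}

.cladeSet <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tipsBelow <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipsBelow), use.names = FALSE)
  }
  vapply(seq.int(n + 1L, n + tree$Nnode),
         function(v) paste(sort(tipsBelow(v)), collapse = "\r"), character(1))
}

#' Write a labeled distance matrix as TSV
#'
#' @param dm Symmetric labeled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
  df <- data.frame(taxon = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
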