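#' Recode preserved CpG sites into binary epigenetic characters
#'
#' Applies the phylo-epigenetic recoding rule: at every admitted CpG site,
#' each taxon receives an `A` when its dinucleotide is exactly `CG` (an
#' intact, conserved CpG) and a `T` when it is mutated in at least one of
#' the two nucleotides.  The assignment is made per taxon so that taxa
#' carrying a deaminated CpG are distinguished from taxa preserving it —
#' the character matrix is what makes a CpG-mode tree informative.
#'
#' Sites must be ungapped and preserved (`conserved_all` or
#' `preserved_variable`); gapped or `not_preserved` sites are rejected.
#' Because all sites come from one shared alignment coordinate frame, the
#' recoded characters are already positionally homologous and no
#' realignment is performed.
#'
#' @param aln The source [CpGAlignment-class].
#' @param sites A [DinucSites-class] from `aln`; defaults to
#'   `scanDinucSites(aln, "CG", "majority")` with gapped sites dropped.
#' @param includeConstant Keep `conserved_all` sites (all-`A` columns)?
#'   They dilute p-distances uniformly without changing UPGMA topology;
#'   default `TRUE`.
#' @return An [EpiMatrix-class].  A matrix with zero columns (no
#'   informative sites) is returned with a warning.
#' @examples
#' aln <- CpGAlignment(c(s1 = "ACGTACGT", s2 = "ACGTATGT", s3 = "ACGTACGT"))
#' recodeCpGMatrix(aln)                           # s1 "AA", s2 "AT", s3 "AA"
#' recodeCpGMatrix(aln, includeConstant = FALSE)  # s1 "A",  s2 "T",  s3 "A"
#' @export
recodeCpGMatrix <- function(aln, sites = NULL, includeConstant = TRUE) {
  stopifnot(is(aln, "CpGAlignment"))
  if (is.null(sites)) {
    sites <- scanDinucSites(aln, "CG", "majority")
    sites <- .dropSites(sites, sites@siteClass == "gapped")
  }
  stopifnot(is(sites, "DinucSites"))
  if (!identical(sort(rownames(sites@states)), sort(alnLabels(aln))))
    stop("sites reference taxa absent from the alignment")
  if (sites@nColumns != alnWidth(aln))
    stop("sites come from an alignment of different width")
  if (any(sites@siteClass == "gapped"))
    stop("gapped sites cannot be recoded; exclude them upstream")
  if (any(sites@siteClass == "not_preserved"))
    stop("not_preserved sites cannot be recoded; use a majority scan or filter")

  labels <- alnLabels(aln)
  st <- sites@states[labels, , drop = FALSE]   # rows in alignment order
  chars <- ifelse(st == sites@dinucType, "A", "T")
  keep <- rep(TRUE, ncol(chars))
  if (!includeConstant && ncol(chars))
    keep <- colSums(chars == "T") > 0L
  chars <- chars[, keep, drop = FALSE]
  if (ncol(chars) == 0L)
    warning("degenerate recoding: no ", if (includeConstant) "" else "variable ",
            "CpG sites; the epigenetic matrix is empty")
  new("EpiMatrix",
      labels = labels,
      characters = apply(chars, 1L, paste, collapse = ""),
      siteIndex = sites@column[keep])
}

.dropSites <- function(sites, drop) {
  new("DinucSites",
      column = sites@column[!drop], dinucType = sites@dinucType,
      states = sites@states[, !drop, drop = FALSE],
      siteClass = sites@siteClass[!drop],
      nColumns = sites@nColumns, rule = sites@rule)
}

#' Write an EpiMatrix as FASTA
#'
#' The A/T character strings are written as plain FASTA records, directly
#' consumable by [pDistanceMatrix()] workflows or external aligners.
#'
#' @param em An [EpiMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEpiFasta <- function(em, path) {
  stopifnot(is(em, "EpiMatrix"))
  s <- Biostrings::BStringSet(stats::setNames(em@characters, em@labels))
  Biostrings::writeXStringSet(s, filepath = path, format = "fasta")
  invisible(path)
}

#' Write an EpiMatrix as TSV
#'
#' One row per taxon; one column per CpG site, headed by the 1-based source
#' alignment column of the site.
#'
#' @inheritParams writeEpiFasta
#' @return `path`, invisibly.
#' @export
writeEpiTable <- function(em, path) {
  stopifnot(is(em, "EpiMatrix"))
  m <- as.matrix(em)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname EpiMatrix-class
#' @param x,object An `EpiMatrix`.
#' @aliases length,EpiMatrix-method
#' @export
setMethod("length", "EpiMatrix", function(x) length(x@siteIndex))

#' @rdname EpiMatrix-class
#' @aliases as.matrix,EpiMatrix-method
#' @export
setMethod("as.matrix", "EpiMatrix", function(x) {
  if (length(x@siteIndex) == 0L) {
    m <- matrix(character(0), nrow = length(x@labels), ncol = 0L)
  } else {
    m <- do.call(rbind, strsplit(x@characters, ""))
  }
  dimnames(m) <- list(x@labels, as.character(x@siteIndex))
  m
})

setMethod("show", "EpiMatrix", function(object) {
  cat(sprintf("EpiMatrix: %d taxa x %d CpG site%s\n",
              length(object@labels), length(object),
              if (length(object) == 1L) "" else "s"))
  for (i in seq_along(object@labels))
    cat(sprintf("  %s  %s\n", object@labels[i],
                if (nchar(object@characters[i]) > 60)
                  paste0(substr(object@characters[i], 1, 57), "...")
                else object@characters[i]))
})
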