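#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   BStringSet
NULL

setOldClass("phylo")

## Letters admitted anywhere in an alignment. Ambiguity codes other than N
## are rejected at read time; '.' is not a gap character here.
.ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
.GAPLIKE <- c("N", "-")

#' CpGAlignment: a validated multiple sequence alignment
#'
#' An immutable set of equal-length, uppercase nucleotide sequences over the
#' alphabet `A,C,G,T,N,-`, with unique taxon labels.  All downstream analyses
#' (dinucleotide scans, recoding, distances) consume this class.  When an
#' alignment was assembled from several blocks (see [concatBlocks()]) the
#' 1-based start column of each block is retained in `blockOffsets`.
#'
#' @slot seqs A [Biostrings::DNAStringSet] holding the aligned rows; names
#'   are the taxon labels.
#' @slot blockOffsets Integer vector of 1-based start columns of the
#'   concatenated blocks (a single-block alignment has `1L`).
#'
#' @seealso [readAlignment()], [writeAlignment()], [concatBlocks()]
#' @export
setClass("CpGAlignment",
  slots = c(seqs = "DNAStringSet", blockOffsets = "integer")
)

setValidity("CpGAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 2L)
    return("an alignment needs at least 2 sequences")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return(sprintf("rows differ in length: %s", paste(unique(w), collapse = ", ")))
  if (w[1L] < 2L)
    return("alignment must have at least 2 columns")
  lb <- names(s)
  if (is.null(lb) || any(!nzchar(lb)))
    return("every sequence needs a nonempty taxon label")
  if (anyDuplicated(lb))
    return(sprintf("duplicate taxon labels: %s",
                   paste(unique(lb[duplicated(lb)]), collapse = ", ")))
  bad <- Biostrings::uniqueLetters(s)
  bad <- setdiff(bad, .ALN_ALPHABET)
  if (length(bad))
    return(sprintf("disallowed characters in alignment: %s (only A,C,G,T,N,- are accepted)",
                   paste(bad, collapse = ", ")))
  off <- object@blockOffsets
  if (length(off) < 1L || off[1L] != 1L || is.unsorted(off, strictly = TRUE) ||
      any(off > w[1L]))
    return("blockOffsets must be strictly increasing 1-based columns starting at 1")
  TRUE
})

#' DinucSites: dinucleotide loci found by an alignment scan
#'
#' One record per reported dinucleotide site: the 1-based start column (the
#' site occupies that column and the next), the per-taxon two-letter states,
#' and a conservation class.  Produced by [scanDinucSites()].
#'
#' Classes are: `conserved_all` (every taxon shows the dinucleotide),
#' `preserved_variable` (a majority shows it, at least one taxon deviates in
#' at least one position), `not_preserved` (reported under a permissive rule
#' but shown by half the taxa or fewer), `gapped` (any taxon has `-` or `N`
#' in either column; takes precedence over the other classes).
#'
#' @slot column Integer, 1-based start columns, strictly increasing.
#' @slot dinucType Length-1 character, e.g. `"CG"`.
#' @slot states Character matrix (taxa x sites) of observed dinucleotides.
#' @slot siteClass Character vector parallel to `column`.
#' @slot nColumns Integer, number of columns of the source alignment.
#' @slot rule The reference rule used for reporting.
#' @export
setClass("DinucSites",
  slots = c(column = "integer", dinucType = "character", states = "matrix",
            siteClass = "character", nColumns = "integer", rule = "character")
)

setValidity("DinucSites", function(object) {
  n <- length(object@column)
  if (length(object@siteClass) != n) return("siteClass length mismatch")
  if (n && ncol(object@states) != n) return("states column count mismatch")
  if (is.unsorted(object@column, strictly = TRUE)) return("columns must be strictly increasing")
  if (n && (min(object@column) < 1L || max(object@column) > object@nColumns - 1L))
    return("site columns out of alignment range")
  bad <- setdiff(object@siteClass, .SITE_CLASSES)
  if (length(bad)) return(sprintf("unknown site class: %s", paste(bad, collapse = ", ")))
  TRUE
})

.SITE_CLASSES <- c("conserved_all", "preserved_variable", "not_preserved", "gapped")

#' EpiMatrix: binary epigenetic characters over preserved CpG sites
#'
#' One character per taxon per admitted CpG site: `A` where that taxon's
#' dinucleotide is exactly the reference dinucleotide (an intact CpG), `T`
#' where it is mutated in at least one of the two positions.  Produced by
#' [recodeCpGMatrix()]; the matrix feeds CpG-mode distances and can be
#' written as FASTA for external tools.
#'
#' @slot labels Taxon names.
#' @slot characters Character vector of A/T strings, parallel to `labels`.
#' @slot siteIndex Integer, 1-based source alignment columns of the retained
#'   sites, strictly increasing.
#' @export
setClass("EpiMatrix",
  slots = c(labels = "character", characters = "character", siteIndex = "integer")
)

setValidity("EpiMatrix", function(object) {
  if (length(object@labels) != length(object@characters))
    return("labels/characters length mismatch")
  if (anyDuplicated(object@labels)) return("duplicate labels")
  if (any(nchar(object@characters) != length(object@siteIndex)))
    return("character strings must have one position per site")
  if (is.unsorted(object@siteIndex, strictly = TRUE))
    return("siteIndex must be strictly increasing")
  if (length(object@siteIndex) &&
      !all(strsplit(paste(object@characters, collapse = ""), "")[[1]] %in% c("A", "T")))
    return("characters must be over {A,T}")
  TRUE
})

#' DivergenceStats: dinucleotide divergence summary of an alignment
#'
#' Per requested dinucleotide type, the number of preserved sites, the
#' number of those altered in at least one taxon, the alteration fraction
#' (altered / preserved), and the genome fraction (altered sites / total
#' alignment columns); plus the overall polymorphic-column fraction.
#'
#' @slot nColumns Alignment length in columns.
#' @slot polymorphicColumnFraction Proportion of columns with >= 2 distinct
#'   non-gap states among taxa.
#' @slot table `data.frame` with one row per dinucleotide type and columns
#'   `dinucType`, `nPreservedSites`, `nPreservedVariableSites`,
#'   `preservedVariableFraction`, `genomeFraction`.
#' @export
setClass("DivergenceStats",
  slots = c(nColumns = "integer", polymorphicColumnFraction = "numeric",
            table = "data.frame")
)

#' SubstitutionModel: nucleotide substitution model with CpG hypermutability
#'
#' A Kimura-style model: transversions occur at a common rate and
#' transitions at `tiTvRatio` times that rate, scaled so the total leaving
#' rate of a non-CpG site is `baseRate` per unit branch length.  At a
#' methylated (unprotected) CpG, the deamination-driven transitions C->T
#' (and G->A at the paired guanine) are multiplied by `cpgMultiplier`,
#' reflecting the 10-50x elevated transition rate of methylated CpG to TpG.
#' CpGs inside protected (unmethylated) islands are exempt.
#'
#' @slot baseRate Expected substitutions per site per unit branch length at
#'   non-CpG sites; with the default 1, branch lengths are in expected
#'   substitutions per site.
#' @slot tiTvRatio Transition/transversion rate ratio (> 0).
#' @slot cpgMultiplier Factor (>= 1) applied to C->T / G->A transitions at
#'   unprotected CpG sites.
#' @slot protectedFraction Default fraction of CpG islands flagged as
#'   protected by the island-spec helpers.
#' @export
setClass("SubstitutionModel",
  slots = c(baseRate = "numeric", tiTvRatio = "numeric",
            cpgMultiplier = "numeric", protectedFraction = "numeric")
)

setValidity("SubstitutionModel", function(object) {
  if (object@baseRate <= 0) return("baseRate must be > 0")
  if (object@tiTvRatio <= 0) return("tiTvRatio must be > 0")
  if (object@cpgMultiplier < 1) return("cpgMultiplier must be >= 1")
  if (object@protectedFraction < 0 || object@protectedFraction > 1)
    return("protectedFraction must be in [0, 1]")
  TRUE
})

#' SimConfig: a complete, seeded simulation configuration
#'
#' @slot tree A rooted `phylo` tree with branch lengths (expected
#'   substitutions per site when `baseRate = 1`).
#' @slot rootLength Root sequence length in bp.
#' @slot islands `data.frame` with columns `start`, `end` (1-based, closed)
#'   and logical `protected`; non-overlapping intervals enriched for CpG.
#' @slot cpgDensityIn,cpgDensityOut Target CpG dinucleotide frequency inside
#'   and outside islands.
#' @slot seed Integer seed; identical configs give byte-identical output.
#' @slot model A [SubstitutionModel-class].
#' @export
setClass("SimConfig",
  slots = c(tree = "phylo", rootLength = "integer", islands = "data.frame",
            cpgDensityIn = "numeric", cpgDensityOut = "numeric",
            seed = "integer", model = "SubstitutionModel")
)

setValidity("SimConfig", function(object) {
  tr <- object@tree
  if (is.null(tr$edge.length)) return("tree must have branch lengths")
  if (any(tr$edge.length < 0)) return("branch lengths must be >= 0")
  if (object@rootLength < 0) return("rootLength must be >= 0")
  isl <- object@islands
  if (nrow(isl)) {
    if (!all(c("start", "end", "protected") %in% names(isl)))
      return("islands needs columns start, end, protected")
    if (any(isl$start < 1 | isl$end > object@rootLength | isl$start > isl$end))
      return("island intervals must lie within [1, rootLength]")
    o <- order(isl$start)
    if (nrow(isl) > 1 && any(isl$start[o][-1] <= isl$end[o][-nrow(isl)]))
      return("island intervals must not overlap")
  }
  for (d in c(object@cpgDensityIn, object@cpgDensityOut))
    if (d < 0 || d > 0.5)
      return("CpG densities must be in [0, 0.5] (a CpG occupies two positions)")
  if (object@cpgDensityIn <= object@cpgDensityOut)
    return("cpgDensityIn must exceed cpgDensityOut")
  TRUE
})

#' CpGSimulation: simulator output with ground truth
#'
#' @slot alignment Leaf sequences as a [CpGAlignment-class] (gap-free, so
#'   leaves are born aligned).
#' @slot tree The true rooted tree the sequences evolved along.
#' @slot mutationLog `data.frame` of every substitution event: `node` (child
#'   node of the branch), `time` (position along the branch), `pos` (1-based
#'   site), `from`, `to`, `wasCpG` (site was part of a CpG before the
#'   event), `protected`.
#' @slot rootSeq The ancestral (root) sequence, one string.
#' @slot config The [SimConfig-class] that produced it.
#' @export
setClass("CpGSimulation",
  slots = c(alignment = "CpGAlignment", tree = "phylo",
            mutationLog = "data.frame", rootSeq = "character",
            config = "SimConfig")
)
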