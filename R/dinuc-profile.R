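#' Scan an alignment for dinucleotide sites
#'
#' Examines every pair of adjacent columns and reports those that "belong
#' to" the requested dinucleotide under a reference rule: `"majority"` (more
#' than half of the taxa show the dinucleotide there), `"any"` (at least one
#' taxon shows it), or `"reference:<label>"` (that taxon shows it).
#' Overlapping sites (e.g. both CGs of `CGCG`) are both reported.
#'
#' Each reported site carries a conservation class (see
#' [DinucSites-class]).  The class itself is anchored to majority semantics
#' — a site is *preserved* when more than half of the taxa show the
#' dinucleotide — while `referenceRule` only governs which sites are
#' reported, so permissive rules can surface `not_preserved` sites.  Any
#' `-` or `N` in either column makes a site `gapped`.
#'
#' @param aln A [CpGAlignment-class].
#' @param dinucType Two-letter dinucleotide, e.g. `"CG"` (default), `"AG"`,
#'   `"TG"`, `"GG"`; any of the 16 is accepted.
#' @param referenceRule `"majority"` (default), `"any"`, or
#'   `"reference:<taxon label>"`.
#' @return A [DinucSites-class] with 1-based start columns.
#' @examples
#' aln <- CpGAlignment(c(s1 = "ACGTACGT", s2 = "ACGTATGT", s3 = "ACGTACGT"))
#' scanDinucSites(aln, "CG")  # sites at columns 2 (conserved) and 6 (variable)
#' @export
scanDinucSites <- function(aln, dinucType = "CG", referenceRule = "majority") {
  stopifnot(is(aln, "CpGAlignment"))
  dinucType <- toupper(dinucType)
  if (!grepl("^[ACGT][ACGT]$", dinucType))
    stop("dinucType must be two letters over A,C,G,T; got '", dinucType, "'")
  m <- as.matrix(aln)
  N <- nrow(m); L <- ncol(m)
  pair <- matrix(paste0(m[, -L, drop = FALSE], m[, -1L, drop = FALSE]), nrow = N)
  gapped_taxon <- matrix(m[, -L, drop = FALSE] %in% .GAPLIKE |
                         m[, -1L, drop = FALSE] %in% .GAPLIKE, nrow = N)
  hit <- pair == dinucType          # FALSE wherever gapped
  nHit <- colSums(hit)

  keep <- switch(.ruleKind(referenceRule),
    majority = nHit > N / 2,
    any      = nHit >= 1L,
    reference = {
      ref <- .ruleTaxon(referenceRule)
      idx <- match(ref, alnLabels(aln))
      if (is.na(idx)) stop("reference taxon '", ref, "' is not in the alignment")
      hit[idx, ]
    })
  cols <- which(keep)

  cls <- character(length(cols))
  for (k in seq_along(cols)) {
    j <- cols[k]
    cls[k] <- if (any(gapped_taxon[, j])) "gapped"
      else if (nHit[j] == N) "conserved_all"
      else if (nHit[j] > N / 2) "preserved_variable"
      else "not_preserved"
  }
  st <- pair[, cols, drop = FALSE]
  rownames(st) <- alnLabels(aln)
  new("DinucSites", column = as.integer(cols), dinucType = dinucType,
      states = st, siteClass = cls, nColumns = L, rule = referenceRule)
}

.ruleKind <- function(rule) {
  if (identical(rule, "majority")) return("majority")
  if (identical(rule, "any")) return("any")
  if (grepl("^reference:.+", rule)) return("reference")
  stop("unknown reference rule '", rule,
       "' (use \"majority\", \"any\" or \"reference:<taxon>\")")
}
.ruleTaxon <- function(rule) sub("^reference:", "", rule)

#' Keep only sites of the given conservation classes
#'
#' Convenience filter for feeding scans into [recodeCpGMatrix()], which
#' accepts only ungapped preserved sites.
#'
#' @param sites A [DinucSites-class].
#' @param classes Site classes to retain; defaults to the preserved ones.
#' @return A [DinucSites-class] with the matching subset of sites.
#' @export
keepSiteClasses <- function(sites,
                            classes = c("conserved_all", "preserved_variable")) {
  stopifnot(is(sites, "DinucSites"), all(classes %in% .SITE_CLASSES))
  .dropSites(sites, !(sites@siteClass %in% classes))
}

#' Tabulate sites by conservation class
#'
#' @param sites A [DinucSites-class] from a single alignment.
#' @return Named integer vector over the four classes `conserved_all`,
#'   `preserved_variable`, `not_preserved`, `gapped`; sums to the number of
#'   sites.
#' @export
classifySites <- function(sites) {
  stopifnot(is(sites, "DinucSites"))
  counts <- table(factor(sites@siteClass, levels = .SITE_CLASSES))
  stats::setNames(as.integer(counts), .SITE_CLASSES)
}

#' Fraction of polymorphic alignment columns
#'
#' A column is polymorphic when at least two distinct nucleotide states
#' occur among its non-gap characters (`-` and `N` are ignored); gap-only
#' and single-state columns are not polymorphic.  The denominator is the
#' total number of alignment columns.
#'
#' @param aln A [CpGAlignment-class].
#' @return Proportion in `[0, 1]`.
#' @examples
#' polymorphicColumnFraction(CpGAlignment(c(a = "ACGT", b = "ACGA")))  # 0.25
#' @export
polymorphicColumnFraction <- function(aln) {
  stopifnot(is(aln, "CpGAlignment"))
  m <- as.matrix(aln)
  poly <- apply(m, 2L, function(col) {
    s <- unique(col[!(col %in% .GAPLIKE)])
    length(s) >= 2L
  })
  sum(poly) / ncol(m)
}

#' Dinucleotide divergence statistics
#'
#' For each requested dinucleotide type, scans the alignment, classifies
#' the sites, and reports: the number of preserved sites (classes
#' `conserved_all` + `preserved_variable`), the number altered in at least
#' one taxon (`preserved_variable`; a site counts once no matter how many
#' taxa or positions differ), the alteration fraction (altered / preserved)
#' and the genome fraction (altered sites / alignment columns).  Gapped and
#' `not_preserved` sites are excluded from the numerators; the column
#' denominator is always the full alignment length.
#'
#' Note the genome fraction counts *sites* (column pairs) in the numerator
#' over *columns* in the denominator; it is the most conservative reading
#' of "percent of the whole aligned sequence".
#'
#' @param aln A [CpGAlignment-class].
#' @param dinucTypes Character vector of dinucleotides to profile.
#' @param referenceRule Passed to [scanDinucSites()].
#' @return A [DivergenceStats-class].
#' @examples
#' aln <- CpGAlignment(c(s1 = "ACGTACGT", s2 = "ACGTATGT", s3 = "ACGTACGT"))
#' dinucDivergenceStats(aln, "CG")
#' @export
dinucDivergenceStats <- function(aln, dinucTypes = c("CG", "AG", "TG", "GG"),
                                 referenceRule = "majority") {
  stopifnot(is(aln, "CpGAlignment"), length(dinucTypes) >= 1L)
  L <- alnWidth(aln)
  rows <- lapply(dinucTypes, function(ty) {
    cnt <- classifySites(scanDinucSites(aln, ty, referenceRule))
    pres <- cnt[["conserved_all"]] + cnt[["preserved_variable"]]
    var <- cnt[["preserved_variable"]]
    data.frame(dinucType = ty,
               nPreservedSites = pres,
               nPreservedVariableSites = var,
               preservedVariableFraction = if (pres > 0) var / pres else 0,
               genomeFraction = var / L)
  })
  new("DivergenceStats",
      nColumns = L,
      polymorphicColumnFraction = polymorphicColumnFraction(aln),
      table = do.call(rbind, rows))
}

#' @rdname DinucSites-class
#' @param x,object A `DinucSites`.
#' @aliases length,DinucSites-method
#' @export
setMethod("length", "DinucSites", function(x) length(x@column))

#' @rdname DinucSites-class
#' @param row.names,optional,... Ignored; for generic compatibility.
#' @export
setMethod("as.data.frame", "DinucSites",
  function(x, row.names = NULL, optional = FALSE, ...) {
    df <- data.frame(column = x@column,
                     dinucType = rep(x@dinucType, length(x@column)),
                     siteClass = x@siteClass)
    if (length(x@column)) {
      st <- t(x@states)
      colnames(st) <- paste0("state.", rownames(x@states))
      df <- cbind(df, as.data.frame(st))
    }
    rownames(df) <- NULL
    df
  })

setMethod("show", "DinucSites", function(object) {
  cat(sprintf("DinucSites: %d %s site%s (rule: %s) in a %d-column alignment\n",
              length(object), object@dinucType,
              if (length(object) == 1L) "" else "s",
              object@rule, object@nColumns))
  if (length(object)) {
    cnt <- classifySites(object)
    cat("  ", paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", "), "\n")
  }
})

#' @rdname DivergenceStats-class
#' @param x,object A `DivergenceStats`.
#' @param row.names,optional,... Ignored; for generic compatibility.
#' @export
setMethod("as.data.frame", "DivergenceStats",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "DivergenceStats", function(object) {
  cat(sprintf("DivergenceStats over %d columns; polymorphic columns: %.4f\n",
              object@nColumns, object@polymorphicColumnFraction))
  print(object@table, row.names = FALSE)
})

#' @describeIn DivergenceStats-class Polymorphic-column fraction of the
#'   profiled alignment.
#' @export
polymorphicFraction <- function(object) object@polymorphicColumnFraction
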