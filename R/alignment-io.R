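#' Construct a CpGAlignment from sequences
#'
#' @param x A named character vector, or a named [Biostrings::DNAStringSet],
#'   of equal-length aligned sequences (>= 2 rows, >= 2 columns).  Lowercase
#'   input is folded to uppercase.
#' @param blockOffsets 1-based start columns of concatenated blocks;
#'   defaults to a single block.
#' @return A [CpGAlignment-class].
#' @examples
#' aln <- CpGAlignment(c(h = "ACGT", g = "ACGA"))
#' alnWidth(aln)
#' @export
CpGAlignment <- function(x, blockOffsets = 1L) {
  if (is.character(x)) {
    x <- toupper(x)
    # DNAStringSet would accept IUPAC ambiguity codes; restrict before coercion
    bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), .ALN_ALPHABET)
    if (length(bad))
      stop("disallowed characters in alignment: ", paste(bad, collapse = ", "),
           " (only A,C,G,T,N,- are accepted)")
    x <- Biostrings::DNAStringSet(x)
  }
  new("CpGAlignment", seqs = x, blockOffsets = as.integer(blockOffsets))
}

#' Read an aligned FASTA file
#'
#' Reads and validates a multiple sequence alignment.  Rows must be of equal
#' length, labels unique and nonempty, and characters restricted to
#' `A,C,G,T,N,-` (lowercase folded to uppercase; ambiguity codes other than
#' `N` and the `.` gap are rejected, as silent coercion would corrupt CpG
#' calls).  Record order is preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @param format Only `"fasta"` is supported.
#' @return A [CpGAlignment-class].
#' @seealso [writeAlignment()], [concatBlocks()]
#' @export
readAlignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("cannot parse '", path, "' as FASTA: ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("'", path, "' contains no FASTA records")
  # readDNAStringSet keeps full description lines; labels are the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- setdiff(Biostrings::uniqueLetters(seqs), .ALN_ALPHABET)
  if (length(bad))
    stop("disallowed characters in '", path, "': ", paste(bad, collapse = ", "),
         " (only A,C,G,T,N,- are accepted; '.' is not a gap here)")
  CpGAlignment(seqs)
}

#' Write an alignment as FASTA
#'
#' Round-trip property: `readAlignment(writeAlignment(x, path))` equals `x`
#' up to line wrapping (object equality, same label order).
#'
#' @param aln A [CpGAlignment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "CpGAlignment"))
  Biostrings::writeXStringSet(aln@seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Concatenate aligned blocks by taxon label
#'
#' Assembles one alignment from several aligned blocks covering the same
#' taxa (e.g. several promoter regions strung together).  Taxa are matched
#' by label, never by record position, so differently ordered blocks cannot
#' be silently misassembled.  Block boundaries are retained as
#' `blockOffsets` on the result.
#'
#' @param blocks A list of [CpGAlignment-class] objects with identical label
#'   sets.
#' @return A [CpGAlignment-class] of width `sum of block widths`, rows in
#'   the label order of the first block.
#' @examples
#' b1 <- CpGAlignment(c(h = "ACGT", g = "ACGA"))
#' b2 <- CpGAlignment(c(g = "TTCG", h = "TTCG"))
#' alnWidth(concatBlocks(list(b1, b2)))  # 8
#' @export
concatBlocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L,
            all(vapply(blocks, is, logical(1), "CpGAlignment")))
  if (length(blocks) == 1L) return(blocks[[1L]])
  ref <- alnLabels(blocks[[1L]])
  for (k in seq_along(blocks)[-1L]) {
    lb <- alnLabels(blocks[[k]])
    if (!setequal(lb, ref))
      stop("block ", k, " has a different taxon set: {",
           paste(sort(lb), collapse = ","), "} vs {",
           paste(sort(ref), collapse = ","), "}")
  }
  rows <- lapply(blocks, function(b) as.character(b@seqs)[ref])
  cat_rows <- do.call(paste0, rows)
  names(cat_rows) <- ref
  widths <- vapply(blocks, alnWidth, integer(1))
  CpGAlignment(cat_rows, blockOffsets = cumsum(c(1L, widths[-length(widths)])))
}

#' @describeIn CpGAlignment-accessors Taxon labels, in record order.
#' @export
alnLabels <- function(aln) names(aln@seqs)

#' Alignment accessors
#'
#' @name CpGAlignment-accessors
#' @param aln A [CpGAlignment-class].
#' @return `alnLabels`: character vector; `alnWidth`: number of columns;
#'   `blockOffsets`: 1-based block start columns.
NULL

#' @describeIn CpGAlignment-accessors Number of alignment columns.
#' @export
alnWidth <- function(aln) Biostrings::width(aln@seqs)[1L]

#' @describeIn CpGAlignment-accessors Block start columns.
#' @export
blockOffsets <- function(aln) aln@blockOffsets

#' @rdname CpGAlignment-class
#' @param x,object A `CpGAlignment`.
#' @aliases length,CpGAlignment-method
#' @export
setMethod("length", "CpGAlignment", function(x) length(x@seqs))

#' @rdname CpGAlignment-class
#' @aliases as.matrix,CpGAlignment-method
#' @export
setMethod("as.matrix", "CpGAlignment", function(x) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), ""))
  rownames(m) <- names(x@seqs)
  m
})

#' @rdname CpGAlignment-class
#' @export
setMethod("as.character", "CpGAlignment", function(x) as.character(x@seqs))

setMethod("show", "CpGAlignment", function(object) {
  cat(sprintf("CpGAlignment: %d taxa x %d columns (%d block%s)\n",
              length(object), alnWidth(object), length(object@blockOffsets),
              if (length(object@blockOffsets) == 1L) "" else "s"))
  cat("  taxa:", paste(alnLabels(object), collapse = ", "), "\n")
})

#' @rdname CpGAlignment-class
#' @param e1,e2 `CpGAlignment` objects; equality compares labels and rows.
#' @aliases ==,CpGAlignment,CpGAlignment-method
#' @export
setMethod("==", signature("CpGAlignment", "CpGAlignment"), function(e1, e2) {
  identical(alnLabels(e1), alnLabels(e2)) &&
    identical(as.character(e1@seqs), as.character(e2@seqs))
})
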