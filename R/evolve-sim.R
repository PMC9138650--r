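.NUC <- c("A", "C", "G", "T")
.TI_PARTNER <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T

#' Construct a substitution model
#'
#' @param baseRate Total leaving rate of a non-CpG site per unit branch
#'   length; the default 1 makes branch lengths expected substitutions per
#'   site.
#' @param tiTvRatio Transition/transversion rate ratio.
#' @param cpgMultiplier Multiplier on the deamination transitions (C->T and
#'   G->A) at unprotected CpG sites; methylated CpGs mutate to TpG at
#'   10-50x the rate of other transitions, so values in that range are
#'   typical.
#' @param protectedFraction Fraction of CpG islands flagged protected by
#'   [studyIslands()].
#' @return A [SubstitutionModel-class].
#' @export
substitutionModel <- function(baseRate = 1, tiTvRatio = 2, cpgMultiplier = 25,
                              protectedFraction = 0.5) {
  new("SubstitutionModel", baseRate = baseRate, tiTvRatio = tiTvRatio,
      cpgMultiplier = cpgMultiplier, protectedFraction = protectedFraction)
}

#' The five-species study tree
#'
#' A rooted ultrametric tree over human, gorilla, chimp, bonobo and
#' orangutan with the great-ape branching pattern (chimp+bonobo closest,
#' then human+gorilla, orangutan most distant).  Heights are in p-distance
#' units and sized for promoter-scale divergence (root height 0.03, i.e. a
#' few percent sequence divergence between orangutan and the rest).
#'
#' @return An [ape::phylo] tree.
#' @export
studyTree <- function() {
  ape::read.tree(text = paste0(
    "(((chimp:0.010,bonobo:0.010):0.012,",
    "(human:0.015,gorilla:0.015):0.007):0.008,orangutan:0.030);"))
}

#' CpG-island layout for a block-structured promoter assembly
#'
#' Emulates an assembly of `nBlocks` equal promoter regions, each carrying
#' one central CpG island covering `islandFraction` of the block.  The
#' first `round(protectedFraction * nBlocks)` islands are flagged
#' protected (unmethylated, hence exempt from deamination
#' hypermutability).
#'
#' @param rootLength Total sequence length (must divide by `nBlocks`).
#' @param nBlocks Number of promoter blocks.
#' @param islandFraction Fraction of each block covered by its island.
#' @param protectedFraction Fraction of islands flagged protected.
#' @return `data.frame` with columns `start`, `end` (1-based, closed) and
#'   `protected`.
#' @export
studyIslands <- function(rootLength = 1600, nBlocks = 5,
                         islandFraction = 100 / 320,
                         protectedFraction = 0.5) {
  blockLen <- rootLength %/% nBlocks
  islandLen <- max(2L, round(blockLen * islandFraction))
  pad <- (blockLen - islandLen) %/% 2L
  start <- (seq_len(nBlocks) - 1L) * blockLen + pad + 1L
  prot <- rep(FALSE, nBlocks)
  if (nBlocks) prot[seq_len(round(protectedFraction * nBlocks))] <- TRUE
  data.frame(start = start, end = start + islandLen - 1L, protected = prot)
}

#' Construct a simulation configuration
#'
#' Defaults describe the study conditions the package is validated
#' against: five primate taxa on the great-ape tree, a 1600-bp assembly of
#' five 320-bp promoter blocks each with a ~100-bp CpG island (CpG density
#' 0.10 inside, 0.01 outside), and a 25x deamination multiplier with half
#' the islands protected.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param rootLength Root sequence length.
#' @param islands Island `data.frame` (see [studyIslands()]); pass a
#'   zero-row data.frame for no islands.
#' @param cpgDensityIn,cpgDensityOut Target CpG frequency inside/outside
#'   islands (per position; must be <= 0.5 and `in > out`).
#' @param seed Integer seed controlling all randomness.
#' @param model A [SubstitutionModel-class].
#' @return A [SimConfig-class].
#' @export
simConfig <- function(tree = studyTree(), rootLength = 1600,
                      islands = studyIslands(rootLength),
                      cpgDensityIn = 0.10, cpgDensityOut = 0.01,
                      seed = 1L, model = substitutionModel()) {
  new("SimConfig", tree = tree, rootLength = as.integer(rootLength),
      islands = islands, cpgDensityIn = cpgDensityIn,
      cpgDensityOut = cpgDensityOut, seed = as.integer(seed), model = model)
}

#' Generate a root sequence with CpG-enriched islands
#'
#' Builds a random sequence whose expected CpG dinucleotide frequency (CpG
#' starts per position) is `cpgDensityIn` inside islands and
#' `cpgDensityOut` outside.  CpGs are planted explicitly; background draws
#' never create an accidental CpG (a `G` is not drawn directly after a
#' `C`), so the planted count is the exact CpG count and its expectation
#' matches the target density.  Base composition is otherwise uniform.
#'
#' @param length Sequence length (0 allowed).
#' @param islands Island `data.frame` (`start`, `end`, 1-based closed), or
#'   `NULL` for none.
#' @param cpgDensityIn,cpgDensityOut Target densities in `[0, 0.5]` with
#'   `in > out`.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first, otherwise the current RNG stream is used.
#' @return A single character string.
#' @export
generateRootSequence <- function(length, islands = NULL, cpgDensityIn = 0.10,
                                 cpgDensityOut = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (d in c(cpgDensityIn, cpgDensityOut))
    if (is.na(d) || d < 0 || d > 0.5)
      stop("CpG density must be in [0, 0.5]; a CpG occupies two positions")
  if (cpgDensityIn <= cpgDensityOut)
    stop("cpgDensityIn must exceed cpgDensityOut")
  if (length == 0L) return("")
  dens <- rep(cpgDensityOut, length)
  if (!is.null(islands) && nrow(islands))
    for (r in seq_len(nrow(islands)))
      dens[islands$start[r]:islands$end[r]] <- cpgDensityIn
  out <- character(length)
  prev <- ""
  p <- 1L
  while (p <= length) {
    q <- dens[p] / (1 - dens[p])       # per-unit planting odds -> density
    if (p < length && stats::runif(1) < q) {
      out[p] <- "C"; out[p + 1L] <- "G"
      prev <- "G"; p <- p + 2L
    } else {
      pool <- if (prev == "C") c("A", "C", "T") else .NUC
      b <- sample(pool, 1L)
      out[p] <- b; prev <- b; p <- p + 1L
    }
  }
  paste(out, collapse = "")
}

## Logical mask: position lies in a *protected* island (operationalizing
## "unmethylated"); a CpG at (i, i+1) is protected iff its C position i is.
.protectedMask <- function(length, islands) {
  mask <- rep(FALSE, length)
  if (!is.null(islands) && nrow(islands))
    for (r in seq_len(nrow(islands)))
      if (isTRUE(islands$protected[r]))
        mask[islands$start[r]:islands$end[r]] <- TRUE
  mask
}

## Per-site total leaving rates for an integer-coded sequence.  The excess
## over baseRate comes only from unprotected CpG context: C->T at the C and
## G->A at the G each gain (m - 1) * alpha.
.siteRatesAll <- function(sq, model, prot) {
  mu <- model@baseRate; kappa <- model@tiTvRatio
  alpha <- kappa * mu / (kappa + 2)
  extra <- (model@cpgMultiplier - 1) * alpha
  L <- length(sq)
  rates <- rep(mu, L)
  if (L >= 2L && extra > 0) {
    cpos <- which(sq[-L] == 2L & sq[-1L] == 3L)  # CpG with its C at cpos
    cpos <- cpos[!prot[cpos]]
    rates[cpos] <- rates[cpos] + extra
    rates[cpos + 1L] <- rates[cpos + 1L] + extra
  }
  rates
}

.siteRateOne <- function(sq, i, model, prot) {
  mu <- model@baseRate; kappa <- model@tiTvRatio
  alpha <- kappa * mu / (kappa + 2)
  extra <- (model@cpgMultiplier - 1) * alpha
  r <- mu
  L <- length(sq)
  if (sq[i] == 2L && i < L && sq[i + 1L] == 3L && !prot[i]) r <- r + extra
  if (sq[i] == 3L && i > 1L && sq[i - 1L] == 2L && !prot[i - 1L]) r <- r + extra
  r
}

## Rates from base sq[i] to each of the four nucleotides (0 at itself).
.targetRates <- function(sq, i, model, prot) {
  mu <- model@baseRate; kappa <- model@tiTvRatio
  beta <- mu / (kappa + 2); alpha <- kappa * beta
  b <- sq[i]
  tr <- rep(beta, 4L)
  tr[.TI_PARTNER[b]] <- alpha
  tr[b] <- 0
  L <- length(sq)
  if (b == 2L && i < L && sq[i + 1L] == 3L && !prot[i])
    tr[4L] <- tr[4L] * model@cpgMultiplier            # C->T deamination
  if (b == 3L && i > 1L && sq[i - 1L] == 2L && !prot[i - 1L])
    tr[1L] <- tr[1L] * model@cpgMultiplier            # G->A on the paired strand
  tr
}

## Gillespie event sampling down one branch; context (CpG status, hence
## rates) is re-evaluated locally after every substitution.
.evolveBranch <- function(sq, t, model, prot) {
  L <- length(sq)
  empty <- data.frame(time = numeric(0), pos = integer(0),
                      from = character(0), to = character(0),
                      wasCpG = logical(0), protected = logical(0))
  if (t <= 0 || L == 0L) return(list(seq = sq, log = empty))
  rates <- .siteRatesAll(sq, model, prot)
  Lam <- sum(rates)
  tm <- 0
  ev_t <- numeric(0); ev_p <- integer(0); ev_f <- integer(0); ev_to <- integer(0)
  ev_cpg <- logical(0); ev_prot <- logical(0)
  repeat {
    tm <- tm + stats::rexp(1L, Lam)
    if (tm > t) break
    i <- sample.int(L, 1L, prob = rates)
    to <- sample.int(4L, 1L, prob = .targetRates(sq, i, model, prot))
    isCpG_C <- sq[i] == 2L && i < L && sq[i + 1L] == 3L
    isCpG_G <- sq[i] == 3L && i > 1L && sq[i - 1L] == 2L
    cpos <- if (isCpG_C) i else if (isCpG_G) i - 1L else NA_integer_
    ev_t <- c(ev_t, tm); ev_p <- c(ev_p, i)
    ev_f <- c(ev_f, sq[i]); ev_to <- c(ev_to, to)
    ev_cpg <- c(ev_cpg, isCpG_C || isCpG_G)
    ev_prot <- c(ev_prot, !is.na(cpos) && prot[cpos])
    sq[i] <- to
    upd <- max(1L, i - 1L):min(L, i + 1L)
    newr <- vapply(upd, function(j) .siteRateOne(sq, j, model, prot), numeric(1))
    Lam <- Lam + sum(newr) - sum(rates[upd])
    rates[upd] <- newr
  }
  list(seq = sq,
       log = data.frame(time = ev_t, pos = ev_p, from = .NUC[ev_f],
                        to = .NUC[ev_to], wasCpG = ev_cpg, protected = ev_prot))
}

#' Simulate sequence evolution along a tree with CpG hypermutability
#'
#' Generates a root sequence (see [generateRootSequence()]) and evolves it
#' down every branch of the configured tree under a continuous-time
#' substitution process, sampled event by event (Gillespie): whenever the
#' *current* sequence carries an unprotected CpG, the C->T transition at
#' its cytosine and the G->A transition at its guanine run at
#' `cpgMultiplier` times the basal transition rate, and site rates are
#' re-evaluated after every substitution, so CpGs gained or lost
#' mid-branch immediately change the local rates.  No indels occur, so the
#' leaves form an alignment by construction.  Output is byte-identical for
#' identical configurations (including the seed).
#'
#' @param cfg A [SimConfig-class].
#' @return A [CpGSimulation-class] carrying the leaf alignment, the true
#'   tree and the per-event mutation log.
#' @examples
#' sim <- evolveAlongTree(simConfig(rootLength = 400, seed = 7))
#' alnWidth(alignment(sim))
#' @export
evolveAlongTree <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  if (cfg@rootLength < 2L)
    stop("rootLength must be >= 2 to form an alignment")
  set.seed(cfg@seed)
  tree <- ape::reorder.phylo(cfg@tree, "cladewise")
  nTip <- length(tree$tip.label)
  root <- generateRootSequence(cfg@rootLength, cfg@islands,
                               cfg@cpgDensityIn, cfg@cpgDensityOut)
  prot <- .protectedMask(cfg@rootLength, cfg@islands)
  seqs <- vector("list", nTip + tree$Nnode)
  seqs[[nTip + 1L]] <- match(strsplit(root, "")[[1]], .NUC)
  logs <- vector("list", nrow(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {     # cladewise: parents precede children
    par <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
    res <- .evolveBranch(seqs[[par]], tree$edge.length[r], cfg@model, prot)
    seqs[[ch]] <- res$seq
    if (nrow(res$log)) {
      res$log$node <- ch
      logs[[r]] <- res$log
    }
  }
  log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  if (is.null(log))
    log <- data.frame(time = numeric(0), pos = integer(0), from = character(0),
                      to = character(0), wasCpG = logical(0),
                      protected = logical(0), node = integer(0))
  leaves <- vapply(seq_len(nTip),
                   function(i) paste(.NUC[seqs[[i]]], collapse = ""), character(1))
  names(leaves) <- tree$tip.label
  new("CpGSimulation",
      alignment = CpGAlignment(leaves),
      tree = tree, mutationLog = log[, c("node", "time", "pos", "from", "to",
                                         "wasCpG", "protected")],
      rootSeq = root, config = cfg)
}

#' @describeIn CpGSimulation-class The simulated leaf alignment.
#' @param sim A `CpGSimulation`.
#' @export
alignment <- function(sim) sim@alignment

#' @describeIn CpGSimulation-class The true tree.
#' @export
trueTree <- function(sim) sim@tree

#' @describeIn CpGSimulation-class The per-event mutation log.
#' @export
mutationLog <- function(sim) sim@mutationLog

#' @describeIn CpGSimulation-class The ancestral root sequence.
#' @export
rootSequence <- function(sim) sim@rootSeq

setMethod("show", "CpGSimulation", function(object) {
  cat(sprintf("CpGSimulation: %d taxa x %d bp, %d substitution events (seed %d)\n",
              length(object@alignment), alnWidth(object@alignment),
              nrow(object@mutationLog), object@config@seed))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf(paste0("SubstitutionModel: baseRate %.3g, ti/tv %.3g, ",
                     "CpG multiplier %.3g, protected fraction %.2f\n"),
              object@baseRate, object@tiTvRatio, object@cpgMultiplier,
              object@protectedFraction))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d taxa, %d bp, %d island(s), seed %d\n",
              length(object@tree$tip.label), object@rootLength,
              nrow(object@islands), object@seed))
})

#' Divergence summary of a simulation with ground truth
#'
#' Runs [dinucDivergenceStats()] on the simulated alignment and sets the
#' observed dinucleotide divergence beside true substitution counts from
#' the mutation log, for calibrating the CpG effect.
#'
#' @param sim A [CpGSimulation-class].
#' @param dinucTypes,referenceRule Passed to [dinucDivergenceStats()].
#' @return A list with elements `stats` (a [DivergenceStats-class]) and
#'   `trueCounts` (`data.frame` of event counts: all events, events at CpG
#'   context, deamination-type events C->T/G->A at unprotected CpGs, and
#'   events at protected CpGs).
#' @export
summarizeDivergence <- function(sim, dinucTypes = c("CG", "AG", "TG", "GG"),
                                referenceRule = "majority") {
  stopifnot(is(sim, "CpGSimulation"))
  log <- sim@mutationLog
  deam <- log$wasCpG & !log$protected &
    ((log$from == "C" & log$to == "T") | (log$from == "G" & log$to == "A"))
  trueCounts <- data.frame(
    category = c("all_events", "cpg_context_events",
                 "cpg_deamination_events", "protected_cpg_events"),
    n = c(nrow(log), sum(log$wasCpG), sum(deam),
          sum(log$wasCpG & log$protected)))
  list(stats = dinucDivergenceStats(sim@alignment, dinucTypes, referenceRule),
       trueCounts = trueCounts)
}
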