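test_that("root sequence generation respects length, seed and densities", {
  expect_identical(generateRootSequence(0, seed = 1), "")
  s1 <- generateRootSequence(500, seed = 9)
  s2 <- generateRootSequence(500, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nchar(s1), 500L)
  expect_error(generateRootSequence(100, cpgDensityIn = 0.6), "0.5")
  expect_error(generateRootSequence(100, cpgDensityIn = 0.01,
                                    cpgDensityOut = 0.05), "exceed")
})

test_that("island CpG density lands within 3 standard errors of target", {
  isl <- data.frame(start = 2001L, end = 6000L, protected = FALSE)
  s <- generateRootSequence(10000, isl, cpgDensityIn = 0.10,
                            cpgDensityOut = 0.01, seed = 10)
  chars <- strsplit(s, "")[[1]]
  starts <- which(chars[-10000] == "C" & chars[-1] == "G")
  inIsland <- sum(starts >= 2001 & starts <= 6000) / 4000
  expect_lt(abs(inIsland - 0.10), 3 * sqrt(0.10 * 0.90 / 4000))
  outside <- sum(starts < 2001 | starts > 6000) / 6000
  expect_lt(abs(outside - 0.01), 4 * sqrt(0.01 * 0.99 / 6000))
})

test_that("zero branch lengths copy the root to every leaf", {
  tr <- studyTree()
  tr$edge.length[] <- 0
  cfg <- simConfig(tree = tr, rootLength = 200, islands = studyIslands(200),
                   seed = 3)
  sim <- evolveAlongTree(cfg)
  expect_identical(nrow(mutationLog(sim)), 0L)
  rows <- as.character(alignment(sim))
  expect_true(all(rows == rootSequence(sim)))
})

test_that("identical configurations give byte-identical output", {
  cfg <- simConfig(rootLength = 400, seed = 77)
  a <- evolveAlongTree(cfg)
  b <- evolveAlongTree(cfg)
  expect_true(alignment(a) == alignment(b))
  expect_identical(mutationLog(a), mutationLog(b))
  expect_identical(rootSequence(a), rootSequence(b))
  c <- evolveAlongTree(simConfig(rootLength = 400, seed = 78))
  expect_false(isTRUE(alignment(a) == alignment(c)))
})

test_that("replaying the mutation log reproduces every leaf", {
  sim <- evolveAlongTree(simConfig(rootLength = 600, seed = 21))
  expect_gt(nrow(mutationLog(sim)), 0)
  replayed <- replayLeaves(sim)
  rows <- as.character(alignment(sim))
  expect_identical(unname(replayed[names(rows)]), unname(rows))
})

test_that("with multiplier 1 event counts are Poisson with the basal rate", {
  # two taxa, one branch pair of total length 2*t; no CpG acceleration, so
  # the event count per replicate is Poisson(2 * t * L * baseRate)
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  L <- 500L
  lambda <- 2 * 0.05 * L
  counts <- vapply(1:50, function(r) {
    cfg <- simConfig(tree = tr, rootLength = L,
                     islands = data.frame(start = integer(0), end = integer(0),
                                          protected = logical(0)),
                     cpgDensityIn = 0.05, cpgDensityOut = 0.01, seed = 1000 + r,
                     model = substitutionModel(cpgMultiplier = 1))
    nrow(mutationLog(evolveAlongTree(cfg)))
  }, numeric(1))
  # mean within 5 sigma of lambda; dispersion index consistent with Poisson
  expect_lt(abs(mean(counts) - lambda), 5 * sqrt(lambda / 50))
  X <- sum((counts - lambda)^2 / lambda)
  expect_gt(X, qchisq(0.0005, df = 50))
  expect_lt(X, qchisq(0.9995, df = 50))
})

test_that("deamination events concentrate at unprotected CpGs when m >> 1", {
  cfg <- simConfig(rootLength = 4000, islands = studyIslands(4000),
                   seed = 55, model = substitutionModel(cpgMultiplier = 25))
  sim <- evolveAlongTree(cfg)
  log <- mutationLog(sim)
  deam <- (log$from == "C" & log$to == "T") | (log$from == "G" & log$to == "A")
  # within CpG context, unprotected sites see far more deamination than
  # protected ones, after accounting for island size (equal by design)
  expect_gt(sum(deam & log$wasCpG & !log$protected),
            5 * sum(deam & log$wasCpG & log$protected))
  tc <- summarizeDivergence(sim)$trueCounts
  expect_identical(tc$n[tc$category == "all_events"], nrow(log))
  expect_identical(tc$n[tc$category == "cpg_context_events"], sum(log$wasCpG))
})

test_that("CpG alteration rises monotonically with the multiplier", {
  pvfCG <- function(m) {
    reps <- vapply(1:5, function(r) {
      cfg <- simConfig(rootLength = 10000,
                       islands = studyIslands(10000, protectedFraction = 0),
                       seed = 7000 + r,
                       model = substitutionModel(cpgMultiplier = m))
      st <- as.data.frame(dinucDivergenceStats(alignment(evolveAlongTree(cfg)),
                                               "CG"))
      st$preservedVariableFraction
    }, numeric(1))
    mean(reps)
  }
  vals <- vapply(c(1, 5, 25, 50), pvfCG, numeric(1))
  expect_false(is.unsorted(vals))
})

test_that("protected island CpGs stay more conserved than unprotected ones", {
  cfg <- simConfig(rootLength = 10000, islands = studyIslands(10000),
                   seed = 88, model = substitutionModel(cpgMultiplier = 25))
  sim <- evolveAlongTree(cfg)
  sites <- scanDinucSites(alignment(sim), "CG")
  keep <- sites@siteClass %in% c("conserved_all", "preserved_variable")
  isl <- cfg@islands
  inProt <- rep(FALSE, length(sites@column))
  inUnprot <- rep(FALSE, length(sites@column))
  for (r in seq_len(nrow(isl))) {
    span <- sites@column >= isl$start[r] & sites@column <= isl$end[r]
    if (isl$protected[r]) inProt <- inProt | span else inUnprot <- inUnprot | span
  }
  pvf <- function(sel) {
    cls <- sites@siteClass[sel & keep]
    sum(cls == "preserved_variable") / length(cls)
  }
  expect_lt(pvf(inProt), pvf(inUnprot))
})

test_that("config validation catches malformed inputs", {
  tr <- studyTree()
  trNoLen <- tr; trNoLen$edge.length <- NULL
  expect_error(simConfig(tree = trNoLen, rootLength = 100,
                         islands = studyIslands(100)), "branch lengths")
  expect_error(simConfig(rootLength = 100,
                         islands = data.frame(start = 50, end = 150,
                                              protected = FALSE)),
               "within")
  expect_error(simConfig(rootLength = 100,
                         islands = data.frame(start = c(10, 20),
                                              end = c(30, 40),
                                              protected = c(TRUE, FALSE))),
               "overlap")
  noIslands <- data.frame(start = integer(0), end = integer(0),
                          protected = logical(0))
  expect_error(evolveAlongTree(simConfig(rootLength = 1, islands = noIslands)),
               ">= 2")
})
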