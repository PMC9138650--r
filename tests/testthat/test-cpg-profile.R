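test_that("CpG scan finds and classifies the worked 3-taxon sites", {
  sites <- scanDinucSites(toyAln(), "CG", "majority")
  df <- as.data.frame(sites)
  expect_identical(df$column, c(2L, 6L))
  expect_identical(df$siteClass, c("conserved_all", "preserved_variable"))
  expect_identical(df$state.s2, c("CG", "TG"))
  expect_identical(classifySites(sites),
                   c(conserved_all = 1L, preserved_variable = 1L,
                     not_preserved = 0L, gapped = 0L))
})

test_that("gap or N in either column makes a site gapped", {
  aln <- CpGAlignment(c(s1 = "AC-T", s2 = "ACGT"))
  sites <- scanDinucSites(aln, "CG", "any")
  expect_identical(sites@column, 2L)
  expect_identical(sites@siteClass, "gapped")
  alnN <- CpGAlignment(c(s1 = "ACGT", s2 = "ANGT"))
  expect_identical(scanDinucSites(alnN, "CG", "any")@siteClass, "gapped")
})

test_that("identical rows give only conserved sites; no CpGs gives none", {
  aln <- CpGAlignment(c(a = "TACGACGA", b = "TACGACGA", c = "TACGACGA"))
  sites <- scanDinucSites(aln, "CG")
  expect_true(all(sites@siteClass == "conserved_all"))
  none <- scanDinucSites(CpGAlignment(c(a = "ATAT", b = "ATAT")), "CG")
  expect_identical(length(none), 0L)
  expect_identical(sum(classifySites(none)), 0L)
})

test_that("a doubly altered site is counted once", {
  # majority CG (3 of 5); one taxon CA, another TG: one variable site
  aln <- CpGAlignment(c(a = "ACGT", b = "ACGT", c = "ACGT",
                        d = "ACAT", e = "ATGT"))
  sites <- scanDinucSites(aln, "CG")
  expect_identical(classifySites(sites)[["preserved_variable"]], 1L)
  st <- dinucDivergenceStats(aln, "CG")
  expect_identical(as.data.frame(st)$nPreservedVariableSites, 1L)
})

test_that("overlapping dinucleotide sites are both reported", {
  aln <- CpGAlignment(c(a = "CGCG", b = "CGCG", c = "CGCG"))
  expect_identical(scanDinucSites(aln, "CG")@column, c(1L, 3L))
})

test_that("reference rules differ as specified and bad input errors", {
  aln <- CpGAlignment(c(a = "ACGT", b = "ATGT", c = "ATGT"))
  expect_identical(length(scanDinucSites(aln, "CG", "majority")), 0L)
  anySites <- scanDinucSites(aln, "CG", "any")
  expect_identical(anySites@siteClass, "not_preserved")
  expect_identical(length(scanDinucSites(aln, "CG", "reference:a")), 1L)
  expect_identical(length(scanDinucSites(aln, "CG", "reference:b")), 0L)
  expect_error(scanDinucSites(aln, "CG", "reference:zz"), "not in the alignment")
  expect_error(scanDinucSites(aln, "CX"), "dinucType")
  expect_error(scanDinucSites(aln, "CG", "plurality"), "unknown reference rule")
})

test_that("site-class filtering keeps the requested classes only", {
  aln <- CpGAlignment(c(s1 = "AC-TACGT", s2 = "ACGTATGT", s3 = "ACGTACGT"))
  sites <- scanDinucSites(aln, "CG", "any")
  kept <- keepSiteClasses(sites)
  expect_true(all(kept@siteClass %in% c("conserved_all", "preserved_variable")))
  expect_identical(length(kept) + sum(sites@siteClass %in%
                                        c("gapped", "not_preserved")),
                   length(sites))
  expect_error(keepSiteClasses(sites, "bogus_class"))
})

test_that("polymorphic column fraction follows its definition", {
  expect_equal(polymorphicColumnFraction(CpGAlignment(c(a = "ACGT", b = "ACGA"))),
               0.25)
  expect_equal(polymorphicColumnFraction(CpGAlignment(c(a = "ACGT", b = "ACGT"))),
               0)
  # gap-only and gap-vs-base columns are not polymorphic
  expect_equal(polymorphicColumnFraction(CpGAlignment(c(a = "-NAC", b = "-TAC"))),
               0)
})

test_that("divergence stats on the worked toy match manual enumeration", {
  st <- as.data.frame(dinucDivergenceStats(toyAln(), "CG"))
  expect_identical(st$nPreservedSites, 2L)
  expect_identical(st$nPreservedVariableSites, 1L)
  expect_equal(st$preservedVariableFraction, 0.5)
  expect_equal(st$genomeFraction, 1 / 8)
  none <- as.data.frame(dinucDivergenceStats(
    CpGAlignment(c(a = "ATAT", b = "ATAT")), "CG"))
  expect_identical(none$nPreservedSites, 0L)
  expect_equal(none$preservedVariableFraction, 0)
  expect_equal(none$genomeFraction, 0)
})

test_that("scan and classify agree with brute-force enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    rows <- randomRows(sample(2:6, 1), sample(10:50, 1),
                       pGap = sample(c(0, 0.05), 1))
    aln <- CpGAlignment(rows)
    for (ty in c("CG", "AG", "TG", "GG")) {
      for (rule in c("majority", "any")) {
        got <- scanDinucSites(aln, ty, rule)
        want <- bruteScanDinuc(rows, ty, rule)
        expect_identical(got@column, vapply(want, `[[`, integer(1), "column"))
        expect_identical(got@siteClass, vapply(want, `[[`, character(1), "class"))
        if (length(want))
          expect_identical(unname(got@states),
                           unname(sapply(want, `[[`, "states")))
      }
      ref <- names(rows)[1]
      gotr <- scanDinucSites(aln, ty, paste0("reference:", ref))
      wantr <- bruteScanDinuc(rows, ty, "reference", refTaxon = ref)
      expect_identical(gotr@column, vapply(wantr, `[[`, integer(1), "column"))
    }
    expect_equal(polymorphicColumnFraction(aln), brutePolymorphicFraction(rows))
  }
})

test_that("statistics are invariant under taxon permutation and bounded", {
  set.seed(102)
  for (rep in 1:10) {
    rows <- randomRows(5, 40, pGap = 0.03)
    aln <- CpGAlignment(rows)
    perm <- CpGAlignment(rows[sample(length(rows))])
    s1 <- as.data.frame(dinucDivergenceStats(aln))
    s2 <- as.data.frame(dinucDivergenceStats(perm))
    expect_equal(s1, s2)
    expect_equal(polymorphicColumnFraction(aln), polymorphicColumnFraction(perm))
    # each altered site spans at most two polymorphic columns
    cg <- s1[s1$dinucType == "CG", ]
    expect_lte(cg$genomeFraction, 2 * polymorphicColumnFraction(aln))
    expect_lte(cg$nPreservedVariableSites, cg$nPreservedSites)
    expect_true(all(s1$preservedVariableFraction >= 0 &
                    s1$preservedVariableFraction <= 1))
  }
})
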