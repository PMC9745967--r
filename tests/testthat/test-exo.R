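test_that("removable termini follow the minimum-run rule", {
  expect_length(removableTermini(parseGlycan("LAM2")), 0L)
  expect_length(removableTermini(parseGlycan("LAM3")), 1L)
  expect_length(removableTermini(parseGlycan("LAM3ol")), 0L)
  expect_length(removableTermini(parseGlycan("LAM4ol")), 1L)
  expect_length(removableTermini(makeLinear(1)), 0L)
  # a residue carrying a 1,6 substituent is never removable, and a stub
  # attached through a 1,6 bond has run length 1
  stub <- glucanSim:::.attachBranch(makeLinear(4), 4L, 1L)
  ids <- removableTermini(stub)
  expect_false(any(vapply(ids, function(i)
    glucanSim:::.hasChildAt(stub, i, 6L), logical(1))))
})

test_that("digestion of linear substrates releases Glc down to LAM2", {
  res <- exoDigest(parseGlycan("LAM5"))
  cnt <- poolCounts(products(res))
  expect_equal(unname(cnt["Glc"]), 3)
  expect_equal(unname(cnt["LAM2"]), 1)
  expect_equal(res@nCleavages, 3L)
  expect_equal(glcLam2Ratio(products(res)), 3)
  expect_equal(glcLam2Ratio(products(exoDigest(parseGlycan("LAM6")))), 4)
})

test_that("reduced substrates stop at the trisaccharide alditol", {
  res <- exoDigest(parseGlycan("LAM5ol"))
  cnt <- poolCounts(products(res))
  expect_equal(unname(cnt["Glc"]), 2)
  expect_equal(unname(cnt["LAM3ol"]), 1)
  # LAM4ol appears as the recorded intermediate
  expect_true("Glc(b1-3)Glc(b1-3)Glc(b1-3)Glc-ol" %in%
                trajectory(res)$intermediate)
})

test_that("linear closed forms agree with the independent chain oracle", {
  for (n in 3:12) {
    res <- poolCounts(products(exoDigest(makeLinear(n))))
    orc <- linearDigestOracle(n)
    expect_equal(unname(res["Glc"]), orc$glc)
    expect_equal(orc$glc, n - 2)
    expect_equal(unname(res["LAM2"]), 1)
  }
  for (n in 4:12) {
    res <- poolCounts(products(exoDigest(makeLinear(n, reduced = TRUE))))
    orc <- linearDigestOracle(n, reduced = TRUE)
    expect_equal(unname(res["Glc"]), orc$glc)
    expect_equal(orc$glc, n - 3)
    expect_equal(orc$residualDP, 3)
    expect_equal(unname(res[paste0("LAM", 3, "ol")]), 1)
  }
})

test_that("final products are invariant to the order of terminus choices", {
  cases <- c(enumerateHybridIsomers(5, 3, "all_O6"),
             list(makeLinear(8), makeLinear(6, reduced = TRUE)),
             withr::with_seed(99, randomGlycans(20, 8)))
  for (g in cases) {
    finals <- allOrderDigestOracle(g)
    expect_length(finals, 1L)
    res <- exoDigest(g)
    traj <- trajectory(res)
    residual <- if (nrow(traj)) traj$intermediate[nrow(traj)] else
      glycanToString(g)
    expect_equal(finals, paste(res@nCleavages, "Glc +", residual))
  }
})

test_that("every digest conserves residues and water-corrected mass", {
  mc <- massConstants()
  cases <- c(list(parseGlycan("H8"), parseGlycan("LAM7ol")),
             withr::with_seed(123, randomGlycans(25, 10)))
  for (g in cases) {
    res <- exoDigest(g)
    pool <- products(res)
    expect_equal(poolTotalResidues(pool), glycanDP(g))
    prodMass <- sum(pool@counts * vapply(poolGlycans(pool), molarMass,
                                         numeric(1), "monoisotopic"))
    expect_equal(prodMass,
                 molarMass(g, "monoisotopic") +
                   res@nCleavages * mc$water_monoisotopic,
                 tolerance = 1e-9)
  }
})

test_that("reduced substrates show the exo signature", {
  # products with a free reducing end match the released glucose count
  for (n in 4:9) {
    res <- exoDigest(makeLinear(n, reduced = TRUE))
    pool <- products(res)
    reducing <- !vapply(poolGlycans(pool), isReduced, logical(1))
    expect_equal(sum(pool@counts[reducing]), res@nCleavages)
  }
})

test_that("rules-mode digestion of the default hybrid octamer leaves a branched pentamer", {
  res <- exoDigest(parseGlycan("H8"))
  cnt <- poolCounts(products(res))
  expect_equal(unname(cnt["Glc"]), 3)
  expect_equal(unname(cnt["H5"]), 1)
  expect_true("Glc(b1-3)Glc(b1-3)[Glc(b1-3)Glc(b1-6)]Glc" %in%
                names(poolGlycans(products(res))))
})

test_that("scheme-mode digestion of a 5+3 octamer applies the published table", {
  for (iso in enumerateHybridIsomers(5, 3, "reducing_side")) {
    res <- exoDigest(iso, exoRules(schemeMode = TRUE))
    cnt <- poolCounts(products(res))
    expect_equal(unname(cnt["Glc"]), 3)
    expect_equal(unname(cnt["LAM2"]), 1)
    expect_equal(unname(cnt["X"]), 1)
    expect_equal(res@mode, "scheme")
  }
  # scheme mode leaves non-octamer substrates on the rule path
  res <- exoDigest(makeLinear(5), exoRules(schemeMode = TRUE))
  expect_equal(unname(poolCounts(products(res))["Glc"]), 3)
})

test_that("branching makes every reducing_side octamer more recalcitrant than LAM8", {
  lam8 <- poolCounts(products(exoDigest(makeLinear(8))))[["Glc"]]
  expect_equal(lam8, 6)
  for (iso in enumerateHybridIsomers(5, 3, "reducing_side")) {
    glc <- poolCounts(products(exoDigest(iso)))["Glc"]
    glc <- if (is.na(glc)) 0 else unname(glc)
    expect_lte(glc, lam8)
  }
})

test_that("the by-product trisaccharide resists further digestion", {
  x <- parseGlycan("Glc(b1-3)Glc(b1-6)Glc")
  expect_length(removableTermini(x), 0L)
  res <- exoDigest(x)
  expect_equal(res@nCleavages, 0L)
})

test_that("branch-chain attack can be disabled", {
  h8 <- parseGlycan("H8")
  res <- exoDigest(h8, exoRules(attackBranchChains = FALSE))
  # only the backbone is trimmed: 2 Glc instead of 3
  expect_equal(unname(poolCounts(products(res))["Glc"]), 2)
})

test_that("ratio helpers fail cleanly on degenerate pools", {
  expect_error(glcLam2Ratio(glycanPool(c(Glc = 3))), "no laminaribiose")
  expect_error(glcBranchedRatio(glycanPool(c(Glc = 3))), "no branched")
  expect_equal(glcLam2Ratio(glycanPool(c(Glc = 2, LAM2 = 2))), 1)
})
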