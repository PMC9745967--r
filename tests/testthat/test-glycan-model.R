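test_that("aliases expand to the expected structures", {
  lam2 <- parseGlycan("LAM2")
  expect_equal(glycanDP(lam2), 2L)
  expect_false(isReduced(lam2))
  expect_equal(lam2@bonds$pos, 3L)

  lam5ol <- parseGlycan("LAM5ol")
  expect_equal(glycanDP(lam5ol), 5L)
  expect_true(isReduced(lam5ol))
  expect_equal(sum(lam5ol@residues$kind == "Glc"), 4L)
  expect_equal(lam5ol@bonds$pos, rep(3L, 4))

  expect_equal(glycanDP(parseGlycan("GLC")), 1L)
  h8 <- parseGlycan("H8")
  expect_equal(glycanDP(h8), 8L)
  expect_true(isBranched(h8))
})

test_that("the condensed dialect parses linear and branched strings", {
  g <- parseGlycan("Glc(b1-6)Glc(b1-3)Glc")
  expect_equal(glycanDP(g), 3L)
  expect_equal(sort(g@bonds$pos), c(3L, 6L))

  br <- parseGlycan(
    "Glc(b1-3)Glc(b1-3)Glc(b1-3)Glc(b1-3)[Glc(b1-3)Glc(b1-3)Glc(b1-6)]Glc")
  expect_equal(glycanDP(br), 8L)
  expect_true(isBranched(br))
  expect_equal(length(glucanSim:::.mainChain(br)), 5L)
})

test_that("malformed strings fail with informative errors", {
  expect_error(parseGlycan("Glx(b1-3)Glc"), "unexpected token")
  expect_error(parseGlycan("Glc(b1-4)Glc"), "unexpected token")
  expect_error(parseGlycan("Glc(b1-3)[Glc(b1-3)]Glc"),
               "two substituents at O3")
  expect_error(parseGlycan("Glc(b1-3)[Glc]Glc"), "lacks its linkage")
  expect_error(parseGlycan("[Glc(b1-3)Glc"), "unterminated")
})

test_that("serialization is canonical and round-trips", {
  expect_equal(glycanToString(makeLinear(2)), "Glc(b1-3)Glc")
  expect_equal(glycanToString(makeLinear(3, reduced = TRUE)),
               "Glc(b1-3)Glc(b1-3)Glc-ol")
  # branch-order permutations of the same tree collapse to one string
  a <- parseGlycan("Glc(b1-3)[Glc(b1-6)]Glc")
  b <- parseGlycan("Glc(b1-6)[Glc(b1-3)]Glc")
  expect_equal(glycanToString(a), glycanToString(b))
  expect_equal(canonOracle(a), canonOracle(b))

  withr::with_seed(42, {
    for (i in 1:1000) {
      g <- genRandomGlycan(sample(1:12, 1))
      rt <- parseGlycan(glycanToString(g))
      expect_true(glycanIdentical(g, rt))
      expect_equal(canonOracle(g), canonOracle(rt))
    }
  })
})

test_that("linear constructors honour DP and reduction", {
  expect_equal(glycanDP(makeLinear(1)), 1L)
  expect_false(isReduced(makeLinear(1)))
  lam5ol <- makeLinear(5, reduced = TRUE)
  expect_true(glycanIdentical(lam5ol, parseGlycan("LAM5ol")))
  expect_equal(glycanDP(makeLinear(6)), 6L)
  expect_error(makeLinear(0), "DP")
})

test_that("molar masses follow the additive model and integer convention", {
  expect_equal(molarMass(makeLinear(1), "paper_integer"), 180)
  expect_equal(molarMass(makeLinear(2), "paper_integer"), 342)
  expect_equal(molarMass(makeLinear(3), "paper_integer"), 504)
  expect_equal(molarMass(makeLinear(8), "paper_integer"), 1315)
  # branched topology is mass-equivalent
  for (iso in enumerateHybridIsomers(5, 3, "all_O6"))
    expect_equal(molarMass(iso, "paper_integer"), 1315)
  expect_equal(molarMass(makeLinear(5, reduced = TRUE), "monoisotopic"),
               5 * 162.0528 + 18.0106 + 2.0157, tolerance = 1e-10)
  # additivity on random trees, exactly
  mc <- massConstants()
  withr::with_seed(7, {
    for (i in 1:50) {
      g <- genRandomGlycan(sample(1:15, 1))
      expect_equal(molarMass(g, "average"),
                   glycanDP(g) * mc$anhydrohexose_average +
                     mc$water_average +
                     if (isReduced(g)) mc$reduction_average else 0)
    }
  })
})

test_that("sodiated m/z matches hand arithmetic and the +DP3 increment", {
  expect_equal(mzSodiated(1), 162.0528 + 18.0106 + 22.9898)
  expect_equal(mzSodiated(8), 1337.4228, tolerance = 1e-9)
  expect_equal(mzSodiated(makeLinear(8)), mzSodiated(8))
  expect_equal(mzSodiated(11) - mzSodiated(8), 3 * 162.0528,
               tolerance = 1e-9)
})

test_that("hybrid isomer enumeration is model-dependent and duplicate-free", {
  antagonism <- enumerateHybridIsomers(5, 3, "reducing_side")
  expect_length(antagonism, 3L)
  all6 <- enumerateHybridIsomers(5, 3, "all_O6")
  expect_length(all6, 5L)
  # oracle: pairwise-exhaustive distinctness under the independent encoding
  for (set in list(antagonism, all6)) {
    enc <- vapply(set, canonOracle, character(1))
    expect_equal(anyDuplicated(enc), 0L)
  }
  # reducing_side positions are a subset of the all-O6 positions
  expect_true(all(vapply(antagonism, glycanToString, character(1)) %in%
                  vapply(all6, glycanToString, character(1))))
  expect_length(enumerateHybridIsomers(5, 0), 1L)
  expect_false(isBranched(enumerateHybridIsomers(5, 0)[[1]]))
  expect_error(enumerateHybridIsomers(3, 5), "exceed")
})

test_that("glycan validity rules reject malformed trees", {
  g <- makeLinear(3)
  bad <- g
  bad@residues$kind[1] <- "Glc-ol"       # glucitol off-root
  expect_error(validObject(bad), "glucitol")
  bad2 <- g
  bad2@bonds$parent[1] <- 1L             # self-loop breaks the tree
  expect_error(validObject(bad2))
})
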