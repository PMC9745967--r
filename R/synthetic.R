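# Seeded synthetic-data generators: substrate pools with contaminant LAM6,
# laminarin-like polymer ensembles, noisy quantification tables and peak
# lists. All randomness is scoped with withr::with_seed, so a fixed seed
# gives bit-identical fixtures without touching the caller's RNG state.

#' Synthetic-data generator configuration
#'
#' @param seed integer seed; fixed seed implies bit-identical output
#' @param lam5ContaminationFraction fraction of LAM6 in a commercial-LAM5
#'   pool (default 0.05; the true contaminant fraction is not quantified,
#'   this is a configuration choice)
#' @param quantNoiseSd gaussian noise on micrograms (default 0.1, the scale
#'   of the published replicate scatter)
#' @param mzNoiseSd gaussian noise on m/z centroids in Da (default 0.1)
#' @param laminarinMeanDP mean chain DP of the laminarin ensemble
#'   (default 25)
#' @param laminarinBranchProb per-internal-residue probability of a 1,6
#'   branch (default 0.07)
#' @param branchStubDP DP of each laminarin branch (default 1, single-Glc
#'   stubs; switchable to 2-3)
#' @param poolSize number of molecules drawn per pool (default 100)
#' @return a list of class \code{generatorConfig}
#' @examples
#' generatorConfig(seed = 7)
#' @export
generatorConfig <- function(seed = 1L,
                            lam5ContaminationFraction = 0.05,
                            quantNoiseSd = 0.1,
                            mzNoiseSd = 0.1,
                            laminarinMeanDP = 25L,
                            laminarinBranchProb = 0.07,
                            branchStubDP = 1L,
                            poolSize = 100L) {
  if (lam5ContaminationFraction < 0 || lam5ContaminationFraction > 1 ||
      laminarinBranchProb < 0 || laminarinBranchProb > 1)
    stop("probabilities must lie in [0, 1]")
  if (quantNoiseSd < 0 || mzNoiseSd < 0)
    stop("noise standard deviations must be >= 0")
  poolSize <- as.integer(poolSize)
  if (is.na(poolSize) || poolSize < 1L) stop("poolSize must be >= 1")
  structure(list(seed = as.integer(seed),
                 lam5ContaminationFraction = lam5ContaminationFraction,
                 quantNoiseSd = quantNoiseSd,
                 mzNoiseSd = mzNoiseSd,
                 laminarinMeanDP = as.integer(laminarinMeanDP),
                 laminarinBranchProb = laminarinBranchProb,
                 branchStubDP = as.integer(branchStubDP),
                 poolSize = poolSize),
            class = "generatorConfig")
}

#' Simulate a commercial LAM5 substrate pool
#'
#' Draws \code{poolSize} molecules that are LAM5 except for a binomial
#' fraction of contaminant LAM6, emulating the minor DP-6 impurity of
#' commercial pentamer preparations.
#'
#' @param config a [generatorConfig()]
#' @return a [GlycanPool-class]
#' @examples
#' poolCounts(genSubstratePool(generatorConfig(seed = 3)))
#' @export
genSubstratePool <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  n6 <- withr::with_seed(config$seed,
    rbinom(1L, config$poolSize, config$lam5ContaminationFraction))
  counts <- c(LAM5 = config$poolSize - n6, LAM6 = n6)
  glycanPool(counts[counts > 0])
}

#' Simulate a laminarin-like polymer ensemble
#'
#' Chains are mostly 1,3-linked with sparse 1,6 branches: chain DP is
#' Poisson(\code{laminarinMeanDP}) truncated at >= 5, and every internal
#' backbone residue independently carries a short 1,6-linked branch
#' (\code{branchStubDP} glucose units) with probability
#' \code{laminarinBranchProb}.
#'
#' @param config a [generatorConfig()]
#' @return a [GlycanPool-class]
#' @examples
#' p <- genLaminarinPool(generatorConfig(seed = 2, poolSize = 5))
#' poolTotalResidues(p)
#' @export
genLaminarinPool <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  withr::with_seed(config$seed, {
    pool <- .emptyPool()
    for (i in seq_len(config$poolSize)) {
      repeat {
        n <- rpois(1L, config$laminarinMeanDP)
        if (n >= 5L) break
      }
      g <- makeLinear(n)
      # internal residues: everything but the root and the non-reducing leaf
      internal <- setdiff(seq_len(n), c(1L, n))
      for (id in internal) {
        if (runif(1L) < config$laminarinBranchProb)
          g <- .attachBranch(g, id, config$branchStubDP)
      }
      pool <- .poolAdd(pool, g, 1)
    }
    pool
  })
}

#' Simulate a noisy quantification table
#'
#' Emulates the measurement layer of a printed product table: true
#' micrograms per species (counts read as nanomoles) plus independent
#' gaussian noise truncated at zero, three replicate draws, means and
#' standard deviations rounded to one decimal.
#'
#' @param truePool the true product [GlycanPool-class]
#' @param config a [generatorConfig()]
#' @param nmolPerCount nanomoles represented by one count unit
#' @return data.frame with columns \code{species}, \code{dp},
#'   \code{mass_ug}, \code{sd_ug}, \code{nmol}, \code{sd_nmol}
#' @examples
#' tab <- genQuantTable(exoDigest(glycanPool(c(LAM5 = 2))),
#'                      generatorConfig(seed = 11))
#' @export
genQuantTable <- function(truePool, config = generatorConfig(),
                          nmolPerCount = 1) {
  stopifnot(is(truePool, "GlycanPool"), inherits(config, "generatorConfig"))
  q <- quantifyPool(truePool, nmolPerCount = nmolPerCount)
  if (!nrow(q))
    return(data.frame(species = character(), dp = integer(),
                      mass_ug = numeric(), sd_ug = numeric(),
                      nmol = numeric(), sd_nmol = numeric()))
  withr::with_seed(config$seed, {
    reps <- vapply(q$mass_ug, function(mu)
      pmax(0, mu + rnorm(3L, 0, config$quantNoiseSd)), numeric(3))
    mass <- round(colMeans(reps), 1)
    sdv <- round(apply(reps, 2, stats::sd), 1)
    red <- vapply(poolGlycans(truePool), isReduced, logical(1))
    nmol <- mapply(toNanomoles, mass, q$dp, red)
    sdn <- round(sdv / (molarMass(as.numeric(q$dp), "paper_integer")) * 1000, 1)
    data.frame(species = q$species, dp = q$dp,
               mass_ug = mass, sd_ug = sdv,
               nmol = nmol, sd_nmol = sdn, row.names = NULL)
  })
}

#' Simulate a noisy MALDI peak list
#'
#' Predicts the [M+Na]+ peaks of a pool and jitters the centroids with
#' gaussian noise of sd \code{mzNoiseSd}.
#'
#' @param pool a [GlycanPool-class]
#' @param config a [generatorConfig()]
#' @return data.frame as [predictPeaks()], with noisy \code{mz}
#' @export
genPeakList <- function(pool, config = generatorConfig()) {
  pk <- predictPeaks(pool)
  if (!nrow(pk)) return(pk)
  withr::with_seed(config$seed, {
    pk$mz <- pk$mz + rnorm(nrow(pk), 0, config$mzNoiseSd)
  })
  pk[order(pk$mz), , drop = FALSE]
}

#' Generate a random glycan tree
#'
#' Random rooted glucan tree used for property testing: grows from a single
#' residue by repeatedly attaching a glucose to a random free O3 or O6
#' (O6 with probability \code{branchProb}); the root is reduced with
#' probability \code{reducedProb}. Uses the caller's RNG state.
#'
#' @param dp target DP (>= 1)
#' @param branchProb probability that a new residue attaches via O6
#' @param reducedProb probability of a glucitol root
#' @return a [Glycan-class]
#' @export
genRandomGlycan <- function(dp, branchProb = 0.25, reducedProb = 0.2) {
  dp <- as.integer(dp)
  if (dp < 1L) stop("DP must be >= 1")
  reduced <- runif(1L) < reducedProb
  g <- makeLinear(1L, reduced = reduced)
  while (glycanDP(g) < dp) {
    ids <- g@residues$id
    pos <- if (runif(1L) < branchProb) 6L else 3L
    free <- ids[!vapply(ids, function(i) .hasChildAt(g, i, pos), logical(1))]
    if (!length(free)) next
    at <- free[sample.int(length(free), 1L)]
    newId <- max(ids) + 1L
    g <- .newGlycan(rbind(g@residues, data.frame(id = newId, kind = "Glc")),
                    rbind(g@bonds, data.frame(child = newId, parent = at,
                                              pos = pos)),
                    g@root)
  }
  g
}

#' Write a fixture set to a directory
#'
#' Writes a substrate pool CSV (species, count), a noisy quantification CSV
#' and a noisy peak-list TSV, all derived from the configured seed; the
#' files are byte-stable for a fixed configuration.
#'
#' @param dir output directory (created if missing)
#' @param config a [generatorConfig()]
#' @return invisible named character vector of file paths
#' @export
genFixtures <- function(dir, config = generatorConfig()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sub <- genSubstratePool(config)
  cnt <- poolCounts(sub)
  poolPath <- file.path(dir, "substrate_pool.csv")
  write.csv(data.frame(species = names(cnt), count = as.numeric(cnt)),
            poolPath, row.names = FALSE, quote = FALSE)
  reacted <- reactBatch(sub, reactionConfig(rounds = 3L))
  digested <- exoDigest(reacted@pool, exoRules(schemeMode = TRUE))
  quantPath <- file.path(dir, "quant_table.csv")
  writeQuantTable(genQuantTable(digested, config), quantPath)
  peakPath <- file.path(dir, "peaks.tsv")
  writePeakList(genPeakList(reacted@pool, config), peakPath)
  invisible(c(pool = poolPath, quant = quantPath, peaks = peakPath))
}
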