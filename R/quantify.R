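# Stoichiometric accounting: microgram/nanomole conversions, the difference
# formulas used to infer unobserved species, molar ratios and enzyme-unit
# arithmetic. Printed-table conventions: micrograms and nanomoles to one
# decimal, percentages to integers; all internal arithmetic is unrounded.

#' Convert micrograms to nanomoles
#'
#' nmol = ug / M * 1000, with M the integer molar mass convention by default
#' (180, 342, 504, 1315 g/mol for DP 1, 2, 3, 8), reported at one decimal.
#'
#' @param massUg mass in micrograms (>= 0)
#' @param dp species degree of polymerization
#' @param reduced logical, alditol end
#' @param masses \code{"paper_integer"} (default) or \code{"average"}
#' @return nanomoles, rounded to one decimal
#' @examples
#' toNanomoles(3.4, 1)  # 18.9
#' toNanomoles(7.7, 8)  # 5.9
#' @export
toNanomoles <- function(massUg, dp, reduced = FALSE,
                        masses = c("paper_integer", "average")) {
  masses <- match.arg(masses)
  if (any(massUg < 0)) stop("mass must be non-negative")
  dp <- as.integer(dp)
  if (any(is.na(dp)) || any(dp < 1L)) stop("unknown species DP")
  M <- molarMass(as.numeric(dp), flavor = masses, reduced = reduced)
  round(massUg / M * 1000, 1)
}

#' Infer the hybrid-oligosaccharide mass by difference
#'
#' In a transglucanase pretreatment every microgram of substrate not
#' recovered as released laminaribiose is hybrid product:
#' hybrid = start - LAM2.
#'
#' @param startUg starting substrate mass (ug)
#' @param lam2Ug released laminaribiose mass (ug)
#' @return inferred hybrid mass (ug), one decimal
#' @examples
#' inferHybridMass(10.23, 2.5)  # 7.7
#' @export
inferHybridMass <- function(startUg, lam2Ug) {
  if (startUg < lam2Ug)
    stop("accounting error: LAM2 exceeds the starting amount")
  round(startUg - lam2Ug, 1)
}

#' Infer the branched by-product mass by difference
#'
#' After exo digestion of pretreated substrate, the mass not recovered as
#' laminaribiose or glucose is the exo-resistant branched by-product:
#' X = start - LAM2 - Glc.
#'
#' @param startUg starting substrate mass (ug)
#' @param lam2Ug laminaribiose mass (ug)
#' @param glcUg glucose mass (ug)
#' @return inferred by-product mass (ug), one decimal
#' @examples
#' inferByproductMass(10.23, 4.1, 3.4)  # 2.7
#' @export
inferByproductMass <- function(startUg, lam2Ug, glcUg) {
  if (startUg < lam2Ug + glcUg)
    stop("accounting error: products exceed the starting amount")
  round(startUg - lam2Ug - glcUg, 1)
}

#' Percent reduction of an activity or amount
#'
#' (1 - treated/reference) x 100, rounded to the nearest integer; with the
#' measured glucose masses 6.2 and 3.4 ug this is the 45 % inhibition of the
#' exo-glucanase by prior branching.
#'
#' @param reference reference amount (> 0)
#' @param treated treated amount
#' @return integer percentage
#' @examples
#' percentReduction(6.2, 3.4)  # 45
#' @export
percentReduction <- function(reference, treated) {
  if (reference <= 0) stop("reference must be positive")
  round((1 - treated / reference) * 100)
}

#' Specific enzyme activity
#'
#' One unit (U) is one micromole of product released per minute; specific
#' activity is U per mg enzyme. Vectors are interpreted as repeated
#' timepoint measurements on the linear phase and the per-timepoint unit
#' values are averaged.
#'
#' @param productUmol micromoles of product released
#' @param timeMin incubation time in minutes
#' @param enzymeMg enzyme amount in mg
#' @return specific activity in U/mg
#' @examples
#' specificActivity(0.6, 20, 0.001)  # 30
#' @export
specificActivity <- function(productUmol, timeMin, enzymeMg) {
  if (any(productUmol <= 0) || any(timeMin <= 0) || any(enzymeMg <= 0))
    stop("activity measurements must be strictly positive")
  mean(productUmol / timeMin / enzymeMg)
}

#' Relative activity
#'
#' Activity at a condition relative to the optimum:
#' Units_x / Units_opt x 100 %.
#'
#' @param unitsX units at the tested condition
#' @param unitsOpt units at the optimum (> 0)
#' @return percentage
#' @examples
#' relativeActivity(0.5, 1)  # 50
#' @export
relativeActivity <- function(unitsX, unitsOpt) {
  if (unitsOpt <= 0) stop("reference units must be positive")
  unitsX / unitsOpt * 100
}

#' Quantify a product pool
#'
#' Converts pool counts into a quantification table. Counts are interpreted
#' as nanomoles times \code{nmolPerCount}; micrograms follow from the molar
#' masses. All values are unrounded; see [genQuantTable()] for the
#' printed-table (noisy, rounded) emulation.
#'
#' @param pool a [GlycanPool-class]
#' @param nmolPerCount nanomoles represented by one count unit
#' @param masses molar mass convention, \code{"paper_integer"} or
#'   \code{"average"}
#' @return data.frame with columns \code{species}, \code{dp}, \code{count},
#'   \code{nmol}, \code{mass_ug}
#' @examples
#' quantifyPool(exoDigest(glycanPool(c(LAM5 = 2))))
#' @export
quantifyPool <- function(pool, nmolPerCount = 1,
                         masses = c("paper_integer", "average")) {
  masses <- match.arg(masses)
  stopifnot(is(pool, "GlycanPool"))
  if (!length(pool@glycans))
    return(data.frame(species = character(), dp = integer(),
                      count = numeric(), nmol = numeric(),
                      mass_ug = numeric()))
  dp <- vapply(pool@glycans, glycanDP, integer(1))
  red <- vapply(pool@glycans, isReduced, logical(1))
  M <- mapply(function(d, r) molarMass(as.numeric(d), flavor = masses,
                                       reduced = r), dp, red)
  nmol <- pool@counts * nmolPerCount
  data.frame(species = vapply(pool@glycans, speciesLabel, character(1)),
             dp = dp, count = pool@counts, nmol = nmol,
             mass_ug = nmol * M / 1000, row.names = NULL)
}

#' Read/write quantification tables
#'
#' CSV round-trip for quantification tables (columns \code{species},
#' \code{mass_ug}, \code{sd_ug}, \code{nmol}, \code{sd_nmol}).
#'
#' @param path file path
#' @param table data.frame to write
#' @return \code{readQuantTable}: the data.frame
#' @export
readQuantTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readQuantTable
#' @export
writeQuantTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
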