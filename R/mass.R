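# Mass arithmetic for hexose oligomers. Only [M+Na]+ centroids are needed,
# so fixed 4-decimal constants suffice; no isotope distributions.

.MASS <- list(
  anhydrohexose_average      = 162.141,
  anhydrohexose_monoisotopic = 162.0528,
  water_average              = 18.015,
  water_monoisotopic         = 18.0106,
  sodium_monoisotopic        = 22.9898,
  reduction_average          = 2.016,   # alditol vs aldose (+2 H)
  reduction_monoisotopic     = 2.0157
)

#' Mass constants used throughout the package
#'
#' @return named list: average and monoisotopic anhydrohexose and water
#'   masses, the monoisotopic mass of sodium, and the alditol reduction
#'   increment (+2 H).
#' @examples
#' massConstants()$anhydrohexose_monoisotopic
#' @export
massConstants <- function() .MASS

.dpMass <- function(dp, reduced, flavor) {
  switch(flavor,
    average = dp * .MASS$anhydrohexose_average + .MASS$water_average +
      if (reduced) .MASS$reduction_average else 0,
    monoisotopic = dp * .MASS$anhydrohexose_monoisotopic +
      .MASS$water_monoisotopic +
      if (reduced) .MASS$reduction_monoisotopic else 0,
    paper_integer = round(dp * .MASS$anhydrohexose_average +
      .MASS$water_average +
      if (reduced) .MASS$reduction_average else 0),
    stop("unknown mass flavor: ", flavor))
}

#' @rdname molarMass
setMethod("molarMass", "Glycan", function(x, flavor = c("average",
    "monoisotopic", "paper_integer"), ...) {
  flavor <- match.arg(flavor)
  .dpMass(glycanDP(x), isReduced(x), flavor)
})

#' @rdname molarMass
#' @param reduced logical, alditol end (numeric method only)
setMethod("molarMass", "numeric", function(x, flavor = c("average",
    "monoisotopic", "paper_integer"), reduced = FALSE, ...) {
  flavor <- match.arg(flavor)
  if (any(x < 1)) stop("DP must be >= 1")
  vapply(x, .dpMass, numeric(1), reduced = reduced, flavor = flavor)
})

.dpMz <- function(dp, reduced) {
  .dpMass(dp, reduced, "monoisotopic") + .MASS$sodium_monoisotopic
}

#' @rdname mzSodiated
setMethod("mzSodiated", "Glycan", function(x, ...) {
  .dpMz(glycanDP(x), isReduced(x))
})

#' @rdname mzSodiated
#' @param reduced logical, alditol end (numeric method only)
setMethod("mzSodiated", "numeric", function(x, reduced = FALSE, ...) {
  if (any(x < 1)) stop("DP must be >= 1")
  vapply(x, .dpMz, numeric(1), reduced = reduced)
})

# nearest hexose-oligomer DP for an observed [M+Na]+ centroid
.dpFromMz <- function(mz, reduced = FALSE) {
  round((mz - .MASS$sodium_monoisotopic - .MASS$water_monoisotopic -
         if (reduced) .MASS$reduction_monoisotopic else 0) /
        .MASS$anhydrohexose_monoisotopic)
}
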