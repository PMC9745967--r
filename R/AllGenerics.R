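#' @name glucanSim-generics
#' @title Generics for glycan objects
#' @description Accessor and computation generics for [Glycan-class] and
#'   [GlycanPool-class] objects.
#' @param x a [Glycan-class] (or, where documented, a [GlycanPool-class])
#' @keywords internal
NULL

#' @rdname glucanSim-generics
#' @export
setGeneric("glycanDP", function(x) standardGeneric("glycanDP"))

#' @rdname glucanSim-generics
#' @export
setGeneric("isReduced", function(x) standardGeneric("isReduced"))

#' @rdname glucanSim-generics
#' @export
setGeneric("isBranched", function(x) standardGeneric("isBranched"))

#' @rdname glucanSim-generics
#' @export
setGeneric("glycanToString", function(x) standardGeneric("glycanToString"))

#' Average, monoisotopic or integer molar mass
#'
#' Oligomer mass is purely additive: DP x anhydrohexose + one water, plus the
#' alditol increment (+2 H) when the root is glucitol. The
#' \code{"paper_integer"} flavour rounds the average mass to the nearest
#' integer, the convention used for microgram-to-nanomole bookkeeping
#' (DP 1, 2, 3, 8 give 180, 342, 504, 1315 g/mol).
#'
#' @param x a [Glycan-class], or an integer DP (with \code{reduced})
#' @param flavor \code{"average"}, \code{"monoisotopic"} or
#'   \code{"paper_integer"}
#' @param ... passed between methods (\code{reduced = FALSE} for the numeric
#'   method)
#' @return mass in g/mol (Da)
#' @examples
#' molarMass(makeLinear(8), "paper_integer")  # 1315
#' molarMass(5, "monoisotopic", reduced = TRUE)
#' @seealso [mzSodiated()], [massConstants()]
#' @export
setGeneric("molarMass",
  function(x, flavor = c("average", "monoisotopic", "paper_integer"), ...)
    standardGeneric("molarMass"))

#' Sodiated monoisotopic m/z ([M+Na]+)
#'
#' The dominant MALDI species for neutral glycans is the singly charged
#' sodium adduct; its m/z is the monoisotopic neutral mass plus the mass of
#' sodium. A glucose octamer gives 1337.42 Da.
#'
#' @param x a [Glycan-class], or an integer DP
#' @param ... \code{reduced = FALSE} for the numeric method
#' @return m/z in Da
#' @examples
#' mzSodiated(8)            # 1337.42
#' mzSodiated(makeLinear(5))
#' @export
setGeneric("mzSodiated", function(x, ...) standardGeneric("mzSodiated"))

#' Exo-1,3-beta-glucanase digestion
#'
#' Sequentially removes removable non-reducing termini (one glucose per
#' step) until none remains; see [removableTermini()] for the removal rule
#' and [exoRules()] for its parameters.
#'
#' @param x a [Glycan-class] or a [GlycanPool-class]
#' @param rules an [exoRules()] configuration
#' @return for a \code{Glycan}, a [DigestResult-class]; for a
#'   \code{GlycanPool}, the pooled product [GlycanPool-class]
#' @examples
#' res <- exoDigest(parseGlycan("LAM5"))
#' poolCounts(products(res))
#' @export
setGeneric("exoDigest", function(x, rules = exoRules()) standardGeneric("exoDigest"))

#' @rdname DigestResult-class
#' @param x a [DigestResult-class]
#' @export
setGeneric("products", function(x) standardGeneric("products"))

#' @rdname DigestResult-class
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
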