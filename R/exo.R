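# Exo-1,3-beta-glucanase engine: sequential release of glucose from
# non-reducing ends, with run-length stopping rules.

#' Exo-glucanase rule configuration
#'
#' The enzyme binds a run of consecutive 1,3-linked glucosyl units counted
#' from the attacked terminus toward the root. The run is terminated (the
#' terminator itself excluded) by a glucitol, by a 1,6 bond, or by a residue
#' carrying a 1,6 substituent. A terminus is removable only when that run is
#' at least \code{minRunLength} residues long -- with the default of 3, linear
#' substrates need a minimum of three units, and reduced chains stop at the
#' trisaccharide alditol.
#'
#' @param minRunLength minimum run of 1,3-linked glucosyl residues (>= 2)
#' @param attackBranchChains if \code{TRUE} (default) chains hanging from a
#'   1,6 bond are attacked under the same rule; if \code{FALSE} only the main
#'   chain is attacked
#' @param schemeMode if \code{TRUE}, digestion of a 5+3 hybrid octamer
#'   returns the product table of the published reaction scheme (3 Glc +
#'   LAM2 + a branched trisaccharide) instead of the rule-derived products;
#'   see the methods vignette for why the two cannot coincide
#' @return a list of class \code{exoRules}
#' @examples
#' exoRules()
#' exoRules(schemeMode = TRUE)
#' @export
exoRules <- function(minRunLength = 3L, attackBranchChains = TRUE,
                     schemeMode = FALSE) {
  minRunLength <- as.integer(minRunLength)
  if (is.na(minRunLength) || minRunLength < 2L)
    stop("minRunLength must be an integer >= 2")
  structure(list(minRunLength = minRunLength,
                 attackBranchChains = isTRUE(attackBranchChains),
                 schemeMode = isTRUE(schemeMode)),
            class = "exoRules")
}

# length of the maximal run of consecutive 1,3-linked glucosyl residues from
# `id` toward the root; terminators (glucitol, a 1,6 bond, or a residue
# bearing a 1,6 substituent) are not counted
.runLength <- function(g, id) {
  len <- 1L
  cur <- id
  repeat {
    pb <- .parentBondOf(g, cur)
    if (!nrow(pb)) break                        # reached the root
    if (pb$pos != 3L) break                     # 1,6 bond terminates
    p <- pb$parent
    if (.kindOf(g, p) != "Glc") break           # glucitol terminates
    if (.hasChildAt(g, p, 6L)) break            # 1,6-substituted residue
    len <- len + 1L
    cur <- p
  }
  len
}

# TRUE if the path from `id` to the root crosses a 1,6 bond
.onBranchChain <- function(g, id) {
  cur <- id
  repeat {
    pb <- .parentBondOf(g, cur)
    if (!nrow(pb)) return(FALSE)
    if (pb$pos == 6L) return(TRUE)
    cur <- pb$parent
  }
}

#' Removable non-reducing termini
#'
#' A residue is removable iff it is an unsubstituted glucosyl leaf, its bond
#' to its parent is 1,3, and the run of consecutive 1,3-linked glucosyl
#' residues from it toward the root (see [exoRules()]) is at least
#' \code{minRunLength} long. Residues bearing a 1,6 substituent are never
#' removable.
#'
#' @param g a [Glycan-class]
#' @param rules an [exoRules()] configuration
#' @return integer vector of removable residue ids (possibly empty)
#' @examples
#' removableTermini(parseGlycan("LAM3"))   # one terminus
#' removableTermini(parseGlycan("LAM2"))   # none: chain too short
#' removableTermini(parseGlycan("LAM3ol")) # none: glucitol shortens the run
#' @export
removableTermini <- function(g, rules = exoRules()) {
  stopifnot(is(g, "Glycan"))
  out <- integer()
  for (id in g@residues$id) {
    if (!.isLeaf(g, id)) next
    if (.kindOf(g, id) != "Glc") next
    pb <- .parentBondOf(g, id)
    if (!nrow(pb) || pb$pos != 3L) next
    if (!rules$attackBranchChains && .onBranchChain(g, id)) next
    if (.runLength(g, id) >= rules$minRunLength) out <- c(out, id)
  }
  out
}

# canonical path-from-root of a residue, for the deterministic tie-break
.pathFromRoot <- function(g, id) {
  path <- character()
  cur <- id
  repeat {
    pb <- .parentBondOf(g, cur)
    if (!nrow(pb)) break
    path <- c(as.character(pb$pos), path)
    cur <- pb$parent
  }
  paste(path, collapse = ".")
}

# TRUE for a non-reduced hybrid of a linear 1,3 pentamer backbone plus one
# 1,6-linked linear 1,3 trisaccharide branch (any attachment position)
.isHybridOctamer53 <- function(g) {
  if (glycanDP(g) != 8L || isReduced(g)) return(FALSE)
  if (sum(g@bonds$pos == 6L) != 1L) return(FALSE)
  length(.mainChain(g)) == 5L
}

# the exo-resistant branched trisaccharide ("by-product X"): a 1,3-linked
# dimer hanging from O6 of the former backbone reducing-end residue
.byproductX <- function() parseGlycan("Glc(b1-3)Glc(b1-6)Glc")

#' @describeIn exoDigest digest one glycan to completion; the trajectory
#'   records every intermediate. With \code{schemeMode = TRUE} and a 5+3
#'   hybrid octamer substrate, the published scheme's product table
#'   (3 Glc + LAM2 + branched trisaccharide X) is applied instead of rule
#'   derivation.
setMethod("exoDigest", "Glycan", function(x, rules = exoRules()) {
  stopifnot(inherits(rules, "exoRules"))
  if (rules$schemeMode && .isHybridOctamer53(x)) {
    prod <- glycanPool(list(makeLinear(1L), makeLinear(2L), .byproductX()),
                       counts = c(3, 1, 1))
    traj <- data.frame(step = 1L,
                       intermediate = .canonString(.byproductX()),
                       released = "3 Glc + LAM2")
    return(new("DigestResult", products = prod, trajectory = traj,
               nCleavages = 4L, substrate = x, mode = "scheme"))
  }
  cur <- x
  n <- 0L
  steps <- list()
  repeat {
    rem <- removableTermini(cur, rules)
    if (!length(rem)) break
    paths <- vapply(rem, function(id) .pathFromRoot(cur, id), character(1))
    pick <- rem[order(paths)][1L]
    cur <- .removeLeaf(cur, pick)
    n <- n + 1L
    steps[[n]] <- data.frame(step = n, intermediate = .canonString(cur),
                             released = "Glc")
  }
  prod <- glycanPool(list(cur), counts = 1)
  if (n > 0L) prod <- .poolAdd(prod, makeLinear(1L), n)
  traj <- if (n) do.call(rbind, steps) else
    data.frame(step = integer(), intermediate = character(),
               released = character())
  new("DigestResult", products = prod, trajectory = traj,
      nCleavages = n, substrate = x,
      mode = if (rules$schemeMode) "scheme" else "rules")
})

#' @describeIn exoDigest digest every species in a pool; per-species product
#'   pools are scaled by the species counts and merged.
setMethod("exoDigest", "GlycanPool", function(x, rules = exoRules()) {
  out <- .emptyPool()
  for (i in seq_along(x@glycans)) {
    r <- exoDigest(x@glycans[[i]], rules)
    out <- .poolMerge(out, products(r), bScale = x@counts[i])
  }
  out
})

setMethod("products", "DigestResult", function(x) x@products)
setMethod("trajectory", "DigestResult", function(x) x@trajectory)

setMethod("show", "DigestResult", function(object) {
  cat(sprintf("DigestResult (%s mode): %d cleavage(s) on %s\n",
              object@mode, object@nCleavages,
              speciesLabel(object@substrate)))
  print(poolCounts(object@products))
})

#' Molar glucose : laminaribiose ratio of a product pool
#'
#' The diagnostic exo-digestion statistic: moles of free glucose divided by
#' moles of laminaribiose. Complete digestion of a linear DP-n substrate
#' gives (n - 2) : 1.
#'
#' @param pool a [GlycanPool-class] of digestion products
#' @return numeric ratio
#' @examples
#' glcLam2Ratio(exoDigest(glycanPool(c(LAM5 = 1))))
#' @export
glcLam2Ratio <- function(pool) {
  stopifnot(is(pool, "GlycanPool"))
  keys <- names(pool@glycans)
  nGlc <- sum(pool@counts[keys == "Glc"])
  nLam2 <- sum(pool@counts[keys == "Glc(b1-3)Glc"])
  if (nLam2 == 0)
    stop("undefined ratio: the pool contains no laminaribiose")
  nGlc / nLam2
}

#' Molar glucose : branched-residual ratio of a product pool
#'
#' Ratio of free glucose to exo-resistant branched residual molecules, the
#' statistic used to compare how strongly 1,6 branching protects a substrate
#' from exo digestion (laminarin versus the hybrid octamer).
#'
#' @param pool a [GlycanPool-class] of digestion products
#' @return numeric ratio
#' @export
glcBranchedRatio <- function(pool) {
  stopifnot(is(pool, "GlycanPool"))
  keys <- names(pool@glycans)
  nGlc <- sum(pool@counts[keys == "Glc"])
  branched <- vapply(pool@glycans, isBranched, logical(1))
  nBr <- sum(pool@counts[branched])
  if (nBr == 0)
    stop("undefined ratio: the pool contains no branched residuals")
  nGlc / nBr
}
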