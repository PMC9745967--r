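# Core tree operations on Glycan objects. Trees are tiny (DP <= a few tens),
# so everything is plain data.frame bookkeeping; no graph library is needed.

.newGlycan <- function(residues, bonds, root) {
  g <- new("Glycan",
           residues = data.frame(id = as.integer(residues$id),
                                 kind = as.character(residues$kind),
                                 stringsAsFactors = FALSE),
           bonds = data.frame(child = as.integer(bonds$child),
                              parent = as.integer(bonds$parent),
                              pos = as.integer(bonds$pos),
                              stringsAsFactors = FALSE),
           root = as.integer(root))
  validObject(g)
  g
}

.emptyBonds <- function()
  data.frame(child = integer(), parent = integer(), pos = integer())

# children of `id`, as a data.frame of (child, pos)
.childrenOf <- function(g, id) {
  b <- g@bonds
  b[b$parent == id, , drop = FALSE]
}

.parentBondOf <- function(g, id) {
  b <- g@bonds
  b[b$child == id, , drop = FALSE]
}

.kindOf <- function(g, id) g@residues$kind[match(id, g@residues$id)]

.hasChildAt <- function(g, id, pos) {
  b <- g@bonds
  any(b$parent == id & b$pos == pos)
}

.isLeaf <- function(g, id) !any(g@bonds$parent == id)

# canonical serialization; subtrees at a residue ordered by
# (acceptor position, canonical subtree string), first subtree written
# inline, the rest bracketed immediately before the parent token
.canonSub <- function(g, id) {
  kids <- .childrenOf(g, id)
  if (!nrow(kids)) return("Glc")
  sub <- vapply(kids$child, function(ch) .canonSub(g, ch), character(1))
  o <- order(kids$pos, sub)
  kids <- kids[o, , drop = FALSE]
  sub <- sub[o]
  inline <- paste0(sub[1L], "(b1-", kids$pos[1L], ")")
  brackets <- if (nrow(kids) > 1L) {
    paste0("[", sub[-1L], "(b1-", kids$pos[-1L], ")]", collapse = "")
  } else ""
  paste0(inline, brackets, "Glc")
}

.canonString <- function(g) {
  s <- .canonSub(g, g@root)
  if (.kindOf(g, g@root) == "Glc-ol") s <- paste0(s, "-ol") else s
}

#' @describeIn glucanSim-generics degree of polymerization (residue count)
setMethod("glycanDP", "Glycan", function(x) nrow(x@residues))

#' @describeIn glucanSim-generics \code{TRUE} if the root is glucitol
setMethod("isReduced", "Glycan",
  function(x) .kindOf(x, x@root) == "Glc-ol")

#' @describeIn glucanSim-generics \code{TRUE} if the glycan carries at least
#'   one 1,6 bond
setMethod("isBranched", "Glycan", function(x) any(x@bonds$pos == 6L))

#' @describeIn glucanSim-generics canonical condensed string (see
#'   [parseGlycan()] for the dialect); equal structures serialize identically
setMethod("glycanToString", "Glycan", function(x) .canonString(x))

setMethod("show", "Glycan", function(object) {
  cat(sprintf("Glycan: DP %d, %s, %s\n  %s\n",
              glycanDP(object),
              if (isReduced(object)) "reduced end" else "reducing end",
              if (isBranched(object)) "branched" else "linear",
              .canonString(object)))
})

#' Structural equality of glycans
#'
#' Two glycans are equal when their canonical serializations coincide, i.e.
#' they are the same tree up to residue renumbering and branch-order
#' permutation.
#'
#' @param a,b [Glycan-class] objects
#' @return logical
#' @export
glycanIdentical <- function(a, b) {
  identical(.canonString(a), .canonString(b))
}

#' Build a linear 1,3-beta-glucan chain
#'
#' @param n integer DP (>= 1)
#' @param reduced if \code{TRUE} the root (reducing-end residue) is a
#'   borohydride-reduced glucitol, as in the LAMnol standards
#' @return a [Glycan-class]
#' @examples
#' makeLinear(5)             # laminaripentaose (LAM5)
#' makeLinear(5, reduced = TRUE)  # LAM5ol
#' @export
makeLinear <- function(n, reduced = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("DP must be an integer >= 1")
  kinds <- rep("Glc", n)
  if (reduced) kinds[n] <- "Glc-ol"
  bonds <- if (n > 1L) {
    data.frame(child = seq_len(n - 1L), parent = seq_len(n - 1L) + 1L,
               pos = rep(3L, n - 1L))
  } else .emptyBonds()
  .newGlycan(data.frame(id = seq_len(n), kind = kinds), bonds, n)
}

# ids along the main chain (root-first), following O3 children from the root
.mainChain <- function(g) {
  out <- g@root
  cur <- g@root
  repeat {
    b <- g@bonds
    ch <- b$child[b$parent == cur & b$pos == 3L]
    if (!length(ch)) break
    cur <- ch[1L]
    out <- c(out, cur)
  }
  out
}

# attach a linear 1,3 chain of `branchDP` residues to O6 of residue `at`;
# the chain's reducing-end C1 forms the new bond
.attachBranch <- function(g, at, branchDP) {
  branchDP <- as.integer(branchDP)
  if (branchDP < 1L) stop("branch DP must be >= 1")
  if (.hasChildAt(g, at, 6L))
    stop("O6 of residue ", at, " already carries a substituent")
  base <- max(g@residues$id)
  ids <- base + seq_len(branchDP)
  res <- rbind(g@residues, data.frame(id = ids, kind = rep("Glc", branchDP)))
  nb <- if (branchDP > 1L) {
    data.frame(child = ids[-branchDP], parent = ids[-1L],
               pos = rep(3L, branchDP - 1L))
  } else .emptyBonds()
  nb <- rbind(nb, data.frame(child = ids[branchDP], parent = at, pos = 6L))
  .newGlycan(res, rbind(g@bonds, nb), g@root)
}

# drop a leaf residue (and its bond); errors if not a leaf
.removeLeaf <- function(g, id) {
  if (!.isLeaf(g, id)) stop("residue ", id, " is not a leaf")
  if (id == g@root) stop("cannot remove the root")
  .newGlycan(g@residues[g@residues$id != id, , drop = FALSE],
             g@bonds[g@bonds$child != id, , drop = FALSE],
             g@root)
}

#' Enumerate branched hybrid isomers
#'
#' Attaches a linear 1,3-linked branch of \code{branchDP} residues through a
#' single 1,6-beta bond to a linear 1,3 backbone of \code{backboneDP}
#' residues, and returns the distinct structures (canonical-form
#' deduplication). Under \code{model = "reducing_side"} the attachment is
#' restricted to the three backbone positions nearest the reducing end --
#' the reading of the published reaction scheme under which exhaustive exo
#' digestion of the octamer can release three glucose units; under
#' \code{model = "all_O6"} every backbone O6 is allowed (5 structures for
#' the 5+3 case).
#'
#' @param backboneDP integer backbone DP
#' @param branchDP integer branch DP (0 returns the bare backbone)
#' @param model \code{"reducing_side"} or \code{"all_O6"}
#' @return list of [Glycan-class] objects
#' @examples
#' length(enumerateHybridIsomers(5, 3, "reducing_side"))  # 3
#' length(enumerateHybridIsomers(5, 3, "all_O6"))   # 5
#' @export
enumerateHybridIsomers <- function(backboneDP, branchDP,
                                   model = c("reducing_side", "all_O6")) {
  model <- match.arg(model)
  backboneDP <- as.integer(backboneDP)
  branchDP <- as.integer(branchDP)
  if (branchDP > backboneDP)
    stop("branch DP must not exceed backbone DP")
  if (branchDP < 0L) stop("branch DP must be >= 0")
  backbone <- makeLinear(backboneDP)
  if (branchDP == 0L) return(list(backbone))
  chain <- .mainChain(backbone)             # root-first
  at <- if (model == "reducing_side") chain[seq_len(min(3L, length(chain)))] else chain
  out <- lapply(at, function(a) .attachBranch(backbone, a, branchDP))
  keys <- vapply(out, .canonString, character(1))
  out[!duplicated(keys)]
}

# backbone position (1 = reducing end) of residue id, NA if off-backbone
.backbonePosition <- function(g, id) {
  match(id, .mainChain(g))
}
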