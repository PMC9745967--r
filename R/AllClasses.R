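#' Glycan: a rooted tree of glucose residues
#'
#' A linear or branched gluco-oligosaccharide modelled as a rooted tree.
#' Residues are glucosyl units (\code{"Glc"}) or, only at the root, a
#' borohydride-reduced glucitol (\code{"Glc-ol"}). Every non-root residue is
#' joined through its C1 to the O3 or O6 of its parent; the root carries the
#' (free or reduced) anomeric carbon, i.e. the reducing end. Anomeric
#' configuration is uniformly beta and not modelled further.
#'
#' @slot residues data.frame with columns \code{id} (integer, unique) and
#'   \code{kind} (\code{"Glc"} or \code{"Glc-ol"}).
#' @slot bonds data.frame with columns \code{child}, \code{parent} (residue
#'   ids) and \code{pos} (acceptor position, 3 or 6); the bond runs from the
#'   child C1 to the parent O-position.
#' @slot root integer id of the root residue.
#'
#' @seealso [parseGlycan()], [makeLinear()], [glycanToString()]
#' @examples
#' lam3 <- makeLinear(3)
#' glycanDP(lam3)
#' glycanToString(lam3)
#' @export
setClass("Glycan",
  slots = c(residues = "data.frame", bonds = "data.frame", root = "integer"))

setValidity("Glycan", function(object) {
  res <- object@residues
  b <- object@bonds
  msg <- character()
  if (nrow(res) < 1L)
    return("a glycan must contain at least one residue")
  if (!all(c("id", "kind") %in% names(res)))
    return("residues must have columns 'id' and 'kind'")
  if (!all(c("child", "parent", "pos") %in% names(b)))
    return("bonds must have columns 'child', 'parent' and 'pos'")
  if (anyDuplicated(res$id))
    msg <- c(msg, "residue ids must be unique")
  if (!all(res$kind %in% c("Glc", "Glc-ol")))
    msg <- c(msg, "residue kind must be 'Glc' or 'Glc-ol'")
  if (length(object@root) != 1L || !object@root %in% res$id)
    msg <- c(msg, "root must reference exactly one residue")
  bad.red <- res$id[res$kind == "Glc-ol"]
  if (length(bad.red) && !identical(bad.red, object@root))
    msg <- c(msg, "glucitol may occur only at the root")
  if (nrow(b) != nrow(res) - 1L)
    msg <- c(msg, "a tree of n residues must have n - 1 bonds")
  if (nrow(b)) {
    if (!all(b$pos %in% c(3L, 6L)))
      msg <- c(msg, "acceptor position must be 3 or 6")
    if (!all(b$child %in% res$id) || !all(b$parent %in% res$id))
      msg <- c(msg, "bonds must reference existing residues")
    if (anyDuplicated(b$child))
      msg <- c(msg, "every residue may have at most one parent")
    if (object@root %in% b$child)
      msg <- c(msg, "the root must not have a parent")
    if (anyDuplicated(paste(b$parent, b$pos)))
      msg <- c(msg, "at most one substituent per O-position")
  }
  if (!length(msg)) {
    # acyclicity/connectedness: every residue must reach the root
    parent.of <- setNames(b$parent, b$child)
    for (id in res$id) {
      seen <- 0L
      cur <- id
      while (cur != object@root) {
        nxt <- parent.of[as.character(cur)]
        if (is.na(nxt) || (seen <- seen + 1L) > nrow(res)) {
          msg <- c(msg, "residues and bonds do not form a single rooted tree")
          break
        }
        cur <- nxt
      }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' GlycanPool: a multiset of glycans with per-species amounts
#'
#' Product pools hold one entry per distinct structure (canonical-form
#' equality) together with a molecule count. Counts are interpreted as molar
#' amounts on an arbitrary scale (one count = one molecule, or one nanomole,
#' depending on context).
#'
#' @slot glycans list of [Glycan-class] objects, named by canonical string.
#' @slot counts numeric vector of non-negative amounts, parallel to
#'   \code{glycans}.
#'
#' @seealso [glycanPool()], [poolCounts()], [exoDigest()]
#' @export
setClass("GlycanPool",
  slots = c(glycans = "list", counts = "numeric"))

setValidity("GlycanPool", function(object) {
  msg <- character()
  if (length(object@glycans) != length(object@counts))
    msg <- c(msg, "glycans and counts must have the same length")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!all(vapply(object@glycans, is, logical(1), "Glycan")))
    msg <- c(msg, "all pool members must be Glycan objects")
  nm <- names(object@glycans)
  if (length(object@glycans) && (is.null(nm) || anyDuplicated(nm)))
    msg <- c(msg, "pool members must be uniquely named by canonical string")
  if (length(msg)) msg else TRUE
})

#' DigestResult: outcome of an exo-glucanase digestion
#'
#' @slot products [GlycanPool-class] of all product molecules, including the
#'   released glucose.
#' @slot trajectory data.frame recording each hydrolytic step: \code{step},
#'   \code{intermediate} (canonical string after the step) and
#'   \code{released}.
#' @slot nCleavages integer number of glycosidic bonds hydrolysed.
#' @slot substrate the digested [Glycan-class].
#' @slot mode \code{"rules"} or \code{"scheme"}.
#'
#' @seealso [exoDigest()], [glcLam2Ratio()]
#' @export
setClass("DigestResult",
  slots = c(products = "GlycanPool", trajectory = "data.frame",
            nCleavages = "integer", substrate = "Glycan", mode = "character"))

#' TransferEvent: one transglucanase cleave-and-transfer step
#'
#' @slot donor donor [Glycan-class] (linear, DP >= the donor threshold).
#' @slot acceptor acceptor [Glycan-class].
#' @slot released the released laminaribiose ([Glycan-class], always linear
#'   DP 2).
#' @slot product the branched hybrid product ([Glycan-class]).
#' @slot attachmentPosition integer backbone position of the new 1,6 bond,
#'   counted from the reducing end (1 = the reducing-end residue).
#'
#' @seealso [transglycosylate()]
#' @export
setClass("TransferEvent",
  slots = c(donor = "Glycan", acceptor = "Glycan", released = "Glycan",
            product = "Glycan", attachmentPosition = "integer"))

setValidity("TransferEvent", function(object) {
  msg <- character()
  if (glycanDP(object@released) != 2L)
    msg <- c(msg, "the released fragment must be a disaccharide")
  if (glycanDP(object@donor) + glycanDP(object@acceptor) !=
      glycanDP(object@released) + glycanDP(object@product))
    msg <- c(msg, "residues must be conserved across the transfer")
  if (length(msg)) msg else TRUE
})

#' ReactionResult: pool and event log of a transglucanase batch reaction
#'
#' @slot pool final [GlycanPool-class] after all rounds.
#' @slot events data.frame event log with columns \code{round}, \code{donor},
#'   \code{acceptor}, \code{released}, \code{product} (canonical strings) and
#'   \code{attachment} (backbone position from the reducing end).
#' @slot config the [reactionConfig()] list used.
#'
#' @seealso [reactBatch()]
#' @export
setClass("ReactionResult",
  slots = c(pool = "GlycanPool", events = "data.frame", config = "list"))
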