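# Parser for the condensed glycan dialect:
#   - residue tokens run right-to-left toward the root: "Glc(b1-3)Glc"
#   - branches sit in square brackets immediately before their parent
#     residue, carrying their linkage inside the bracket:
#     "Glc(b1-3)Glc(b1-3)[Glc(b1-6)]Glc"
#   - an "-ol" suffix on the whole string marks a reduced (glucitol) root
# Aliases LAM2..LAM20, LAM2ol..LAM20ol, GLC/Glc and H8..H16 expand
# deterministically before parsing.

.TOKEN.RE <- "^(Glc|\\(b1-3\\)|\\(b1-6\\)|\\[|\\])"

.tokenize <- function(text) {
  s <- text
  toks <- character()
  while (nchar(s)) {
    m <- regmatches(s, regexpr(.TOKEN.RE, s))
    if (!length(m))
      stop("glycan parse error: unexpected token at \"",
           substr(s, 1L, 12L), "\"")
    toks <- c(toks, m)
    s <- substr(s, nchar(m) + 1L, nchar(s))
  }
  toks
}

# recursive-descent chain parser; `env` accumulates residues/bonds
.parseChain <- function(toks, i, inBracket, env) {
  pending <- list()   # subtrees (id, pos) awaiting their parent residue
  repeat {
    if (i > length(toks)) {
      if (inBracket) stop("glycan parse error: unterminated '['")
      stop("glycan parse error: unexpected end of string")
    }
    t <- toks[i]
    if (t == "[") {
      r <- .parseChain(toks, i + 1L, TRUE, env)
      pending[[length(pending) + 1L]] <- list(id = r$id, pos = r$pos)
      i <- r$nexti
      if (i > length(toks) || toks[i] != "]")
        stop("glycan parse error: expected ']'")
      i <- i + 1L
    } else if (t == "Glc") {
      env$nid <- env$nid + 1L
      id <- env$nid
      env$kind[[as.character(id)]] <- "Glc"
      for (p in pending) {
        key <- paste(id, p$pos)
        if (key %in% env$taken)
          stop("glycan validity error: two substituents at O", p$pos,
               " of one residue")
        env$taken <- c(env$taken, key)
        env$bonds[[length(env$bonds) + 1L]] <-
          c(child = p$id, parent = id, pos = p$pos)
      }
      pending <- list()
      i <- i + 1L
      nxt <- if (i <= length(toks)) toks[i] else ""
      if (nxt %in% c("(b1-3)", "(b1-6)")) {
        pos <- if (nxt == "(b1-3)") 3L else 6L
        i <- i + 1L
        after <- if (i <= length(toks)) toks[i] else ""
        if (inBracket && after == "]")
          return(list(id = id, pos = pos, nexti = i))
        pending[[length(pending) + 1L]] <- list(id = id, pos = pos)
      } else if (nxt == "]") {
        stop("glycan parse error: bracketed branch lacks its linkage")
      } else if (nxt == "") {
        if (inBracket) stop("glycan parse error: unterminated '['")
        return(list(id = id, pos = NA_integer_, nexti = i))
      } else {
        stop("glycan parse error: unexpected token \"", nxt, "\"")
      }
    } else {
      stop("glycan parse error: unexpected token \"", t, "\"")
    }
  }
}

.expandAlias <- function(text) {
  if (grepl("^(GLC|Glc)$", text)) return(makeLinear(1L))
  m <- regmatches(text, regexec("^LAM([0-9]+)(ol)?$", text))[[1]]
  if (length(m)) {
    n <- as.integer(m[2])
    if (n < 1L || n > 20L)
      stop("glycan parse error: alias DP out of range in \"", text, "\"")
    if (nzchar(m[3]) && n < 2L)
      stop("glycan parse error: reduced alias needs DP >= 2")
    return(makeLinear(n, reduced = nzchar(m[3])))
  }
  m <- regmatches(text, regexec("^H([0-9]+)$", text))[[1]]
  if (length(m)) {
    n <- as.integer(m[2])
    if (n < 8L || n > 16L)
      stop("glycan parse error: hybrid alias H", m[2],
           " outside the supported range H8..H16")
    return(.makeHybridAlias(n))
  }
  NULL
}

# Hn: backbone LAMb (b in 5..7, b == n mod 3) plus (n - b)/3 trisaccharide
# branches placed at the default attachment positions, mirroring iterated
# transglucanase transfers onto the same acceptor
.makeHybridAlias <- function(n) {
  base <- 5L + (n - 8L) %% 3L
  k <- (n - base) %/% 3L
  g <- makeLinear(base)
  for (i in seq_len(k)) g <- .attachBranch(g, .defaultAttachment(g), 3L)
  g
}

# default 1,6 attachment site: the backbone residue with a free O6 nearest
# the reducing end (see the methods vignette for why reducing-side
# attachment is the structurally consistent default)
.defaultAttachment <- function(g) {
  chain <- .mainChain(g)
  free <- chain[!vapply(chain, function(id) .hasChildAt(g, id, 6L), logical(1))]
  if (!length(free)) stop("no free backbone O6 available for attachment")
  free[1L]
}

#' Parse a glycan string or alias
#'
#' Accepts the condensed dialect (residues written right-to-left toward the
#' root, branches in square brackets immediately before their parent, an
#' \code{"-ol"} suffix marking a reduced root) or one of the registered
#' aliases: \code{GLC}/\code{Glc}, \code{LAM2}..\code{LAM20},
#' \code{LAM2ol}..\code{LAM20ol} and the hybrid series \code{H8}..\code{H16}.
#'
#' @param text character scalar
#' @return a validated [Glycan-class]
#' @examples
#' parseGlycan("LAM5ol")
#' parseGlycan("Glc(b1-6)Glc(b1-3)Glc")
#' parseGlycan("Glc(b1-3)Glc(b1-3)[Glc(b1-3)Glc(b1-3)Glc(b1-6)]Glc")
#' @seealso [glycanToString()], [makeLinear()]
#' @export
parseGlycan <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  ali <- .expandAlias(text)
  if (!is.null(ali)) return(ali)
  reduced <- grepl("-ol$", text)
  body <- sub("-ol$", "", text)
  if (!nchar(body)) stop("glycan parse error: empty string")
  toks <- .tokenize(body)
  env <- new.env(parent = emptyenv())
  env$nid <- 0L
  env$kind <- list()
  env$bonds <- list()
  env$taken <- character()
  r <- .parseChain(toks, 1L, FALSE, env)
  root <- r$id
  kinds <- vapply(as.character(seq_len(env$nid)),
                  function(k) env$kind[[k]], character(1))
  if (reduced) kinds[root] <- "Glc-ol"
  bonds <- if (length(env$bonds)) {
    as.data.frame(do.call(rbind, env$bonds))
  } else .emptyBonds()
  .newGlycan(data.frame(id = seq_len(env$nid), kind = kinds), bonds, root)
}

#' Human-readable species label
#'
#' Names a glycan the way the field labels chromatographic/MS species:
#' \code{"Glc"} for glucose, \code{"LAMn"} / \code{"LAMnol"} for linear
#' (reduced) laminarioligomers, \code{"Hn"} for 1,6-branched hybrids and
#' \code{"X"} for the exo-resistant branched trisaccharide by-product.
#'
#' @param g a [Glycan-class]
#' @return character scalar
#' @examples
#' speciesLabel(parseGlycan("LAM5"))
#' speciesLabel(parseGlycan("H8"))
#' @export
speciesLabel <- function(g) {
  dp <- glycanDP(g)
  if (isBranched(g)) {
    if (dp == 3L) "X" else paste0("H", dp)
  } else if (isReduced(g)) {
    paste0("LAM", dp, "ol")
  } else if (dp == 1L) "Glc" else paste0("LAM", dp)
}
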