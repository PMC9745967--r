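# Independent oracles used by the property tests. These deliberately avoid
# the package's tree machinery: linear chains are plain character vectors,
# canonical forms are sorted nested-parenthesis encodings.

# brute-force digestion of a linear chain written as a symbol vector from
# the non-reducing end: "G" = glucosyl, "Gol" = glucitol
linearDigestOracle <- function(n, reduced = FALSE, minRun = 3) {
  chain <- c(rep("G", n - as.integer(reduced)), if (reduced) "Gol")
  glc <- 0
  repeat {
    lead <- 0
    for (s in chain) {
      if (s != "G") break
      lead <- lead + 1
    }
    if (lead < minRun) break
    chain <- chain[-1]
    glc <- glc + 1
  }
  list(glc = glc, residualDP = length(chain), residualReduced = reduced)
}

# independent canonical encoding of a Glycan: sorted nested parentheses over
# (pos, subtree); no reliance on the package's serializer
canonOracle <- function(g) {
  enc <- function(id) {
    b <- g@bonds
    kids <- b[b$parent == id, , drop = FALSE]
    kind <- g@residues$kind[match(id, g@residues$id)]
    if (!nrow(kids)) return(paste0("(", kind, ")"))
    parts <- sort(vapply(seq_len(nrow(kids)), function(i)
      paste0(kids$pos[i], enc(kids$child[i])), character(1)))
    paste0("(", kind, paste(parts, collapse = ""), ")")
  }
  enc(g@root)
}

# signature of a product pool: sorted "count x canonical string"
poolSignature <- function(pool) {
  keys <- names(glucanSim::poolGlycans(pool))
  counts <- pool@counts
  paste(sort(paste(counts, keys, sep = " x ")), collapse = "; ")
}

# explore every possible order of removable-terminus choices and collect
# the distinct final product multisets
allOrderDigestOracle <- function(g, rules = exoRules()) {
  seen <- new.env(parent = emptyenv())
  finals <- new.env(parent = emptyenv())
  recurse <- function(cur, glc) {
    key <- paste(glycanToString(cur), glc)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    rem <- removableTermini(cur, rules)
    if (!length(rem)) {
      sig <- paste(glc, "Glc +", glycanToString(cur))
      finals[[sig]] <- TRUE
      return(invisible())
    }
    for (id in rem) {
      nxt <- glucanSim:::.removeLeaf(cur, id)
      recurse(nxt, glc + 1L)
    }
  }
  recurse(g, 0L)
  ls(finals)
}

# TRUE if any 3-subset of mz values is arithmetic with the given spacing
# within tol (exhaustive check; used to certify negative controls)
anyArithmeticTriple <- function(mz, spacing, tol) {
  mz <- sort(mz)
  n <- length(mz)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k &&
        abs(mz[j] - mz[i] - spacing) <= tol &&
        abs(mz[k] - mz[j] - spacing) <= tol) return(TRUE)
  }
  FALSE
}

# random glycan with reproducible draw inside the caller's seed scope
randomGlycans <- function(n, maxDP, ...) {
  lapply(seq_len(n), function(i) genRandomGlycan(sample(1:maxDP, 1), ...))
}
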