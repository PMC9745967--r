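# GlycanPool construction and accessors.

#' Build a glycan pool
#'
#' @param x either a named numeric vector of counts (names are glycan strings
#'   or aliases, e.g. \code{c(LAM5 = 2)}), or a list of [Glycan-class]
#'   objects (with \code{counts})
#' @param counts amounts parallel to \code{x} when \code{x} is a list
#'   (default 1 each)
#' @return a [GlycanPool-class]; duplicate structures are merged by
#'   canonical-form equality
#' @examples
#' p <- glycanPool(c(LAM5 = 2))
#' poolCounts(p)
#' @export
glycanPool <- function(x, counts = NULL) {
  if (is.numeric(x) && !is.null(names(x))) {
    glycans <- lapply(names(x), parseGlycan)
    counts <- unname(x)
  } else if (is.list(x)) {
    glycans <- x
    if (is.null(counts)) counts <- rep(1, length(x))
  } else if (is(x, "Glycan")) {
    glycans <- list(x)
    if (is.null(counts)) counts <- 1
  } else {
    stop("x must be a named count vector, a Glycan, or a list of Glycans")
  }
  keys <- vapply(glycans, .canonString, character(1))
  agg <- tapply(counts, keys, sum)
  uniq <- glycans[!duplicated(keys)]
  names(uniq) <- keys[!duplicated(keys)]
  uniq <- uniq[names(agg)]
  new("GlycanPool", glycans = uniq, counts = as.numeric(agg))
}

.emptyPool <- function() new("GlycanPool", glycans = list(), counts = numeric())

.poolAdd <- function(pool, glycan, count = 1) {
  key <- .canonString(glycan)
  i <- match(key, names(pool@glycans))
  if (is.na(i)) {
    pool@glycans[[key]] <- glycan
    pool@counts <- c(pool@counts, count)
  } else {
    pool@counts[i] <- pool@counts[i] + count
  }
  pool
}

.poolRemove <- function(pool, glycan, count = 1) {
  key <- .canonString(glycan)
  i <- match(key, names(pool@glycans))
  if (is.na(i) || pool@counts[i] < count)
    stop("pool does not contain ", count, " x ", key)
  pool@counts[i] <- pool@counts[i] - count
  if (pool@counts[i] == 0) {
    pool@glycans[[key]] <- NULL
    pool@counts <- pool@counts[-i]
  }
  pool
}

.poolMerge <- function(a, b, bScale = 1) {
  for (i in seq_along(b@glycans))
    a <- .poolAdd(a, b@glycans[[i]], b@counts[i] * bScale)
  a
}

#' @rdname glycanPool
#' @param pool a [GlycanPool-class]
#' @return \code{poolCounts}: named numeric vector of amounts, named by
#'   species label (see [speciesLabel()])
#' @export
poolCounts <- function(pool) {
  stopifnot(is(pool, "GlycanPool"))
  setNames(pool@counts,
           vapply(pool@glycans, speciesLabel, character(1)))
}

#' @rdname glycanPool
#' @return \code{poolGlycans}: list of [Glycan-class] members, named by
#'   canonical string
#' @export
poolGlycans <- function(pool) pool@glycans

#' @rdname glycanPool
#' @return \code{poolTotalResidues}: total anhydroglucose residues,
#'   \eqn{\sum count_i \times DP_i}
#' @export
poolTotalResidues <- function(pool) {
  if (!length(pool@glycans)) return(0)
  sum(pool@counts * vapply(pool@glycans, glycanDP, integer(1)))
}

setMethod("show", "GlycanPool", function(object) {
  cat(sprintf("GlycanPool with %d species (%g molecules)\n",
              length(object@glycans), sum(object@counts)))
  if (length(object@glycans)) {
    lab <- vapply(object@glycans, speciesLabel, character(1))
    dp <- vapply(object@glycans, glycanDP, integer(1))
    df <- data.frame(species = lab, dp = dp, count = object@counts,
                     row.names = NULL)
    print(df[order(-df$count, df$dp), ], row.names = FALSE)
  }
})
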