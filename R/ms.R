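# MALDI-style [M+Na]+ peak prediction and +DP3 arithmetic-series detection.
# Peak lists here are tens of peaks, so series detection is an exact
# exhaustive search, not a heuristic.

.DP3.SPACING <- 3 * 162.0528   # 486.1584 Da, three anhydrohexose units

#' Predict the [M+Na]+ peak list of a pool
#'
#' One singly sodiated monoisotopic peak per distinct DP/reduction state
#' (isomers are isobaric and merge); intensities are proportional to pool
#' abundance. Annotations use the field's species labels; an isobaric
#' mixture of branched and linear species of the same DP is annotated
#' \code{"DPn"}.
#'
#' @param pool a [GlycanPool-class]
#' @return data.frame with columns \code{mz}, \code{intensity},
#'   \code{annotation}, \code{dp}, \code{reduced}, sorted by m/z
#' @examples
#' predictPeaks(glycanPool(c(H8 = 1)))  # one peak at 1337.42
#' @export
predictPeaks <- function(pool) {
  stopifnot(is(pool, "GlycanPool"))
  if (!length(pool@glycans))
    return(data.frame(mz = numeric(), intensity = numeric(),
                      annotation = character(), dp = integer(),
                      reduced = logical()))
  dp <- vapply(pool@glycans, glycanDP, integer(1))
  red <- vapply(pool@glycans, isReduced, logical(1))
  br <- vapply(pool@glycans, isBranched, logical(1))
  key <- paste(dp, red)
  out <- lapply(unique(key), function(k) {
    i <- which(key == k)
    lab <- if (all(br[i])) {
      speciesLabel(pool@glycans[[i[1]]])
    } else if (any(br[i])) {
      paste0("DP", dp[i[1]])
    } else {
      speciesLabel(pool@glycans[[i[1]]])
    }
    data.frame(mz = .dpMz(dp[i[1]], red[i[1]]),
               intensity = sum(pool@counts[i]),
               annotation = lab, dp = dp[i[1]], reduced = red[i[1]])
  })
  out <- do.call(rbind, out)
  out[order(out$mz), , drop = FALSE]
}

#' Detect +DP3 arithmetic series in a peak list
#'
#' Finds all maximal chains of peaks whose consecutive spacings equal three
#' anhydrohexose units (486.16 Da) within \code{tol}. A chain needs at least
#' three member peaks: a single ~486 Da gap between two random peaks is a
#' coincidence, two consecutive gaps establish a series. Detection is
#' invariant to peak order and intensity scaling. Each series is mapped back
#' to a starting DP via the nearest hexose-oligomer [M+Na]+ mass.
#'
#' @param peaks data.frame with at least an \code{mz} column
#' @param tol matching tolerance in Da (default 0.5, the external-calibration
#'   scale of linear MALDI-TOF)
#' @param minMembers minimum chain length (default 3)
#' @return data.frame with one row per series: \code{start_dp},
#'   \code{n_members}, \code{spacing} (mean observed) and a list column
#'   \code{members} of member m/z values
#' @examples
#' pk <- predictPeaks(glycanPool(c(LAM5 = 4, H8 = 3, H11 = 2, H14 = 1)))
#' detectDP3Series(pk)
#' @export
detectDP3Series <- function(peaks, tol = 0.5, minMembers = 3L) {
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks), tol > 0)
  mz <- sort(unique(peaks$mz))
  n <- length(mz)
  if (n < minMembers)
    return(data.frame(start_dp = integer(), n_members = integer(),
                      spacing = numeric(),
                      members = I(list())))
  succ <- lapply(seq_len(n), function(i)
    which(abs(mz - mz[i] - .DP3.SPACING) <= tol))
  hasPred <- rep(FALSE, n)
  for (s in succ) hasPred[s] <- TRUE
  chains <- list()
  walk <- function(path) {
    nxt <- succ[[path[length(path)]]]
    if (!length(nxt)) {
      chains[[length(chains) + 1L]] <<- path
    } else {
      for (j in nxt) walk(c(path, j))
    }
  }
  for (i in which(!hasPred)) walk(i)
  chains <- Filter(function(p) length(p) >= minMembers, chains)
  if (!length(chains))
    return(data.frame(start_dp = integer(), n_members = integer(),
                      spacing = numeric(),
                      members = I(list())))
  rows <- lapply(chains, function(p) {
    m <- mz[p]
    data.frame(start_dp = .dpFromMz(m[1]),
               n_members = length(m),
               spacing = mean(diff(m)),
               members = I(list(m)))
  })
  do.call(rbind, rows)
}

#' Read/write peak lists
#'
#' Tab-separated peak lists with columns \code{mz}, \code{intensity} and an
#' optional \code{annotation} column.
#'
#' @param path file path
#' @param peaks data.frame to write
#' @return \code{readPeakList}: the data.frame
#' @export
readPeakList <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readPeakList
#' @export
writePeakList <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
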