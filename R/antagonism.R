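# End-to-end experiment driver: transglucanase pretreatment followed by exo
# digestion, with side-by-side quantification of treated and untreated arms.

#' Run the two-enzyme antagonism experiment
#'
#' Executes the headline in-silico experiment: the substrate pool is (i)
#' digested directly with the exo-glucanase (untreated arm) and (ii) first
#' pretreated with the transglucanase (one transfer event per two donor
#' molecules, largest-acceptor policy) and then digested (treated arm).
#' Both arms are quantified and the glucose : laminaribiose molar ratios and
#' the percent reduction in released glucose are reported. For 2 x LAM5 the
#' scheme mode yields ratios 3.0 (untreated) and 1.5 (treated). In rules
#' mode the strictly exo-acting engine leaves a single branched pentamer
#' residual instead of the scheme's separate laminaribiose + branched
#' trisaccharide; the discrepancy is surfaced in \code{notes}, never
#' silently resolved.
#'
#' @param pool starting [GlycanPool-class] (typically \code{c(LAM5 = 2)})
#' @param mode \code{"scheme"} or \code{"rules"} digestion of branched
#'   hybrids (see [exoRules()])
#' @param config optional [reactionConfig()] overriding the pretreatment
#'   (its \code{rounds} is recomputed from the pool)
#' @return object of class \code{antagonismReport}: a list with elements
#'   \code{mode}, \code{untreatedProducts}, \code{treatedProducts},
#'   \code{untreatedTable}, \code{treatedTable}, \code{ratioUntreated},
#'   \code{ratioTreated}, \code{glcReductionPct}, \code{events},
#'   \code{notes} and \code{provenance}
#' @examples
#' rep <- runAntagonismExperiment(glycanPool(c(LAM5 = 2)), mode = "scheme")
#' rep$ratioTreated    # 1.5
#' rep$ratioUntreated  # 3.0
#' @export
runAntagonismExperiment <- function(pool, mode = c("scheme", "rules"),
                              config = reactionConfig()) {
  mode <- match.arg(mode)
  stopifnot(is(pool, "GlycanPool"))

  untreated <- exoDigest(pool, exoRules(schemeMode = FALSE))

  nDonors <- sum(pool@counts[vapply(pool@glycans, isDonorSubstrate,
                                    logical(1), config)])
  events <- data.frame()
  treatedPool <- pool
  if (nDonors >= 2) {
    config$rounds <- as.integer(nDonors %/% 2)
    reacted <- reactBatch(pool, config)
    treatedPool <- reacted@pool
    events <- reacted@events
  }
  treated <- exoDigest(treatedPool, exoRules(schemeMode = mode == "scheme"))

  notes <- character()
  if (mode == "rules") {
    resid <- vapply(treated@glycans, function(g)
      isBranched(g) && glycanDP(g) > 3L, logical(1))
    if (any(resid))
      notes <- c(notes, paste0(
        "scheme-discrepancy: strict exo rules leave residual(s) ",
        paste(names(treated@glycans)[resid], collapse = ", "),
        " instead of the scheme's separate LAM2 + branched trisaccharide"))
  }

  ratioU <- tryCatch(glcLam2Ratio(untreated), error = function(e) NA_real_)
  ratioT <- tryCatch(glcLam2Ratio(treated), error = function(e) NA_real_)
  cntU <- poolCounts(untreated)
  cntT <- poolCounts(treated)
  glcU <- sum(cntU[names(cntU) == "Glc"])
  glcT <- sum(cntT[names(cntT) == "Glc"])
  redPct <- if (glcU > 0) percentReduction(glcU, glcT) else NA_real_

  structure(list(
    mode = mode,
    untreatedProducts = untreated,
    treatedProducts = treated,
    untreatedTable = quantifyPool(untreated),
    treatedTable = quantifyPool(treated),
    ratioUntreated = ratioU,
    ratioTreated = ratioT,
    glcReductionPct = redPct,
    events = events,
    notes = notes,
    provenance = list(package = "glucanSim",
                      version = as.character(packageVersion("glucanSim")),
                      mode = mode, config = unclass(config),
                      date = format(Sys.time(), "%Y-%m-%d"))),
    class = "antagonismReport")
}

#' @export
print.antagonismReport <- function(x, ...) {
  cat(sprintf("Two-enzyme antagonism experiment (%s mode)\n", x$mode))
  cat(sprintf("  transfer events: %d\n", nrow(x$events)))
  cat(sprintf("  Glc:LAM2  untreated %.2f, treated %.2f\n",
              x$ratioUntreated, x$ratioTreated))
  cat(sprintf("  Glc released reduced by %s%%\n", x$glcReductionPct))
  if (length(x$notes)) cat("  note:", x$notes, sep = "\n  ")
  invisible(x)
}

#' Write an antagonism report to files
#'
#' Emits the two quantification tables as CSV and a short human-readable
#' text summary; file contents are byte-stable for a fixed input.
#'
#' @param report an \code{antagonismReport}
#' @param dir output directory (created if missing)
#' @return invisible named vector of file paths
#' @export
writeAntagonismReport <- function(report, dir) {
  stopifnot(inherits(report, "antagonismReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tU <- file.path(dir, "untreated_products.csv")
  tT <- file.path(dir, "treated_products.csv")
  write.csv(report$untreatedTable, tU, row.names = FALSE, quote = FALSE)
  write.csv(report$treatedTable, tT, row.names = FALSE, quote = FALSE)
  sm <- file.path(dir, "summary.txt")
  lines <- c(
    sprintf("mode: %s", report$mode),
    sprintf("package: %s %s", report$provenance$package,
            report$provenance$version),
    sprintf("transfer events: %d", nrow(report$events)),
    sprintf("Glc:LAM2 untreated: %s", format(report$ratioUntreated)),
    sprintf("Glc:LAM2 treated: %s", format(report$ratioTreated)),
    sprintf("Glc reduction (%%): %s", format(report$glcReductionPct)),
    report$notes)
  writeLines(lines, sm)
  invisible(c(untreated = tU, treated = tT, summary = sm))
}
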