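# 1,3-beta-transglucanase engine: DP-dependent cleave-and-transfer.
# A donor laminarioligomer (DP >= 5) is cleaved after the second glucosyl
# residue from its reducing end, releasing laminaribiose; the remaining
# DP - 2 fragment is transferred onto an acceptor through a new 1,6-beta
# bond, producing a branched hybrid (2 x LAM5 -> LAM2 + H8).

#' Transglucanase reaction configuration
#'
#' @param minDonorDP smallest linear donor DP accepted (default 5; no
#'   activity is observed on LAM2-LAM4)
#' @param attachmentModel \code{"reducing_side"} (1,6 bond placed on the backbone
#'   residue with a free O6 nearest the reducing end) or \code{"all_O6"}
#'   (any free backbone O6; sampled in stochastic mode)
#' @param mode \code{"exhaustive"} (deterministic largest-acceptor pairing)
#'   or \code{"stochastic"} (seeded uniform donor/acceptor sampling)
#' @param rounds number of transfer events to attempt (>= 1)
#' @param seed integer seed for stochastic mode
#' @return a list of class \code{reactionConfig}
#' @examples
#' reactionConfig(rounds = 3)
#' @export
reactionConfig <- function(minDonorDP = 5L,
                           attachmentModel = c("reducing_side", "all_O6"),
                           mode = c("exhaustive", "stochastic"),
                           rounds = 1L, seed = 1L) {
  minDonorDP <- as.integer(minDonorDP)
  if (is.na(minDonorDP) || minDonorDP < 2L)
    stop("minDonorDP must be an integer >= 2")
  rounds <- as.integer(rounds)
  if (is.na(rounds) || rounds < 1L) stop("rounds must be an integer >= 1")
  structure(list(minDonorDP = minDonorDP,
                 attachmentModel = match.arg(attachmentModel),
                 mode = match.arg(mode),
                 rounds = rounds,
                 seed = as.integer(seed)),
            class = "reactionConfig")
}

#' Donor eligibility
#'
#' A donor must be a linear, all-1,3-linked, non-reduced oligomer of DP at
#' least \code{minDonorDP}: reduced chains and branched hybrids are never
#' cleaved (hybrids act as acceptors only).
#'
#' @param g a [Glycan-class]
#' @param config a [reactionConfig()]
#' @return logical
#' @examples
#' isDonorSubstrate(parseGlycan("LAM4"))   # FALSE
#' isDonorSubstrate(parseGlycan("LAM5"))   # TRUE
#' isDonorSubstrate(parseGlycan("LAM5ol")) # FALSE
#' @export
isDonorSubstrate <- function(g, config = reactionConfig()) {
  stopifnot(is(g, "Glycan"))
  !isBranched(g) && !isReduced(g) && glycanDP(g) >= config$minDonorDP
}

.isAcceptor <- function(g, config) {
  isDonorSubstrate(g, config) || (isBranched(g) && !isReduced(g))
}

.pickAttachment <- function(acceptor, config, sample. = FALSE) {
  chain <- .mainChain(acceptor)
  free <- chain[!vapply(chain, function(id)
    .hasChildAt(acceptor, id, 6L), logical(1))]
  if (!length(free)) stop("acceptor has no free backbone O6")
  if (config$attachmentModel == "all_O6" && sample.) {
    free[sample.int(length(free), 1L)]
  } else {
    free[1L]   # nearest the reducing end
  }
}

#' One cleave-and-transfer event
#'
#' Splits the donor after the second glucosyl residue from the reducing end
#' (releasing laminaribiose) and attaches the remaining DP - 2 fragment to
#' the acceptor through a new 1,6-beta bond; product DP = acceptor DP +
#' donor DP - 2.
#'
#' @param donor,acceptor [Glycan-class] objects; the acceptor is an eligible
#'   donor-grade oligomer or a previously formed hybrid
#' @param config a [reactionConfig()]
#' @return a [TransferEvent-class]
#' @examples
#' ev <- transglycosylate(parseGlycan("LAM5"), parseGlycan("LAM5"))
#' glycanDP(ev@product)  # 8
#' @export
transglycosylate <- function(donor, acceptor, config = reactionConfig()) {
  if (!isDonorSubstrate(donor, config))
    stop("substrate error: donor must be a linear non-reduced oligomer ",
         "with DP >= ", config$minDonorDP)
  if (!.isAcceptor(acceptor, config))
    stop("substrate error: acceptor must be donor-eligible or a hybrid")
  at <- .pickAttachment(acceptor, config,
                        sample. = config$mode == "stochastic")
  product <- .attachBranch(acceptor, at, glycanDP(donor) - 2L)
  new("TransferEvent",
      donor = donor, acceptor = acceptor,
      released = makeLinear(2L), product = product,
      attachmentPosition = .backbonePosition(acceptor, at))
}

setMethod("show", "TransferEvent", function(object) {
  cat(sprintf("TransferEvent: %s + %s -> LAM2 + %s (1,6 bond at backbone position %d)\n",
              speciesLabel(object@donor), speciesLabel(object@acceptor),
              speciesLabel(object@product), object@attachmentPosition))
})

# deterministic donor/acceptor choice for exhaustive mode: smallest eligible
# donor; acceptor is the largest hybrid if any, else the largest eligible
# linear oligomer distinct from the chosen donor molecule
.chooseExhaustive <- function(pool, config) {
  gl <- pool@glycans
  dp <- vapply(gl, glycanDP, integer(1))
  donors <- which(vapply(gl, isDonorSubstrate, logical(1), config) &
                  pool@counts > 0)
  if (!length(donors)) return(NULL)
  d <- donors[which.min(dp[donors])]
  hyb <- which(vapply(gl, function(g) isBranched(g) && !isReduced(g),
                      logical(1)) & pool@counts > 0)
  if (length(hyb)) {
    a <- hyb[which.max(dp[hyb])]
  } else {
    acc <- donors[pool@counts[donors] >= ifelse(donors == d, 2, 1)]
    if (!length(acc)) return(NULL)
    a <- acc[which.max(dp[acc])]
  }
  list(donor = d, acceptor = a)
}

.chooseStochastic <- function(pool, config) {
  gl <- pool@glycans
  eligD <- vapply(gl, isDonorSubstrate, logical(1), config)
  eligA <- vapply(gl, .isAcceptor, logical(1), config)
  wD <- pool@counts * eligD
  if (sum(wD) == 0) return(NULL)
  d <- sample.int(length(gl), 1L, prob = wD)
  wA <- pool@counts * eligA
  wA[d] <- wA[d] - 1          # the donor molecule cannot be its own acceptor
  if (sum(wA) <= 0) return(NULL)
  a <- sample.int(length(gl), 1L, prob = wA)
  list(donor = d, acceptor = a)
}

#' Batch transglucanase reaction on a pool
#'
#' Runs up to \code{rounds} transfer events. In exhaustive mode events are
#' chosen deterministically with the largest-acceptor policy, so iterated
#' transfers build the +DP3 ladder (LAM5, H8, H11, H14, ...); stochastic
#' mode samples donor/acceptor pairs by abundance under the configured seed,
#' reproducing the qualitative abundance ordering H8 >> H11 >> H14. Rounds
#' stop early when no eligible donor/acceptor pair remains.
#'
#' @param pool starting [GlycanPool-class]
#' @param config a [reactionConfig()]
#' @return a [ReactionResult-class] (final pool + event log)
#' @examples
#' r <- reactBatch(glycanPool(c(LAM5 = 2)), reactionConfig(rounds = 1))
#' poolCounts(r@pool)
#' @export
reactBatch <- function(pool, config = reactionConfig()) {
  stopifnot(is(pool, "GlycanPool"), inherits(config, "reactionConfig"))
  run <- function() {
    cur <- pool
    events <- list()
    for (round in seq_len(config$rounds)) {
      sel <- if (config$mode == "exhaustive") {
        .chooseExhaustive(cur, config)
      } else {
        .chooseStochastic(cur, config)
      }
      if (is.null(sel)) break
      donor <- cur@glycans[[sel$donor]]
      acceptor <- cur@glycans[[sel$acceptor]]
      ev <- transglycosylate(donor, acceptor, config)
      cur <- .poolRemove(cur, donor)
      cur <- .poolRemove(cur, acceptor)
      cur <- .poolAdd(cur, ev@released)
      cur <- .poolAdd(cur, ev@product)
      events[[length(events) + 1L]] <- data.frame(
        round = round,
        donor = .canonString(donor),
        acceptor = .canonString(acceptor),
        released = .canonString(ev@released),
        product = .canonString(ev@product),
        attachment = ev@attachmentPosition)
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(round = integer(), donor = character(),
                 acceptor = character(), released = character(),
                 product = character(), attachment = integer())
    new("ReactionResult", pool = cur, events = ev,
        config = unclass(config))
  }
  if (config$mode == "stochastic") {
    withr::with_seed(config$seed, run())
  } else {
    run()
  }
}

setMethod("show", "ReactionResult", function(object) {
  cat(sprintf("ReactionResult: %d transfer event(s), %s mode\n",
              nrow(object@events), object@config$mode))
  print(poolCounts(object@pool))
})

#' Predicted +DP3 product series
#'
#' Iterated trisaccharide transfer onto the same acceptor produces products
#' whose DPs form the arithmetic sequence start, start + 3, ...,
#' start + 3 * nRounds (LAM5, H8, H11, H14; contaminant-seeded LAM6, H9,
#' H12).
#'
#' @param startDP seed DP (>= 5)
#' @param nRounds number of transfers (>= 0)
#' @return integer vector of DPs
#' @examples
#' predictSeries(5, 3)  # 5 8 11 14
#' @export
predictSeries <- function(startDP, nRounds) {
  startDP <- as.integer(startDP)
  nRounds <- as.integer(nRounds)
  if (is.na(startDP) || startDP < 5L) stop("startDP must be >= 5")
  if (is.na(nRounds) || nRounds < 0L) stop("nRounds must be >= 0")
  startDP + 3L * (0:nRounds)
}
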