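#' Simulate experiment outcome metadata
#'
#' Generates per-cell experiment records with an end pipette resistance
#' (endR, MOhm) whose separation between failed and good (high/medium)
#' morphology outcomes has an analytically known AUC: log(endR) is normal in
#' both groups with equal SD and a mean shift of
#' \code{sqrt(2) * qnorm(aucTarget)} SDs, so the theoretical AUC equals
#' \code{aucTarget} exactly (AUC is invariant under the exp transform). For
#' \code{aucTarget = 1} the two groups are drawn from disjoint uniform
#' supports instead. cDNA quantity and quality are correlated with the
#' nucleus outcome.
#'
#' @param n number of records.
#' @param aucTarget analytic endR AUC for good vs failed morphology, in
#'   [0.5, 1].
#' @param seed integer.
#' @param failRate fraction of failed morphology outcomes.
#' @param nucleusRate fraction of nucleus+ cells.
#' @return data.frame of outcome records (one row per cell).
#' @examples
#' meta <- makeMetadata(200, aucTarget = 0.8, seed = 1)
#' @export
makeMetadata <- function(n, aucTarget = 0.8, seed = 1L, failRate = 0.35,
                         nucleusRate = 0.7) {
  if (aucTarget < 0.5 || aucTarget > 1) {
    stop("aucTarget must be in [0.5, 1]")
  }
  withSeed(seed, {
    outcome <- sample(
      c("failed", "high", "medium", "insufficient_axon", "not_assessed"),
      n, replace = TRUE,
      prob = c(failRate, 0.55 * (1 - failRate), 0.25 * (1 - failRate),
               0.15 * (1 - failRate), 0.05 * (1 - failRate)))
    good <- outcome %in% c("high", "medium")
    sdl <- 1
    if (aucTarget < 1) {
      delta <- sqrt(2) * sdl * stats::qnorm(aucTarget)
      lend <- stats::rnorm(n, mean = log(150) + delta * good, sd = sdl)
      endR <- exp(lend)
    } else {
      endR <- ifelse(good, 1500 + stats::runif(n, 0, 1000),
                     stats::runif(n, 10, 500))
    }
    nuc <- stats::runif(n) < nucleusRate
    cdnaQuantity <- exp(stats::rnorm(n, mean = log(8) + 0.9 * nuc, sd = 0.5))
    cdnaQuality <- stats::rbeta(n, shape1 = 5 + 7 * nuc, shape2 = 5)
    data.frame(
      cellId = sprintf("cell%05d", seq_len(n)),
      endPipetteResistance = endR,
      nucleusPlus = nuc,
      cdnaQuantity = cdnaQuantity,
      cdnaQuality = cdnaQuality,
      morphologyOutcome = outcome,
      recordingDuration = stats::runif(n, 3, 12),
      retrievalDuration = stats::runif(n, 0.5, 5),
      extractionDuration = stats::runif(n, 0.5, 8),
      healthRating = sample(1:5, n, replace = TRUE,
                            prob = c(0.05, 0.1, 0.25, 0.35, 0.25)),
      stringsAsFactors = FALSE
    )
  })
}
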