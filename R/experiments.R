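#' Calibration and recovery experiments over the full pipeline
#'
#' Repeatable end-to-end experiments used for validating the chain:
#' `nullCalibration` runs effect-free cohorts and reports the per-cell
#' Kruskal-Wallis rejection rate (which should sit near the nominal
#' level), `effectRecovery` plants a delta-band amplitude effect in the
#' posterior cingulate (PCC) for the CI group and reports how often the
#' statistics layer flags (PCC, delta) in the CI-HC FDR rejection set,
#' along with the recovered effect directions.
#'
#' @param nCohorts number of independent effect-free cohorts.
#' @param nPerGroup subjects per group.
#' @param seed master seed; cohort c uses seed + c.
#' @param duration,rate,nSensors,nVertices generator scale.
#' @param alpha nominal level.
#' @return `nullCalibration`: list(rate, nCells, pvalues).
#' @export
nullCalibration <- function(nCohorts = 2, nPerGroup = 8, seed = 1,
                            duration = 60, rate = 600, nSensors = 64,
                            nVertices = 520, alpha = 0.05) {
  pvals <- c()
  noEffect <- data.frame(group = character(), roi = character(),
                         band = character(), multiplier = numeric())
  for (ch in seq_len(nCohorts)) {
    d <- cohortDesign(nPerGroup = nPerGroup, nSensors = nSensors,
                      nVertices = nVertices, rate = rate,
                      duration = duration, effects = noEffect,
                      seed = seed + ch)
    res <- runPipeline(d, withStats = TRUE)
    t <- statTests(res$report)
    pvals <- c(pvals, t$p_raw[t$contrast == "omnibus"])
  }
  list(rate = mean(pvals <= alpha), nCells = length(pvals), pvalues = pvals)
}

#' @rdname nullCalibration
#' @param nRuns number of seeded replicate studies.
#' @param multiplier planted delta amplitude multiplier in PCC (CI group).
#' @return `effectRecovery`: list(hits, nRuns, directionOk, detail).
#' @export
effectRecovery <- function(nRuns = 20, nPerGroup = 24, seed = 1,
                           multiplier = 2, duration = 32, rate = 600,
                           nSensors = 64, nVertices = 520, alpha = 0.05) {
  eff <- data.frame(group = "CI", roi = c("PCC.L", "PCC.R"),
                    band = "delta", multiplier = multiplier)
  hits <- 0L; dirOk <- 0L
  detail <- vector("list", nRuns)
  for (run in seq_len(nRuns)) {
    d <- cohortDesign(nPerGroup = nPerGroup, nSensors = nSensors,
                      nVertices = nVertices, rate = rate,
                      duration = duration, effects = eff,
                      seed = seed + 1000L * run)
    res <- runPipeline(d, groups = c("CI", "HC"))
    rej <- rejectedRois(res$report, "delta", "CI-HC", alpha = alpha)
    hit <- any(c("PCC.L", "PCC.R") %in% rej)
    v <- powerValues(res$table)
    g <- res$manifest$group
    dDelta <- mean(v[g == "CI", c("PCC.L", "PCC.R"), "delta"]) -
      mean(v[g == "HC", c("PCC.L", "PCC.R"), "delta"])
    dAlpha <- mean(v[g == "CI", c("PCC.L", "PCC.R"), "alpha"]) -
      mean(v[g == "HC", c("PCC.L", "PCC.R"), "alpha"])
    ok <- dDelta > 0 && dAlpha < 0
    hits <- hits + hit
    dirOk <- dirOk + ok
    detail[[run]] <- data.frame(run = run, hit = hit,
                                delta_shift = dDelta, alpha_shift = dAlpha)
  }
  list(hits = hits, nRuns = nRuns, directionOk = dirOk,
       detail = do.call(rbind, detail))
}

#' @rdname nullCalibration
#' @param multipliers increasing amplitude multipliers to probe.
#' @param nSubjects subjects simulated per multiplier.
#' @return `effectMonotonicity`: named numeric vector of mean (PCC.L,
#'   delta) relative power per multiplier.
#' @export
effectMonotonicity <- function(multipliers = c(1, 1.5, 2), nSubjects = 20,
                               seed = 1, duration = 32, rate = 600,
                               nSensors = 64, nVertices = 520) {
  out <- numeric(length(multipliers))
  for (i in seq_along(multipliers)) {
    eff <- data.frame(group = "CI", roi = c("PCC.L", "PCC.R"),
                      band = "delta", multiplier = multipliers[i])
    d <- cohortDesign(nPerGroup = nSubjects, nSensors = nSensors,
                      nVertices = nVertices, rate = rate,
                      duration = duration, effects = eff, seed = seed)
    res <- runPipeline(d, groups = "CI", withStats = FALSE)
    out[i] <- mean(powerValues(res$table)[, "PCC.L", "delta"])
  }
  names(out) <- paste0("x", multipliers)
  out
}
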