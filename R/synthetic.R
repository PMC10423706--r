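#' @include fluorescence.R simulate.R
NULL

# cycle-trend shapes of the molar fluorescences: the inactive probe shows
# an early maximum (around cycle 2-3) followed by a slow photobleaching
# decay; the active probe's molar fluorescence drifts slowly upward.
# Fixture shapes, not scientific claims.
.trendMinus <- function(i, bumpAmp = 0.03, bumpPeak = 2.5, decay = 0.002) {
    (1 + bumpAmp * (i / bumpPeak) * exp(1 - i / bumpPeak)) *
        exp(-decay * (i - 1))
}

.trendPlus <- function(i, slope = 0.002) 1 + slope * (i - 1)

#' Generate synthetic no-template control plates
#'
#' Emulates the control experiment used to calibrate molar fluorescence:
#' for each probe state, `q` plates at distinct total probe concentrations
#' are measured over `nCycles` cycles and `nWells` wells.  The ground-truth
#' molar fluorescence is `base * (1 + well effect) * cycle trend`, where
#' the well effect is a per-well Gaussian perturbation and the cycle trend
#' reproduces the qualitative background shape (early maximum, slow
#' photobleaching decay).  Observed readings are
#' `F = f * C * (1 + eps)` with `eps ~ Normal(0, noiseCV^2)` —
#' multiplicative noise, so `F / C` is i.i.d. normal across plates at fixed
#' (cycle, well).
#'
#' Defaults are chosen so that at the working concentration 0.125 pmol/L
#' and a 20 uL reaction the derived background and incremental parameters
#' are near 1 and 1e-6.
#'
#' @param qActive,qInactive number of plates (distinct concentrations) per
#'   probe state.
#' @param activeConcentrations,inactiveConcentrations increasing
#'   concentration series (mol/L); default an evenly spaced series
#'   bracketing 0.125 pmol/L.
#' @param nCycles,nWells plate geometry (wells at most 96).
#' @param fMinusBase,fPlusBase molar fluorescences (fluorescence L/mol) of
#'   inactive and active probe at cycle 1 for an average well.
#' @param wellEffectSD standard deviation of the relative well effect.
#' @param noiseCV relative measurement noise.
#' @param seed integer seed.
#' @return list with `activePlates` and `inactivePlates` (lists of
#'   [ProbePlate]), and `truth` (the generating [MolarFluorescence], whose
#'   dispersion entries hold the true per-plate standard deviation
#'   `f * noiseCV`).
#' @examples
#' g <- generateControlPlates(nCycles = 5, nWells = 4, seed = 1)
#' fitMolarFluorescence(g$inactivePlates)$f[1, 1] / g$truth@fMinus[1, 1]
#' @export
generateControlPlates <- function(qActive = 4, qInactive = 3,
                                  activeConcentrations = NULL,
                                  inactiveConcentrations = NULL,
                                  nCycles = 45, nWells = 96,
                                  fMinusBase = 8e12, fPlusBase = 2.0044e13,
                                  wellEffectSD = 0.03, noiseCV = 0.01,
                                  seed = 1) {
    stopifnot(qActive >= 1, qInactive >= 1, nWells <= 96, noiseCV >= 0,
              fPlusBase > fMinusBase)
    defaultC <- function(q) {
        if (q == 1L) pmolPerL(0.125)
        else pmolPerL(seq(0.075, 0.15, length.out = q))
    }
    if (is.null(activeConcentrations))
        activeConcentrations <- defaultC(qActive)
    if (is.null(inactiveConcentrations))
        inactiveConcentrations <- defaultC(qInactive)
    stopifnot(length(activeConcentrations) == qActive,
              length(inactiveConcentrations) == qInactive,
              !is.unsorted(activeConcentrations, strictly = TRUE),
              !is.unsorted(inactiveConcentrations, strictly = TRUE))
    set.seed(seed)
    wells <- plateWellLabels(nWells)
    i <- seq_len(nCycles)
    mkTruth <- function(base, trend) {
        wellEff <- 1 + rnorm(nWells, 0, wellEffectSD)
        f <- outer(trend(i), wellEff) * base
        dimnames(f) <- list(i, wells)
        f
    }
    fMinus <- mkTruth(fMinusBase, .trendMinus)
    fPlus <- mkTruth(fPlusBase, .trendPlus)
    if (any(fPlus <= fMinus))
        stop("generated truth has fPlus <= fMinus; reduce 'wellEffectSD' ",
             "or widen the base gap")
    mkPlates <- function(f, conc, state) {
        lapply(seq_along(conc), function(j) {
            eps <- matrix(rnorm(length(f), 0, noiseCV), nrow(f), ncol(f))
            ProbePlate(f * conc[j] * (1 + eps), concentration = conc[j],
                       probeState = state,
                       plateId = sprintf("%s_%02d", state, j),
                       wellLabels = wells)
        })
    }
    list(activePlates = mkPlates(fPlus, activeConcentrations, "active"),
         inactivePlates = mkPlates(fMinus, inactiveConcentrations,
                                   "inactive"),
         truth = MolarFluorescence(fMinus, fPlus,
                                   sigmaMinus = fMinus * noiseCV,
                                   sigmaPlus = fPlus * noiseCV))
}

#' Generate a synthetic amplification-run plate
#'
#' Simulates one independent amplification trajectory per well with the
#' stochastic branching-process model and converts it to fluorescence via
#' `F = b + d * DeltaX`.
#'
#' @param eff an [EfficiencyParams] object.
#' @param input an [InputDistribution].
#' @param params a [FluorescenceParams] covering the requested cycles and
#'   wells.
#' @param nWells,nCycles plate geometry.
#' @param seed integer seed.
#' @param plateId plate identifier.
#' @return a [ProbePlate] with probe state `"sample"`; the underlying
#'   [TrajectoryEnsemble] is attached as metadata element `"ensemble"`.
#' @export
generateAmplificationRuns <- function(eff, input, params, nWells = 96,
                                      nCycles = 45, seed = 1,
                                      plateId = "run_01") {
    stopifnot(is(params, "FluorescenceParams"),
              nrow(params@b) >= nCycles, ncol(params@b) >= nWells)
    ens <- simulatePCR(eff, input, nCycles, nWells, seed)
    dX <- t(ens@X[, -1L, drop = FALSE] - ens@X[, 1L])   # cycle x well
    b <- params@b[seq_len(nCycles), seq_len(nWells), drop = FALSE]
    d <- params@d[seq_len(nCycles), seq_len(nWells), drop = FALSE]
    plate <- ProbePlate(b + d * dX, concentration = params@conc,
                        probeState = "sample", plateId = plateId,
                        wellLabels = plateWellLabels(nWells))
    metadata(plate)$ensemble <- ens
    plate
}
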