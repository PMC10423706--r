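#' @include pcruq-package.R
NULL

.scalarOk <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x)

# ---------------------------------------------------------------------------
# EfficiencyParams
# ---------------------------------------------------------------------------

#' Amplification-efficiency parameters of the two-type model
#'
#' Per cycle, each reverse strand templates a new forward strand with
#' probability `pBar * R` and each forward strand templates a new reverse
#' strand with probability `pBar / R`.  `pBar` is therefore the geometric
#' mean of the two directional efficiencies and `R` the square root of their
#' ratio; `r` is the reverse-transcription efficiency used when the input is
#' single-stranded RNA.  Both directional probabilities must lie in (0, 1];
#' the closed right endpoint (perfect efficiency) is accepted as the natural
#' doubling limit.
#'
#' @slot pBar numeric(1), geometric-mean amplification efficiency in (0, 1].
#' @slot R numeric(1), directional-efficiency ratio parameter, positive.
#' @slot r numeric(1), reverse-transcription efficiency in (0, 1], or `NA`
#'   when the input is double-stranded DNA.
#' @aliases EfficiencyParams-class
#' @exportClass EfficiencyParams
setClass("EfficiencyParams",
    slots = c(pBar = "numeric", R = "numeric", r = "numeric"))

setValidity("EfficiencyParams", function(object) {
    msg <- character()
    if (!.scalarOk(object@pBar) || object@pBar <= 0 || object@pBar > 1)
        msg <- c(msg, "'pBar' must be a single value in (0, 1]")
    if (!.scalarOk(object@R) || object@R <= 0)
        msg <- c(msg, "'R' must be a single positive value")
    if (length(msg) == 0L) {
        if (object@pBar * object@R > 1 + 1e-12)
            msg <- c(msg, sprintf(
                "derived probability pBar*R = %.6g exceeds 1", object@pBar * object@R))
        if (object@pBar / object@R > 1 + 1e-12)
            msg <- c(msg, sprintf(
                "derived probability pBar/R = %.6g exceeds 1", object@pBar / object@R))
    }
    if (length(object@r) != 1L)
        msg <- c(msg, "'r' must have length 1 (possibly NA)")
    else if (!is.na(object@r) && (object@r <= 0 || object@r > 1))
        msg <- c(msg, "'r' must lie in (0, 1] when given")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# InputDistribution
# ---------------------------------------------------------------------------

#' Input copy-number model
#'
#' Describes the number of nucleic-acid strands pipetted into the reaction:
#' the input case (`"D"` double-stranded DNA, `"RF"` forward-stranded RNA,
#' `"RR"` reverse-stranded RNA), the expected copy number `meanI`, its
#' variance `varI`, and the distribution family used by the simulator.  For
#' the Poisson family the variance-to-mean ratio (dispersion) is 1; the
#' negative-binomial family has dispersion greater than 1; the fixed family
#' is deterministic with zero variance.
#'
#' @slot case character(1), one of `"D"`, `"RF"`, `"RR"`.
#' @slot meanI numeric(1), expected input copies, nonnegative.
#' @slot varI numeric(1), input variance, nonnegative.
#' @slot family character(1), one of `"poisson"`, `"negative_binomial"`,
#'   `"fixed"`.
#' @aliases InputDistribution-class
#' @exportClass InputDistribution
setClass("InputDistribution",
    slots = c(case = "character", meanI = "numeric", varI = "numeric",
              family = "character"))

setValidity("InputDistribution", function(object) {
    msg <- character()
    if (length(object@case) != 1L || !object@case %in% c("D", "RF", "RR"))
        msg <- c(msg, "'case' must be one of \"D\", \"RF\", \"RR\"")
    if (!.scalarOk(object@meanI) || object@meanI < 0)
        msg <- c(msg, "'meanI' must be a single nonnegative value")
    if (!.scalarOk(object@varI) || object@varI < 0)
        msg <- c(msg, "'varI' must be a single nonnegative value")
    fam <- object@family
    if (length(fam) != 1L ||
        !fam %in% c("poisson", "negative_binomial", "fixed"))
        msg <- c(msg, paste0("'family' must be \"poisson\", ",
                             "\"negative_binomial\" or \"fixed\""))
    else if (length(msg) == 0L) {
        if (fam == "poisson" && abs(object@varI - object@meanI) >
                1e-8 * max(1, object@meanI))
            msg <- c(msg, "poisson family requires varI == meanI (dispersion 1)")
        if (fam == "negative_binomial" &&
            object@varI <= object@meanI)
            msg <- c(msg, "negative_binomial family requires dispersion chi > 1")
        if (fam == "fixed" && object@varI != 0)
            msg <- c(msg, "fixed family requires varI == 0")
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SpectralDecomposition
# ---------------------------------------------------------------------------

#' Spectral decomposition of the expected-amplification matrix
#'
#' The one-cycle expectation matrix `A = [[1, pBar*R], [pBar/R, 1]]` has
#' eigenvalues `1 + pBar` and `1 - pBar`.  Right eigenvectors are the
#' columns of `X`, left eigenvectors the rows of `Z = X^-1`; they are
#' computed from closed forms (not a numeric eigensolver) so signs and
#' scaling are deterministic, with the `1/sqrt(2)` normalisation that makes
#' all four vectors unit-norm when `R = 1`.
#'
#' @slot lambda numeric(2), eigenvalues `(1 + pBar, 1 - pBar)`.
#' @slot X 2x2 matrix of right eigenvectors (columns).
#' @slot Z 2x2 matrix of left eigenvectors (rows), the inverse of `X`.
#' @aliases SpectralDecomposition-class
#' @exportClass SpectralDecomposition
setClass("SpectralDecomposition",
    slots = c(lambda = "numeric", X = "matrix", Z = "matrix"))

setValidity("SpectralDecomposition", function(object) {
    msg <- character()
    if (length(object@lambda) != 2L) msg <- c(msg, "'lambda' must have length 2")
    if (!all(dim(object@X) == c(2L, 2L))) msg <- c(msg, "'X' must be 2x2")
    if (!all(dim(object@Z) == c(2L, 2L))) msg <- c(msg, "'Z' must be 2x2")
    if (length(msg) == 0L &&
        max(abs(object@X %*% object@Z - diag(2))) > 1e-8)
        msg <- c(msg, "'Z' is not the inverse of 'X'")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MomentTrajectory
# ---------------------------------------------------------------------------

#' Per-cycle moments of the strand-count vector
#'
#' Holds, for cycles `0..n`, the expected forward/reverse strand counts
#' (copies), the 2x2 variance-covariance matrix of the counts (copies^2),
#' and the covariances of each strand count with its initial value.  All
#' cycles are computed in one pass by [momentTrajectory()] and cached here.
#'
#' @slot cycles integer vector `0:n`.
#' @slot meanU `(n+1) x 2` matrix, columns `X` (forward) and `Y` (reverse).
#' @slot varU `2 x 2 x (n+1)` array of symmetric covariance matrices.
#' @slot covXX0 numeric, `Cov[X_i, X_0]` per cycle.
#' @slot covYY0 numeric, `Cov[Y_i, Y_0]` per cycle.
#' @slot eff the [EfficiencyParams] used.
#' @slot input the [InputDistribution] used, or `NULL` when the trajectory
#'   was built from explicit initial moments.
#' @aliases MomentTrajectory-class
#' @exportClass MomentTrajectory
setClass("MomentTrajectory",
    slots = c(cycles = "integer", meanU = "matrix", varU = "array",
              covXX0 = "numeric", covYY0 = "numeric",
              eff = "EfficiencyParams", input = "ANY"))

setValidity("MomentTrajectory", function(object) {
    n1 <- length(object@cycles)
    msg <- character()
    if (!all(dim(object@meanU) == c(n1, 2L)))
        msg <- c(msg, "'meanU' must be (n+1) x 2")
    if (!all(dim(object@varU) == c(2L, 2L, n1)))
        msg <- c(msg, "'varU' must be 2 x 2 x (n+1)")
    if (length(object@covXX0) != n1 || length(object@covYY0) != n1)
        msg <- c(msg, "cross-covariances must have one value per cycle")
    if (length(msg) == 0L) {
        if (any(object@meanU < -1e-9))
            msg <- c(msg, "expected counts must be nonnegative")
        if (any(object@varU[1, 1, ] < -1e-9) || any(object@varU[2, 2, ] < -1e-9))
            msg <- c(msg, "variances must be nonnegative")
        if (max(abs(object@varU[1, 2, ] - object@varU[2, 1, ])) > 1e-6)
            msg <- c(msg, "covariance matrices must be symmetric")
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TrajectoryEnsemble
# ---------------------------------------------------------------------------

#' Monte-Carlo ensemble of strand-count trajectories
#'
#' Replicate trajectories of the exact stochastic model: integer-valued
#' forward (`X`) and reverse (`Y`) strand counts for cycles `0..n`, plus the
#' input draws that seeded each replicate.  Counts are stored as doubles to
#' accommodate copy numbers beyond the 32-bit integer range.
#'
#' @slot X,Y `replicates x (n+1)` matrices of strand counts.
#' @slot inputDraws `replicates x 2` matrix of input copies `(I_X, I_Y)`.
#' @slot eff the [EfficiencyParams] used.
#' @slot input the [InputDistribution] used.
#' @slot seed integer(1), master seed of the run.
#' @aliases TrajectoryEnsemble-class
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
    slots = c(X = "matrix", Y = "matrix", inputDraws = "matrix",
              eff = "EfficiencyParams", input = "InputDistribution",
              seed = "integer"))

setValidity("TrajectoryEnsemble", function(object) {
    msg <- character()
    if (!identical(dim(object@X), dim(object@Y)))
        msg <- c(msg, "'X' and 'Y' must have identical dimensions")
    if (nrow(object@inputDraws) != nrow(object@X) ||
        ncol(object@inputDraws) != 2L)
        msg <- c(msg, "'inputDraws' must be replicates x 2")
    if (length(msg) == 0L && (any(object@X < 0) || any(object@Y < 0)))
        msg <- c(msg, "strand counts must be nonnegative")
    if (length(msg) == 0L && ncol(object@X) > 1L) {
        if (any(object@X[, -1L, drop = FALSE] <
                object@X[, -ncol(object@X), drop = FALSE]) ||
            any(object@Y[, -1L, drop = FALSE] <
                object@Y[, -ncol(object@Y), drop = FALSE]))
            msg <- c(msg, "strand counts must be nondecreasing in cycle")
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ProbePlate
# ---------------------------------------------------------------------------

#' A fluorescence plate read
#'
#' One plate of per-cycle, per-well fluorescence readings, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with a single
#' `"fluorescence"` assay whose rows are cycles (1..n) and whose columns are
#' wells in row-major 96-well order (A1, A2, ..., H12).  Control plates
#' carry a known total probe concentration and a probe state (`"active"` or
#' `"inactive"`); plates produced by amplification runs use state
#' `"sample"`.
#'
#' @slot plateId character(1) identifier.
#' @slot probeState character(1), `"active"`, `"inactive"` or `"sample"`.
#' @slot concentration numeric(1), total probe concentration in mol/L.
#' @aliases ProbePlate-class
#' @exportClass ProbePlate
setClass("ProbePlate",
    contains = "SummarizedExperiment",
    slots = c(plateId = "character", probeState = "character",
              concentration = "numeric"))

setValidity("ProbePlate", function(object) {
    msg <- character()
    if (!"fluorescence" %in% names(assays(object)))
        msg <- c(msg, "assay 'fluorescence' is required")
    if (length(object@probeState) != 1L ||
        !object@probeState %in% c("active", "inactive", "sample"))
        msg <- c(msg, "'probeState' must be \"active\", \"inactive\" or \"sample\"")
    if (!.scalarOk(object@concentration) || object@concentration <= 0)
        msg <- c(msg, "'concentration' must be a single positive value (mol/L)")
    if (ncol(object) > 96L)
        msg <- c(msg, "at most 96 wells per plate")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MolarFluorescence
# ---------------------------------------------------------------------------

#' Cycle- and well-resolved molar fluorescence of both probe states
#'
#' Fluorescence per mole of inactive (`fMinus`) and active (`fPlus`) probe,
#' with pointwise dispersion estimates (`sigmaMinus`, `sigmaPlus`).  The
#' active probe is brighter, so `fPlus > fMinus` everywhere.  Dispersions
#' are `NA` when fitted from a single plate (no replication).
#'
#' @slot fMinus,fPlus cycle x well matrices, fluorescence L/mol.
#' @slot sigmaMinus,sigmaPlus cycle x well matrices, same units, possibly
#'   `NA`.
#' @aliases MolarFluorescence-class
#' @exportClass MolarFluorescence
setClass("MolarFluorescence",
    slots = c(fMinus = "matrix", fPlus = "matrix",
              sigmaMinus = "matrix", sigmaPlus = "matrix"))

setValidity("MolarFluorescence", function(object) {
    msg <- character()
    d <- dim(object@fMinus)
    if (!identical(dim(object@fPlus), d) ||
        !identical(dim(object@sigmaMinus), d) ||
        !identical(dim(object@sigmaPlus), d))
        msg <- c(msg, "all four matrices must share dimensions")
    if (length(msg) == 0L && any(object@fPlus <= object@fMinus, na.rm = TRUE))
        msg <- c(msg, "'fPlus' must exceed 'fMinus' elementwise")
    if (length(msg) == 0L &&
        (any(object@sigmaMinus < 0, na.rm = TRUE) ||
         any(object@sigmaPlus < 0, na.rm = TRUE)))
        msg <- c(msg, "dispersions must be nonnegative")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# FluorescenceParams
# ---------------------------------------------------------------------------

#' Background and incremental fluorescence parameters
#'
#' The hydrolysis-probe fluorescence model is `F = b + d * DeltaX`, where
#' `b = fMinus * C` is the background contribution of the inactive probe and
#' `d = (fPlus - fMinus) / (V * N_A)` the fluorescence gained per monitored
#' strand synthesised.  Both vary with cycle and well.
#'
#' @slot b cycle x well matrix, background fluorescence (arbitrary units).
#' @slot d cycle x well matrix, fluorescence per synthesised strand,
#'   positive.
#' @slot conc numeric(1), total probe concentration, mol/L.
#' @slot vol numeric(1), reaction volume, litres.
#' @aliases FluorescenceParams-class
#' @exportClass FluorescenceParams
setClass("FluorescenceParams",
    slots = c(b = "matrix", d = "matrix", conc = "numeric", vol = "numeric"))

setValidity("FluorescenceParams", function(object) {
    msg <- character()
    if (!identical(dim(object@b), dim(object@d)))
        msg <- c(msg, "'b' and 'd' must share dimensions")
    if (any(object@d <= 0, na.rm = TRUE))
        msg <- c(msg, "'d' must be positive elementwise")
    if (!.scalarOk(object@conc) || object@conc <= 0)
        msg <- c(msg, "'conc' must be a single positive value (mol/L)")
    if (!.scalarOk(object@vol) || object@vol <= 0)
        msg <- c(msg, "'vol' must be a single positive value (litres)")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# FluorescenceCurve
# ---------------------------------------------------------------------------

#' Fluorescence mean, variance and normal band per cycle and well
#'
#' @slot meanF,varF cycle x well matrices.
#' @slot lo,hi cycle x well matrices, `meanF -/+ kappa * sqrt(varF)`.
#' @slot kappa numeric(1), standard-deviation multiplier of the band.
#' @aliases FluorescenceCurve-class
#' @exportClass FluorescenceCurve
setClass("FluorescenceCurve",
    slots = c(meanF = "matrix", varF = "matrix", lo = "matrix",
              hi = "matrix", kappa = "numeric"))

setValidity("FluorescenceCurve", function(object) {
    msg <- character()
    d <- dim(object@meanF)
    if (!identical(dim(object@varF), d) || !identical(dim(object@lo), d) ||
        !identical(dim(object@hi), d))
        msg <- c(msg, "all matrices must share dimensions")
    if (any(object@varF < -1e-12, na.rm = TRUE))
        msg <- c(msg, "'varF' must be nonnegative")
    if (!.scalarOk(object@kappa) || object@kappa <= 0)
        msg <- c(msg, "'kappa' must be a single positive value")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# LODResult
# ---------------------------------------------------------------------------

#' Limit of detection at one parameter point
#'
#' `L` is the smallest positive-integer expected input copy number
#' satisfying the kappa-sigma detectability constraint
#' `E[I] >= (chi*alpha + beta) * kappa^2`; `M = sqrt(chi / L)` is the
#' largest detectable coefficient of variation of the input.
#'
#' @slot L integer(1), detectable copies, at least 1.
#' @slot M numeric(1), maximal detectable input CV.
#' @slot alpha,beta numeric(1), asymptotic CV^2 coefficients at the point.
#' @slot pBar,R,r,chi,kappa numeric(1), the evaluated parameter point.
#' @slot case character(1), input case.
#' @aliases LODResult-class
#' @exportClass LODResult
setClass("LODResult",
    slots = c(L = "integer", M = "numeric", alpha = "numeric",
              beta = "numeric", pBar = "numeric", R = "numeric",
              r = "numeric", chi = "numeric", kappa = "numeric",
              case = "character"))

setValidity("LODResult", function(object) {
    msg <- character()
    if (object@L < 1L) msg <- c(msg, "'L' must be at least 1")
    if (abs(object@M - sqrt(object@chi / object@L)) >
            1e-12 * max(1, object@M))
        msg <- c(msg, "'M' must equal sqrt(chi / L)")
    if (length(msg)) msg else TRUE
})
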