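#' @include moments.R
NULL

# deterministic sub-stream seeds so each stage (input draw, RT, cycling)
# can be rerun independently with identical results
.subSeeds <- function(seed, n = 3L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sample.int(.Machine$integer.max, n)
}

#' Draw input copy numbers
#'
#' Draws the input strand counts `(I_X, I_Y)` for each replicate.  For
#' double-stranded DNA (case D) the two strands are i.i.d. draws from the
#' input family; for RNA all copies share one strandedness, so the other
#' component is 0.  The negative binomial is parameterised by its mean
#' `meanI` and dispersion `chi` (variance `chi * meanI`, i.e. size
#' `meanI / (chi - 1)`); the fixed family returns `round(meanI)`.
#'
#' @param input an [InputDistribution] object.
#' @param nReplicates number of replicates.
#' @param seed integer seed.
#' @return `nReplicates x 2` matrix of input copies, columns `IX`, `IY`.
#' @export
drawInput <- function(input, nReplicates, seed) {
    stopifnot(is(input, "InputDistribution"), nReplicates >= 1)
    set.seed(seed)
    draw <- function(n) switch(input@family,
        poisson = rpois(n, input@meanI),
        negative_binomial = {
            chi <- dispersion(input)
            if (!is.finite(chi) || chi <= 1)
                stop("negative binomial input requires dispersion chi > 1")
            rnbinom(n, size = input@meanI / (chi - 1), mu = input@meanI)
        },
        fixed = rep(round(input@meanI), n))
    out <- switch(input@case,
        D  = cbind(IX = draw(nReplicates), IY = draw(nReplicates)),
        RF = cbind(IX = draw(nReplicates), IY = 0),
        RR = cbind(IX = 0, IY = draw(nReplicates)))
    storage.mode(out) <- "double"
    out
}

#' Apply the reverse-transcription step
#'
#' Each RNA strand yields one cDNA strand (of the complementary sense) with
#' probability `r`, independently: case RF maps `(I_X, 0)` to
#' `(0, B(I_X; r))` and case RR maps `(0, I_Y)` to `(B(I_Y; r), 0)`.  Case D
#' has no RT step and passes through unchanged.
#'
#' @param inputDraws `replicates x 2` matrix from [drawInput()].
#' @param r reverse-transcription efficiency in (0, 1].
#' @param case input case.
#' @param seed integer seed.
#' @return `replicates x 2` matrix of initial strand counts `(X_0, Y_0)`.
#' @export
applyRT <- function(inputDraws, r, case = c("D", "RF", "RR"), seed) {
    case <- match.arg(case)
    if (case == "D") {
        out <- inputDraws
        colnames(out) <- c("X0", "Y0")
        return(out)
    }
    if (is.na(r) || r <= 0 || r > 1)
        stop("'r' must lie in (0, 1] for case ", case)
    set.seed(seed)
    n <- nrow(inputDraws)
    if (case == "RF")
        cbind(X0 = 0, Y0 = rbinom(n, inputDraws[, 1], r))
    else
        cbind(X0 = rbinom(n, inputDraws[, 2], r), Y0 = 0)
}

#' Run the per-cycle amplification model
#'
#' Iterates the exact stochastic model: per cycle,
#' `X_i = X_(i-1) + B(Y_(i-1); pBar*R)` and
#' `Y_i = Y_(i-1) + B(X_(i-1); pBar/R)`, with both binomial draws
#' conditioning on the counts of the previous cycle (synchronous update)
#' and all trials independent.
#'
#' @param U0 `replicates x 2` matrix of initial strand counts.
#' @param eff an [EfficiencyParams] object.
#' @param nCycles number of cycles.
#' @param seed integer seed.
#' @return list of `X` and `Y`, each `replicates x (nCycles+1)`.
#' @export
runCycles <- function(U0, eff, nCycles, seed) {
    stopifnot(is(eff, "EfficiencyParams"), ncol(U0) == 2L)
    n <- .checkCycles(nCycles)
    nr <- nrow(U0)
    prf <- pRf(eff)
    pfr <- pFr(eff)
    X <- matrix(0, nr, n + 1L)
    Y <- matrix(0, nr, n + 1L)
    X[, 1] <- U0[, 1]
    Y[, 1] <- U0[, 2]
    set.seed(seed)
    for (q in seq_len(n)) {
        X[, q + 1] <- X[, q] + rbinom(nr, Y[, q], prf)
        Y[, q + 1] <- Y[, q] + rbinom(nr, X[, q], pfr)
    }
    colnames(X) <- colnames(Y) <- 0:n
    list(X = X, Y = Y)
}

#' Monte-Carlo simulation of the strand-specific PCR model
#'
#' Draws input copies, applies the reverse-transcription step for RNA
#' cases, and runs the per-cycle binomial amplification model.  The three
#' stages use sub-seeds derived deterministically from `seed`, so a rerun
#' of any stage with the same configuration is bit-identical.
#'
#' @param eff an [EfficiencyParams] object.
#' @param input an [InputDistribution] object.
#' @param nCycles number of cycles.
#' @param nReplicates number of independent replicate reactions.
#' @param seed integer master seed.
#' @return a [TrajectoryEnsemble] object.
#' @examples
#' ens <- simulatePCR(EfficiencyParams(0.9),
#'                    InputDistribution("D", meanI = 10, family = "fixed"),
#'                    nCycles = 5, nReplicates = 100, seed = 1)
#' head(ensembleMoments(ens))
#' @export
simulatePCR <- function(eff, input, nCycles, nReplicates, seed) {
    stopifnot(is(eff, "EfficiencyParams"), is(input, "InputDistribution"),
              nReplicates >= 1)
    seeds <- .subSeeds(seed)
    draws <- drawInput(input, nReplicates, seeds[1])
    U0 <- applyRT(draws, eff@r, input@case, seeds[2])
    tr <- runCycles(U0, eff, nCycles, seeds[3])
    new("TrajectoryEnsemble", X = tr$X, Y = tr$Y, inputDraws = draws,
        eff = eff, input = input, seed = as.integer(seed))
}

setMethod("show", "TrajectoryEnsemble", function(object) {
    cat("TrajectoryEnsemble:", nrow(object@X), "replicates x",
        ncol(object@X) - 1L, "cycles (seed", object@seed, ")\n")
    cat("  final mean N =", signif(mean(object@X[, ncol(object@X)] +
                                        object@Y[, ncol(object@Y)]), 6), "\n")
})

#' @describeIn simulatePCR number of simulated cycles.
#' @param object a `TrajectoryEnsemble`.
#' @export
setMethod("nCycles", "TrajectoryEnsemble",
    function(object) ncol(object@X) - 1L)

#' Empirical per-cycle moments of a simulated ensemble
#'
#' Unbiased sample means, variances and covariances per cycle, the sample
#' covariance of each cycle's forward count with the initial forward count,
#' and standard errors for each quantity (standard errors for variances and
#' covariances use the empirical fourth-moment / delta-method form).
#'
#' @param ensemble a [TrajectoryEnsemble] with at least 2 replicates.
#' @return data.frame with columns `cycle`, `EX`, `EY`, `VarX`, `VarY`,
#'   `CovXY`, `CovX_X0` and matching `se*` columns.
#' @export
ensembleMoments <- function(ensemble) {
    stopifnot(is(ensemble, "TrajectoryEnsemble"))
    X <- ensemble@X
    Y <- ensemble@Y
    nr <- nrow(X)
    if (nr < 2L) stop("at least 2 replicates are required")
    mx <- colMeans(X)
    my <- colMeans(Y)
    cx <- sweep(X, 2, mx)
    cy <- sweep(Y, 2, my)
    fac <- nr / (nr - 1)
    vX <- colMeans(cx^2) * fac
    vY <- colMeans(cy^2) * fac
    cXY <- colMeans(cx * cy) * fac
    cX0 <- colMeans(cx * cx[, 1]) * fac
    seOf <- function(prod, est) {
        # se of a mean-of-products estimator, delta-method
        sqrt(pmax(colMeans(prod^2) - (est * (nr - 1) / nr)^2, 0) / nr)
    }
    data.frame(cycle = as.integer(colnames(X)),
               EX = mx, EY = my, VarX = vX, VarY = vY, CovXY = cXY,
               CovX_X0 = cX0,
               seEX = sqrt(vX / nr), seEY = sqrt(vY / nr),
               seVarX = seOf(cx^2, vX), seVarY = seOf(cy^2, vY),
               seCovXY = seOf(cx * cy, cXY),
               seCovX_X0 = seOf(cx * cx[, 1], cX0))
}

#' Write a trajectory ensemble to CSV
#'
#' Long format, one row per replicate and cycle with integer strand counts.
#'
#' @param ensemble a [TrajectoryEnsemble].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEnsembleCSV <- function(ensemble, path) {
    stopifnot(is(ensemble, "TrajectoryEnsemble"))
    n1 <- ncol(ensemble@X)
    nr <- nrow(ensemble@X)
    df <- data.frame(
        replicate = rep(seq_len(nr), times = n1),
        cycle = rep(as.integer(colnames(ensemble@X)), each = nr),
        X = as.vector(ensemble@X), Y = as.vector(ensemble@Y))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
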