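#' @include efficiency.R input.R
NULL

.checkCycles <- function(nCycles) {
    if (!.scalarOk(nCycles) || nCycles < 0 || nCycles != round(nCycles))
        stop("'nCycles' must be a single nonnegative integer")
    if (nCycles > 500)
        stop("'nCycles' > 500 would overflow double precision ",
             "(lambda1^(2i) grows beyond ~1e308)")
    as.integer(nCycles)
}

#' Expected strand counts per cycle
#'
#' Evaluates the spectral form of the expected counts,
#' `E[U_i] = (z1' E[U_0]) lambda1^i x1 + (z2' E[U_0]) lambda2^i x2`,
#' equivalent to `A^i E[U_0]`, for all cycles `0..nCycles`.
#'
#' @param eff an [EfficiencyParams] object.
#' @param meanU0 numeric(2), expected initial counts `(E[X_0], E[Y_0])`.
#' @param nCycles number of cycles.
#' @return `(nCycles+1) x 2` matrix with columns `X` and `Y`; row `i+1`
#'   holds the expectations after `i` cycles.
#' @examples
#' expectedCounts(EfficiencyParams(0.9), c(5, 5), 2)
#' @export
expectedCounts <- function(eff, meanU0, nCycles) {
    stopifnot(is(eff, "EfficiencyParams"), length(meanU0) == 2L,
              all(meanU0 >= 0))
    n <- .checkCycles(nCycles)
    sdec <- spectralDecomposition(eff)
    i <- 0:n
    w1 <- sum(sdec@Z[1, ] * meanU0)    # z1' E[U0]
    w2 <- sum(sdec@Z[2, ] * meanU0)
    out <- outer(sdec@lambda[1]^i * w1, sdec@X[, 1]) +
           outer(sdec@lambda[2]^i * w2, sdec@X[, 2])
    dimnames(out) <- list(cycle = i, c("X", "Y"))
    out
}

#' Limiting ratio of expected forward to reverse strand counts
#'
#' After the initial lag cycles the ratio `E[X_i] / E[Y_i]` converges to its
#' critical value `R` (whenever `E[Y_i] > 0`), regardless of the input case.
#'
#' @param eff an [EfficiencyParams] object.
#' @return numeric(1), the ratio parameter `R`.
#' @export
ratioLimit <- function(eff) {
    stopifnot(is(eff, "EfficiencyParams"))
    eff@R
}

# K_l matrices of the variance recursion/closed form: per-cycle binomial
# noise projected onto the eigenbasis of A.
.kMatrices <- function(eff, sdec, meanU0) {
    a <- pRf(eff) * (1 - pRf(eff))    # forward-strand production noise
    b <- pFr(eff) * (1 - pFr(eff))    # reverse-strand production noise
    lapply(1:2, function(l) {
        diag(c(a * sdec@X[2, l], b * sdec@X[1, l])) *
            sum(sdec@Z[l, ] * meanU0)
    })
}

#' Variance-covariance of strand counts per cycle (closed form)
#'
#' Evaluates the closed-form solution of the two-type variance recursion
#' `Var[U_i] = A Var[U_(i-1)] A' + sum_l lambda_l^(i-1) K_l`: with
#' `nu_jk = z_j' Var[U_0] z_k` and
#' `eta^l_jk = z_j' K_l z_k / (lambda_j lambda_k - lambda_l)`,
#' `Var[U_i] = sum_jk { (nu_jk + sum_l eta^l_jk) (lambda_j lambda_k)^i -
#' sum_l eta^l_jk lambda_l^i } x_j x_k'`.  After evaluation each matrix is
#' symmetrised by averaging the off-diagonal pair to guard against
#' floating-point asymmetry.
#'
#' @param eff an [EfficiencyParams] object.
#' @param meanU0 numeric(2), expected initial counts.
#' @param varU0 2x2 symmetric initial covariance matrix with nonnegative
#'   diagonal (use [initialMoments()] to derive it from an input model).
#' @param nCycles number of cycles.
#' @return `2 x 2 x (nCycles+1)` array of covariance matrices (copies^2).
#' @examples
#' v <- varianceCounts(EfficiencyParams(0.9), c(5, 5), diag(0, 2), 1)
#' sum(v[, , 2])   # one-cycle Var[N_1] = 10 * 0.9 * 0.1
#' @export
varianceCounts <- function(eff, meanU0, varU0, nCycles) {
    stopifnot(is(eff, "EfficiencyParams"), length(meanU0) == 2L)
    varU0 <- as.matrix(varU0)
    if (!all(dim(varU0) == 2L) || max(abs(varU0 - t(varU0))) > 1e-9)
        stop("'varU0' must be a symmetric 2x2 matrix")
    if (any(diag(varU0) < 0))
        stop("'varU0' must have a nonnegative diagonal")
    n <- .checkCycles(nCycles)
    sdec <- spectralDecomposition(eff)
    lam <- sdec@lambda
    K <- .kMatrices(eff, sdec, meanU0)
    i <- 0:n
    out <- array(0, dim = c(2L, 2L, n + 1L),
                 dimnames = list(c("X", "Y"), c("X", "Y"), cycle = i))
    for (j in 1:2) for (k in 1:2) {
        nu <- drop(sdec@Z[j, ] %*% varU0 %*% sdec@Z[k, ])
        etas <- vapply(1:2, function(l) {
            num <- drop(sdec@Z[j, ] %*% K[[l]] %*% sdec@Z[k, ])
            if (num == 0) return(0)
            den <- lam[j] * lam[k] - lam[l]
            if (abs(den) < 1e-12)
                stop("degenerate eigenvalue combination in variance closed ",
                     "form (lambda_j lambda_k == lambda_l)")
            num / den
        }, numeric(1))
        coefI <- (nu + sum(etas)) * (lam[j] * lam[k])^i -
                 etas[1] * lam[1]^i - etas[2] * lam[2]^i
        xjk <- outer(sdec@X[, j], sdec@X[, k])
        for (q in seq_along(i))
            out[, , q] <- out[, , q] + coefI[q] * xjk
    }
    # symmetrise off-diagonals (guards ~1e-16 fp asymmetry)
    off <- (out[1, 2, ] + out[2, 1, ]) / 2
    out[1, 2, ] <- off
    out[2, 1, ] <- off
    out
}

# Direct iteration of the one-cycle variance recursion.  Used internally as
# a numerical cross-check; the closed form above is the implementation.
.varianceCountsRecursion <- function(eff, meanU0, varU0, nCycles) {
    n <- .checkCycles(nCycles)
    A <- .ampMatrix(eff)
    EU <- expectedCounts(eff, meanU0, n)
    out <- array(0, dim = c(2L, 2L, n + 1L))
    V <- as.matrix(varU0)
    out[, , 1] <- V
    a <- pRf(eff) * (1 - pRf(eff))
    b <- pFr(eff) * (1 - pFr(eff))
    for (q in seq_len(n)) {
        V <- A %*% V %*% t(A) +
            diag(c(a * EU[q, 2], b * EU[q, 1]))
        out[, , q + 1] <- V
    }
    out
}

#' Covariance of a strand count with its initial value
#'
#' `Cov[X_i, X_0] = (Var[X_0] / 2) (lambda1^i + lambda2^i)`; the same form
#' holds for the reverse strand with `Var[Y_0]`.
#'
#' @param eff an [EfficiencyParams] object.
#' @param varX0 variance of the initial count of the strand of interest.
#' @param nCycles number of cycles.
#' @return numeric vector of length `nCycles + 1`.
#' @export
crossCov <- function(eff, varX0, nCycles) {
    stopifnot(is(eff, "EfficiencyParams"), .scalarOk(varX0), varX0 >= 0)
    n <- .checkCycles(nCycles)
    lam <- .lambdas(eff)
    i <- 0:n
    varX0 / 2 * (lam[1]^i + lam[2]^i)
}

#' Conventional single-type moments
#'
#' Closed forms for the branching process that does not distinguish
#' complementary strands (the `R = 1` special case):
#' `E[N_i] = E[N_0] (1 + p)^i` and
#' `Var[N_i] = (Var[N_0] + E[N_0] (1-p)/(1+p)) (1+p)^(2i) -
#'  E[N_0] (1-p) (1+p)^(i-1)`.
#'
#' @param p per-cycle amplification probability, in (0, 1].
#' @param meanN0 expected initial total strand count.
#' @param varN0 variance of the initial total strand count.
#' @param nCycles number of cycles.
#' @return data.frame with columns `cycle`, `EN`, `VarN`.
#' @examples
#' conventionalMoments(0.9, meanN0 = 10, varN0 = 0, nCycles = 3)
#' @export
conventionalMoments <- function(p, meanN0, varN0, nCycles) {
    if (!.scalarOk(p) || p <= 0 || p > 1)
        stop("'p' must be a single probability in (0, 1]")
    stopifnot(meanN0 >= 0, varN0 >= 0)
    n <- .checkCycles(nCycles)
    i <- 0:n
    EN <- meanN0 * (1 + p)^i
    VarN <- (varN0 + meanN0 * (1 - p) / (1 + p)) * (1 + p)^(2 * i) -
        meanN0 * (1 - p) * (1 + p)^(i - 1)
    data.frame(cycle = i, EN = EN, VarN = VarN)
}

#' Asymptotic squared coefficient of variation coefficients
#'
#' The large-cycle limit of every entry of the relative-variance matrix
#' `Var[U_i] / (E[U_i] E[U_i]')` is `alpha * CV[I]^2 + beta / E[I]`, with
#' `alpha` and `beta` depending only on the reaction efficiencies and the
#' input case:
#' \describe{
#'   \item{Case D}{`alpha = (R^2 + 1) / (R + 1)^2`;
#'     `beta = (lambda2/lambda1)/2 -
#'      (pBar lambda1 / (lambda1^2 - lambda2)) ((R-1)/(R+1))^2 / 2`.}
#'   \item{Case RF}{`alpha = 1`; `beta = (1-r)/r +
#'     (lambda2/lambda1)(R+1)/(2 R r) -
#'     (pBar lambda1 / (lambda1^2 - lambda2)) (R-1)/(2 R r)`.}
#'   \item{Case RR}{`alpha = 1`; `beta = (1-r)/r +
#'     (lambda2/lambda1)(R+1)/(2 r) +
#'     (pBar lambda1 / (lambda1^2 - lambda2)) (R-1)/(2 r)`.}
#' }
#'
#' @param eff an [EfficiencyParams] object (its `r` is used for RNA cases).
#' @param case input case, `"D"`, `"RF"` or `"RR"`.
#' @return named numeric(2), `c(alpha = , beta = )`.
#' @examples
#' alphaBeta(EfficiencyParams(0.9), "D")   # alpha 0.5, beta ~0.0263
#' @export
alphaBeta <- function(eff, case = c("D", "RF", "RR")) {
    stopifnot(is(eff, "EfficiencyParams"))
    case <- match.arg(case)
    ab <- .alphaBetaVec(eff@pBar, eff@R, eff@r, case)
    c(alpha = ab$alpha, beta = ab$beta)
}

# vectorised alpha/beta kernel shared with the LOD grid scan
.alphaBetaVec <- function(pBar, R, r, case) {
    l1 <- 1 + pBar
    l2 <- 1 - pBar
    g <- pBar * l1 / (l1^2 - l2)
    if (case == "D") {
        alpha <- (R^2 + 1) / (R + 1)^2
        beta <- (l2 / l1) / 2 - g * ((R - 1) / (R + 1))^2 / 2
    } else {
        if (any(is.na(r)))
            stop("reverse-transcription efficiency 'r' is required for case ",
                 case)
        alpha <- rep(1, length.out = max(length(pBar), length(R), length(r)))
        beta <- if (case == "RF")
            (1 - r) / r + (l2 / l1) * (R + 1) / (2 * R * r) -
                g * (R - 1) / (2 * R * r)
        else
            (1 - r) / r + (l2 / l1) * (R + 1) / (2 * r) +
                g * (R - 1) / (2 * r)
    }
    list(alpha = alpha, beta = beta)
}

#' Asymptotic squared coefficient of variation of the strand counts
#'
#' Evaluates `alpha * CV[I]^2 + beta / E[I]` for the given efficiencies and
#' input model, the cycle-independent limit that every entry of
#' `Var[U_i] / (E[U_i] E[U_i]')` approaches at rate `O(lambda1^-i)`.
#'
#' @param eff an [EfficiencyParams] object.
#' @param input an [InputDistribution] object with positive mean.
#' @return numeric(1).
#' @export
asymptoticCV2 <- function(eff, input) {
    stopifnot(is(eff, "EfficiencyParams"), is(input, "InputDistribution"))
    if (input@meanI <= 0)
        stop("'meanI' must be positive (CV of the input is undefined at 0)")
    ab <- alphaBeta(eff, input@case)
    ab[["alpha"]] * input@varI / input@meanI^2 + ab[["beta"]] / input@meanI
}

# ---------------------------------------------------------------------------
# MomentTrajectory
# ---------------------------------------------------------------------------

#' Compute all strand-count moments for cycles 0..n
#'
#' One-pass computation of expected counts, covariance matrices and the
#' covariances with the initial counts, cached in a [MomentTrajectory].
#' Initial moments are derived from `input` via [initialMoments()], or can
#' be supplied directly through `meanU0` / `varU0`.
#'
#' @param eff an [EfficiencyParams] object.
#' @param input an [InputDistribution] object, or `NULL` when `meanU0` and
#'   `varU0` are given explicitly.
#' @param nCycles number of cycles.
#' @param meanU0,varU0 optional explicit initial moments overriding `input`.
#' @return a [MomentTrajectory] object.
#' @examples
#' traj <- momentTrajectory(EfficiencyParams(0.9),
#'                          InputDistribution("D", meanI = 5), nCycles = 10)
#' head(as.data.frame(traj))
#' @export
momentTrajectory <- function(eff, input = NULL, nCycles, meanU0 = NULL,
                             varU0 = NULL) {
    stopifnot(is(eff, "EfficiencyParams"))
    if (is.null(meanU0) || is.null(varU0)) {
        if (is.null(input))
            stop("either 'input' or both 'meanU0' and 'varU0' must be given")
        m0 <- initialMoments(input, eff)
        if (is.null(meanU0)) meanU0 <- m0$mean
        if (is.null(varU0)) varU0 <- m0$var
    }
    n <- .checkCycles(nCycles)
    varU0 <- as.matrix(varU0)
    new("MomentTrajectory",
        cycles = 0:n,
        meanU = expectedCounts(eff, meanU0, n),
        varU = varianceCounts(eff, meanU0, varU0, n),
        covXX0 = crossCov(eff, varU0[1, 1], n),
        covYY0 = crossCov(eff, varU0[2, 2], n),
        eff = eff, input = input)
}

#' @describeIn momentTrajectory number of amplification cycles covered.
#' @param object a `MomentTrajectory` object.
#' @export
setMethod("nCycles", "MomentTrajectory",
    function(object) length(object@cycles) - 1L)

#' @describeIn momentTrajectory `(n+1) x 2` matrix of expected counts.
#' @export
setMethod("meanCounts", "MomentTrajectory", function(object) object@meanU)

#' @describeIn momentTrajectory `2 x 2 x (n+1)` covariance array.
#' @export
setMethod("varCounts", "MomentTrajectory", function(object) object@varU)

#' @describeIn momentTrajectory per-cycle covariance of a strand count with
#'   its initial value.
#' @param strand `"forward"` for `Cov[X_i, X_0]`, `"reverse"` for
#'   `Cov[Y_i, Y_0]`.
#' @export
setMethod("covWithInitial", "MomentTrajectory",
    function(object, strand = c("forward", "reverse")) {
        strand <- match.arg(strand)
        if (strand == "forward") object@covXX0 else object@covYY0
    })

setMethod("show", "MomentTrajectory", function(object) {
    n <- nCycles(object)
    cat("MomentTrajectory over cycles 0..", n, "\n", sep = "")
    cat("  E[U_", n, "] = (", signif(object@meanU[n + 1, 1], 6), ", ",
        signif(object@meanU[n + 1, 2], 6), ")\n", sep = "")
    cat("  Var[X_", n, "] = ", signif(object@varU[1, 1, n + 1], 6),
        "  Var[Y_", n, "] = ", signif(object@varU[2, 2, n + 1], 6),
        "\n", sep = "")
})

#' Tabulate a moment trajectory
#'
#' @param x a [MomentTrajectory] object.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame with columns `cycle`, `EX`, `EY`, `VarX`, `VarY`,
#'   `CovXY`, `CovX_X0`.
#' @export
as.data.frame.MomentTrajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(cycle = x@cycles,
               EX = x@meanU[, 1], EY = x@meanU[, 2],
               VarX = x@varU[1, 1, ], VarY = x@varU[2, 2, ],
               CovXY = x@varU[1, 2, ], CovX_X0 = x@covXX0)
}

#' Write a moment trajectory to CSV
#'
#' @param traj a [MomentTrajectory] object (or the data.frame produced by
#'   [ensembleMoments()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMomentTrajectory <- function(traj, path) {
    df <- if (is.data.frame(traj)) traj else as.data.frame(traj)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
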