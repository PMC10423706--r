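#' @include fluorescence.R
NULL

#' Limit of detection at a single parameter point
#'
#' Detection after `n` cycles requires the fluorescence to exceed its
#' background by at least `kappa` standard deviations, which (using the
#' cycle-independent asymptote of the squared CV) reduces to
#' `E[I] >= (chi * alpha + beta) * kappa^2`.  The limit of detection is the
#' smallest positive integer satisfying the bound (the inequality is
#' non-strict: an exactly integer threshold is itself the limit, and an
#' expected input of 0 copies is never considered detectable, so `L >= 1`),
#' and `M = sqrt(chi / L)` is the largest detectable input CV.
#'
#' @param eff an [EfficiencyParams] object (its `r` is used for RNA cases).
#' @param case input case, `"D"`, `"RF"` or `"RR"`.
#' @param chi input variance-to-mean ratio (1 for Poisson input).
#' @param kappa standard-deviation multiplier of the detection rule.
#' @return an [LODResult] object.
#' @examples
#' lodPoint(EfficiencyParams(0.9, 1), "D")          # L = 5, M ~ 0.447
#' @export
lodPoint <- function(eff, case = c("D", "RF", "RR"), chi = 1, kappa = 3) {
    stopifnot(is(eff, "EfficiencyParams"), chi > 0, kappa > 0)
    case <- match.arg(case)
    ab <- alphaBeta(eff, case)
    thr <- (chi * ab[["alpha"]] + ab[["beta"]]) * kappa^2
    if (!is.finite(thr)) stop("non-finite detection threshold")
    L <- max(1L, as.integer(ceiling(thr - 1e-12 * abs(thr))))
    if (L < thr - 1e-9) L <- L + 1L   # guard: L must satisfy L >= threshold
    new("LODResult", L = L, M = sqrt(chi / L), alpha = ab[["alpha"]],
        beta = ab[["beta"]], pBar = eff@pBar, R = eff@R, r = eff@r,
        chi = as.numeric(chi), kappa = as.numeric(kappa), case = case)
}

#' @describeIn lodPoint smallest reliably detectable expected input copies.
#' @param object an `LODResult`.
#' @export
setMethod("detectionLimit", "LODResult", function(object) object@L)

#' @describeIn lodPoint largest detectable input coefficient of variation.
#' @export
setMethod("maxDetectableCV", "LODResult", function(object) object@M)

setMethod("show", "LODResult", function(object) {
    cat("LODResult (case ", object@case, "): L = ", object@L,
        " copies, M = ", signif(object@M, 4), "\n", sep = "")
    cat("  at pBar =", object@pBar, " R =", object@R,
        if (!is.na(object@r)) paste(" r =", object@r) else "",
        " chi =", object@chi, " kappa =", object@kappa, "\n")
    cat("  alpha =", signif(object@alpha, 6), " beta =",
        signif(object@beta, 6), "\n")
})

#' Limit-of-detection scan over a parameter grid
#'
#' Evaluates the asymptotic detectability criterion over the Cartesian grid
#' of `pBar`, `R` and (for RNA cases) `r` values.  The default grid is 100
#' equally spaced values of `pBar` in [0.8, 0.99], `R` in [0.9, 1.1] and
#' `r` in [0.2, 0.99], endpoints included; for case D the `r` dimension is
#' collapsed.  The scan is a vectorised closed-form evaluation (about 10^6
#' points for the RNA cases).
#'
#' @param case input case.
#' @param pBarGrid,RGrid,rGrid numeric grids of parameter values.
#' @param chi,kappa as in [lodPoint()].
#' @return data.frame with columns `p_bar`, `R`, `r`, `alpha`, `beta`, `L`,
#'   `M`; see [lodSummary()] for the extremes.
#' @examples
#' g <- lodGrid("D", pBarGrid = seq(0.8, 0.99, length.out = 10),
#'              RGrid = seq(0.9, 1.1, length.out = 10))
#' lodSummary(g)$range
#' @export
lodGrid <- function(case = c("D", "RF", "RR"),
                    pBarGrid = seq(0.8, 0.99, length.out = 100),
                    RGrid = seq(0.9, 1.1, length.out = 100),
                    rGrid = seq(0.2, 0.99, length.out = 100),
                    chi = 1, kappa = 3) {
    case <- match.arg(case)
    stopifnot(length(pBarGrid) >= 1, length(RGrid) >= 1, chi > 0, kappa > 0)
    if (case == "D") rGrid <- NA_real_
    grid <- expand.grid(p_bar = pBarGrid, R = RGrid, r = rGrid,
                        KEEP.OUT.ATTRS = FALSE)
    ab <- .alphaBetaVec(grid$p_bar, grid$R, grid$r, case)
    thr <- (chi * ab$alpha + ab$beta) * kappa^2
    L <- pmax(1, ceiling(thr - 1e-12 * abs(thr)))
    L <- L + (L < thr - 1e-9)
    data.frame(grid, alpha = ab$alpha, beta = ab$beta, L = as.integer(L),
               M = sqrt(chi / L))
}

#' Summarise a limit-of-detection grid
#'
#' @param grid the data.frame returned by [lodGrid()].
#' @return list with `range` (`c(minL, maxL)`), `M` (the CV limits paired
#'   with the extremes: max M at min L, min M at max L), and `argmin` /
#'   `argmax` (one grid row attaining each extreme).
#' @export
lodSummary <- function(grid) {
    stopifnot(is.data.frame(grid), "L" %in% names(grid))
    lo <- min(grid$L)
    hi <- max(grid$L)
    chi <- grid$M[1]^2 * grid$L[1]
    list(range = c(minL = lo, maxL = hi),
         M = c(maxM = sqrt(chi / lo), minM = sqrt(chi / hi)),
         argmin = grid[which.min(grid$L), , drop = FALSE],
         argmax = grid[which.max(grid$L), , drop = FALSE])
}

#' Write a limit-of-detection grid with summary
#'
#' Writes the grid CSV (`p_bar, R, r, alpha, beta, L, M`) and, beside it, a
#' small `*_summary.csv` with the extremes and the parameter points
#' attaining them.
#'
#' @param grid the data.frame returned by [lodGrid()].
#' @param path grid CSV path.
#' @return the path, invisibly.
#' @export
writeLODGridCSV <- function(grid, path) {
    write.csv(grid, path, row.names = FALSE)
    s <- lodSummary(grid)
    sm <- rbind(cbind(extreme = "min", s$argmin),
                cbind(extreme = "max", s$argmax))
    write.csv(sm, sub("\\.csv$", "_summary.csv", path), row.names = FALSE)
    invisible(path)
}

#' Exact finite-cycle detectability check
#'
#' Evaluates the exact-moment detection inequality
#' `E[F_n] - kappa * sqrt(Var[F_n]) >= b_n` well by well (not the
#' asymptote), plus the well-independent criterion
#' `CV[DeltaX_n]^2 <= 1 / kappa^2` (the incremental parameter `d` cancels).
#' An input with zero expected copies is infeasible everywhere.
#'
#' @param eff an [EfficiencyParams] object.
#' @param input an [InputDistribution].
#' @param params a [FluorescenceParams] with at least `nCycles` rows.
#' @param nCycles cycle at which detection is assessed (>= 1).
#' @param kappa standard-deviation multiplier.
#' @return list with `feasibleWell` (named logical per well),
#'   `cvCriterion` (logical) and `cvDeltaX2` (the exact squared CV).
#' @export
feasibilityCheck <- function(eff, input, params, nCycles, kappa = 3) {
    stopifnot(is(params, "FluorescenceParams"), nCycles >= 1,
              nrow(params@b) >= nCycles)
    traj <- momentTrajectory(eff, input, nCycles)
    n1 <- nCycles + 1L
    mu <- traj@meanU[n1, 1] - traj@meanU[1, 1]
    vv <- traj@varU[1, 1, n1] + traj@varU[1, 1, 1] - 2 * traj@covXX0[n1]
    d <- params@d[nCycles, ]
    feas <- if (mu <= 0) rep(FALSE, length(d))
            else d * (mu - kappa * sqrt(max(vv, 0))) >= 0
    names(feas) <- colnames(params@d)
    cv2 <- if (mu > 0) vv / mu^2 else Inf
    list(feasibleWell = feas, cvCriterion = cv2 <= 1 / kappa^2,
         cvDeltaX2 = cv2)
}
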