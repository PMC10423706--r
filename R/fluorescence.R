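#' @include plates-io.R moments.R
NULL

#' Fit molar fluorescence from no-template control plates
#'
#' With no template present the measured fluorescence is `F = f * C`, so
#' repeating the control at `q` probe concentrations gives, per cycle and
#' well, a regression through the origin whose least-squares solution is
#' `f = sum_j F_j C_j / sum_j C_j^2`.  The per-plate ratios `F_j / C_j` are
#' taken as i.i.d. normal about `f`, so the pointwise dispersion estimate
#' `sigma = ||F/C - f|| / sqrt(q - 1)` is on the same scale as `f` (its
#' ratio `sigma / f` is the coefficient of variation summarised by
#' [qcSummary()]).  With a single plate (`q = 1`) the fit degenerates to
#' pointwise division and `sigma` is reported missing (`NA`), not zero.
#'
#' @param plates list of [ProbePlate] objects of one probe state, sharing
#'   the cycle/well grid, with distinct concentrations when `q > 1`.
#' @return list with matrices `f` and `sigma` (cycle x well), the
#'   concentration vector `C` and the shared `probeState`.
#' @examples
#' p <- lapply(1:3, function(j) ProbePlate(matrix(2 * j, 4, 4), j,
#'             "inactive", paste0("c", j)))
#' fitMolarFluorescence(p)$f[1, 1]   # exactly 2
#' @export
fitMolarFluorescence <- function(plates) {
    if (is(plates, "ProbePlate")) plates <- list(plates)
    stopifnot(length(plates) >= 1L,
              all(vapply(plates, is, logical(1), "ProbePlate")))
    states <- vapply(plates, probeState, character(1))
    if (length(unique(states)) != 1L)
        stop("all plates must share one probe state")
    dims <- vapply(plates, dim, integer(2))
    if (any(dims != dims[, 1]))
        stop("all plates must share the cycle/well grid")
    C <- vapply(plates, probeConcentration, numeric(1))
    if (all(C == 0)) stop("concentrations must not all be zero")
    q <- length(plates)
    if (q > 1L && anyDuplicated(C))
        stop("plates must have distinct concentrations when q > 1")
    Fs <- lapply(plates, assay, "fluorescence")
    num <- Reduce(`+`, Map(function(m, c) m * c, Fs, C))
    f <- num / sum(C^2)
    if (q == 1L) {
        f <- Fs[[1]] / C
        sigma <- array(NA_real_, dim = dim(f), dimnames = dimnames(f))
    } else {
        rss <- Reduce(`+`, Map(function(m, c) (m / c - f)^2, Fs, C))
        sigma <- sqrt(rss / (q - 1))
    }
    list(f = f, sigma = sigma, C = C, probeState = states[1])
}

#' Combine inactive- and active-probe fits
#'
#' @param fMinus,sigmaMinus inactive-probe molar fluorescence and
#'   dispersion (cycle x well matrices); `sigma` matrices may be `NULL`
#'   (stored as `NA`).
#' @param fPlus,sigmaPlus the same for the active probe.
#' @return a [MolarFluorescence] object.
#' @export
MolarFluorescence <- function(fMinus, fPlus, sigmaMinus = NULL,
                              sigmaPlus = NULL) {
    fMinus <- as.matrix(fMinus)
    fPlus <- as.matrix(fPlus)
    naLike <- function(s, f) {
        if (is.null(s)) array(NA_real_, dim(f), dimnames(f)) else as.matrix(s)
    }
    new("MolarFluorescence", fMinus = fMinus, fPlus = fPlus,
        sigmaMinus = naLike(sigmaMinus, fMinus),
        sigmaPlus = naLike(sigmaPlus, fPlus))
}

setMethod("show", "MolarFluorescence", function(object) {
    cat("MolarFluorescence:", nrow(object@fMinus), "cycles x",
        ncol(object@fMinus), "wells\n")
    cat("  median f- =", signif(stats::median(object@fMinus), 4),
        "  median f+ =", signif(stats::median(object@fPlus), 4), "L/mol\n")
})

#' Read and write molar-fluorescence tables
#'
#' CSV with columns `cycle, well, f_minus, sigma_minus, f_plus,
#' sigma_plus`.
#'
#' @param path CSV file path.
#' @return `readMolarFluorescenceCSV`: a [MolarFluorescence] object.
#' @export
readMolarFluorescenceCSV <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("cycle", "well", "f_minus", "sigma_minus", "f_plus",
              "sigma_plus")
    if (!all(need %in% names(df)))
        stop("molar-fluorescence CSV must have columns: ",
             paste(need, collapse = ", "))
    cyc <- sort(unique(df$cycle))
    wells <- unique(df$well)
    mk <- function(col) {
        m <- matrix(NA_real_, length(cyc), length(wells),
                    dimnames = list(cyc, wells))
        m[cbind(match(df$cycle, cyc), match(df$well, wells))] <- df[[col]]
        m
    }
    MolarFluorescence(mk("f_minus"), mk("f_plus"), mk("sigma_minus"),
                      mk("sigma_plus"))
}

#' @rdname readMolarFluorescenceCSV
#' @param mf a [MolarFluorescence] object.
#' @return `writeMolarFluorescenceCSV`: the path, invisibly.
#' @export
writeMolarFluorescenceCSV <- function(mf, path) {
    stopifnot(is(mf, "MolarFluorescence"))
    m <- mf@fMinus
    wells <- colnames(m)
    if (is.null(wells)) wells <- plateWellLabels(ncol(m))
    df <- data.frame(
        cycle = rep(seq_len(nrow(m)), times = ncol(m)),
        well = rep(wells, each = nrow(m)),
        f_minus = as.vector(mf@fMinus),
        sigma_minus = as.vector(mf@sigmaMinus),
        f_plus = as.vector(mf@fPlus),
        sigma_plus = as.vector(mf@sigmaPlus))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Derive background and incremental fluorescence parameters
#'
#' `b = fMinus * C` and `d = (fPlus - fMinus) / (V * N_A)`, per cycle and
#' well, with `N_A` the Avogadro constant.
#'
#' @param mf a [MolarFluorescence] object.
#' @param C total probe concentration, mol/L (see [pmolPerL()]).
#' @param V reaction volume, litres (see [microliters()]).
#' @return a [FluorescenceParams] object.
#' @examples
#' mf <- MolarFluorescence(matrix(8e12, 2, 2), matrix(2.0044e13, 2, 2))
#' p <- deriveFluorParams(mf, C = pmolPerL(0.125), V = microliters(20))
#' p@b[1, 1]   # ~1
#' @export
deriveFluorParams <- function(mf, C, V) {
    stopifnot(is(mf, "MolarFluorescence"))
    bad <- which(mf@fPlus <= mf@fMinus, arr.ind = TRUE)
    if (nrow(bad)) {
        wells <- colnames(mf@fMinus)
        w <- if (is.null(wells)) bad[1, 2] else wells[bad[1, 2]]
        stop("fPlus <= fMinus at cycle ", bad[1, 1], ", well ", w,
             if (nrow(bad) > 1) sprintf(" (and %d more entries)",
                                        nrow(bad) - 1L) else "")
    }
    new("FluorescenceParams", b = mf@fMinus * C,
        d = (mf@fPlus - mf@fMinus) / (V * .AVOGADRO),
        conc = as.numeric(C), vol = as.numeric(V))
}

#' Constant background/incremental parameters
#'
#' Convenience constructor for a [FluorescenceParams] surface that is flat
#' across cycles and wells, as used for idealised curve calculations.
#'
#' @param b background fluorescence (scalar).
#' @param d incremental fluorescence per synthesised strand (scalar).
#' @param nCycles,nWells grid dimensions.
#' @param C,V probe concentration (mol/L) and volume (litres).
#' @return a [FluorescenceParams] object.
#' @export
constantFluorParams <- function(b = 1, d = 1e-6, nCycles = 45, nWells = 1,
                                C = pmolPerL(0.125), V = microliters(20)) {
    dn <- list(seq_len(nCycles), plateWellLabels(nWells))
    new("FluorescenceParams",
        b = matrix(b, nCycles, nWells, dimnames = dn),
        d = matrix(d, nCycles, nWells, dimnames = dn),
        conc = as.numeric(C), vol = as.numeric(V))
}

#' @describeIn deriveFluorParams background fluorescence matrix.
#' @param object a `FluorescenceParams` object.
#' @export
setMethod("background", "FluorescenceParams", function(object) object@b)

#' @describeIn deriveFluorParams incremental fluorescence matrix.
#' @export
setMethod("incremental", "FluorescenceParams", function(object) object@d)

setMethod("show", "FluorescenceParams", function(object) {
    cat("FluorescenceParams:", nrow(object@b), "cycles x", ncol(object@b),
        "wells\n")
    cat("  median b =", signif(stats::median(object@b), 4),
        "  median d =", signif(stats::median(object@d), 4), "\n")
    cat("  C =", format(object@conc, digits = 4), "mol/L  V =",
        format(object@vol, digits = 4), "L\n")
})

#' Fluorescence mean, variance and normal band
#'
#' Combines the branching-process moments with the probe model
#' `F = b + d * DeltaX` (hydrolysis chemistry; `DeltaX_i = X_i - X_0` is
#' the number of monitored strands synthesised): `E[F] = b + d E[DeltaX]`
#' and `Var[F] = d^2 Var[DeltaX]` with
#' `Var[DeltaX_i] = Var[X_i] + Var[X_0] - 2 Cov[X_i, X_0]`.  For probes
#' that anneal to the monitored strand instead (`chemistry = "annealing"`)
#' the fluorescence read at cycle `i` reflects `X_(i-1)`, so
#' `E[F] = b + d E[X_(i-1)]` and `Var[F] = d^2 Var[X_(i-1)]`.  By default
#' the probe binds the reverse strand so fluorescence tracks forward-strand
#' synthesis; `monitored = "reverse"` swaps strands for the mirrored
#' chemistry.
#'
#' @param params a [FluorescenceParams] object with `n` cycle rows.
#' @param traj a [MomentTrajectory] covering at least cycles `0..n`.
#' @param kappa standard-deviation multiplier for the reported band.
#' @param chemistry `"hydrolysis"` (default) or `"annealing"`.
#' @param monitored strand whose synthesis the probe reports.
#' @return a [FluorescenceCurve] object over cycles `1..n`.
#' @examples
#' traj <- momentTrajectory(EfficiencyParams(0.9),
#'                          InputDistribution("D", meanI = 64), 45)
#' curve <- fluorescenceMoments(constantFluorParams(), traj)
#' @export
fluorescenceMoments <- function(params, traj, kappa = 3,
                                chemistry = c("hydrolysis", "annealing"),
                                monitored = c("forward", "reverse")) {
    stopifnot(is(params, "FluorescenceParams"), is(traj, "MomentTrajectory"))
    chemistry <- match.arg(chemistry)
    monitored <- match.arg(monitored)
    n <- nrow(params@b)
    if (nCycles(traj) < n)
        stop("'traj' must cover cycles 0..", n)
    s <- if (monitored == "forward") 1L else 2L
    mAll <- traj@meanU[, s]
    vAll <- traj@varU[s, s, ]
    cc <- covWithInitial(traj, monitored)
    i <- seq_len(n)
    if (chemistry == "hydrolysis") {
        mu <- mAll[i + 1L] - mAll[1L]
        vv <- pmax(vAll[i + 1L] + vAll[1L] - 2 * cc[i + 1L], 0)
    } else {
        mu <- mAll[i]          # X_(i-1): annealing reads the previous cycle
        vv <- vAll[i]
    }
    meanF <- params@b + params@d * mu
    varF <- params@d^2 * vv
    sdF <- sqrt(varF)
    new("FluorescenceCurve", meanF = meanF, varF = varF,
        lo = meanF - kappa * sdF, hi = meanF + kappa * sdF,
        kappa = as.numeric(kappa))
}

setMethod("show", "FluorescenceCurve", function(object) {
    cat("FluorescenceCurve:", nrow(object@meanF), "cycles x",
        ncol(object@meanF), "wells (kappa =", object@kappa, ")\n")
    n <- nrow(object@meanF)
    cat("  final-cycle mean F:", signif(range(object@meanF[n, ]), 5), "\n")
})

#' Write a fluorescence curve to CSV
#'
#' Columns `cycle, well, mean_F, sd_F, lo, hi`.
#'
#' @param curve a [FluorescenceCurve].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFluorescenceCurveCSV <- function(curve, path) {
    stopifnot(is(curve, "FluorescenceCurve"))
    m <- curve@meanF
    wells <- colnames(m)
    if (is.null(wells)) wells <- plateWellLabels(ncol(m))
    df <- data.frame(
        cycle = rep(seq_len(nrow(m)), times = ncol(m)),
        well = rep(wells, each = nrow(m)),
        mean_F = as.vector(m), sd_F = as.vector(sqrt(curve@varF)),
        lo = as.vector(curve@lo), hi = as.vector(curve@hi))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Exact squared coefficient of variation of background-subtracted
#' fluorescence
#'
#' Because the incremental parameter `d` cancels,
#' `CV[F - b]^2 = Var[DeltaX_i] / E[DeltaX_i]^2`, independent of well.  It
#' converges to the asymptote `alpha CV[I]^2 + beta / E[I]` (see
#' [asymptoticCV2()]) at rate `O(lambda1^-i)`.
#'
#' @param eff an [EfficiencyParams] object.
#' @param input an [InputDistribution] with positive mean.
#' @param nCycles number of cycles.
#' @return numeric vector over cycles `1..nCycles`.
#' @export
fluorescenceCV2 <- function(eff, input, nCycles) {
    stopifnot(is(input, "InputDistribution"))
    if (input@meanI <= 0)
        stop("'meanI' must be positive (CV undefined at 0)")
    traj <- momentTrajectory(eff, input, nCycles)
    i <- seq_len(nCycles)
    mu <- traj@meanU[i + 1L, 1] - traj@meanU[1L, 1]
    vv <- traj@varU[1, 1, i + 1L] + traj@varU[1, 1, 1L] -
        2 * traj@covXX0[i + 1L]
    setNames(vv / mu^2, i)
}

#' QC summary of a molar-fluorescence table
#'
#' Tabulates the pointwise coefficient of variation `sigma / f` for each
#' probe state and flags entries above a threshold (default 0.022, a
#' conservative outlier boundary for the inactive probe).
#'
#' @param mf a [MolarFluorescence] with dispersions present (fits with
#'   `q >= 2`).
#' @param threshold CV flagging threshold.
#' @return data.frame with columns `probe_state`, `cycle`, `well`, `cv`,
#'   `flagged`; the threshold is attached as attribute `"threshold"`.
#' @export
qcSummary <- function(mf, threshold = 0.022) {
    stopifnot(is(mf, "MolarFluorescence"))
    if (all(is.na(mf@sigmaMinus)) && all(is.na(mf@sigmaPlus)))
        stop("no dispersion estimates present (fits used a single plate)")
    wells <- colnames(mf@fMinus)
    if (is.null(wells)) wells <- plateWellLabels(ncol(mf@fMinus))
    one <- function(state, f, s) {
        data.frame(probe_state = state,
                   cycle = rep(seq_len(nrow(f)), times = ncol(f)),
                   well = rep(wells, each = nrow(f)),
                   cv = as.vector(s / f))
    }
    df <- rbind(one("inactive", mf@fMinus, mf@sigmaMinus),
                one("active", mf@fPlus, mf@sigmaPlus))
    df <- df[!is.na(df$cv), , drop = FALSE]
    df$flagged <- df$cv > threshold
    attr(df, "threshold") <- threshold
    df
}
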