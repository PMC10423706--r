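makePlates <- function(Fs, C, state = "inactive") {
    Map(function(m, cc, j) ProbePlate(m, cc, state, paste0("p", j)),
        Fs, C, seq_along(C))
}

test_that("molar-fluorescence fit solves regression through the origin", {
    # noiseless line through the origin is recovered exactly
    fTrue <- matrix(c(2, 3, 4, 5), 2, 2)
    C <- c(1e-13, 2e-13, 4e-13)
    fit <- fitMolarFluorescence(makePlates(lapply(C, function(cc) fTrue * cc),
                                           C))
    expect_equal(fit$f, fTrue, ignore_attr = TRUE)
    expect_equal(max(fit$sigma), 0)

    # small noisy instance against the normal-equation arithmetic
    C <- c(1, 2, 3)
    F <- c(2.1, 3.9, 6.0)
    fit <- fitMolarFluorescence(makePlates(lapply(F, function(x)
        matrix(x, 1, 1)), C))
    expect_equal(fit$f[1, 1], 27.9 / 14)
    expect_equal(fit$f[1, 1], oracleGridLS(C, F), tolerance = 1e-7)
    # dispersion of the per-plate ratios about the fit, on f's scale
    expect_equal(fit$sigma[1, 1],
                 sqrt(sum((F / C - fit$f[1, 1])^2) / 2))

    # single plate: pointwise division, dispersion missing (not zero)
    fit1 <- fitMolarFluorescence(makePlates(list(matrix(4, 1, 1)), 2))
    expect_equal(fit1$f[1, 1], 2)
    expect_true(is.na(fit1$sigma[1, 1]))

    expect_error(fitMolarFluorescence(makePlates(
        list(matrix(1, 1, 1), matrix(1, 1, 1)), c(1, 1))), "distinct")
})

test_that("least-squares fit matches a grid-search minimiser on random instances", {
    set.seed(31)
    for (q in 1:30) {
        qn <- sample(2:5, 1)
        C <- sort(runif(qn, 0.5, 4))
        fTrue <- runif(1, 0.5, 10)
        F <- fTrue * C * (1 + rnorm(qn, 0, 0.05))
        fit <- fitMolarFluorescence(makePlates(lapply(F, function(x)
            matrix(x, 1, 1)), C))
        expect_equal(fit$f[1, 1], oracleGridLS(C, F),
                     tolerance = 1e-7)
    }
})

test_that("background and incremental parameters follow the unit arithmetic", {
    mf <- MolarFluorescence(matrix(8e12, 3, 2),
                            matrix(8e12 + 1.20443e13, 3, 2))
    p <- deriveFluorParams(mf, C = 1.25e-13, V = 2e-5)
    expect_equal(p@b[1, 1], 1.0)
    expect_equal(p@d[2, 2], 1.20443e13 / (2e-5 * 6.02214076e23))
    expect_equal(p@d[1, 1], 1e-6, tolerance = 1e-4)
    expect_equal(pmolPerL(0.125), 1.25e-13)
    expect_equal(microliters(20), 2e-5)

    # equal molar fluorescences are rejected, naming the offending entry
    bad <- matrix(8e12, 2, 2)
    bad2 <- bad
    bad2[2, 1] <- bad[2, 1]    # fPlus == fMinus there
    bad2[1, ] <- 9e12
    bad2[2, 2] <- 9e12
    expect_error(MolarFluorescence(bad, bad2), "fPlus")
    mfBad <- MolarFluorescence(bad, bad + 1)
    mfBad@fPlus[2, 1] <- bad[2, 1]
    expect_error(deriveFluorParams(mfBad, 1e-13, 2e-5), "cycle 2")
})

test_that("fluorescence moments combine the probe model with strand moments", {
    # no amplification: curve equals the background surface
    params <- constantFluorParams(b = 1, d = 1e-6, nCycles = 10)
    traj0 <- momentTrajectory(EfficiencyParams(0.9),
                              InputDistribution("D", meanI = 0), 10)
    cv <- fluorescenceMoments(params, traj0)
    expect_equal(cv@meanF, params@b, ignore_attr = TRUE)
    expect_equal(max(cv@varF), 0)

    # deterministic input: mean follows the lambda1 power law
    traj <- momentTrajectory(EfficiencyParams(0.9, 1),
                             InputDistribution("D", meanI = 100,
                                               family = "fixed"), 20)
    curve <- fluorescenceMoments(constantFluorParams(nCycles = 20), traj)
    expect_equal(curve@meanF[20, 1], 1 + 1e-6 * 100 * (1.9^20 - 1),
                 tolerance = 1e-12)
    # band construction
    expect_equal(curve@hi, curve@meanF + 3 * sqrt(curve@varF))

    # rs-RNA input: the mean fluorescence is independent of R
    mkMean <- function(R) {
        eff <- EfficiencyParams(0.85, R, r = 0.6)
        traj <- momentTrajectory(eff, InputDistribution("RR", meanI = 40),
                                 15)
        fluorescenceMoments(constantFluorParams(nCycles = 15), traj)@meanF
    }
    m1 <- mkMean(0.9)
    m2 <- mkMean(1.1)
    expect_equal(m1, m2, tolerance = 1e-12)
    # and matches the closed form b + (r d / 2) E[I] (l1^i + l2^i - 2)
    i <- 1:15
    expect_equal(m1[, 1],
                 1 + (0.6 * 1e-6 / 2) * 40 * (1.85^i + 0.15^i - 2),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("annealing chemistry reads the previous cycle's monitored strand", {
    eff <- EfficiencyParams(0.9, 1)
    input <- InputDistribution("D", meanI = 50)
    traj <- momentTrajectory(eff, input, 10)
    params <- constantFluorParams(nCycles = 10)
    ann <- fluorescenceMoments(params, traj, chemistry = "annealing")
    expect_equal(ann@meanF[, 1], 1 + 1e-6 * meanCounts(traj)[1:10, 1],
                 ignore_attr = TRUE)
    expect_equal(ann@varF[, 1], 1e-12 * varCounts(traj)[1, 1, 1:10],
                 ignore_attr = TRUE)
    # the mirrored probe orientation tracks the reverse strand
    effA <- EfficiencyParams(0.8, 1.1, r = 0.5)
    trajA <- momentTrajectory(effA, InputDistribution("RF", meanI = 30), 10)
    fwd <- fluorescenceMoments(params, trajA, monitored = "forward")
    rev <- fluorescenceMoments(params, trajA, monitored = "reverse")
    expect_false(isTRUE(all.equal(fwd@meanF, rev@meanF)))
    expect_equal(rev@meanF[5, 1],
                 1 + 1e-6 * (meanCounts(trajA)[6, 2] - meanCounts(trajA)[1, 2]))
})

test_that("fluorescence CV^2 is well-independent and converges to its asymptote", {
    eff <- EfficiencyParams(0.9, 1)
    input <- InputDistribution("D", meanI = 64)
    cv2 <- fluorescenceCV2(eff, input, 30)
    a <- (1 * 0.5 + (0.1 / 1.9) / 2) / 64
    expect_equal(unname(cv2[30]), a, tolerance = 1e-3)
    d <- abs(cv2 - a)
    expect_true(all(d[11:25] / d[10:24] <= (1 / 1.9) * (1 + 1e-3)))
    # perfect amplification: beta vanishes, so the asymptote is exactly
    # 1/(2 E[I]) and the exact CV^2 halves its distance to it each cycle
    expect_equal(asymptoticCV2(EfficiencyParams(1, 1),
                               InputDistribution("D", meanI = 32)), 1 / 64)
    cvP <- fluorescenceCV2(EfficiencyParams(1, 1),
                           InputDistribution("D", meanI = 32), 12)
    expect_equal(unname(cvP[12]), 1 / 64, tolerance = 1e-6)
    dP <- cvP - 1 / 64
    expect_true(all(abs(dP[4:11] / dP[3:10] - 0.5) < 0.3))
    expect_error(fluorescenceCV2(eff, InputDistribution("D", 0), 5),
                 "positive")
})

test_that("QC summary flags high-dispersion entries", {
    f <- matrix(10, 4, 3)
    sig0 <- matrix(0, 4, 3)
    mf0 <- MolarFluorescence(f, f * 2, sig0, sig0)
    expect_equal(sum(qcSummary(mf0)$flagged), 0)
    # one noisy well dominates the flags
    sig <- matrix(0.01 * 10, 4, 3)
    sig[, 2] <- 0.05 * 10
    mf <- MolarFluorescence(f, f * 2, sig, sig0)
    qc <- qcSummary(mf)
    flagged <- qc[qc$flagged, ]
    expect_gt(nrow(flagged), 0)
    expect_true(all(flagged$well == plateWellLabels(3)[2]))
    expect_error(qcSummary(MolarFluorescence(f, f * 2)), "single plate")
})

test_that("plate and molar-fluorescence CSVs round-trip", {
    set.seed(33)
    m <- matrix(runif(12, 1, 2), 4, 3)
    p <- ProbePlate(m, concentration = 1.25e-13, probeState = "inactive",
                    plateId = "rt1")
    path <- tempfile(fileext = ".csv")
    writePlateCSV(p, path)
    back <- readPlateCSV(path)[["rt1"]]
    expect_equal(SummarizedExperiment::assay(back, "fluorescence"),
                 SummarizedExperiment::assay(p, "fluorescence"))
    expect_equal(probeConcentration(back), 1.25e-13)
    expect_equal(probeState(back), "inactive")

    # missing wells are masked as NA, malformed rows are rejected by line
    df <- read.csv(path)
    write.csv(df[-2, ], path, row.names = FALSE)
    expect_true(is.na(SummarizedExperiment::assay(
        readPlateCSV(path)[["rt1"]])[df$cycle[2], df$well[2]]))
    df2 <- read.csv(path)
    df2$fluorescence[3] <- NA
    p2 <- tempfile(fileext = ".csv")
    write.csv(df2, p2, row.names = FALSE)
    expect_error(readPlateCSV(p2), "line")

    mf <- MolarFluorescence(m, m * 3, m * 0.01, m * 0.001)
    mpath <- tempfile(fileext = ".csv")
    writeMolarFluorescenceCSV(mf, mpath)
    mback <- readMolarFluorescenceCSV(mpath)
    expect_equal(mback@fMinus, mf@fMinus, ignore_attr = TRUE)
    expect_equal(mback@sigmaPlus, mf@sigmaPlus, ignore_attr = TRUE)
})
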