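# random valid parameter set used by the property-style checks
randomEff <- function() {
    R <- runif(1, 0.85, 1.15)
    pBar <- runif(1, 0.5, min(1, 1 / R, R) - 1e-6)
    EfficiencyParams(pBar, R, r = runif(1, 0.2, 0.99))
}

test_that("initial moments follow the input case", {
    effD <- EfficiencyParams(0.9)
    m <- initialMoments(InputDistribution("D", meanI = 5), effD)
    expect_equal(m$mean, c(5, 5))
    expect_equal(m$var, diag(c(5, 5)))

    effR <- EfficiencyParams(0.9, r = 0.5)
    m <- initialMoments(InputDistribution("RF", meanI = 10), effR)
    expect_equal(m$mean, c(0, 5))
    # law of total variance: 10 * 0.25 + 0.5 * 0.5 * 10 = 5
    expect_equal(m$var, diag(c(0, 5)))

    effP <- EfficiencyParams(0.9, r = 1)
    m <- initialMoments(InputDistribution("RR", meanI = 7, family = "fixed"),
                        effP)
    expect_equal(m$mean, c(7, 0))
    expect_equal(m$var, matrix(0, 2, 2))

    # off-diagonals are always zero: initial strands are independent
    m <- initialMoments(InputDistribution("D", meanI = 3, chi = 2,
                                          family = "negative_binomial"),
                        effD)
    expect_equal(m$var[1, 2], 0)
    expect_error(initialMoments(InputDistribution("RF", meanI = 1),
                                EfficiencyParams(0.9)), "'r'")
    expect_error(InputDistribution("D", meanI = -1), "meanI")
})

test_that("expected counts match repeated multiplication by A", {
    eff <- EfficiencyParams(0.9, 1)
    ec <- expectedCounts(eff, c(5, 5), 10)
    expect_equal(ec[1, ], c(X = 5, Y = 5))              # A^0 = identity
    expect_equal(unname(ec[3, ]), c(18.05, 18.05))
    expect_equal(unname(ec), oracleMeanPower(0.9, 1, c(5, 5), 10))
    # Case D at R = 1 reduces to the conventional E[N_i] = N_0 (1+p)^i
    expect_equal(rowSums(ec), 10 * 1.9^(0:10), ignore_attr = TRUE)

    set.seed(21)
    for (q in 1:20) {
        eff <- randomEff()
        m0 <- runif(2, 0, 50)
        ec <- expectedCounts(eff, m0, 15)
        expect_equal(unname(ec),
                     oracleMeanPower(pBar(eff), strandRatio(eff), m0, 15),
                     tolerance = 1e-12)
    }
})

test_that("weighted sum and difference evolve as pure eigenmodes", {
    set.seed(22)
    for (q in 1:20) {
        eff <- randomEff()
        R <- strandRatio(eff)
        lam <- c(1 + pBar(eff), 1 - pBar(eff))
        m0 <- runif(2, 0, 30)
        ec <- expectedCounts(eff, m0, 12)
        i <- 0:12
        expect_equal(ec[, 1] + R * ec[, 2],
                     (m0[1] + R * m0[2]) * lam[1]^i, ignore_attr = TRUE)
        expect_equal(ec[, 1] - R * ec[, 2],
                     (m0[1] - R * m0[2]) * lam[2]^i, ignore_attr = TRUE,
                     tolerance = 1e-9)
    }
})

test_that("forward/reverse ratio converges to R from any input case", {
    expect_equal(ratioLimit(EfficiencyParams(0.9, 1.05)), 1.05)
    # RNA input: ratio starts at the RT-determined value, ends at R
    eff <- EfficiencyParams(0.9, 1.05, r = 0.5)
    ec <- expectedCounts(eff, initialMoments(
        InputDistribution("RF", meanI = 10), eff)$mean, 25)
    expect_lt(abs(ec[26, 1] / ec[26, 2] - 1.05), 1e-6)
    # dsDNA with strongly asymmetric efficiencies: ratio 1 -> R
    eff2 <- EfficiencyParams(0.45, 2)
    ec2 <- expectedCounts(eff2, c(5, 5), 40)
    expect_equal(unname(ec2[1, 1] / ec2[1, 2]), 1)
    expect_lt(abs(ec2[41, 1] / ec2[41, 2] - 2), 1e-6)
    # symmetric efficiencies: ratio stays at 1
    ec3 <- expectedCounts(EfficiencyParams(0.9, 1), c(3, 8), 30)
    expect_lt(abs(ec3[31, 1] / ec3[31, 2] - 1), 1e-10)
})

test_that("monotone growth of the expected total strand count", {
    set.seed(23)
    for (q in 1:10) {
        eff <- randomEff()
        ec <- rowSums(expectedCounts(eff, runif(2, 0.1, 10), 20))
        expect_true(all(diff(ec) > 0))
    }
})

test_that("closed-form variance equals the iterated recursion", {
    # single-cycle binomial sanity: Var[N_1] = N_0 p (1 - p)
    v <- varianceCounts(EfficiencyParams(0.9), c(5, 5), diag(0, 2), 1)
    expect_equal(sum(v[, , 2]), 10 * 0.9 * 0.1)
    expect_equal(v[, , 1], diag(0, 2), ignore_attr = TRUE)  # i = 0 unchanged

    set.seed(24)
    for (q in 1:25) {
        eff <- randomEff()
        m0 <- runif(2, 0, 20)
        v0 <- diag(runif(2, 0, 10))
        vc <- varianceCounts(eff, m0, v0, 50)
        vr <- oracleVarRecursion(pBar(eff), strandRatio(eff), m0, v0, 50)
        for (i in c(1, 2, 5, 10, 25, 50) + 1L)
            expect_lt(relDiff(vc[, , i], vr[, , i]), 1e-9)
    }
})

test_that("two-type moments reduce to the conventional forms at R = 1", {
    p <- 0.9
    eff <- EfficiencyParams(p, 1)
    conv <- conventionalMoments(p, meanN0 = 10, varN0 = 4, nCycles = 30)
    ec <- expectedCounts(eff, c(5, 5), 30)
    vc <- varianceCounts(eff, c(5, 5), diag(c(2, 2)), 30)
    expect_equal(rowSums(ec), conv$EN, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(apply(vc, 3, sum), conv$VarN, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # and the deterministic-initial special case over cycles 1..20
    conv0 <- conventionalMoments(p, 10, 0, 20)
    vc0 <- varianceCounts(eff, c(5, 5), diag(0, 2), 20)
    expect_equal(apply(vc0, 3, sum), conv0$VarN, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # E[X_i] / lambda1^i -> E[N_0] / 2 when R = 1
    expect_equal(ec[31, 1] / 1.9^30, 5, tolerance = 1e-9)
})

test_that("dsDNA expected total matches its two-eigenvalue closed form", {
    # E[N_i] = E[N_0] [ (R+1)^2/(4R) l1^i - (R-1)^2/(4R) l2^i ] for Case D
    eff <- EfficiencyParams(0.88, 1.08)
    EI <- 7
    ec <- expectedCounts(eff, c(EI, EI), 20)
    i <- 0:20
    R <- 1.08
    lam <- c(1.88, 0.12)
    expected <- 2 * EI * ((R + 1)^2 / (4 * R) * lam[1]^i -
                          (R - 1)^2 / (4 * R) * lam[2]^i)
    expect_equal(rowSums(ec), expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("conventional moments match one-step law of total variance", {
    cm <- conventionalMoments(0.9, meanN0 = 10, varN0 = 0, nCycles = 1)
    expect_equal(cm$EN[2], 19)
    expect_equal(cm$VarN[2], 0.9)
    # perfect doubling
    cm2 <- conventionalMoments(1, meanN0 = 3, varN0 = 2, nCycles = 5)
    expect_equal(cm2$EN, 3 * 2^(0:5))
    expect_equal(cm2$VarN, 2 * 4^(0:5))
    expect_error(conventionalMoments(0, 1, 0, 3), "'p'")
})

test_that("cross-covariance with the initial count follows its closed form", {
    eff <- EfficiencyParams(0.9)
    cc <- crossCov(eff, varX0 = 5, nCycles = 3)
    expect_equal(cc[1], 5)                      # i = 0: Var[X_0]
    expect_equal(cc[4], 2.5 * (1.9^3 + 0.1^3))
    expect_equal(crossCov(eff, 0, 10), rep(0, 11))
})

test_that("alpha and beta coefficients match their case-specific forms", {
    expect_equal(alphaBeta(EfficiencyParams(0.7, 1), "D")[["alpha"]], 0.5)
    expect_equal(alphaBeta(EfficiencyParams(0.9, 1), "D")[["beta"]],
                 (0.1 / 1.9) / 2)
    # RNA cases always have alpha = 1
    eff <- EfficiencyParams(0.9, 1.05, 0.4)
    expect_equal(alphaBeta(eff, "RF")[["alpha"]], 1)
    expect_equal(alphaBeta(eff, "RR")[["alpha"]], 1)
    # RF and RR differ only in the R-dependence of the last two beta terms
    l1 <- 1.9; l2 <- 0.1; R <- 1.05; r <- 0.4
    g <- 0.9 * l1 / (l1^2 - l2)
    expect_equal(alphaBeta(eff, "RF")[["beta"]],
                 (1 - r) / r + (l2 / l1) * (R + 1) / (2 * R * r) -
                     g * (R - 1) / (2 * R * r))
    expect_equal(alphaBeta(eff, "RR")[["beta"]],
                 (1 - r) / r + (l2 / l1) * (R + 1) / (2 * r) +
                     g * (R - 1) / (2 * r))
    expect_error(alphaBeta(EfficiencyParams(0.9), "RF"), "'r'")
})

test_that("asymptotic CV^2 equals the large-cycle relative variance", {
    eff <- EfficiencyParams(0.9, 1)
    input <- InputDistribution("D", meanI = 100)
    a <- asymptoticCV2(eff, input)
    expect_equal(a, (0.5 + (0.1 / 1.9) / 2) / 100, tolerance = 1e-10)
    # matches every entry of Var[U_i] / (E[U_i] E[U_i]') at large i
    m0 <- initialMoments(input, eff)
    ec <- expectedCounts(eff, m0$mean, 40)
    vc <- varianceCounts(eff, m0$mean, m0$var, 40)
    rel <- vc[, , 41] / outer(ec[41, ], ec[41, ])
    expect_equal(unname(rel), matrix(a, 2, 2), tolerance = 1e-4)
    # perfect amplification: only the input variance survives
    expect_equal(asymptoticCV2(EfficiencyParams(1, 1),
                               InputDistribution("D", meanI = 50)),
                 1 / (2 * 50))
    expect_error(asymptoticCV2(eff, InputDistribution("D", meanI = 0)),
                 "positive")
})

test_that("exact CV^2 approaches the asymptote at rate 1/lambda1", {
    # at assay-realistic efficiencies (pBar >= 0.8) the dominant
    # correction term decays at exactly 1/lambda1 per cycle from i ~ 10
    set.seed(26)
    for (q in 1:5) {
        R <- runif(1, 0.9, 1.1)
        eff <- EfficiencyParams(runif(1, 0.8, min(1, 1 / R, R) - 1e-6), R,
                                r = runif(1, 0.2, 0.99))
        input <- InputDistribution(sample(c("D", "RF", "RR"), 1),
                                   meanI = runif(1, 20, 100))
        m0 <- initialMoments(input, eff)
        if (sum(m0$mean) == 0) next
        n <- 30
        ec <- expectedCounts(eff, m0$mean, n)
        vc <- varianceCounts(eff, m0$mean, m0$var, n)
        s <- if (input@case == "RF") 2 else 1   # strand present from cycle 0
        cv2 <- vc[s, s, ] / ec[, s]^2
        d <- abs(cv2 - asymptoticCV2(eff, input))
        lam1 <- 1 + pBar(eff)
        ratios <- d[12:(n + 1)] / d[11:n]
        # exclude differences at the floating-point floor of the CV^2
        keep <- d[11:n] > 1e-10 * cv2[11:n]
        expect_true(all(ratios[keep] <= 1 / lam1 * (1 + 1e-3)))
    }
})

test_that("the directional-asymmetry variance term vanishes as R -> 1", {
    etas <- vapply(c(1.2, 1.1, 1.05, 1.01, 1.001), function(R) {
        eff <- EfficiencyParams(0.8, R)
        sdec <- spectralDecomposition(eff)
        meanU0 <- c(10, 10)     # Case D
        K <- pcruq:::.kMatrices(eff, sdec, meanU0)
        lam <- sdec@lambda
        drop(sdec@Z[1, ] %*% K[[2]] %*% sdec@Z[1, ]) / (lam[1]^2 - lam[2])
    }, numeric(1))
    expect_true(all(diff(abs(etas)) < 0))   # strictly shrinking
    expect_lt(abs(etas[5]), 1e-4 * abs(etas[1]))
})

test_that("moment trajectories cache all cycles and serialise to CSV", {
    eff <- EfficiencyParams(0.9, 1.02, 0.5)
    input <- InputDistribution("RF", meanI = 10)
    traj <- momentTrajectory(eff, input, 12)
    expect_equal(nCycles(traj), 12)
    df <- as.data.frame(traj)
    expect_equal(names(df), c("cycle", "EX", "EY", "VarX", "VarY",
                              "CovXY", "CovX_X0"))
    expect_equal(df$EX, expectedCounts(eff, c(0, 5), 12)[, 1],
                 ignore_attr = TRUE)
    expect_equal(covWithInitial(traj, "forward"), rep(0, 13)) # Var[X_0]=0
    path <- tempfile(fileext = ".csv")
    writeMomentTrajectory(traj, path)
    back <- read.csv(path)
    expect_equal(back$VarY, df$VarY)
    # explicit initial moments override the input model
    traj2 <- momentTrajectory(eff, nCycles = 3, meanU0 = c(1, 2),
                              varU0 = diag(0, 2))
    expect_equal(meanCounts(traj2)[1, ], c(X = 1, Y = 2))
})
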