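# Independent oracles used to check the package's closed forms.  These are
# deliberately naive implementations (direct matrix iteration, dense grid
# search) kept separate from the package code paths they validate.

# one-cycle expectation matrix
oracleAmpMatrix <- function(pBar, R) {
    matrix(c(1, pBar / R, pBar * R, 1), 2, 2)
}

# expected counts by repeated multiplication with A
oracleMeanPower <- function(pBar, R, meanU0, n) {
    A <- oracleAmpMatrix(pBar, R)
    out <- matrix(0, n + 1, 2)
    m <- meanU0
    out[1, ] <- m
    for (i in seq_len(n)) {
        m <- drop(A %*% m)
        out[i + 1, ] <- m
    }
    out
}

# variance by direct iteration of the one-cycle law-of-total-variance
# recursion: Var_i = A Var_(i-1) A' + diag of binomial noise at the
# previous cycle's expected counts
oracleVarRecursion <- function(pBar, R, meanU0, varU0, n) {
    A <- oracleAmpMatrix(pBar, R)
    prf <- pBar * R
    pfr <- pBar / R
    m <- meanU0
    V <- as.matrix(varU0)
    out <- array(0, c(2, 2, n + 1))
    out[, , 1] <- V
    for (i in seq_len(n)) {
        V <- A %*% V %*% t(A) +
            diag(c(prf * (1 - prf) * m[2], pfr * (1 - pfr) * m[1]))
        m <- drop(A %*% m)
        out[, , i + 1] <- V
    }
    out
}

# regression through the origin by successively refined dense grid search
oracleGridLS <- function(C, F, stages = 3, npts = 2001) {
    lo <- 0
    hi <- 2 * max(abs(F) / C)
    if (hi == 0) hi <- 1
    best <- NA_real_
    for (s in seq_len(stages)) {
        grid <- seq(lo, hi, length.out = npts)
        rss <- vapply(grid, function(f) sum((F - f * C)^2), numeric(1))
        best <- grid[which.min(rss)]
        step <- (hi - lo) / (npts - 1)
        lo <- best - 2 * step
        hi <- best + 2 * step
    }
    best
}

# relative difference robust to zero entries
relDiff <- function(a, b) {
    max(abs(a - b)) / max(abs(b), 1e-300)
}
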