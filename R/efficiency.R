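#' @include AllGenerics.R
NULL

#' Construct amplification-efficiency parameters
#'
#' @param pBar geometric-mean amplification efficiency, in (0, 1].
#' @param R directional-efficiency ratio parameter, positive; both derived
#'   probabilities `pBar * R` (reverse -> forward) and `pBar / R`
#'   (forward -> reverse) must lie in (0, 1].
#' @param r reverse-transcription efficiency in (0, 1]; required only for
#'   RNA inputs (cases RF and RR).
#' @return an [EfficiencyParams] object.
#' @examples
#' eff <- EfficiencyParams(pBar = 0.9, R = 1.05, r = 0.5)
#' pFr(eff); pRf(eff)
#' @export
EfficiencyParams <- function(pBar, R = 1, r = NA_real_) {
    new("EfficiencyParams", pBar = as.numeric(pBar), R = as.numeric(R),
        r = as.numeric(r))
}

#' @describeIn EfficiencyParams geometric-mean efficiency.
#' @param object an `EfficiencyParams` object.
#' @export
setMethod("pBar", "EfficiencyParams", function(object) object@pBar)

#' @describeIn EfficiencyParams ratio parameter `R`.
#' @export
setMethod("strandRatio", "EfficiencyParams", function(object) object@R)

#' @describeIn EfficiencyParams reverse-transcription efficiency `r`.
#' @export
setMethod("rtEfficiency", "EfficiencyParams", function(object) object@r)

#' Directional amplification probabilities
#'
#' `pFr` is the probability that a forward strand templates a new reverse
#' strand in one cycle (`pBar / R`); `pRf` the probability that a reverse
#' strand templates a new forward strand (`pBar * R`).
#'
#' @param eff an [EfficiencyParams] object.
#' @return numeric(1).
#' @export
pFr <- function(eff) eff@pBar / eff@R

#' @rdname pFr
#' @export
pRf <- function(eff) eff@pBar * eff@R

# eigenvalues of the one-cycle expectation matrix
.lambdas <- function(eff) c(1 + eff@pBar, 1 - eff@pBar)

# the one-cycle expectation matrix A
.ampMatrix <- function(eff) {
    matrix(c(1, pFr(eff), pRf(eff), 1), 2L, 2L)
}

setMethod("show", "EfficiencyParams", function(object) {
    cat("EfficiencyParams: pBar =", object@pBar, " R =", object@R,
        if (!is.na(object@r)) paste(" r =", object@r) else "", "\n")
    cat("  directional probabilities: p(f->r) =", signif(pFr(object), 6),
        " p(r->f) =", signif(pRf(object), 6), "\n")
    lam <- .lambdas(object)
    cat("  eigenvalues: lambda1 =", lam[1], " lambda2 =", lam[2], "\n")
})

#' Spectral decomposition of the expectation matrix
#'
#' Decomposes `A = [[1, pBar*R], [pBar/R, 1]]` as `X Lambda Z` with
#' `Z = X^-1`, using the closed forms
#' `X = (1/sqrt(2)) [[R, R], [1, -1]]` and
#' `Z = (1/(R*sqrt(2))) [[1, R], [1, -R]]`, so that when `R = 1` all
#' eigenvectors have unit Euclidean norm.
#'
#' @param eff an [EfficiencyParams] object.
#' @return a [SpectralDecomposition] object.
#' @examples
#' sd <- spectralDecomposition(EfficiencyParams(0.9, 1.05))
#' sd@X %*% diag(sd@lambda) %*% sd@Z   # reconstructs A
#' @export
spectralDecomposition <- function(eff) {
    stopifnot(is(eff, "EfficiencyParams"))
    R <- eff@R
    X <- matrix(c(R, 1, R, -1), 2L, 2L) / sqrt(2)
    Z <- matrix(c(1, R, 1, -R), 2L, 2L, byrow = TRUE) / (R * sqrt(2))
    new("SpectralDecomposition", lambda = .lambdas(eff), X = X, Z = Z)
}

setMethod("show", "SpectralDecomposition", function(object) {
    cat("SpectralDecomposition\n  lambda:", object@lambda, "\n")
    cat("  right eigenvectors (columns of X):\n")
    print(object@X)
})
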