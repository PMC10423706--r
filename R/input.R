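#' @include AllGenerics.R
NULL

#' Construct an input copy-number model
#'
#' The input variance can be given either directly (`varI`) or through the
#' variance-to-mean ratio `chi` (`varI = chi * meanI`).  The `family` fixes
#' the distribution the simulator draws from and constrains the dispersion:
#' Poisson has `chi = 1`, the negative binomial has `chi > 1` and the fixed
#' (deterministic) input has zero variance.
#'
#' @param case input nucleic-acid type: `"D"` (double-stranded DNA),
#'   `"RF"` (forward-stranded RNA) or `"RR"` (reverse-stranded RNA).
#' @param meanI expected input copies (nonnegative; treated as a real-valued
#'   Poisson mean, not constrained to integers).
#' @param chi variance-to-mean ratio; ignored if `varI` is supplied.
#' @param varI input variance; defaults to `chi * meanI`.
#' @param family `"poisson"`, `"negative_binomial"` or `"fixed"`.
#' @return an [InputDistribution] object.
#' @examples
#' InputDistribution("D", meanI = 20)                      # Poisson
#' InputDistribution("RF", meanI = 20, chi = 2,
#'                   family = "negative_binomial")
#' @export
InputDistribution <- function(case = c("D", "RF", "RR"), meanI,
                              chi = NULL, varI = NULL,
                              family = c("poisson", "negative_binomial",
                                         "fixed")) {
    case <- match.arg(case)
    family <- match.arg(family)
    if (is.null(varI)) {
        if (is.null(chi))
            chi <- switch(family, poisson = 1, negative_binomial = 2,
                          fixed = 0)
        varI <- chi * meanI
    }
    if (family == "fixed") varI <- 0
    new("InputDistribution", case = case, meanI = as.numeric(meanI),
        varI = as.numeric(varI), family = family)
}

#' @describeIn InputDistribution input case (`"D"`, `"RF"`, `"RR"`).
#' @param object an `InputDistribution` object.
#' @export
setMethod("inputCase", "InputDistribution", function(object) object@case)

#' @describeIn InputDistribution expected input copies.
#' @export
setMethod("meanInput", "InputDistribution", function(object) object@meanI)

#' @describeIn InputDistribution input variance.
#' @export
setMethod("varInput", "InputDistribution", function(object) object@varI)

#' @describeIn InputDistribution distribution family used by the simulator.
#' @export
setMethod("inputFamily", "InputDistribution", function(object) object@family)

#' @describeIn InputDistribution variance-to-mean ratio `chi`
#'   (`NaN` when the mean is 0).
#' @export
setMethod("dispersion", "InputDistribution",
    function(object) object@varI / object@meanI)

setMethod("show", "InputDistribution", function(object) {
    cat("InputDistribution: case", object@case, "\n")
    cat("  E[I] =", object@meanI, " Var[I] =", object@varI,
        " family =", object@family, "\n")
})

#' Mean and variance of the initial strand counts
#'
#' Maps the input-copy moments onto the moments of the initial strand-count
#' vector `U_0 = (X_0, Y_0)`.  For double-stranded DNA the two strands are
#' i.i.d. copies of the input; for RNA the reverse-transcription step thins
#' the input binomially with efficiency `r`, so by the law of total variance
#' `Var[B(I; r)] = r^2 Var[I] + r (1 - r) E[I]`.  `X_0` and `Y_0` are
#' independent, so off-diagonal covariances are zero.
#'
#' @param input an [InputDistribution] object.
#' @param eff an [EfficiencyParams] object; its `r` slot is required for
#'   cases RF and RR.
#' @return a list with `mean` (numeric(2), `(E[X_0], E[Y_0])`) and `var`
#'   (2x2 diagonal covariance matrix).
#' @examples
#' eff <- EfficiencyParams(0.9, r = 0.5)
#' initialMoments(InputDistribution("RF", meanI = 10), eff)
#' @export
initialMoments <- function(input, eff) {
    stopifnot(is(input, "InputDistribution"), is(eff, "EfficiencyParams"))
    m <- input@meanI
    v <- input@varI
    if (input@case == "D")
        return(list(mean = c(m, m), var = diag(c(v, v))))
    r <- eff@r
    if (is.na(r))
        stop("reverse-transcription efficiency 'r' is required for case ",
             input@case)
    vB <- v * r^2 + r * (1 - r) * m
    if (input@case == "RF")
        list(mean = c(0, r * m), var = diag(c(0, vB)))
    else
        list(mean = c(r * m, 0), var = diag(c(vB, 0)))
}
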