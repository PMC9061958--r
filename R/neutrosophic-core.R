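#' Construct an indeterminacy interval
#'
#' The indeterminacy measure is dimensionless and nonnegative;
#' `indeterminacyInterval(0, 0)` (the default) encodes the classical,
#' fully determinate case. Values above 1 mean the indeterminate part
#' can exceed the determinate part, which is unusual for measurement
#' uncertainty; by default the constructor refuses them, and with
#' `cap = FALSE` it accepts them with a warning.
#'
#' @param lower,upper nonnegative scalars with `lower <= upper`.
#' @param cap logical; if `TRUE` (default), reject `upper > 1`.
#' @return an [IndeterminacyInterval-class].
#' @examples
#' indeterminacyInterval(0, 0.05)
#' @export
indeterminacyInterval <- function(lower = 0, upper = lower, cap = TRUE) {
    if (!is.numeric(lower) || !is.numeric(upper))
        stop("indeterminacy bounds must be numeric")
    if (length(upper) && length(lower) && any(upper > 1)) {
        if (cap)
            stop("indeterminacy upper bound exceeds 1; ",
                 "use cap = FALSE to allow values above 1")
        warning("indeterminacy upper bound exceeds 1")
    }
    new("IndeterminacyInterval", lower = as.numeric(lower),
        upper = as.numeric(upper))
}

## Internal general constructor for the additive form a + b*I.
.NeutrosophicValue <- function(determinate, coefficient, indeterminacy) {
    new("NeutrosophicValue",
        lower = determinate + coefficient * indeterminacy@lower,
        upper = determinate + coefficient * indeterminacy@upper,
        determinate = as.numeric(determinate),
        coefficient = as.numeric(coefficient),
        indeterminacy = indeterminacy)
}

#' Construct a neutrosophic value in multiplicative form
#'
#' Builds the neutrosophic number \eqn{(1 + I_N) x} for a nonnegative
#' determinate value \eqn{x} and indeterminacy \eqn{I_N \in [I_L, I_U]}:
#' the endpoints are \eqn{x (1 + I_L)} and \eqn{x (1 + I_U)}, and the
#' indeterminate coefficient equals the determinate part. This is the
#' form the test statistic and the worked nucleotide example use; the
#' additive decomposition \eqn{x + x I_N} is recoverable through
#' [determinatePart()] and [indeterminateCoefficient()].
#'
#' @param determinate nonnegative scalar (probabilities and chi-square
#'   statistics are nonnegative; negative input is an error).
#' @param indeterminacy an [IndeterminacyInterval-class].
#' @return a [NeutrosophicValue-class].
#' @examples
#' makeNeutrosophic(0.00664, indeterminacyInterval(0, 0.05))
#' @export
makeNeutrosophic <- function(determinate,
                             indeterminacy = indeterminacyInterval(0, 0)) {
    if (!is.numeric(determinate) || length(determinate) != 1L ||
        !is.finite(determinate))
        stop("'determinate' must be a finite scalar")
    if (determinate < 0)
        stop("'determinate' must be nonnegative")
    if (!is(indeterminacy, "IndeterminacyInterval"))
        stop("'indeterminacy' must be an IndeterminacyInterval")
    .NeutrosophicValue(determinate, determinate, indeterminacy)
}

#' @rdname accessors
setMethod("lowerBound", "IndeterminacyInterval", function(x) x@lower)
#' @rdname accessors
setMethod("upperBound", "IndeterminacyInterval", function(x) x@upper)
#' @rdname accessors
setMethod("lowerBound", "NeutrosophicValue", function(x) x@lower)
#' @rdname accessors
setMethod("upperBound", "NeutrosophicValue", function(x) x@upper)
#' @rdname accessors
setMethod("determinatePart", "NeutrosophicValue", function(x) x@determinate)
#' @rdname accessors
setMethod("indeterminateCoefficient", "NeutrosophicValue",
    function(x) x@coefficient)
#' @rdname accessors
setMethod("indeterminacy", "NeutrosophicValue", function(x) x@indeterminacy)

#' @rdname evaluateAt
setMethod("evaluateAt", "NeutrosophicValue", function(x, i) {
    if (!is.numeric(i) || length(i) != 1L || !is.finite(i))
        stop("'i' must be a finite scalar")
    if (i < x@indeterminacy@lower || i > x@indeterminacy@upper)
        stop(sprintf("i = %g outside the indeterminacy interval [%g, %g]",
                     i, x@indeterminacy@lower, x@indeterminacy@upper))
    x@determinate + x@coefficient * i
})

#' @rdname isClassical
setMethod("isClassical", "NeutrosophicValue",
    function(x) x@indeterminacy@lower == 0 && x@indeterminacy@upper == 0)

setMethod("show", "IndeterminacyInterval", function(object) {
    cat(sprintf("IndeterminacyInterval [%g, %g]\n", object@lower, object@upper))
})

setMethod("show", "NeutrosophicValue", function(object) {
    cat(sprintf("NeutrosophicValue [%.6f, %.6f]\n", object@lower, object@upper))
    cat(sprintf("  form: %.6f + %.6f * I,  I in [%g, %g]\n",
                object@determinate, object@coefficient,
                object@indeterminacy@lower, object@indeterminacy@upper))
})
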