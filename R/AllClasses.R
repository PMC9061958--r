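#' Indeterminacy interval
#'
#' The measure of indeterminacy \eqn{I \in [I_L, I_U]} attached to a
#' neutrosophic quantity. \eqn{I_L = I_U = 0} encodes the classical
#' (fully determinate) case.
#'
#' @slot lower numeric(1), lower bound of the indeterminacy measure.
#' @slot upper numeric(1), upper bound of the indeterminacy measure.
#' @seealso [indeterminacyInterval()]
#' @exportClass IndeterminacyInterval
setClass("IndeterminacyInterval",
    representation(lower = "numeric", upper = "numeric"),
    prototype(lower = 0, upper = 0))

setValidity("IndeterminacyInterval", function(object) {
    msg <- character()
    if (length(object@lower) != 1L || length(object@upper) != 1L)
        msg <- c(msg, "'lower' and 'upper' must each have length 1")
    else {
        if (!is.finite(object@lower) || !is.finite(object@upper))
            msg <- c(msg, "indeterminacy bounds must be finite")
        else {
            if (object@lower < 0)
                msg <- c(msg, "indeterminacy lower bound must be >= 0")
            if (object@lower > object@upper)
                msg <- c(msg, "indeterminacy lower bound must not exceed upper bound")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Neutrosophic value
#'
#' An interval \eqn{[L, U]} together with its neutrosophic-form
#' decomposition \eqn{x_N = a + b I_N}, where \eqn{a} is the determinate
#' part, \eqn{b} the indeterminate coefficient and \eqn{I_N \in [I_L,
#' I_U]} the indeterminacy measure. The endpoints always satisfy
#' \eqn{L = a + b I_L} and \eqn{U = a + b I_U}. In the multiplicative
#' form \eqn{(1 + I_N) x} used by the test statistic, \eqn{b = a = x}.
#'
#' @slot lower,upper numeric(1), interval endpoints.
#' @slot determinate numeric(1), determinate part.
#' @slot coefficient numeric(1), indeterminate coefficient.
#' @slot indeterminacy an [IndeterminacyInterval-class].
#' @seealso [makeNeutrosophic()], [evaluateAt()], [isClassical()]
#' @exportClass NeutrosophicValue
setClass("NeutrosophicValue",
    representation(lower = "numeric", upper = "numeric",
                   determinate = "numeric", coefficient = "numeric",
                   indeterminacy = "IndeterminacyInterval"))

setValidity("NeutrosophicValue", function(object) {
    msg <- character()
    for (s in c("lower", "upper", "determinate", "coefficient"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    if (!length(msg)) {
        tol <- 1e-8 * max(1, abs(object@determinate), abs(object@coefficient))
        if (object@lower > object@upper + tol)
            msg <- c(msg, "lower endpoint exceeds upper endpoint")
        eL <- object@determinate + object@coefficient * object@indeterminacy@lower
        eU <- object@determinate + object@coefficient * object@indeterminacy@upper
        if (abs(object@lower - eL) > tol || abs(object@upper - eU) > tol)
            msg <- c(msg, "endpoints inconsistent with neutrosophic decomposition a + b*I")
    }
    if (length(msg)) msg else TRUE
})

#' Multinomial count table
#'
#' A groups x categories matrix of nonnegative integer counts, the input
#' to the homogeneity test. Rows are independent multinomial samples
#' (groups), columns are categories; for DNA data the categories are the
#' nucleotides A, C, G, T. Row/column names carry the group and category
#' labels. The `metadata` list stores provenance such as the per-group
#' number of excluded (non-ACGT) characters from FASTA counting.
#'
#' @slot counts numeric matrix of nonnegative integers with unique
#'   dimnames; at least 1 row and 2 columns.
#' @slot metadata list of optional annotations.
#' @seealso [countTable()], [readCountTable()], [countNucleotides()]
#' @exportClass CountTable
setClass("CountTable",
    representation(counts = "matrix", metadata = "list"),
    prototype(metadata = list()))

setValidity("CountTable", function(object) {
    m <- object@counts
    msg <- character()
    if (!is.numeric(m))
        return("'counts' must be a numeric matrix")
    if (nrow(m) < 1L)
        msg <- c(msg, "need at least one group (row)")
    if (ncol(m) < 2L)
        msg <- c(msg, "need at least two categories (columns)")
    if (anyNA(m))
        msg <- c(msg, "counts must not contain NA")
    else {
        if (any(m < 0))
            msg <- c(msg, "counts must be nonnegative")
        if (any(abs(m - round(m)) > 1e-8))
            msg <- c(msg, "counts must be integer-valued")
    }
    dn <- dimnames(m)
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
        msg <- c(msg, "counts must have group (row) and category (column) labels")
    else {
        if (anyDuplicated(dn[[1L]]) || any(!nzchar(dn[[1L]])))
            msg <- c(msg, "group labels must be unique and non-empty")
        if (anyDuplicated(dn[[2L]]) || any(!nzchar(dn[[2L]])))
            msg <- c(msg, "category labels must be unique and non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Interval-valued (neutrosophic) count table
#'
#' A pair of [CountTable-class] objects holding the lower and upper
#' endpoint counts of genuinely interval-valued data. Both tables must
#' share shape and labels, with lower counts elementwise no larger than
#' upper counts. The degenerate case lower == upper recovers a classical
#' table.
#'
#' @slot lower,upper [CountTable-class] endpoint tables.
#' @seealso [neutrosophicCountTable()]
#' @exportClass NeutrosophicCountTable
setClass("NeutrosophicCountTable",
    representation(lower = "CountTable", upper = "CountTable"))

setValidity("NeutrosophicCountTable", function(object) {
    lo <- object@lower@counts
    up <- object@upper@counts
    if (!identical(dim(lo), dim(up)) || !identical(dimnames(lo), dimnames(up)))
        return("lower and upper tables must have identical shape and labels")
    if (any(lo > up))
        return("lower counts must not exceed upper counts")
    TRUE
})

#' Pooled category-probability estimates
#'
#' Under the homogeneity null all groups share one category-probability
#' vector, estimated by pooling: \eqn{\hat p_i = \sum_j Y_{ij} / \sum_j
#' n_j}, computed separately from the lower and the upper endpoint
#' tables. Each endpoint vector sums to 1.
#'
#' @slot probLower,probUpper named numeric vectors of length k.
#' @slot totalsLower,totalsUpper per-group totals of the source tables.
#' @seealso [estimatePooledProbabilities()]
#' @exportClass PooledEstimates
setClass("PooledEstimates",
    representation(probLower = "numeric", probUpper = "numeric",
                   totalsLower = "numeric", totalsUpper = "numeric"))

setValidity("PooledEstimates", function(object) {
    msg <- character()
    for (s in c("probLower", "probUpper")) {
        p <- slot(object, s)
        if (any(p < 0) || any(p > 1))
            msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
        if (abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, sprintf("'%s' must sum to 1 (tolerance 1e-9)", s))
    }
    if (length(object@probLower) != length(object@probUpper))
        msg <- c(msg, "endpoint probability vectors must have equal length")
    if (length(msg)) msg else TRUE
})

#' Result of the neutrosophic chi-square test
#'
#' Holds the interval statistic \eqn{Q_N \in [Q_L, Q_U]}, the per-cell
#' contributions of its determinate part, the degrees of freedom, the
#' critical value actually used, and the trichotomous decision:
#' `"do_not_reject"` when \eqn{Q_U \le} critical value, `"reject"` when
#' \eqn{Q_L >} critical value, and `"indeterminate"` when the interval
#' straddles it.
#'
#' @slot statistic [NeutrosophicValue-class], the interval statistic.
#' @slot cellContributions matrix of per-cell terms of the determinate
#'   (lower-endpoint) Pearson sum.
#' @slot df integer, degrees of freedom.
#' @slot criticalValue numeric(1), threshold compared against.
#' @slot decision character(1), one of `"reject"`, `"do_not_reject"`,
#'   `"indeterminate"`.
#' @slot alpha numeric(1), significance level.
#' @slot mode character(1), `"homogeneity"` or `"goodness_of_fit"`.
#' @seealso [neutroChisqTest()]
#' @exportClass NeutrosophicChisqTest
setClass("NeutrosophicChisqTest",
    representation(statistic = "NeutrosophicValue",
                   cellContributions = "matrix",
                   df = "integer",
                   criticalValue = "numeric",
                   decision = "character",
                   alpha = "numeric",
                   mode = "character"))

setValidity("NeutrosophicChisqTest", function(object) {
    msg <- character()
    if (!object@decision %in% c("reject", "do_not_reject", "indeterminate"))
        msg <- c(msg, "unknown decision state")
    if (object@statistic@lower < 0 || any(object@cellContributions < 0))
        msg <- c(msg, "statistic and cell contributions must be nonnegative")
    tol <- 1e-8 * max(1, object@statistic@determinate)
    if (abs(sum(object@cellContributions) - object@statistic@determinate) > tol)
        msg <- c(msg, "cell contributions must sum to the determinate part")
    if (length(msg)) msg else TRUE
})
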