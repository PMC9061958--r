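#' @name accessors
#' @title Accessors for neutroChisq objects
#' @description Slot accessors for the S4 containers: interval endpoints
#'   and neutrosophic decomposition of a [NeutrosophicValue-class];
#'   counts, labels and totals of a [CountTable-class]; components of a
#'   [NeutrosophicChisqTest-class] result.
#' @param x an object of the documented class.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("lowerBound", function(x) standardGeneric("lowerBound"))
#' @rdname accessors
#' @export
setGeneric("upperBound", function(x) standardGeneric("upperBound"))
#' @rdname accessors
#' @export
setGeneric("determinatePart", function(x) standardGeneric("determinatePart"))
#' @rdname accessors
#' @export
setGeneric("indeterminateCoefficient",
    function(x) standardGeneric("indeterminateCoefficient"))
#' @rdname accessors
#' @export
setGeneric("indeterminacy", function(x) standardGeneric("indeterminacy"))

#' Evaluate a neutrosophic value at an indeterminacy level
#'
#' Returns the value of the neutrosophic form \eqn{a + b i} at a
#' specific indeterminacy level \eqn{i} within the attached interval;
#' for the multiplicative form of the statistic this is
#' \eqn{(1 + i) Q_L}. Evaluating at \eqn{i = 0} recovers the
#' determinate part.
#'
#' @param x a [NeutrosophicValue-class].
#' @param i numeric(1) with `lowerBound(indeterminacy(x)) <= i <=
#'   upperBound(indeterminacy(x))`.
#' @return numeric(1).
#' @examples
#' q <- makeNeutrosophic(0.00664, indeterminacyInterval(0, 0.05))
#' evaluateAt(q, 0.05)   # 0.006972
#' @export
setGeneric("evaluateAt", function(x, i) standardGeneric("evaluateAt"))

#' Does a neutrosophic value reduce to a classical one?
#'
#' `TRUE` iff the attached indeterminacy interval is [0, 0], i.e. the
#' interval collapses to its determinate part and every downstream
#' computation coincides with classical statistics.
#'
#' @param x a [NeutrosophicValue-class].
#' @return logical(1).
#' @export
setGeneric("isClassical", function(x) standardGeneric("isClassical"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("categoryLabels", function(x) standardGeneric("categoryLabels"))
#' @rdname accessors
#' @export
setGeneric("groupTotals", function(x) standardGeneric("groupTotals"))
#' @rdname accessors
#' @export
setGeneric("excludedCounts", function(x) standardGeneric("excludedCounts"))
#' @rdname accessors
#' @export
setGeneric("lowerTable", function(x) standardGeneric("lowerTable"))
#' @rdname accessors
#' @export
setGeneric("upperTable", function(x) standardGeneric("upperTable"))

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))
#' @rdname accessors
#' @export
setGeneric("cellContributions",
    function(x) standardGeneric("cellContributions"))

#' Pooled probability estimation under the homogeneity null
#'
#' Estimates the shared category-probability vector by pooling all
#' groups: \eqn{\hat p_i = \sum_j Y_{ij} / \sum_j n_j}, computed
#' separately from the lower and upper endpoint tables of an
#' interval-valued input (for a classical [CountTable-class] the two
#' coincide).
#'
#' @param x a [CountTable-class] or [NeutrosophicCountTable-class].
#' @return a [PooledEstimates-class].
#' @examples
#' t1 <- brca2CountTable()
#' probabilities(estimatePooledProbabilities(t1))
#' @export
setGeneric("estimatePooledProbabilities",
    function(x) standardGeneric("estimatePooledProbabilities"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
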