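#' @rdname estimatePooledProbabilities
setMethod("estimatePooledProbabilities", "CountTable", function(x)
    estimatePooledProbabilities(neutrosophicCountTable(x)))

#' @rdname estimatePooledProbabilities
setMethod("estimatePooledProbabilities", "NeutrosophicCountTable",
    function(x) {
        pool <- function(tab) {
            m <- counts(tab)
            total <- sum(m)
            if (total <= 0)
                stop("zero grand total: pooled probabilities undefined")
            colSums(m) / total
        }
        new("PooledEstimates",
            probLower = pool(x@lower), probUpper = pool(x@upper),
            totalsLower = unname(groupTotals(x@lower)),
            totalsUpper = unname(groupTotals(x@upper)))
    })

#' @rdname accessors
setMethod("probabilities", "PooledEstimates", function(x)
    rbind(lower = x@probLower, upper = x@probUpper))

setMethod("show", "PooledEstimates", function(object) {
    cat("PooledEstimates (category probabilities under H0)\n")
    print(probabilities(object))
})

#' Expected counts under given category probabilities
#'
#' Entry `[j, i]` is \eqn{n_j p_i}: group total times category
#' probability, the expectation entering each Pearson term. Row sums
#' reproduce the group totals.
#'
#' @param x a [CountTable-class].
#' @param probabilities numeric vector of length `ncol(x)` summing to 1
#'   (absolute tolerance 1e-9). A zero probability makes the statistic
#'   undefined and is an error.
#' @return numeric matrix, same shape and labels as `counts(x)`.
#' @export
expectedCounts <- function(x, probabilities) {
    stopifnot(is(x, "CountTable"))
    p <- as.numeric(probabilities)
    if (length(p) != ncol(x@counts))
        stop("need one probability per category")
    if (abs(sum(p) - 1) > 1e-9)
        stop("probabilities must sum to 1 (absolute tolerance 1e-9)")
    if (any(p <= 0))
        stop("zero expected count: a category probability is 0, ",
             "the chi-square statistic is undefined")
    e <- outer(rowSums(x@counts), p)
    dimnames(e) <- dimnames(x@counts)
    e
}

#' Pearson chi-square statistic for a count table
#'
#' The classical sum \eqn{Q = \sum_j \sum_i (Y_{ij} - n_j p_i)^2 /
#' (n_j p_i)} over all groups and categories, with the per-cell terms
#' returned alongside (the first printed term of the worked nucleotide
#' example is the (group 1, A) cell).
#'
#' @inheritParams expectedCounts
#' @return a list with elements `statistic` (numeric scalar, >= 0) and
#'   `contributions` (matrix of per-cell terms summing to `statistic`).
#' @examples
#' t1 <- brca2CountTable()
#' p <- probabilities(estimatePooledProbabilities(t1))["lower", ]
#' pearsonStatistic(t1, p)$statistic   # 0.00664
#' @export
pearsonStatistic <- function(x, probabilities) {
    e <- expectedCounts(x, probabilities)
    contributions <- (x@counts - e)^2 / e
    list(statistic = sum(contributions), contributions = contributions)
}

#' Neutrosophic statistic in simplified multiplicative form
#'
#' Lifts a classical (lower-endpoint) chi-square value to its
#' neutrosophic form \eqn{(1 + I_N) Q_L}, the simplified form used when
#' the lower and upper data coincide: the upper endpoint is
#' \eqn{(1 + I_U) Q_L}.
#'
#' @param qLower nonnegative scalar, the determinate Pearson statistic.
#' @param indeterminacy an [IndeterminacyInterval-class].
#' @return a [NeutrosophicValue-class].
#' @examples
#' neutrosophicStatistic(0.00664, indeterminacyInterval(0, 0.05))
#' @export
neutrosophicStatistic <- function(qLower, indeterminacy) {
    if (!is.numeric(qLower) || length(qLower) != 1L || qLower < 0)
        stop("'qLower' must be a nonnegative scalar")
    makeNeutrosophic(qLower, indeterminacy)
}

#' Neutrosophic statistic for genuinely interval-valued counts
#'
#' Assembles the two-sum form \eqn{Q_N = Q_L^{sum} + Q_U^{sum} I_N}: the
#' determinate part is the Pearson statistic of the lower table with the
#' lower pooled estimates, the indeterminate coefficient the Pearson
#' statistic of the upper table with the upper estimates, and the
#' endpoints follow the additive decomposition at \eqn{I_L} and
#' \eqn{I_U}. When the two endpoint tables coincide this reduces to the
#' multiplicative form of [neutrosophicStatistic()].
#'
#' @param x a [NeutrosophicCountTable-class].
#' @param estimates a [PooledEstimates-class] (defaults to pooling `x`).
#' @param indeterminacy an [IndeterminacyInterval-class].
#' @return a [NeutrosophicValue-class].
#' @export
generalIntervalStatistic <- function(x,
                                     estimates = estimatePooledProbabilities(x),
                                     indeterminacy = indeterminacyInterval(0, 0)) {
    stopifnot(is(x, "NeutrosophicCountTable"), is(estimates, "PooledEstimates"))
    qL <- pearsonStatistic(x@lower, estimates@probLower)$statistic
    qU <- pearsonStatistic(x@upper, estimates@probUpper)$statistic
    .NeutrosophicValue(qL, qU, indeterminacy)
}

#' Degrees of freedom of the chi-square reference distribution
#'
#' \eqn{h (k - 1)} when the category probabilities are pre-specified
#' (goodness-of-fit regime) and \eqn{(h - 1)(k - 1)} when they are
#' estimated from the pooled data (homogeneity regime, which needs at
#' least two groups).
#'
#' @param h number of groups (>= 1; >= 2 in homogeneity mode).
#' @param k number of categories (>= 2).
#' @param mode `"homogeneity"` or `"goodness_of_fit"`.
#' @return integer degrees of freedom.
#' @export
degreesOfFreedom <- function(h, k, mode = c("homogeneity", "goodness_of_fit")) {
    mode <- match.arg(mode)
    h <- as.integer(h); k <- as.integer(k)
    if (h < 1L || k < 2L)
        stop("need h >= 1 group and k >= 2 categories")
    if (mode == "goodness_of_fit")
        return(h * (k - 1L))
    if (h < 2L)
        stop("homogeneity mode needs at least 2 groups (df would be 0)")
    (h - 1L) * (k - 1L)
}

#' Critical value of the test
#'
#' The \eqn{1 - \alpha} quantile of the chi-square distribution with
#' `df` degrees of freedom, unless an explicit `override` is supplied
#' (useful to reproduce a published tabulated value exactly).
#'
#' @param alpha significance level in (0, 1).
#' @param df positive integer degrees of freedom.
#' @param override optional positive scalar returned verbatim.
#' @return numeric(1).
#' @examples
#' criticalValue(0.05, 3)          # 7.8147
#' criticalValue(0.05, 3, 9.35)    # 9.35
#' @export
criticalValue <- function(alpha, df, override = NULL) {
    if (!is.null(override)) {
        if (!is.numeric(override) || length(override) != 1L || override <= 0)
            stop("'override' must be a positive scalar")
        return(as.numeric(override))
    }
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie strictly between 0 and 1")
    if (!is.numeric(df) || length(df) != 1L || df < 1)
        stop("'df' must be a positive integer")
    stats::qchisq(1 - alpha, df = df)
}

.decide <- function(qLower, qUpper, crit) {
    if (qUpper <= crit) "do_not_reject"
    else if (qLower > crit) "reject"
    else "indeterminate"
}

#' Neutrosophic chi-square test of homogeneity / goodness of fit
#'
#' Runs the full test on a [CountTable-class] (classical counts) or a
#' [NeutrosophicCountTable-class] (interval-valued counts). In
#' `"homogeneity"` mode the shared category probabilities are estimated
#' by pooling and the reference distribution has \eqn{(h-1)(k-1)}
#' degrees of freedom; in `"goodness_of_fit"` mode `probabilities` must
#' be supplied and the distribution has \eqn{h(k-1)} degrees of
#' freedom. The interval statistic \eqn{[Q_L, Q_U]} is compared with
#' the critical value under a trichotomous rule: do not reject when the
#' whole interval is at or below it, reject when the whole interval is
#' above it, and `"indeterminate"` when it straddles it — the state the
#' indeterminacy measure adds over the classical test.
#'
#' A warning is raised when any expected cell is below 5, the classical
#' adequacy heuristic for the chi-square approximation; an expected
#' cell of exactly 0 is an error.
#'
#' @param x a [CountTable-class] or [NeutrosophicCountTable-class].
#' @param indeterminacy an [IndeterminacyInterval-class]; the default
#'   `[0, 0]` reproduces the classical test.
#' @param alpha significance level, default 0.05.
#' @param mode `"homogeneity"` (default) or `"goodness_of_fit"`.
#' @param probabilities category probabilities, required in
#'   goodness-of-fit mode and ignored otherwise.
#' @param critical optional critical-value override (see
#'   [criticalValue()]).
#' @return a [NeutrosophicChisqTest-class].
#' @examples
#' res <- neutroChisqTest(brca2CountTable(),
#'                        indeterminacy = indeterminacyInterval(0, 0.05),
#'                        critical = 9.35)
#' res
#' @export
neutroChisqTest <- function(x,
                            indeterminacy = indeterminacyInterval(0, 0),
                            alpha = 0.05,
                            mode = c("homogeneity", "goodness_of_fit"),
                            probabilities = NULL,
                            critical = NULL) {
    mode <- match.arg(mode)
    if (is(x, "CountTable"))
        x <- neutrosophicCountTable(x)
    stopifnot(is(x, "NeutrosophicCountTable"))
    h <- nrow(counts(x@lower)); k <- ncol(counts(x@lower))
    if (mode == "homogeneity") {
        est <- estimatePooledProbabilities(x)
        pL <- est@probLower; pU <- est@probUpper
    } else {
        if (is.null(probabilities))
            stop("goodness_of_fit mode requires 'probabilities'")
        pL <- pU <- as.numeric(probabilities)
    }
    eL <- expectedCounts(x@lower, pL)
    if (any(eL < 5) || any(expectedCounts(x@upper, pU) < 5))
        warning("some expected cell counts are below 5; ",
                "the chi-square approximation may be poor")
    lowerPearson <- pearsonStatistic(x@lower, pL)
    upperPearson <- pearsonStatistic(x@upper, pU)
    stat <- .NeutrosophicValue(lowerPearson$statistic,
                               upperPearson$statistic, indeterminacy)
    df <- degreesOfFreedom(h, k, mode)
    crit <- criticalValue(alpha, df, override = critical)
    new("NeutrosophicChisqTest",
        statistic = stat,
        cellContributions = lowerPearson$contributions,
        df = df,
        criticalValue = crit,
        decision = .decide(stat@lower, stat@upper, crit),
        alpha = alpha,
        mode = mode)
}

#' @rdname accessors
setMethod("statistic", "NeutrosophicChisqTest", function(x) x@statistic)
#' @rdname accessors
setMethod("decision", "NeutrosophicChisqTest", function(x) x@decision)
#' @rdname accessors
setMethod("cellContributions", "NeutrosophicChisqTest",
    function(x) x@cellContributions)

#' Convert a test result to a plain list
#'
#' Flat representation of every component of the result, suitable for
#' JSON serialization (`jsonlite::toJSON(as.list(res), auto_unbox =
#' TRUE)`).
#'
#' @param x a [NeutrosophicChisqTest-class].
#' @param ... ignored.
#' @return a named list.
#' @export
setMethod("as.list", "NeutrosophicChisqTest", function(x, ...) {
    s <- x@statistic
    list(statistic_lower = s@lower,
         statistic_upper = s@upper,
         determinate_part = s@determinate,
         indeterminate_coefficient = s@coefficient,
         indeterminacy_lower = s@indeterminacy@lower,
         indeterminacy_upper = s@indeterminacy@upper,
         degrees_of_freedom = x@df,
         alpha = x@alpha,
         critical_value = x@criticalValue,
         decision = x@decision,
         mode = x@mode,
         cell_contributions = x@cellContributions)
})

setMethod("show", "NeutrosophicChisqTest", function(object) {
    s <- object@statistic
    hyp <- if (object@mode == "homogeneity")
        "category allocation is the same in every group"
    else "counts follow the specified category probabilities"
    cat("Neutrosophic chi-square test (", object@mode, ")\n", sep = "")
    cat("Step 1: H0: ", hyp, " vs. H1: it is not\n", sep = "")
    cat(sprintf("Step 2: alpha = %g, critical value = %g (df = %d)\n",
                object@alpha, object@criticalValue, object@df))
    cat(sprintf("Step 3: Q_N in [%.6f, %.6f]  (form %.6f + %.6f*I, I in [%g, %g])\n",
                s@lower, s@upper, s@determinate, s@coefficient,
                s@indeterminacy@lower, s@indeterminacy@upper))
    verdict <- switch(object@decision,
        do_not_reject = "do not reject H0",
        reject = "reject H0",
        indeterminate = "indeterminate (interval straddles the critical value)")
    cat("Step 4: decision: ", verdict, "\n", sep = "")
})
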