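#' Default indeterminacy sweep grid
#'
#' The 20-point grid 0, 0.01, ..., 0.09, 0.1, 0.2, ..., 1.0 over which
#' the effect of the indeterminacy measure on the statistic is
#' tabulated.
#'
#' @return numeric vector of length 20.
#' @export
defaultSweepGrid <- function()
    c(0, seq(0.01, 0.09, by = 0.01), seq(0.1, 1, by = 0.1))

#' Indeterminacy sweep of the neutrosophic statistic
#'
#' Recomputes the test over a grid of indeterminacy upper bounds
#' \eqn{I_U} (with \eqn{I_L} fixed at 0): the determinate statistic
#' \eqn{Q_L} is constant across the sweep and the upper endpoint is
#' \eqn{(1 + I_U) Q_L}, so the sweep shows at which level of
#' indeterminacy — if any — the decision leaves the do-not-reject
#' state.
#'
#' @param x a [CountTable-class].
#' @param iUppers nonnegative, ascending grid of \eqn{I_U} values;
#'   default [defaultSweepGrid()].
#' @inheritParams neutroChisqTest
#' @return a `data.frame` with columns `i_lower`, `i_upper`, `q_lower`,
#'   `q_upper`, `decision`, one row per grid point.
#' @examples
#' head(indeterminacySweep(brca2CountTable(), critical = 9.35), 3)
#' @export
indeterminacySweep <- function(x, iUppers = defaultSweepGrid(),
                               alpha = 0.05,
                               mode = c("homogeneity", "goodness_of_fit"),
                               probabilities = NULL, critical = NULL) {
    mode <- match.arg(mode)
    if (!is.numeric(iUppers) || length(iUppers) == 0L || any(iUppers < 0))
        stop("'iUppers' must be nonnegative")
    if (is.unsorted(iUppers, strictly = FALSE))
        stop("'iUppers' must be sorted ascending")
    base <- neutroChisqTest(x, indeterminacy = indeterminacyInterval(0, 0),
                            alpha = alpha, mode = mode,
                            probabilities = probabilities,
                            critical = critical)
    qL <- determinatePart(statistic(base))
    crit <- base@criticalValue
    qU <- (1 + iUppers) * qL
    data.frame(i_lower = 0, i_upper = iUppers, q_lower = qL, q_upper = qU,
               decision = vapply(seq_along(iUppers), function(r)
                   .decide(qL, qU[r], crit), character(1)),
               stringsAsFactors = FALSE)
}

## Evaluate fn() under a temporary RNG state seeded with 'seed',
## restoring the caller's state afterwards.
.withSeed <- function(seed, fn) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    fn()
}

## Spawn per-replicate substream seeds from one root seed, so results
## do not depend on the order replicates are executed in.
.spawnSeeds <- function(seed, n)
    .withSeed(seed, function() sample.int(.Machine$integer.max, n))

#' Generate a count table under the homogeneity null
#'
#' Draws each group independently from a multinomial distribution with
#' the shared category-probability vector, the sampling model the test
#' assumes under H0. Reproducible: a fixed seed yields an identical
#' table.
#'
#' @param groupSizes integer vector of per-group trial counts
#'   (\eqn{n_j}).
#' @param probabilities shared category probabilities (sum to 1,
#'   absolute tolerance 1e-9).
#' @param seed integer seed.
#' @param categoryLabels optional labels, default `cat1..k`.
#' @return a [CountTable-class] with `length(groupSizes)` rows.
#' @export
generateNullTable <- function(groupSizes, probabilities, seed,
                              categoryLabels = NULL) {
    p <- as.numeric(probabilities)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("probabilities must be nonnegative and sum to 1")
    if (length(groupSizes) < 1L || any(groupSizes < 1))
        stop("group sizes must be positive")
    m <- .withSeed(seed, function()
        t(vapply(groupSizes, function(n)
            stats::rmultinom(1, size = n, prob = p)[, 1L],
            numeric(length(p)))))
    countTable(m, categoryLabels = categoryLabels)
}

## Shared Monte Carlo engine: probRows is an h x k matrix (one row of
## sampling probabilities per group; identical rows under H0).
.monteCarlo <- function(replicates, seed, groupSizes, probRows, alpha,
                        indeterminacy, critical = NULL) {
    if (!is.numeric(replicates) || replicates < 1)
        stop("'replicates' must be >= 1")
    replicates <- as.integer(replicates)
    h <- length(groupSizes)
    stopifnot(nrow(probRows) == h)
    seeds <- .spawnSeeds(seed, replicates)
    decisions <- vapply(seq_len(replicates), function(r) {
        tab <- .withSeed(seeds[r], function()
            t(vapply(seq_len(h), function(j)
                stats::rmultinom(1, groupSizes[j], probRows[j, ])[, 1L],
                numeric(ncol(probRows)))))
        res <- suppressWarnings(
            neutroChisqTest(countTable(tab), indeterminacy = indeterminacy,
                            alpha = alpha, critical = critical))
        res@decision
    }, character(1))
    rej <- mean(decisions == "reject")
    structure(list(
        rejection_rate = rej,
        indeterminate_rate = mean(decisions == "indeterminate"),
        standard_error = sqrt(rej * (1 - rej) / replicates),
        replicates_run = replicates), class = "MonteCarloResult")
}

#' @export
print.MonteCarloResult <- function(x, ...) {
    cat(sprintf(paste0("Monte Carlo: %d replicates, rejection rate %.4f ",
                       "(SE %.4f), indeterminate rate %.4f\n"),
                x$replicates_run, x$rejection_rate, x$standard_error,
                x$indeterminate_rate))
    invisible(x)
}

#' Empirical type-I error of the test
#'
#' Repeatedly samples count tables under the homogeneity null (all
#' groups share `nullProbabilities`), runs the test on each, and
#' reports the fraction of replicates rejected and the fraction left
#' indeterminate. With indeterminacy [0, 0] and the default critical
#' value the rejection rate estimates the classical type-I error and
#' should sit near `alpha`; widening the indeterminacy interval can
#' only move rejections into the indeterminate state.
#'
#' @param replicates number of Monte Carlo replicates (>= 1).
#' @param seed integer root seed; per-replicate substreams are derived
#'   from it, so results are independent of execution order.
#' @param groupSizes per-group multinomial trial counts.
#' @param nullProbabilities shared category probabilities under H0.
#' @inheritParams neutroChisqTest
#' @return a `MonteCarloResult` list: `rejection_rate`,
#'   `indeterminate_rate`, `standard_error` (binomial SE of the
#'   rejection rate), `replicates_run`.
#' @export
estimateTypeIError <- function(replicates, seed, groupSizes,
                               nullProbabilities, alpha = 0.05,
                               indeterminacy = indeterminacyInterval(0, 0),
                               critical = NULL) {
    p <- as.numeric(nullProbabilities)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("probabilities must be nonnegative and sum to 1")
    probRows <- matrix(p, nrow = length(groupSizes), ncol = length(p),
                       byrow = TRUE)
    .monteCarlo(replicates, seed, groupSizes, probRows, alpha,
                indeterminacy, critical)
}

#' Empirical power of the test
#'
#' Like [estimateTypeIError()], but sampling each group from its own
#' row of `alternativeProbabilities`, so the homogeneity null is false
#' whenever the rows differ; passing identical rows recovers the null
#' and the rejection rate falls back to `alpha`.
#'
#' @inheritParams estimateTypeIError
#' @param alternativeProbabilities h x k matrix, one probability vector
#'   per group (rows sum to 1).
#' @return a `MonteCarloResult` list (see [estimateTypeIError()]).
#' @export
estimatePower <- function(replicates, seed, groupSizes,
                          alternativeProbabilities, alpha = 0.05,
                          indeterminacy = indeterminacyInterval(0, 0),
                          critical = NULL) {
    probRows <- as.matrix(alternativeProbabilities)
    if (nrow(probRows) != length(groupSizes))
        stop("'alternativeProbabilities' needs one row per group")
    if (any(probRows < 0) || any(abs(rowSums(probRows) - 1) > 1e-9))
        stop("each probability row must be nonnegative and sum to 1")
    .monteCarlo(replicates, seed, groupSizes, probRows, alpha,
                indeterminacy, critical)
}

#' Write a synthetic FASTA file with multinomial base composition
#'
#' Each record is an i.i.d. sequence over {A, C, G, T} with the given
#' base probabilities, so its composition is multinomial(length, p) and
#' [countNucleotides()] on the written file recovers the generated
#' counts exactly. Byte-identical output under a fixed seed.
#'
#' @param records number of records (>= 1).
#' @param length sequence length per record (> 0); scalar or one value
#'   per record.
#' @param probabilities length-4 vector over (A, C, G, T) summing to 1.
#' @param seed integer root seed (one substream per record).
#' @param path destination FASTA path.
#' @return invisibly, the [CountTable-class] of the generated per-record
#'   base counts.
#' @export
generateSyntheticFasta <- function(records, length, probabilities, seed,
                                   path) {
    p <- as.numeric(probabilities)
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("'probabilities' must be 4 nonnegative values over (A,C,G,T) summing to 1")
    if (records < 1L)
        stop("'records' must be >= 1")
    len <- rep_len(as.integer(length), records)
    if (any(len <= 0))
        stop("'length' must be positive")
    seeds <- .spawnSeeds(seed, records)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(records), function(r)
        .withSeed(seeds[r], function()
            paste(sample(bases, len[r], replace = TRUE, prob = p),
                  collapse = "")), character(1))
    names(seqs) <- paste0("synthetic_", seq_len(records))
    set <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(set, filepath = path, width = 70L)
    tab <- Biostrings::letterFrequency(set, letters = bases)
    rownames(tab) <- names(seqs)
    invisible(countTable(tab))
}
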