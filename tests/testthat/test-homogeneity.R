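t1 <- brca2CountTable()

test_that("pooled estimation matches hand-computed proportions", {
    est <- estimatePooledProbabilities(t1)
    p <- probabilities(est)
    expect_equal(unname(p["lower", "A"]), 77064 / 254252)
    expect_equal(unname(p["lower", ]), unname(p["upper", ]))
    expect_equal(sum(p["lower", ]), 1)
    expect_equal(sum(p["upper", ]), 1)

    single <- countTable(rbind(g1 = c(10, 10)))
    expect_equal(unname(probabilities(estimatePooledProbabilities(single))["lower", ]),
                 c(0.5, 0.5))

    # distinct endpoint tables give distinct endpoint estimates
    lo <- countTable(rbind(g1 = c(5, 5), g2 = c(5, 5)))
    hi <- countTable(rbind(g1 = c(6, 5), g2 = c(6, 5)))
    est2 <- estimatePooledProbabilities(neutrosophicCountTable(lo, hi))
    expect_equal(unname(probabilities(est2)["lower", ]), c(0.5, 0.5))
    expect_equal(unname(probabilities(est2)["upper", ]), c(12, 10) / 22)

    empty <- countTable(rbind(g1 = c(0, 0)))
    expect_error(estimatePooledProbabilities(empty), "zero grand total")
})

test_that("expected counts reproduce n_j * p_i and conserve group totals", {
    p <- probabilities(estimatePooledProbabilities(t1))["lower", ]
    e <- expectedCounts(t1, p)
    expect_equal(unname(e["Count Group 1", "A"]), 127079 * 77064 / 254252)
    expect_equal(unname(e["Count Group 1", "A"]), 38517.75, tolerance = 1e-6)
    expect_equal(unname(rowSums(e)), unname(groupTotals(t1)))

    u <- countTable(rbind(g = c(40, 30, 20, 10)))
    expect_equal(unname(expectedCounts(u, rep(0.25, 4))[1, ]), rep(25, 4))
    expect_error(expectedCounts(u, c(0.5, 0.5, 0, 0)), "zero expected")
    expect_error(expectedCounts(u, c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
})

test_that("Pearson statistic reproduces the worked nucleotide example", {
    p <- probabilities(estimatePooledProbabilities(t1))["lower", ]
    ps <- pearsonStatistic(t1, p)
    expect_equal(ps$statistic, 0.00664, tolerance = 1e-3)
    expect_equal(unname(ps$contributions["Count Group 1", "A"]),
                 0.000365921, tolerance = 1e-5)
    expect_equal(unname(ps$contributions["Count Group 2", "T"]),
                 0.000748132, tolerance = 1e-5)
    expect_equal(sum(ps$contributions), ps$statistic)

    # observed == expected gives exactly zero
    even <- countTable(rbind(g1 = c(25, 25), g2 = c(50, 50)))
    expect_equal(pearsonStatistic(
        even, probabilities(estimatePooledProbabilities(even))["lower", ])$statistic, 0)

    # 2x2 closed form
    m <- countTable(rbind(g1 = c(30, 10), g2 = c(10, 30)))
    pm <- probabilities(estimatePooledProbabilities(m))["lower", ]
    expect_equal(pearsonStatistic(m, pm)$statistic, 20)
    expect_equal(closedForm2x2(30, 10, 10, 30), 20)
})

test_that("neutrosophic statistic forms agree with published values and each other", {
    q <- neutrosophicStatistic(0.00664, indeterminacyInterval(0, 0.05))
    expect_equal(c(lowerBound(q), upperBound(q)), c(0.00664, 0.006972))
    q2 <- neutrosophicStatistic(0.00664, indeterminacyInterval(0, 0.2))
    expect_equal(upperBound(q2), 0.007968)
    q0 <- neutrosophicStatistic(1.23, indeterminacyInterval(0, 0))
    expect_equal(lowerBound(q0), upperBound(q0))
    expect_error(neutrosophicStatistic(-0.1, indeterminacyInterval(0, 0)),
                 "nonnegative")

    # degenerate interval table: general two-sum form == multiplicative form
    nt <- neutrosophicCountTable(t1)
    g <- generalIntervalStatistic(nt, indeterminacy = indeterminacyInterval(0, 0.05))
    qL <- pearsonStatistic(
        t1, probabilities(estimatePooledProbabilities(t1))["lower", ])$statistic
    m <- neutrosophicStatistic(qL, indeterminacyInterval(0, 0.05))
    expect_equal(lowerBound(g), lowerBound(m))
    expect_equal(upperBound(g), upperBound(m))

    # doubling all counts doubles the Pearson sum, so with I = [0, 1]
    # the upper endpoint is Q_L + 2 Q_L = 3 Q_L
    lo <- countTable(rbind(g1 = c(30, 10), g2 = c(10, 30)))
    hi <- countTable(2 * counts(lo))
    gi <- generalIntervalStatistic(neutrosophicCountTable(lo, hi),
                                   indeterminacy = indeterminacyInterval(0, 1))
    expect_equal(lowerBound(gi), 20)
    expect_equal(upperBound(gi), 3 * 20)
    expect_equal(indeterminateCoefficient(gi), 40)

    gz <- generalIntervalStatistic(neutrosophicCountTable(lo, hi),
                                   indeterminacy = indeterminacyInterval(0, 0))
    expect_equal(lowerBound(gz), upperBound(gz))
})

test_that("degrees of freedom and critical values follow the two regimes", {
    expect_identical(degreesOfFreedom(2, 4, "homogeneity"), 3L)
    expect_identical(degreesOfFreedom(2, 4, "goodness_of_fit"), 6L)
    expect_identical(degreesOfFreedom(1, 2, "goodness_of_fit"), 1L)
    expect_error(degreesOfFreedom(1, 4, "homogeneity"), "at least 2 groups")
    expect_error(degreesOfFreedom(2, 1), "categories")

    expect_equal(criticalValue(0.05, 3, override = 9.35), 9.35)
    expect_equal(criticalValue(0.05, 3), 7.8147, tolerance = 1e-4)
    expect_lt(criticalValue(0.999, 3), 0.03)  # alpha -> 1 sends the threshold to 0
    expect_error(criticalValue(1.2, 3), "between 0 and 1")
    expect_error(criticalValue(0.05, 0), "positive")
    expect_error(criticalValue(0.05, 3, override = -1), "positive")
})

test_that("the full test reproduces the worked example decision", {
    res <- neutroChisqTest(t1, indeterminacy = indeterminacyInterval(0, 0.05),
                           critical = 9.35)
    s <- statistic(res)
    expect_equal(lowerBound(s), 0.00664, tolerance = 1e-3)
    expect_equal(upperBound(s), 0.006972, tolerance = 1e-3)
    expect_identical(decision(res), "do_not_reject")
    expect_identical(res@df, 3L)
    expect_equal(sum(cellContributions(res)), determinatePart(s))

    # classical defaults: degenerate interval statistic
    res0 <- neutroChisqTest(t1)
    expect_equal(lowerBound(statistic(res0)), upperBound(statistic(res0)))
    expect_equal(res0@criticalValue, qchisq(0.95, 3))

    # clearly heterogeneous table rejects classically
    m <- countTable(rbind(g1 = c(30, 10), g2 = c(10, 30)))
    resm <- neutroChisqTest(m)
    expect_identical(decision(resm), "reject")
    expect_equal(lowerBound(statistic(resm)), 20)
    expect_equal(resm@criticalValue, qchisq(0.95, 1))

    expect_error(neutroChisqTest(m, mode = "goodness_of_fit"),
                 "requires 'probabilities'")
    gof <- neutroChisqTest(countTable(rbind(g = c(25, 25, 25, 25))),
                           mode = "goodness_of_fit",
                           probabilities = rep(0.25, 4))
    expect_identical(gof@df, 3L)
    expect_equal(lowerBound(statistic(gof)), 0)
    expect_identical(decision(gof), "do_not_reject")

    small <- countTable(rbind(g1 = c(3, 7), g2 = c(4, 6)))
    expect_warning(neutroChisqTest(small), "below 5")
})

test_that("trichotomous decisions partition the critical range", {
    m <- countTable(rbind(g1 = c(30, 10), g2 = c(10, 30)))  # Q_L = 20
    ind <- indeterminacyInterval(0, 0.5)
    crit_below <- 19       # whole interval above -> reject
    crit_inside <- 25      # straddles [20, 30] -> indeterminate
    crit_above <- 31       # whole interval at/below -> do not reject
    d <- vapply(c(crit_below, crit_inside, crit_above), function(cv)
        decision(neutroChisqTest(m, indeterminacy = ind, critical = cv)),
        character(1))
    expect_identical(d, c("reject", "indeterminate", "do_not_reject"))
    # boundary: Q_U == crit counts as do-not-reject, Q_L == crit is not a rejection
    expect_identical(decision(neutroChisqTest(m, indeterminacy = ind,
                                              critical = 30)), "do_not_reject")
    expect_identical(decision(neutroChisqTest(m, indeterminacy = ind,
                                              critical = 20)), "indeterminate")
})

test_that("classical reduction and invariances hold on random tables", {
    set.seed(99)
    for (rep in 1:25) {
        m <- randomCountMatrix(sample(2:4, 1), sample(2:5, 1), 300)
        tab <- countTable(m)
        res <- suppressWarnings(neutroChisqTest(tab))
        qL <- lowerBound(statistic(res))
        expect_equal(qL, upperBound(statistic(res)))
        expect_equal(qL, bruteForcePearson(m), tolerance = 1e-12)
        # label/permutation invariance
        gp <- sample(nrow(m)); cp <- sample(ncol(m))
        perm <- suppressWarnings(neutroChisqTest(countTable(m[gp, cp, drop = FALSE])))
        expect_equal(lowerBound(statistic(perm)), qL)
        # monotonicity of the upper endpoint in I_U
        u1 <- upperBound(statistic(suppressWarnings(
            neutroChisqTest(tab, indeterminacy = indeterminacyInterval(0, 0.3)))))
        u2 <- upperBound(statistic(suppressWarnings(
            neutroChisqTest(tab, indeterminacy = indeterminacyInterval(0, 0.7)))))
        expect_gte(u2, u1)
    }
})

test_that("results serialize to a flat list", {
    res <- neutroChisqTest(t1, indeterminacy = indeterminacyInterval(0, 0.05),
                           critical = 9.35)
    l <- as.list(res)
    expect_equal(l$statistic_upper, upperBound(statistic(res)))
    expect_identical(l$decision, "do_not_reject")
    expect_identical(dim(l$cell_contributions), c(2L, 4L))
    out <- capture.output(show(res))
    expect_true(any(grepl("Step 4", out)))
})
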