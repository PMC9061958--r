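# Independent oracles and fixture builders used across the suite.

# Brute-force Pearson chi-square of homogeneity: pooled estimates and an
# explicit double loop, deliberately independent of the package's
# vectorised implementation.
bruteForcePearson <- function(m) {
    p <- colSums(m) / sum(m)
    q <- 0
    for (j in seq_len(nrow(m))) {
        nj <- sum(m[j, ])
        for (i in seq_len(ncol(m))) {
            e <- nj * p[i]
            q <- q + (m[j, i] - e)^2 / e
        }
    }
    q
}

# Closed form for a 2x2 table: N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
closedForm2x2 <- function(a, b, c, d) {
    (a + b + c + d) * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
}

# Seeded random count table with all-positive column sums.
randomCountMatrix <- function(h, k, nPerGroup = 200) {
    p <- as.numeric(rmultinom(1, 50, rep(1 / k, k)) + 1)
    p <- p / sum(p)
    t(vapply(seq_len(h), function(j)
        rmultinom(1, nPerGroup, p)[, 1], numeric(k)))
}

table1Counts <- function() {
    rbind(`Count Group 1` = c(A = 38514, C = 24631, G = 25685, T = 38249),
          `Count Group 2` = c(A = 38550, C = 24635, G = 25700, T = 38288))
}

# (I_U, Q_U) pairs of the published indeterminacy sweep on the worked
# example; Q_L is 0.00664 throughout.
table2SweepValues <- function() {
    data.frame(
        i_upper = c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09,
                    0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
        q_upper = c(0.00664, 0.006706, 0.006773, 0.006839, 0.006906, 0.006972,
                    0.007038, 0.007105, 0.007171, 0.007238,
                    0.007304, 0.007968, 0.008632, 0.009296, 0.00996,
                    0.010624, 0.011288, 0.011952, 0.012616, 0.01328))
}
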