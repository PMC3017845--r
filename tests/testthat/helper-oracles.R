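# Independent oracles used across the suite. These deliberately do not share
# code with the package internals.

# Step-up FDR adjustment, literal definition: sort ascending,
# q_i = min_{j >= i} (m * p_(j) / j) capped at 1, return in input order.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    run <- Inf
    for (i in m:1) {
        run <- min(run, m * ps[i] / i)
        q[i] <- min(run, 1)
    }
    q[order(o)]
}

# Exact two-sided rank-sum p-value by full enumeration of all group-1
# assignments (midranks; deviation-based two-sided p).
rankSumEnumOracle <- function(v1, v2) {
    v <- c(v1, v2)
    n1 <- length(v1); N <- length(v)
    r <- rank(v)
    mu <- n1 * (N + 1) / 2
    obs <- abs(sum(r[seq_len(n1)]) - mu)
    idx <- utils::combn(N, n1)
    Wall <- colSums(matrix(r[idx], nrow = n1))
    mean(abs(Wall - mu) >= obs - 1e-9)
}

# Small deterministic two-group PeptideSet used by several unit tests.
tinyPeptideSet <- function() {
    a <- rbind(p1 = c(10, 12, 0, 3, 2, 0),
               p2 = c(0, 0, 0, 5, 6, 7),
               p3 = c(2, 3, 4, 2.5, 3.5, 4.5))
    colnames(a) <- c("F1", "F2", "F3", "M1", "M2", "M3")
    PeptideSet(a, group = c("F", "F", "F", "M", "M", "M"),
               mass = c(1000, 2000, 3000), ceTime = c(20, 25, 30))
}
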