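# Independent reference implementations used to cross-check the package.

# Brute-force O(n^3) UPGMA on a distance matrix: at every step, recompute
# the mean pairwise distance between every pair of current clusters from
# the original matrix and merge the closest pair. Returns sorted merge
# heights.
upgmaOracleHeights <- function(D) {
    n <- nrow(D)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- c(NA, NA)
        bestd <- Inf
        for (i in seq_len(length(clusters) - 1L)) {
            for (j in (i + 1L):length(clusters)) {
                dij <- mean(D[clusters[[i]], clusters[[j]]])
                if (dij < bestd) {
                    bestd <- dij
                    best <- c(i, j)
                }
            }
        }
        heights <- c(heights, bestd)
        clusters[[best[1]]] <- c(clusters[[best[1]]],
                                 clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    sort(heights)
}

# Hypergeometric upper-tail P(X >= k) as an explicit sum of
# choose-products (log scale for stability).
hyperTailOracle <- function(k, K, N, m) {
    hi <- min(m, K)
    if (k > hi)
        return(0)
    j <- k:hi
    sum(exp(lchoose(K, j) + lchoose(N - K, m - j) - lchoose(N, m)))
}

# Best-of-two-permutations agreement between a recovered LB/RB partition
# and the planted branch truth (branch names are arbitrary).
branchAgreement <- function(branchLabels, truth) {
    truth <- truth[names(branchLabels)[branchLabels != "excluded"]]
    lab <- branchLabels[branchLabels != "excluded"]
    a1 <- mean((lab == "LB") == (truth == "B1"))
    max(a1, 1 - a1)
}

# Recovered cluster membership as an integer vector over all genes
# (0 = not assigned).
membershipVector <- function(clusterSet, allGenes) {
    memb <- stats::setNames(rep(0L, length(allGenes)), allGenes)
    cl <- geneSets(clusterSet)
    for (i in seq_along(cl))
        memb[cl[[i]]] <- i
    memb
}

# A small, quick synthetic configuration used across module tests.
smallConfig <- function(seed = 1, distortion = NULL, ...) {
    syntheticConfig(
        nGenes = 2000,
        clusters = list(clusterSpec(120, c(0, -1, 0)),
                        clusterSpec(100, c(0, 0, 1)),
                        clusterSpec(100, c(0, -1, -1)),
                        clusterSpec(120, c(0, 1, 1)),
                        clusterSpec(110, c(0, 1, -1))),
        distortion = distortion,
        seed = seed, ...)
}

randomExpressionMatrix <- function(n, p, seed = 1, groups = NULL) {
    set.seed(seed)
    V <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("g%03d", seq_len(n)),
                                sprintf("s%02d", seq_len(p))))
    ExpressionMatrix(V, groups = groups)
}
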