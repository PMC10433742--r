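test_that("uncentered Pearson distance matches hand computations", {
    expect_equal(uncenteredPearsonDistance(c(1, 2, 3), c(2, 4, 6)), 0)
    expect_equal(uncenteredPearsonDistance(c(1, 0), c(0, 1)), 1)
    # s = 1 / sqrt(2 * 2) = 1/2
    expect_equal(uncenteredPearsonDistance(c(1, 1, 0), c(0, 1, 1)), 0.5)
    expect_equal(uncenteredPearsonDistance(c(0, 0), c(1, 2)), 1)
    expect_error(uncenteredPearsonDistance(1:3, 1:4), "equal lengths")
})

test_that("uncentered similarity is scale- but not shift-invariant", {
    set.seed(30)
    for (i in 1:20) {
        x <- stats::rnorm(8)
        y <- stats::rnorm(8)
        a <- stats::runif(1, 0.1, 10)
        b <- stats::runif(1, 0.1, 10)
        expect_equal(uncenteredPearsonDistance(a * x, b * y),
                     uncenteredPearsonDistance(x, y), tolerance = 1e-12)
    }
    # (1,2) vs (2,3) are perfectly correlated but not proportional
    expect_gt(uncenteredPearsonDistance(c(1, 2), c(2, 3)), 1e-3)
})

test_that("average linkage reproduces small UPGMA arithmetic", {
    # 2 items: single merge at their distance
    D2 <- matrix(c(0, 0.3, 0.3, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    t2 <- averageLinkage(distances = D2)
    expect_equal(t2$height, 0.3)
    # 3 items, d(1,2)=0.1, d(1,3)=d(2,3)=0.5: merges at 0.1 then 0.5
    D3 <- matrix(c(0, 0.1, 0.5,
                   0.1, 0, 0.5,
                   0.5, 0.5, 0), 3, byrow = TRUE,
                 dimnames = list(letters[1:3], letters[1:3]))
    t3 <- averageLinkage(distances = D3)
    expect_equal(t3$height, c(0.1, 0.5))
    expect_identical(sort(t3$merge[1, ]), c(-2L, -1L))
})

test_that("linkage heights match a brute-force UPGMA oracle", {
    set.seed(31)
    for (i in 1:30) {
        n <- sample(3:25, 1)
        X <- matrix(stats::rnorm(n * 6), n)
        D <- uncenteredPearsonDist(X)
        tree <- averageLinkage(distances = D)
        expect_lt(max(abs(sort(tree$height) - upgmaOracleHeights(D))),
                  1e-9)
        expect_true(all(diff(tree$height) >= -1e-12))
    }
})

test_that("linkage agrees with hclust average linkage on random data", {
    set.seed(32)
    X <- matrix(stats::rnorm(40 * 6), 40)
    D <- uncenteredPearsonDist(X)
    ours <- averageLinkage(distances = D)
    ref <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-10)
})

test_that("tree cutting honours fraction, min size and leaf order", {
    # hand-built 4-leaf tree: pairs at 0.1 and 0.15, root at 1.0
    tree <- structure(list(
        merge = matrix(c(-1L, -2L, -3L, -4L, 1L, 2L), 3, 2,
                       byrow = TRUE),
        height = c(0.1, 0.15, 1.0), order = 1:4,
        labels = c("a", "b", "c", "d"), method = "average"),
        class = "hclust")
    cs <- cutGeneTree(tree, fraction = 0.2, minSize = 2)
    expect_identical(geneSets(cs),
                     list(C1 = c("a", "b"), C2 = c("c", "d")))
    # fraction 1: everything in one cluster
    cs1 <- cutGeneTree(tree, fraction = 1, minSize = 1)
    expect_length(geneSets(cs1), 1)
    expect_length(geneSets(cs1)$C1, 4)
    # fraction 0 with positive heights: all singletons, dropped at
    # minSize 2
    cs0 <- cutGeneTree(tree, fraction = 0, minSize = 2)
    expect_length(geneSets(cs0), 0)
    expect_length(cs0@discarded, 4)
    # absolute cut at the same height gives the same partition
    csA <- cutGeneTree(tree, fraction = 0.2, minSize = 2,
                       absolute = TRUE)
    expect_identical(geneSets(csA), geneSets(cs))
})

test_that("clusters from one cut partition the leaves", {
    set.seed(33)
    X <- matrix(stats::rnorm(60 * 8), 60,
                dimnames = list(sprintf("g%02d", 1:60), NULL))
    tree <- averageLinkage(X, "genes")
    cs <- cutGeneTree(tree, fraction = 0.5, minSize = 3)
    members <- unlist(geneSets(cs), use.names = FALSE)
    expect_false(anyDuplicated(members) > 0)
    expect_setequal(c(members, cs@discarded), rownames(X))
})

test_that("collective test compares per-sample cluster means", {
    set.seed(34)
    V <- matrix(stats::rnorm(20 * 12, sd = 0.2), 20, 12,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%02d", 1:12)))
    grp <- rep(c("trt", "ctl"), each = 6)
    V[, grp == "trt"] <- V[, grp == "trt"] + 1
    em <- ExpressionMatrix(V, groups = grp)
    res <- collectiveTest(em, rownames(V), "trt", "ctl")
    expect_lt(res$p, 0.01)
    expect_identical(res$direction, "up")
    # identical cluster means in both groups: t = 0, p = 1
    Vc <- matrix(rep(stats::rnorm(12), each = 4), 4, 12,
                 dimnames = list(paste0("g", 1:4),
                                 sprintf("s%02d", 1:12)))
    Vc[] <- 1
    emc <- ExpressionMatrix(Vc, groups = grp)
    resc <- collectiveTest(emc, paste0("g", 1:4), "trt", "ctl")
    expect_equal(resc$t, 0)
    expect_equal(resc$p, 1)
    # singleton cluster equals a per-gene t-test
    res1 <- collectiveTest(em, "g01", "trt", "ctl")
    ht <- stats::t.test(V["g01", grp == "trt"], V["g01", grp == "ctl"],
                        var.equal = TRUE)
    expect_equal(res1$t, unname(ht$statistic))
    expect_equal(res1$p, ht$p.value)
})

test_that("differential clusters carry the planted direction patterns", {
    ds <- generateDataset(smallConfig(seed = 35))
    em <- log2AndCenter(ds@matrix, log2 = FALSE)
    tree <- averageLinkage(em, "genes")
    cs <- cutGeneTree(tree, 0.2, minSize = 10)
    dc <- extractDifferentialClusters(
        em, cs, list(A = c("mimicA", "control"),
                     B = c("mimicB", "control")))
    # the cut recovers all five planted clusters ...
    expect_length(geneSets(cs), 5)
    # ... extraction keeps at least the multi-contrast ones (a cluster
    # shifted in a single contrast has ~88% collective-test power at the
    # planted cofactor strength, so one may legitimately drop out)
    expect_gte(length(geneSets(dc)), 4)
    planted <- c(`1` = "down@A|flat@B", `2` = "flat@A|up@B",
                 `3` = "down@A|down@B", `4` = "up@A|up@B",
                 `5` = "up@A|down@B")
    majors <- vapply(geneSets(dc), function(g) {
        tcl <- ds@truthClusters[g]
        as.integer(names(which.max(table(tcl[tcl > 0]))))
    }, integer(1))
    expect_true(all(c(3L, 4L, 5L) %in% majors))
    # every significant leg must agree in direction with the truth
    for (cn in names(dc@patterns)) {
        pat <- strsplit(dc@patterns[[cn]], "|", fixed = TRUE)[[1]]
        tru <- strsplit(planted[[as.character(majors[cn])]], "|",
                        fixed = TRUE)[[1]]
        bad <- pat != tru & !grepl("flat", pat) & !grepl("flat", tru)
        expect_equal(sum(bad), 0)
    }
    expect_true(all(dc@collective$p >= 0 & dc@collective$p <= 1))
    # alpha = 0 keeps nothing
    dc0 <- extractDifferentialClusters(
        em, cs, list(A = c("mimicA", "control")), alpha = 0)
    expect_length(geneSets(dc0), 0)
})
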