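test_that("generation is deterministic under a fixed seed", {
    d1 <- generateDataset(smallConfig(seed = 11))
    d2 <- generateDataset(smallConfig(seed = 11))
    expect_identical(exprValues(d1@matrix), exprValues(d2@matrix))
    expect_identical(d1@truthClusters, d2@truthClusters)
    expect_identical(geneSets(d1@truthTargets), geneSets(d2@truthTargets))
    d3 <- generateDataset(smallConfig(seed = 12))
    expect_false(identical(exprValues(d1@matrix), exprValues(d3@matrix)))
})

test_that("pure-noise variances follow the scaled inverse chi-square law", {
    cfg <- syntheticConfig(nGenes = 10000, clusters = list(),
                           groups = c(control = 6), distortion = NULL,
                           targetSpecs = list(), seed = 5)
    ds <- generateDataset(cfg)
    # true variances: d0 * s0^2 / sigma^2 ~ chi-square(d0)
    expect_gt(stats::ks.test(4 * 0.05 / ds@truthVariances, "pchisq",
                             df = 4)$p.value, 0.01)
    # observed per-gene sample variances: s^2 / s0^2 ~ F(n-1, d0)
    s2 <- apply(exprValues(ds@matrix), 1, stats::var)
    expect_gt(stats::ks.test(s2 / 0.05, "pf", df1 = 5, df2 = 4)$p.value,
              0.01)
})

test_that("background means and planted shifts match the configuration", {
    ds <- generateDataset(smallConfig(seed = 3))
    V <- exprValues(ds@matrix)
    grp <- sampleGroups(ds@matrix)
    bg <- names(ds@truthClusters)[ds@truthClusters == 0]
    expect_true(all(rowMeans(V[bg, ]) > 3 & rowMeans(V[bg, ]) < 13))
    # cluster 1 planted pattern (0, -1, 0): mimicA shifted down ~1
    c1 <- names(ds@truthClusters)[ds@truthClusters == 1]
    dAC <- mean(V[c1, grp == "mimicA"]) - mean(V[c1, grp == "control"])
    se <- stats::sd(colMeans(V[c1, grp == "mimicA"]) -
                    mean(V[c1, grp == "control"])) / sqrt(6)
    expect_lt(abs(dAC - (-1)), 3 * max(se, 0.1))
    dBC <- mean(V[c1, grp == "mimicB"]) - mean(V[c1, grp == "control"])
    expect_lt(abs(dBC), 3 * max(se, 0.1))
})

test_that("cluster genes are more mutually similar than background", {
    cfg <- syntheticConfig(nGenes = 500,
                           clusters = list(clusterSpec(100, c(0, -1, 0))),
                           distortion = NULL, targetSpecs = list(),
                           seed = 8)
    ds <- generateDataset(cfg)
    Vc <- log2AndCenter(ds@matrix, log2 = FALSE)
    V <- exprValues(Vc)
    inC <- names(ds@truthClusters)[ds@truthClusters == 1]
    outC <- names(ds@truthClusters)[ds@truthClusters == 0]
    simIn <- 1 - uncenteredPearsonDist(V[inC[1:50], ])
    simOut <- 1 - uncenteredPearsonDist(V[outC[1:50], ])
    mOff <- function(S) mean(S[upper.tri(S)])
    expect_gt(mOff(simIn), mOff(simOut))
})

test_that("target lists realize the configured enrichment folds", {
    truth <- stats::setNames(c(rep(1L, 500), rep(0L, 4500)),
                             sprintf("G%05d", 1:5000))
    tc <- generateTargetLists(truth,
                              list(targetSpec("t", 0.1, 4)), seed = 2)
    r <- foldEnrichment(names(truth)[truth == 1], geneSets(tc)$t,
                        geneBackground(tc))
    expect_gt(r$fold, 3)
    expect_lt(r$fold, 5)
    # fold 1 everywhere: membership independent of clusters
    tc1 <- generateTargetLists(truth,
                               list(targetSpec("t", 0.1, 1)), seed = 2)
    r1 <- foldEnrichment(names(truth)[truth == 1], geneSets(tc1)$t,
                         geneBackground(tc1))
    expect_gt(r1$p, 0.001)
    # zero background rate: empty list
    tc0 <- generateTargetLists(truth,
                               list(targetSpec("t", 0, 4)), seed = 2)
    expect_length(geneSets(tc0)$t, 0)
})

test_that("target specs referencing unknown clusters are rejected", {
    truth <- stats::setNames(c(rep(1L, 5), rep(2L, 5)),
                             sprintf("g%02d", 1:10))
    expect_error(generateTargetLists(truth,
                                     list(targetSpec("t", 0.1, 2)),
                                     seed = 1),
                 "lacks folds")
})

test_that("external cohort plants opposite shifts on signature genes", {
    sig <- sprintf("G%05d", 1:100)
    ec <- generateExternalCohort(sig, nPerBranch = 10, effect = 2,
                                 seed = 4, nBackgroundGenes = 200)
    V <- exprValues(ec$matrix)
    tr <- ec$truthBranches
    gap <- mean(V[sig, tr == "B1"]) - mean(V[sig, tr == "B2"])
    expect_lt(abs(gap - 2), 0.3)
    bg <- setdiff(rownames(V), sig)
    expect_lt(abs(mean(V[bg, tr == "B1"]) - mean(V[bg, tr == "B2"])),
              0.2)
    # effect 0: no planted structure
    ec0 <- generateExternalCohort(sig, nPerBranch = 10, effect = 0,
                                  seed = 4, nBackgroundGenes = 200)
    V0 <- exprValues(ec0$matrix)
    expect_lt(abs(mean(V0[sig, tr == "B1"]) - mean(V0[sig, tr == "B2"])),
              0.3)
    expect_error(generateExternalCohort(character(0), 10, 2, 1),
                 "non-empty")
    expect_error(generateExternalCohort(sig, 1, 2, 1), "at least 2")
})

test_that("invalid configurations are rejected", {
    expect_error(syntheticConfig(nGenes = 100,
                                 clusters = list(clusterSpec(80, c(0, 1, 0)),
                                                 clusterSpec(80, c(0, 1, 0)))),
                 "sum of cluster sizes")
    expect_error(clusterSpec(1, c(0, 1, 0)), ">= 2")
    expect_error(syntheticConfig(targetSpecs = list(
        targetSpec("t", 1.5, c(1, 1, 1, 1, 1)))), "background_rate")
})

test_that("synthetic datasets roundtrip to disk", {
    ds <- generateDataset(syntheticConfig(
        nGenes = 200, clusters = list(clusterSpec(50, c(0, 1, 0))),
        targetSpecs = list(targetSpec("t", 0.2, 2)), seed = 6))
    pfx <- file.path(withr::local_tempdir(), "ds")
    paths <- writeSyntheticDataset(ds, pfx)
    expect_true(all(file.exists(paths)))
    back <- readExpressionMatrix(paths["matrix"], "tsv")
    expect_equal(exprValues(back), exprValues(ds@matrix),
                 tolerance = 1e-12)
    tc <- readGeneSets(paths["targets"], "gmt")
    expect_identical(geneSets(tc)$t, geneSets(ds@truthTargets)$t)
})
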