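makeClusterSet <- function(clusters) {
    new("GeneClusterSet", clusters = clusters, discarded = character(0),
        cutHeight = 0.2, collective = data.frame(),
        patterns = character(0))
}

test_that("signature union keeps cluster provenance", {
    cs <- makeClusterSet(list(C1 = c("a", "b"), C2 = "c"))
    sig <- buildSignature(cs)
    expect_identical(signatureGenes(sig), c("a", "b", "c"))
    expect_identical(unname(provenance(sig)["c"]), "C2")
    expect_error(buildSignature(makeClusterSet(list())), "empty")
})

test_that("shared-target reduction is a symmetric subset operation", {
    cs <- makeClusterSet(list(C1 = c("a", "b", "c"),
                              C2 = c("d", "e")))
    sig <- buildSignature(cs)
    A <- c("a", "c", "d", "x")
    B <- c("a", "d", "e", "y")
    r1 <- reduceSharedTargets(sig, A, B)
    r2 <- reduceSharedTargets(sig, B, A)
    expect_identical(signatureGenes(r1), c("a", "d"))
    expect_identical(signatureGenes(r1), signatureGenes(r2))
    expect_true(all(signatureGenes(r1) %in% signatureGenes(sig)))
    expect_identical(unname(provenance(r1)[c("a", "d")]),
                     c("C1", "C2"))
    # brute-force three-way intersection oracle on a random instance
    set.seed(60)
    genes <- sprintf("g%03d", 1:200)
    cs2 <- makeClusterSet(list(C1 = genes[1:100],
                               C2 = genes[101:150]))
    s2 <- buildSignature(cs2)
    sa <- sample(genes, 80)
    sb <- sample(genes, 80)
    r <- reduceSharedTargets(s2, sa, sb)
    expect_setequal(signatureGenes(r),
                    intersect(intersect(signatureGenes(s2), sa), sb))
    # identity and disjoint limits
    expect_identical(
        signatureGenes(reduceSharedTargets(sig, signatureGenes(sig),
                                           signatureGenes(sig))),
        signatureGenes(sig))
    expect_warning(rEmpty <- reduceSharedTargets(sig, "x", "y"),
                   "empty")
    expect_length(signatureGenes(rEmpty), 0)
    # additional-set overlap counts
    rc <- reduceSharedTargets(sig, A, B,
                              alsoCount = list(extra = c("a", "z")))
    expect_equal(unname(attr(rc, "alsoCounts")["extra"]), 1L)
})

test_that("projection recovers planted branches and reports match rate", {
    sig <- sprintf("G%05d", 1:150)
    ec <- generateExternalCohort(sig, nPerBranch = 20, effect = 2,
                                 seed = 61, nBackgroundGenes = 500)
    bc <- projectSignature(ec$matrix, sig)
    expect_gte(branchAgreement(branches(bc), ec$truthBranches), 0.95)
    expect_equal(bc@matchRate, 1)
    # excluded samples are labelled and kept out of the branches
    bc2 <- projectSignature(ec$matrix, sig,
                            excludeSamples = c("S001", "S002"))
    expect_identical(unname(branches(bc2)[c("S001", "S002")]),
                     c("excluded", "excluded"))
    # low match rate: error advising harmonization
    expect_error(projectSignature(ec$matrix, paste0("nope", 1:50)),
                 "harmonize")
})

test_that("projection is invariant to orderings and positive rescaling", {
    sig <- sprintf("G%05d", 1:100)
    ec <- generateExternalCohort(sig, nPerBranch = 10, effect = 2,
                                 seed = 62, nBackgroundGenes = 300)
    V <- exprValues(ec$matrix)
    base <- branches(projectSignature(V, sig))
    set.seed(63)
    Vp <- V[sample(nrow(V)), sample(ncol(V))]
    expect_identical(branches(projectSignature(Vp, sig))[names(base)],
                     base)
    # uncentered-Pearson scale invariance: rescaling a centered sample
    # profile cannot move it across branches; rescale post-centering by
    # scaling the deviations around the gene medians
    meds <- apply(V, 1, stats::median)
    Vs <- V
    Vs[, 4] <- meds + 2.5 * (V[, 4] - meds)
    expect_identical(branches(projectSignature(Vs, sig))[names(base)],
                     base)
})

test_that("branch differential tests the whole transcriptome", {
    sig <- sprintf("G%05d", 1:120)
    ec <- generateExternalCohort(sig, nPerBranch = 12, effect = 2,
                                 seed = 64, nBackgroundGenes = 800)
    bc <- projectSignature(ec$matrix, sig)
    bd <- branchDifferential(ec$matrix, bc, fdrThreshold = 0.01)
    expect_equal(nrow(bd$table), nrow(ec$matrix))   # all genes tested
    hits <- union(bd$up, bd$down)
    expect_gt(length(intersect(hits, sig)), 0.9 * length(sig))
    # identical branch profiles: no genes
    V <- exprValues(ec$matrix)
    Vnull <- cbind(V[, 1:12], V[, 1:12])
    colnames(Vnull) <- sprintf("S%03d", 1:24)
    bdn <- branchDifferential(Vnull, new("BranchClassification",
        branches = stats::setNames(rep(c("LB", "RB"), each = 12),
                                   colnames(Vnull)),
        matchedGenes = sig, matchRate = 1, sampleTree = NULL),
        fdrThreshold = 0.01)
    expect_length(union(bdn$up, bdn$down), 0)
})

test_that("null cohorts yield almost no branch-differential genes", {
    set.seed(65)
    fracs <- numeric(10)
    sig <- sprintf("G%05d", 1:80)
    for (i in 1:10) {
        ec <- generateExternalCohort(sig, nPerBranch = 10, effect = 0,
                                     seed = 100 + i,
                                     nBackgroundGenes = 1000)
        bc <- projectSignature(ec$matrix, sig)
        bd <- branchDifferential(ec$matrix, bc, fdrThreshold = 0.01)
        fracs[i] <- length(union(bd$up, bd$down)) / nrow(ec$matrix)
    }
    expect_lte(mean(fracs), 0.01)
})

test_that("signatures roundtrip through their TSV representation", {
    cs <- makeClusterSet(list(C1 = c("a", "b"), C2 = c("c")))
    sig <- buildSignature(cs)
    red <- reduceSharedTargets(sig, c("a", "c"), c("a", "c"),
                               names = c("mirA", "mirB"))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSignature(red, path)
    back <- readSignature(path)
    expect_identical(signatureGenes(back), signatureGenes(red))
    expect_identical(provenance(back), provenance(red))
    expect_identical(back@reduction, c("mirA", "mirB"))
})
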