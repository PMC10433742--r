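#' Specify a planted co-expression cluster
#'
#' A planted cluster is a block of genes sharing (i) a group-specific mean
#' shift pattern and (ii) a within-cluster latent cofactor, so its members
#' are strongly positively correlated after centering, the structure the
#' co-expression clustering stage is designed to find.
#'
#' @param size number of member genes (>= 2).
#' @param pattern numeric vector of per-group mean shifts in log2 units,
#'   one per experimental group, 0 for the control group. The default
#'   pattern vocabulary mirrors the observed cluster classes: down in one
#'   mimic only, up in the other only, down/up in both, opposite in the
#'   two mimics.
#' @param loadingSd spread of the per-gene positive effect loadings
#'   around 1 (default 0.2).
#' @param cofactorSd strength of the shared per-sample latent factor
#'   (default 0.5).
#' @return a list, one element of the \code{clusters} field of
#'   [syntheticConfig()].
#' @export
clusterSpec <- function(size, pattern, loadingSd = 0.2, cofactorSd = 0.5) {
    if (size < 2)
        stop("cluster size must be >= 2")
    list(size = as.integer(size), pattern = as.numeric(pattern),
         loading_sd = loadingSd, cofactor_sd = cofactorSd)
}

#' Specify a planted target list
#'
#' @param name set name.
#' @param backgroundRate membership probability for background genes, in
#'   \code{[0, 1]}.
#' @param fold per-cluster enrichment folds (membership probability in
#'   cluster c is \code{min(1, fold[c] * backgroundRate)}).
#' @return a list, one element of \code{targetSpecs} in
#'   [syntheticConfig()].
#' @export
targetSpec <- function(name, backgroundRate, fold) {
    list(name = name, background_rate = backgroundRate,
         fold = as.numeric(fold))
}

.defaultClusterSpecs <- function() list(
    clusterSpec(400, c(0, -1,  0)),   # down in mimic A only
    clusterSpec(300, c(0,  0,  1)),   # up in mimic B only
    clusterSpec(300, c(0, -1, -1)),   # down in both mimics
    clusterSpec(400, c(0,  1,  1)),   # up in both mimics
    clusterSpec(350, c(0,  1, -1)))   # up in A, down in B

.defaultTargetSpecs <- function() list(
    targetSpec("mirA_targets", 0.10, c(4.0, 1.0, 1.5, 1.5, 2.0)),
    targetSpec("mirB_targets", 0.10, c(1.0, 1.5, 1.5, 2.0, 4.0)),
    targetSpec("rbp_targets",  0.15, c(2.6, 1.5, 2.2, 2.7, 2.0)))

#' Configure the synthetic expression-data generator
#'
#' Defaults emulate the study design the pipeline assumes: three
#' experimental groups (negative-control mimic and two microRNA mimics,
#' n = 6 each), five planted co-expressed clusters with group-specific
#' shift patterns, gene noise variances drawn from a scaled inverse
#' chi-square prior (so variance shrinkage is recoverable), target lists
#' enriched in the planted clusters at known folds, and smooth per-sample
#' quadratic intensity distortions for the LOWESS stage to remove.
#'
#' @param nGenes total gene count (default 12000).
#' @param groups named integer vector, group label -> sample count
#'   (default \code{c(control = 6, mimicA = 6, mimicB = 6)}).
#' @param clusters list of [clusterSpec()]s.
#' @param ebPrior an [EBPrior-class]; per-gene noise variances are drawn
#'   as \code{s0Sq * d0 / rchisq(d0)} (default d0 = 4, s0Sq = 0.05, a
#'   moderate-shrinkage regime).
#' @param distortion list with elements \code{c1Max} (max |linear|
#'   coefficient) and \code{c2Min}/\code{c2Max} (quadratic coefficient
#'   magnitude range, random sign), or \code{NULL} for no distortion.
#'   The per-sample transform is \code{y = x + c1 (x - xbar) + c2 (x -
#'   xbar)^2}; the default coefficient ranges keep it monotone over the
#'   simulated intensity range.
#' @param targetSpecs list of [targetSpec()]s; folds are per planted
#'   cluster.
#' @param seed integer seed; the generator is fully reproducible.
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nGenes = 12000,
                            groups = c(control = 6, mimicA = 6,
                                       mimicB = 6),
                            clusters = .defaultClusterSpecs(),
                            ebPrior = EBPrior(d0 = 4, s0Sq = 0.05),
                            distortion = list(c1Max = 0.08,
                                              c2Min = 0.015,
                                              c2Max = 0.035),
                            targetSpecs = .defaultTargetSpecs(),
                            seed = 1L) {
    gdf <- data.frame(label = names(groups), n = as.integer(groups),
                      stringsAsFactors = FALSE)
    if (is.null(distortion))
        distortion <- list()
    new("SyntheticConfig", nGenes = nGenes, groups = gdf,
        clusters = clusters, ebPrior = ebPrior, distortion = distortion,
        targetSpecs = targetSpecs, seed = as.numeric(seed))
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Gene g in sample j is simulated as \code{x_gj = mu_g + a_g *
#' (pattern_c[group(j)] + cofactorSd * z_cj) + eps_gj} for cluster genes
#' (with \code{z_cj} a per-sample standard-normal latent value shared by
#' the cluster and \code{a_g > 0} the gene loading) and \code{x_gj = mu_g
#' + eps_gj} for background genes; \code{eps_gj ~ N(0, sigma_g^2)} with
#' \code{sigma_g^2 ~ s0Sq * d0 / chisq(d0)}. Baselines \code{mu_g} are
#' uniform on [4, 12] (a log2-microarray-like dynamic range). The
#' configured per-sample monotone distortion, if any, is applied last.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [SyntheticDataset-class] with the matrix, the true gene ->
#'   cluster map (0 = background), the planted target lists and the true
#'   per-gene variances.
#' @export
generateDataset <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    set.seed(config@seed)
    n <- config@nGenes
    glabels <- rep(config@groups$label, config@groups$n)
    S <- length(glabels)
    sampleIds <- unlist(lapply(seq_len(nrow(config@groups)), function(i)
        paste0(config@groups$label[i], "_",
               seq_len(config@groups$n[i]))))
    geneIds <- sprintf("G%05d", seq_len(n))

    mu <- stats::runif(n, 4, 12)
    d0 <- config@ebPrior@d0
    s0 <- config@ebPrior@s0Sq
    sigma2 <- if (is.infinite(d0)) rep(s0, n)
              else s0 * d0 / stats::rchisq(n, df = d0)
    X <- mu + matrix(stats::rnorm(n * S, sd = sqrt(sigma2)), n, S)

    truth <- integer(n)
    pos <- 0L
    grpIdx <- match(glabels, config@groups$label)
    for (ci in seq_along(config@clusters)) {
        cl <- config@clusters[[ci]]
        idx <- pos + seq_len(cl$size)
        pos <- pos + cl$size
        truth[idx] <- ci
        a <- pmax(stats::rnorm(cl$size, 1, cl$loading_sd), 0.1)
        z <- stats::rnorm(S)
        shift <- cl$pattern[grpIdx] + cl$cofactor_sd * z
        X[idx, ] <- X[idx, ] + outer(a, shift)
    }
    names(truth) <- geneIds
    names(sigma2) <- geneIds

    if (length(config@distortion)) {
        d <- config@distortion
        c1 <- stats::runif(S, -d$c1Max, d$c1Max)
        c2 <- sample(c(-1, 1), S, replace = TRUE) *
              stats::runif(S, d$c2Min, d$c2Max)
        for (j in seq_len(S)) {
            xc <- X[, j] - mean(X[, j])
            X[, j] <- X[, j] + c1[j] * xc + c2[j] * xc^2
        }
    }
    dimnames(X) <- list(geneIds, sampleIds)
    em <- ExpressionMatrix(X, groups = glabels)

    targets <- if (length(config@targetSpecs))
        generateTargetLists(truth, config@targetSpecs,
                            seed = config@seed + 1)
    else TargetCollection(list(), background = geneIds)

    new("SyntheticDataset", matrix = em, truthClusters = truth,
        truthTargets = targets, truthVariances = sigma2)
}

#' Generate planted target lists over a cluster structure
#'
#' Each gene joins a target list independently with probability
#' \code{backgroundRate} outside the clusters and \code{min(1, fold[c] *
#' backgroundRate)} inside cluster c, so the realized per-cluster
#' fold-enrichment approaches the specified fold as cluster size grows.
#'
#' @param truthClusters named integer vector, gene -> cluster index (0 =
#'   background).
#' @param targetSpecs list of [targetSpec()]s; each \code{fold} vector
#'   must have one entry per cluster index present.
#' @param seed integer seed.
#' @return a [TargetCollection-class] whose background is all genes.
#' @export
generateTargetLists <- function(truthClusters, targetSpecs, seed = 1L) {
    set.seed(seed)
    genes <- names(truthClusters)
    nclust <- max(truthClusters)
    sets <- list()
    for (ts in targetSpecs) {
        if (nclust > 0 && length(ts$fold) < nclust)
            stop("target spec '", ts$name, "' lacks folds for ",
                 nclust, " clusters")
        prob <- rep(ts$background_rate, length(genes))
        for (ci in seq_len(nclust))
            prob[truthClusters == ci] <-
                min(1, ts$fold[ci] * ts$background_rate)
        sets[[ts$name]] <- genes[stats::runif(length(genes)) < prob]
    }
    TargetCollection(sets, background = genes)
}

#' Generate an external cohort with two planted sample branches
#'
#' Two sample subpopulations receive opposite mean shifts (+effect/2 and
#' -effect/2, log2 units) on the signature genes; all other genes carry
#' independent noise. Projection of the signature onto this cohort should
#' recover the two branches.
#'
#' @param signatureGenes character vector (or [Signature-class]) of
#'   signature gene ids.
#' @param nPerBranch samples per branch (>= 2; default 20).
#' @param effect total between-branch log2 shift on signature genes
#'   (default 2).
#' @param seed integer seed.
#' @param nBackgroundGenes extra unshifted genes (default 3000).
#' @param ebPrior noise-variance prior as in [syntheticConfig()].
#' @return list with \code{matrix} (an [ExpressionMatrix-class], no group
#'   labels) and \code{truthBranches} (named character, "B1"/"B2").
#' @export
generateExternalCohort <- function(signatureGenes, nPerBranch = 20,
                                   effect = 2, seed = 1L,
                                   nBackgroundGenes = 3000,
                                   ebPrior = EBPrior(d0 = 4,
                                                     s0Sq = 0.05)) {
    if (is(signatureGenes, "Signature"))
        signatureGenes <- signatureGenes@genes
    if (length(signatureGenes) == 0L)
        stop("signature must be non-empty")
    if (nPerBranch < 2)
        stop("need at least 2 samples per branch")
    set.seed(seed)
    bg <- setdiff(sprintf("X%05d", seq_len(nBackgroundGenes +
                                           length(signatureGenes))),
                  signatureGenes)[seq_len(nBackgroundGenes)]
    genes <- c(signatureGenes, bg)
    n <- length(genes)
    S <- 2L * nPerBranch
    truth <- rep(c("B1", "B2"), each = nPerBranch)
    mu <- stats::runif(n, 4, 12)
    sigma2 <- if (is.infinite(ebPrior@d0)) rep(ebPrior@s0Sq, n)
              else ebPrior@s0Sq * ebPrior@d0 /
                   stats::rchisq(n, df = ebPrior@d0)
    X <- mu + matrix(stats::rnorm(n * S, sd = sqrt(sigma2)), n, S)
    isSig <- seq_along(signatureGenes)
    X[isSig, truth == "B1"] <- X[isSig, truth == "B1"] + effect / 2
    X[isSig, truth == "B2"] <- X[isSig, truth == "B2"] - effect / 2
    sids <- sprintf("S%03d", seq_len(S))
    dimnames(X) <- list(genes, sids)
    names(truth) <- sids
    list(matrix = ExpressionMatrix(X), truthBranches = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression matrix as a tab-delimited table, the truth
#' (clusters, variances, config echo) as JSON, and the planted target
#' lists as GMT.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param pathPrefix output path prefix; writes
#'   \code{<prefix>_matrix.tsv}, \code{<prefix>_truth.json},
#'   \code{<prefix>_targets.gmt}.
#' @return invisibly, the named vector of written paths.
#' @export
writeSyntheticDataset <- function(dataset, pathPrefix) {
    stopifnot(is(dataset, "SyntheticDataset"))
    paths <- c(matrix = paste0(pathPrefix, "_matrix.tsv"),
               truth = paste0(pathPrefix, "_truth.json"),
               targets = paste0(pathPrefix, "_targets.gmt"))
    writeExpressionMatrix(dataset@matrix, paths["matrix"])
    jsonlite::write_json(
        list(clusters = as.list(dataset@truthClusters),
             variances = as.list(dataset@truthVariances),
             groups = as.list(sampleGroups(dataset@matrix))),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    writeGeneSets(dataset@truthTargets, paths["targets"])
    invisible(paths)
}
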