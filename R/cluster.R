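#' Uncentered Pearson distance between two vectors
#'
#' The similarity is the cosine-like uncentered correlation
#' \eqn{s = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}} and the distance is
#' \eqn{d = 1 - s \in [0, 2]}. Unlike the centered Pearson correlation it is
#' scale-invariant but not shift-invariant. By convention an all-zero vector
#' has similarity 0 (distance 1) with anything.
#'
#' @param x,y numeric vectors of equal length.
#' @return the distance, a number in \code{[0, 2]}.
#' @examples
#' uncenteredPearsonDistance(c(1, 2, 3), c(2, 4, 6))  # 0: proportional
#' uncenteredPearsonDistance(c(1, 0), c(0, 1))        # 1: orthogonal
#' @export
uncenteredPearsonDistance <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal lengths")
    if (length(x) == 0L)
        stop("vectors must be non-empty")
    nx <- sqrt(sum(x^2))
    ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0)
        return(1)
    s <- sum(x * y) / (nx * ny)
    1 - max(-1, min(1, s))
}

#' Uncentered Pearson distance matrix over the rows of a matrix
#'
#' @param X numeric matrix; distances are computed between rows.
#' @return symmetric numeric matrix of distances \code{1 - s} with zero
#'   diagonal; rows with zero norm get distance 1 to everything.
#' @export
uncenteredPearsonDist <- function(X) {
    X <- as.matrix(X)
    norms <- sqrt(rowSums(X^2))
    zero <- norms == 0
    norms[zero] <- 1
    S <- tcrossprod(X / norms)
    if (any(zero)) {
        S[zero, ] <- 0
        S[, zero] <- 0
    }
    D <- pmin(pmax(1 - S, 0), 2)   # guard rounding just outside [0, 2]
    diag(D) <- 0
    dimnames(D) <- list(rownames(X), rownames(X))
    D
}

# Convert chronological nearest-neighbour-chain merges into a stats::hclust
# object: sort by height (stable, so equal-height children precede their
# parents), renumber nodes, derive the leaf order.
.mergesToHclust <- function(h, repLo, repHi, labels) {
    n <- length(labels)
    ord <- order(h)                      # stable for ties
    height <- h[ord]
    merge <- matrix(0L, n - 1L, 2L)
    nodeOf <- -seq_len(n)
    for (i in seq_len(n - 1L)) {
        j <- ord[i]
        a <- nodeOf[repLo[j] + 1L]
        b <- nodeOf[repHi[j] + 1L]
        # hclust convention: leaves (negative) before internal nodes;
        # within a kind, ascending leaf index / node number
        swap <- (a < 0 && b < 0 && -a > -b) ||
                (a > 0 && b > 0 && a > b) ||
                (a > 0 && b < 0)
        merge[i, ] <- if (swap) c(b, a) else c(a, b)
        nodeOf[repLo[j] + 1L] <- i
    }
    structure(
        list(merge = merge, height = height,
             order = .leafOrder(merge), labels = labels,
             method = "average", call = NULL,
             dist.method = "uncentered-pearson"),
        class = "hclust")
}

.leafOrder <- function(merge) {
    n <- nrow(merge) + 1L
    out <- integer(n)
    oi <- 0L
    stack <- integer(2L * n)
    sp <- 1L
    stack[1L] <- nrow(merge)
    while (sp > 0L) {
        node <- stack[sp]
        sp <- sp - 1L
        if (node < 0L) {
            oi <- oi + 1L
            out[oi] <- -node
        } else {
            stack[sp + 1L] <- merge[node, 2L]
            stack[sp + 2L] <- merge[node, 1L]
            sp <- sp + 2L
        }
    }
    out
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering of the genes or the samples of an expression
#' matrix using the uncentered Pearson distance and unweighted average
#' linkage, via a nearest-neighbour-chain agglomeration (exact for average
#' linkage, which is reducible). Ties in merge distance are broken
#' deterministically (reciprocal chain neighbour, then smallest index), so
#' results are reproducible across platforms.
#'
#' @param x an [ExpressionMatrix-class] or a numeric matrix (genes in
#'   rows). Typically the log2, gene-median-centered matrix.
#' @param axis cluster \code{"genes"} (rows) or \code{"samples"}
#'   (columns).
#' @param distances optional precomputed symmetric distance matrix; when
#'   supplied, \code{x} and \code{axis} are ignored for the distance step.
#' @return an object of class \code{hclust} with \code{n - 1} merges and
#'   non-decreasing heights.
#' @seealso [cutGeneTree()] to delimit clusters, [writeClusteredOutput()]
#'   to export the dendrograms.
#' @export
averageLinkage <- function(x, axis = c("genes", "samples"),
                           distances = NULL) {
    axis <- match.arg(axis)
    if (is.null(distances)) {
        V <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
        if (axis == "samples")
            V <- t(V)
        if (nrow(V) < 2L)
            stop("need at least 2 items on the clustering axis")
        distances <- uncenteredPearsonDist(V)
        labels <- rownames(V)
    } else {
        distances <- as.matrix(distances)
        labels <- rownames(distances)
    }
    if (any(!is.finite(distances)))
        stop("non-finite distances")
    if (is.null(labels))
        labels <- as.character(seq_len(nrow(distances)))
    res <- .nnChainAverage(distances)
    .mergesToHclust(res$height, res$repLo, res$repHi, labels)
}

#' Cut a gene dendrogram into clusters at a fractional height
#'
#' The tree is cut at \code{h* = fraction * root height} (or at the
#' absolute distance \code{fraction} when \code{absolute = TRUE}); clusters
#' are the maximal subtrees whose internal merges all lie at or below
#' \code{h*}. Clusters smaller than \code{minSize} are discarded (recorded
#' in the \code{discarded} slot). Cluster ids \code{C1, C2, ...} follow the
#' dendrogram leaf order.
#'
#' @param tree an \code{hclust} object from [averageLinkage()].
#' @param fraction cut height as a fraction of the root merge height
#'   (default 1/5), or an absolute distance when \code{absolute = TRUE}.
#' @param minSize minimum cluster size retained (default 10).
#' @param absolute interpret \code{fraction} as an absolute distance.
#' @return a [GeneClusterSet-class].
#' @export
cutGeneTree <- function(tree, fraction = 0.2, minSize = 10,
                        absolute = FALSE) {
    if (!absolute && (fraction < 0 || fraction > 1))
        stop("'fraction' must lie in [0, 1]")
    hstar <- if (absolute) fraction else fraction * max(tree$height)
    memb <- stats::cutree(tree, h = hstar)
    labs <- names(memb)
    # order cluster ids by first appearance along the dendrogram leaves
    leafSeq <- memb[tree$order]
    firstSeen <- unique(leafSeq)
    sizes <- table(memb)
    keep <- firstSeen[sizes[as.character(firstSeen)] >= minSize]
    clusters <- lapply(keep, function(k) labs[memb == k])
    names(clusters) <- if (length(keep)) paste0("C", seq_along(keep))
                       else character(0)
    discarded <- setdiff(labs, unlist(clusters, use.names = FALSE))
    new("GeneClusterSet", clusters = clusters, discarded = discarded,
        cutHeight = hstar, collective = data.frame(),
        patterns = character(0))
}

#' Cluster-level collective test
#'
#' For each sample, the mean expression over the cluster's genes is
#' computed; the per-sample means are then compared between two groups with
#' a two-sample Student t-test (equal variances by default, Welch
#' optionally). This is the cluster-level alternative to gene-wise multiple
#' testing: one test per cluster and contrast.
#'
#' @param x an [ExpressionMatrix-class] with group labels.
#' @param genes character vector, the cluster members.
#' @param groupA,groupB group labels to compare; the direction is reported
#'   for \code{groupA} ("up" = higher in A).
#' @param varEqual use the pooled-variance Student form (default TRUE).
#' @return a list with elements \code{contrast}, \code{means} (named
#'   per-sample cluster means over both groups), \code{t}, \code{p},
#'   \code{direction}.
#' @export
collectiveTest <- function(x, genes, groupA, groupB, varEqual = TRUE) {
    grp <- sampleGroups(x)
    if (is.null(grp))
        stop("expression matrix carries no group labels")
    sa <- names(grp)[grp == groupA]
    sb <- names(grp)[grp == groupB]
    if (length(sa) < 2L || length(sb) < 2L)
        stop("both groups need at least 2 samples")
    V <- exprValues(x)
    genes <- intersect(genes, rownames(V))
    if (length(genes) == 0L)
        stop("no cluster gene found in the matrix")
    means <- colMeans(V[genes, c(sa, sb), drop = FALSE])
    xa <- means[sa]
    xb <- means[sb]
    delta <- mean(xa) - mean(xb)
    pooled <- ((length(xa) - 1) * stats::var(xa) +
               (length(xb) - 1) * stats::var(xb)) /
              (length(xa) + length(xb) - 2)
    if (pooled == 0) {
        tt <- if (delta == 0) 0 else sign(delta) * Inf
        pv <- if (delta == 0) 1 else 0
    } else {
        ht <- stats::t.test(xa, xb, var.equal = varEqual)
        tt <- unname(ht$statistic)
        pv <- ht$p.value
    }
    list(contrast = paste0(groupA, ".vs.", groupB), means = means,
         t = tt, p = pv, direction = if (delta >= 0) "up" else "down")
}

#' Extract differential clusters across contrasts
#'
#' Runs [collectiveTest()] for every cluster and contrast, keeps the
#' clusters whose collective p-value falls below \code{alpha} in at least
#' one contrast, and annotates each kept cluster with its direction
#' pattern (e.g. \code{"down@mimicA|flat@mimicB"}), the vocabulary in
#' which co-expression clusters are described (down in one mimic,
#' unchanged in the other, opposite in both, ...).
#'
#' @param x an [ExpressionMatrix-class] with group labels.
#' @param clusterSet a [GeneClusterSet-class] from [cutGeneTree()].
#' @param contrasts list of 2-vectors \code{c(groupA, groupB)}; optional
#'   element names label the contrasts (default \code{"A.vs.B"}).
#' @param alpha collective p-value threshold (default 0.05).
#' @param varEqual passed to [collectiveTest()].
#' @return a [GeneClusterSet-class] restricted to the significant
#'   clusters, with the \code{collective} results table (all clusters
#'   tested) and per-cluster \code{patterns} filled in.
#' @export
extractDifferentialClusters <- function(x, clusterSet, contrasts,
                                        alpha = 0.05, varEqual = TRUE) {
    if (is.null(names(contrasts)) || any(names(contrasts) == ""))
        names(contrasts) <- vapply(contrasts,
                                   function(ct) paste0(ct[1], ".vs.", ct[2]),
                                   character(1))
    cl <- geneSets(clusterSet)
    rows <- list()
    for (cn in names(cl)) {
        for (ctn in names(contrasts)) {
            ct <- contrasts[[ctn]]
            res <- collectiveTest(x, cl[[cn]], ct[1], ct[2],
                                  varEqual = varEqual)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = cn, contrast = ctn, n_genes = length(cl[[cn]]),
                t = res$t, p = res$p, direction = res$direction,
                stringsAsFactors = FALSE)
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(cluster = character(0), contrast = character(0),
                   n_genes = integer(0), t = numeric(0), p = numeric(0),
                   direction = character(0))
    keep <- unique(tab$cluster[tab$p < alpha])
    keep <- names(cl)[names(cl) %in% keep]   # preserve leaf order
    patterns <- vapply(keep, function(cn) {
        sub <- tab[tab$cluster == cn, , drop = FALSE]
        lab <- ifelse(sub$p < alpha, sub$direction, "flat")
        paste(paste0(lab, "@", sub$contrast), collapse = "|")
    }, character(1))
    new("GeneClusterSet", clusters = cl[keep],
        discarded = clusterSet@discarded, cutHeight = clusterSet@cutHeight,
        collective = tab, patterns = patterns)
}
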