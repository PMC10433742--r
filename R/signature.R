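#' Build the cluster-union signature
#'
#' The union of all member genes of the differential clusters, with each
#' gene's source cluster kept as provenance. Clusters from one tree cut
#' are disjoint, so no gene can appear twice.
#'
#' @param clusterSet a [GeneClusterSet-class] (typically the output of
#'   [extractDifferentialClusters()]).
#' @return a [Signature-class].
#' @export
buildSignature <- function(clusterSet) {
    cl <- geneSets(clusterSet)
    if (length(cl) == 0L || sum(lengths(cl)) == 0L)
        stop("no cluster genes: signature would be empty")
    genes <- unlist(cl, use.names = FALSE)
    if (anyDuplicated(genes))
        stop("clusters are not disjoint")
    prov <- rep(names(cl), lengths(cl))
    names(prov) <- genes
    new("Signature", genes = genes, provenance = prov,
        reduction = character(0))
}

#' Reduce a signature to the shared targets of two sets
#'
#' Keeps the signature genes present in both target sets (e.g. the
#' targets of both microRNAs), preserving cluster provenance. Optionally
#' counts the overlap of the reduced signature with further sets (for
#' "x/y were also targets of ..." style reporting, returned as the
#' \code{alsoCounts} attribute).
#'
#' @param signature a [Signature-class].
#' @param targetsA,targetsB character vectors of target genes.
#' @param names length-2 character, the names recorded in the
#'   \code{reduction} slot.
#' @param alsoCount optional named list of additional gene sets to count
#'   overlaps with.
#' @return a [Signature-class] (possibly empty, with a warning); when
#'   \code{alsoCount} is given, the integer overlap counts are attached
#'   as \code{attr(, "alsoCounts")}.
#' @export
reduceSharedTargets <- function(signature, targetsA, targetsB,
                                names = c("targetsA", "targetsB"),
                                alsoCount = list()) {
    stopifnot(is(signature, "Signature"))
    if (length(targetsA) == 0L || length(targetsB) == 0L)
        stop("target sets must be non-empty")
    keep <- signature@genes[signature@genes %in% targetsA &
                            signature@genes %in% targetsB]
    if (length(keep) == 0L)
        warning("no signature gene is a shared target; ",
                "returning an empty signature")
    out <- new("Signature", genes = keep,
               provenance = signature@provenance[keep],
               reduction = names)
    if (length(alsoCount)) {
        counts <- vapply(alsoCount, function(s)
            length(intersect(keep, s)), integer(1))
        attr(out, "alsoCounts") <- counts
    }
    out
}

# leaves (as label indices) under a node of an hclust merge matrix
.nodeLeaves <- function(merge, node) {
    if (node < 0L)
        return(-node)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (v < 0L) out <- c(out, -v)
        else stack <- c(stack, merge[v, ])
    }
    out
}

#' Project a signature onto an external cohort
#'
#' Subsets the external matrix to the matched signature genes,
#' gene-median-centers it, clusters the samples (uncentered Pearson,
#' average linkage) and splits them at the root of the sample dendrogram
#' into a left and a right branch (LB/RB). The naming is arbitrary: LB is
#' the branch containing the first retained sample. Excluded samples
#' (e.g. healthy controls) are removed before clustering and labelled
#' \code{"excluded"}.
#'
#' @param x the external [ExpressionMatrix-class] (or numeric matrix),
#'   log2 scale.
#' @param signature a [Signature-class] or character vector of gene
#'   symbols. Matching is exact, case-sensitive symbol equality after
#'   trimming.
#' @param excludeSamples sample ids to keep out of the clustering and the
#'   branch statistics.
#' @return a [BranchClassification-class].
#' @export
projectSignature <- function(x, signature, excludeSamples = character(0)) {
    sig <- if (is(signature, "Signature")) signature@genes
           else as.character(signature)
    sig <- unique(trimws(sig))
    if (length(sig) == 0L)
        stop("empty signature")
    V <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    retained <- setdiff(colnames(V), excludeSamples)
    if (length(retained) < 4L)
        stop("need at least 4 retained samples")
    matched <- intersect(sig, trimws(rownames(V)))
    rate <- length(matched) / length(sig)
    if (rate < 0.2)
        stop(sprintf(paste0(
            "only %.1f%% of signature genes matched; harmonize gene ",
            "identifiers (e.g. supply an alias map) before projecting"),
            100 * rate))
    if (length(matched) < 10L)
        stop("fewer than 10 signature genes matched")
    sub <- V[matched, retained, drop = FALSE]
    sub <- sub - apply(sub, 1L, stats::median)
    tree <- averageLinkage(sub, axis = "samples")
    root <- nrow(tree$merge)
    left <- tree$labels[.nodeLeaves(tree$merge, tree$merge[root, 1])]
    right <- tree$labels[.nodeLeaves(tree$merge, tree$merge[root, 2])]
    if (retained[1] %in% right) {
        tmp <- left; left <- right; right <- tmp
    }
    br <- stats::setNames(rep("excluded", ncol(V)), colnames(V))
    br[left] <- "LB"
    br[right] <- "RB"
    new("BranchClassification", branches = br, matchedGenes = matched,
        matchRate = rate, sampleTree = tree)
}

#' Transcriptome-wide differential statistics between the two branches
#'
#' Moderated t-tests over the whole transcriptome (not only the signature
#' genes) between the LB and RB samples of a projection; excluded samples
#' take no part. Selection applies the FDR threshold only (no fold-change
#' filter).
#'
#' @param x the external [ExpressionMatrix-class] (or numeric matrix),
#'   log2 scale.
#' @param classification a [BranchClassification-class] from
#'   [projectSignature()].
#' @param fdrThreshold FDR cutoff (default 0.01).
#' @return list with \code{up} and \code{down} (gene sets up/down in LB
#'   relative to RB) and \code{table} (the full [moderatedTTable()]
#'   output).
#' @export
branchDifferential <- function(x, classification, fdrThreshold = 0.01) {
    stopifnot(is(classification, "BranchClassification"))
    V <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    br <- branches(classification)
    br <- br[br != "excluded"]
    if (sum(br == "LB") < 2L || sum(br == "RB") < 2L)
        stop("both branches need at least 2 samples")
    em <- ExpressionMatrix(V[, names(br), drop = FALSE],
                           groups = unname(br))
    tab <- moderatedTTable(em, "LB", "RB")
    sel <- selectDifferential(tab, fdrThreshold = fdrThreshold,
                              foldThreshold = 1)
    list(up = sel$up, down = sel$down, table = tab)
}

#' Write / read a signature as TSV
#'
#' Two columns: \code{gene}, \code{cluster} (provenance); the
#' \code{reduction} metadata is stored in a header comment line.
#'
#' @param signature a [Signature-class].
#' @param path file path.
#' @return [writeSignature()]: invisibly \code{path};
#'   [readSignature()]: a [Signature-class].
#' @export
writeSignature <- function(signature, path) {
    stopifnot(is(signature, "Signature"))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(signature@reduction))
        writeLines(paste0("# reduction: ",
                          paste(signature@reduction, collapse = " & ")),
                   con)
    writeLines("gene\tcluster", con)
    writeLines(paste(signature@genes,
                     signature@provenance[signature@genes], sep = "\t"),
               con)
    invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    lines <- readLines(path)
    red <- character(0)
    if (length(lines) && startsWith(lines[1], "# reduction: ")) {
        red <- strsplit(sub("^# reduction: ", "", lines[1]),
                        " & ", fixed = TRUE)[[1]]
        lines <- lines[-1]
    }
    df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    prov <- stats::setNames(as.character(df$cluster), df$gene)
    new("Signature", genes = df$gene, provenance = prov, reduction = red)
}
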