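#' Accessors for mirSig S4 classes
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @describeIn accessors numeric expression matrix of an
#'   [ExpressionMatrix-class].
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn accessors gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn accessors sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn accessors per-sample group labels (NULL if absent).
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @describeIn accessors named list of gene sets of a
#'   [TargetCollection-class], or the clusters of a [GeneClusterSet-class].
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @describeIn accessors background gene universe.
#' @export
setGeneric("geneBackground", function(x) standardGeneric("geneBackground"))

#' @describeIn accessors genes of a [Signature-class].
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @describeIn accessors gene -> source-cluster map of a
#'   [Signature-class].
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn accessors sample -> branch map of a
#'   [BranchClassification-class].
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

setMethod("exprValues", "ExpressionMatrix", function(x)
    SummarizedExperiment::assay(x, "exprs"))
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))
setMethod("sampleGroups", "ExpressionMatrix", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("group" %in% colnames(cd)) {
        g <- as.character(cd$group)
        names(g) <- rownames(cd)
        g
    } else NULL
})

setMethod("geneSets", "TargetCollection", function(x) x@sets)
setMethod("geneBackground", "TargetCollection", function(x) x@background)
setMethod("geneSets", "GeneClusterSet", function(x) x@clusters)

setMethod("signatureGenes", "Signature", function(x) x@genes)
setMethod("provenance", "Signature", function(x) x@provenance)

setMethod("branches", "BranchClassification", function(x) x@branches)

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
        "samples\n")
    g <- sampleGroups(object)
    if (!is.null(g)) {
        tab <- table(g)
        cat("  groups:",
            paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
    }
})

setMethod("show", "TargetCollection", function(object) {
    cat("TargetCollection:", length(object@sets), "sets, background of",
        length(object@background), "genes\n")
    if (length(object@sets))
        cat("  ", paste(sprintf("%s (%d)", names(object@sets),
                                lengths(object@sets)), collapse = ", "),
            "\n")
})

setMethod("show", "EBPrior", function(object) {
    cat(sprintf("EBPrior: d0 = %s, s0^2 = %.6g\n",
                format(object@d0), object@s0Sq))
})

setMethod("show", "GeneClusterSet", function(object) {
    cat("GeneClusterSet:", length(object@clusters),
        sprintf("clusters (cut height %.4g),", object@cutHeight),
        length(object@discarded), "genes discarded\n")
    if (length(object@clusters)) {
        sz <- lengths(object@clusters)
        cat("  sizes:", paste(sprintf("%s=%d", names(sz), sz),
                              collapse = ", "), "\n")
    }
    if (length(object@patterns))
        cat("  patterns:",
            paste(sprintf("%s: %s", names(object@patterns),
                          object@patterns), collapse = "; "), "\n")
})

setMethod("show", "Signature", function(object) {
    cat("Signature:", length(object@genes), "genes from",
        length(unique(object@provenance)), "clusters")
    if (length(object@reduction))
        cat(" (reduced by:", paste(object@reduction, collapse = " & "),
            ")")
    cat("\n")
})

setMethod("show", "BranchClassification", function(object) {
    b <- object@branches
    cat(sprintf(
        "BranchClassification: LB n=%d, RB n=%d, excluded n=%d\n",
        sum(b == "LB"), sum(b == "RB"), sum(b == "excluded")))
    cat(sprintf("  %d signature genes matched (%.1f%%)\n",
                length(object@matchedGenes), 100 * object@matchRate))
})

setMethod("show", "SyntheticDataset", function(object) {
    cat("SyntheticDataset\n  ")
    show(object@matrix)
    k <- sum(tabulate(object@truthClusters) > 0)
    cat("  planted clusters:", k, "| target lists:",
        length(object@truthTargets@sets), "\n")
})
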