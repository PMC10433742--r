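#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ExpressionMatrix: genes x samples expression container
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding a single
#' numeric assay (\code{"exprs"}) on a log2 (or raw intensity) scale, with
#' unique gene and sample identifiers and an optional group label per
#' sample (stored in \code{colData()$group}).
#'
#' @slot .
#' Inherits all slots from \linkS4class{SummarizedExperiment}.
#'
#' @seealso [ExpressionMatrix()] for the constructor,
#'   [exprValues()], [geneIds()], [sampleIds()], [sampleGroups()]
#'   for accessors.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

.validExpressionMatrix <- function(object) {
    msg <- NULL
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v))
        msg <- c(msg, "assay 'exprs' must be numeric")
    if (any(!is.finite(v)))
        msg <- c(msg, "expression values must all be finite")
    gid <- rownames(object)
    sid <- colnames(object)
    if (is.null(gid) || anyDuplicated(gid) || any(gid == ""))
        msg <- c(msg, "gene identifiers must be unique and non-empty")
    if (is.null(sid) || anyDuplicated(sid) || any(sid == ""))
        msg <- c(msg, "sample identifiers must be unique and non-empty")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry unique rownames (gene symbols or probe ids) and colnames.
#' @param groups optional character/factor of per-sample group labels,
#'   length \code{ncol(values)}.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- ExpressionMatrix(m, groups = c("ctrl", "ctrl", "mimic"))
#' @export
ExpressionMatrix <- function(values, groups = NULL) {
    if (!is.matrix(values))
        values <- as.matrix(values)
    storage.mode(values) <- "double"
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(groups)) {
        if (length(groups) != ncol(values))
            stop("'groups' must have one label per sample")
        cd$group <- as.character(groups)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    new("ExpressionMatrix", se)
}

#' TargetCollection: named gene sets with a fixed background
#'
#' Holds named gene-symbol sets (e.g. microRNA targets, RNA-binding-protein
#' targets, annotation terms) together with the background universe against
#' which every enrichment is evaluated (the "whole chip": the genes present
#' on the processed matrix).
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot background character vector, the gene universe.
#' @export
setClass("TargetCollection",
         representation(sets = "list", background = "character"))

setValidity("TargetCollection", function(object) {
    msg <- NULL
    if (length(object@background) == 0L)
        msg <- c(msg, "background must be non-empty")
    if (anyDuplicated(object@background))
        msg <- c(msg, "background contains duplicated symbols")
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || any(names(object@sets) == ""))
            msg <- c(msg, "all sets must be named")
        if (!all(vapply(object@sets, is.character, logical(1))))
            msg <- c(msg, "sets must be character vectors")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a TargetCollection
#'
#' @param sets named list of character vectors (gene symbols); duplicates
#'   within a set are removed.
#' @param background character vector of background gene symbols.
#' @return a [TargetCollection-class].
#' @export
TargetCollection <- function(sets, background) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    new("TargetCollection", sets = sets,
        background = unique(as.character(background)))
}

#' EBPrior: empirical-Bayes variance prior
#'
#' The chip-wide prior of the moderated-t model: prior degrees of freedom
#' \code{d0} (possibly \code{Inf}) and prior variance \code{s0Sq}
#' (log2-squared units).
#'
#' @slot d0 numeric(1), prior degrees of freedom, > 0 (may be Inf).
#' @slot s0Sq numeric(1), prior variance, > 0.
#' @export
setClass("EBPrior", representation(d0 = "numeric", s0Sq = "numeric"))

setValidity("EBPrior", function(object) {
    msg <- NULL
    if (length(object@d0) != 1L || is.na(object@d0) || object@d0 <= 0)
        msg <- c(msg, "d0 must be a single positive number (possibly Inf)")
    if (length(object@s0Sq) != 1L || !is.finite(object@s0Sq) ||
        object@s0Sq <= 0)
        msg <- c(msg, "s0Sq must be a single positive finite number")
    if (is.null(msg)) TRUE else msg
})

#' Construct an EBPrior
#' @param d0 prior degrees of freedom (> 0, may be \code{Inf}).
#' @param s0Sq prior variance (> 0).
#' @return an [EBPrior-class].
#' @export
EBPrior <- function(d0, s0Sq) new("EBPrior", d0 = d0, s0Sq = s0Sq)

#' GeneClusterSet: disjoint gene clusters from one tree cut
#'
#' @slot clusters named list ("C1", "C2", ...) of character vectors of
#'   member genes, disjoint, ordered by dendrogram leaf order.
#' @slot discarded character vector of genes in subtrees below the cut that
#'   failed the minimum-size filter.
#' @slot cutHeight numeric(1), the absolute height of the cut.
#' @slot collective data.frame of cluster-level collective-test results
#'   (empty until [extractDifferentialClusters()] is run): columns
#'   cluster, contrast, t, p, direction.
#' @slot patterns named character vector: per-cluster direction pattern
#'   across contrasts (filled by [extractDifferentialClusters()]).
#' @export
setClass("GeneClusterSet",
         representation(clusters = "list", discarded = "character",
                        cutHeight = "numeric", collective = "data.frame",
                        patterns = "character"))

setValidity("GeneClusterSet", function(object) {
    msg <- NULL
    all_members <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(all_members))
        msg <- c(msg, "clusters must be disjoint")
    if (length(object@clusters) &&
        any(lengths(object@clusters) == 0L))
        msg <- c(msg, "clusters must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' Signature: ordered gene list with cluster provenance
#'
#' @slot genes character vector of gene symbols, no duplicates.
#' @slot provenance named character vector mapping every signature gene to
#'   its source cluster id.
#' @slot reduction character vector naming the target sets intersected to
#'   obtain this signature (empty for the full cluster-union signature).
#' @export
setClass("Signature",
         representation(genes = "character", provenance = "character",
                        reduction = "character"))

setValidity("Signature", function(object) {
    msg <- NULL
    if (anyDuplicated(object@genes))
        msg <- c(msg, "signature genes must be unique")
    if (!identical(sort(names(object@provenance)), sort(object@genes)))
        msg <- c(msg, "provenance must cover exactly the signature genes")
    if (is.null(msg)) TRUE else msg
})

#' BranchClassification: two-branch partition of an external cohort
#'
#' @slot branches named character vector mapping each sample to "LB",
#'   "RB" or "excluded".
#' @slot matchedGenes character vector of signature genes found in the
#'   external matrix.
#' @slot matchRate numeric(1), fraction of signature genes matched.
#' @slot sampleTree the sample dendrogram (an \code{hclust} object).
#' @export
setClass("BranchClassification",
         representation(branches = "character", matchedGenes = "character",
                        matchRate = "numeric", sampleTree = "ANY"))

setValidity("BranchClassification", function(object) {
    msg <- NULL
    if (!all(object@branches %in% c("LB", "RB", "excluded")))
        msg <- c(msg, "branch labels must be LB, RB or excluded")
    if (!any(object@branches == "LB") || !any(object@branches == "RB"))
        msg <- c(msg, "both LB and RB must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticConfig: parameters of the synthetic-data generator
#'
#' @slot nGenes total gene count.
#' @slot groups data.frame with columns \code{label}, \code{n}.
#' @slot clusters list of cluster specifications (see [clusterSpec()]).
#' @slot ebPrior an [EBPrior-class]: the scaled-inverse-chi-square law the
#'   per-gene noise variances are drawn from.
#' @slot distortion list of per-sample distortion parameters or empty list
#'   for none (see [syntheticConfig()]).
#' @slot targetSpecs list of target-list specifications.
#' @slot seed integer seed.
#' @export
setClass("SyntheticConfig",
         representation(nGenes = "numeric", groups = "data.frame",
                        clusters = "list", ebPrior = "EBPrior",
                        distortion = "list", targetSpecs = "list",
                        seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
    msg <- NULL
    csizes <- vapply(object@clusters, function(cl) cl$size, numeric(1))
    if (object@nGenes < sum(csizes))
        msg <- c(msg, "nGenes must be at least the sum of cluster sizes")
    ngrp <- nrow(object@groups)
    for (cl in object@clusters) {
        if (cl$size < 2)
            msg <- c(msg, "cluster size must be >= 2")
        if (length(cl$pattern) != ngrp)
            msg <- c(msg, "cluster pattern must have one shift per group")
    }
    for (ts in object@targetSpecs) {
        if (ts$background_rate < 0 || ts$background_rate > 1)
            msg <- c(msg, "background_rate must lie in [0, 1]")
        if (any(ts$fold < 0))
            msg <- c(msg, "enrichment folds must be >= 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' SyntheticDataset: a generated dataset plus its ground truth
#'
#' @slot matrix the generated [ExpressionMatrix-class] (log2 scale,
#'   distortion applied if configured).
#' @slot truthClusters named integer vector, gene -> planted cluster index
#'   (0 = background).
#' @slot truthTargets a [TargetCollection-class] of planted target lists.
#' @slot truthVariances named numeric vector of the true per-gene noise
#'   variances.
#' @export
setClass("SyntheticDataset",
         representation(matrix = "ExpressionMatrix",
                        truthClusters = "integer",
                        truthTargets = "TargetCollection",
                        truthVariances = "numeric"))

setValidity("SyntheticDataset", function(object) {
    msg <- NULL
    g <- rownames(object@matrix)
    if (!all(names(object@truthClusters) %in% g))
        msg <- c(msg, "truthClusters genes must exist in the matrix")
    if (!all(unlist(object@truthTargets@sets) %in% g))
        msg <- c(msg, "truthTargets must be subsets of matrix genes")
    if (is.null(msg)) TRUE else msg
})
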