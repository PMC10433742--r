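#' Run the full signature-discovery pipeline
#'
#' Chains normalization (LOWESS against the median reference, optional
#' log2, gene-median centering), gene clustering with a fractional tree
#' cut, cluster-level collective tests, gene-wise moderated t statistics,
#' target-list enrichment, and signature construction/reduction, writing
#' each stage's table plus a machine-readable JSON report.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{matrix}{an [ExpressionMatrix-class] or path to a TSV.}
#'     \item{groups}{named character vector sample -> group (may be
#'       omitted when the matrix carries labels).}
#'     \item{contrasts}{list of 2-vectors \code{c(groupA, groupB)}.}
#'     \item{normalize}{list(span = 0.4, log2 = FALSE,
#'       center = "median"); set \code{skip = TRUE} for pre-normalized
#'       input.}
#'     \item{cluster}{list(fraction = 0.2, absolute = FALSE,
#'       minSize = 10, alpha = 0.05).}
#'     \item{differential}{list(fdr = 0.05, fold = 2).}
#'     \item{terms}{optional [TargetCollection-class] or GMT path
#'       (background defaults to the chip).}
#'     \item{sharedTargets}{optional length-2 character: names of two
#'       sets in \code{terms} whose shared targets define the reduced
#'       signature.}
#'     \item{seed}{integer (default 1).}
#'   }
#' @param outDir output directory (created if needed).
#' @return the report, invisibly (also written to
#'   \code{<outDir>/report.json}).
#' @export
runDiscovery <- function(config, outDir) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    set.seed(seed)

    em <- .stage("input", {
        m <- config$matrix
        if (is.character(m))
            m <- readExpressionMatrix(m, format = "tsv")
        if (!is.null(config$groups)) {
            g <- config$groups
            if (!is.null(names(g)))
                g <- g[sampleIds(m)]
            m <- ExpressionMatrix(exprValues(m), groups = g)
        }
        if (is.null(sampleGroups(m)))
            stop("no group labels available")
        m
    })
    contrasts <- config$contrasts
    if (is.null(contrasts))
        stop("stage 'input' failed: no contrasts configured")

    np <- utils::modifyList(list(span = 0.4, log2 = FALSE,
                                 center = "median", skip = FALSE),
                            as.list(config$normalize))
    em <- .stage("normalize", {
        if (np$skip) em
        else log2AndCenter(normalizeToReference(em, span = np$span),
                           log2 = np$log2, center = np$center)
    })

    cp <- utils::modifyList(list(fraction = 0.2, absolute = FALSE,
                                 minSize = 10, alpha = 0.05),
                            as.list(config$cluster))
    diffClusters <- .stage("cluster", {
        tree <- averageLinkage(em, axis = "genes")
        cs <- cutGeneTree(tree, fraction = cp$fraction,
                          minSize = cp$minSize, absolute = cp$absolute)
        extractDifferentialClusters(em, cs, contrasts, alpha = cp$alpha)
    })

    dp <- utils::modifyList(list(fdr = 0.05, fold = 2),
                            as.list(config$differential))
    diffs <- .stage("differential", {
        lapply(contrasts, function(ct) {
            tab <- moderatedTTable(em, ct[1], ct[2])
            sel <- selectDifferential(tab, fdrThreshold = dp$fdr,
                                      foldThreshold = dp$fold)
            list(table = tab, up = sel$up, down = sel$down)
        })
    })

    terms <- config$terms
    if (is.character(terms))
        terms <- readGeneSets(terms, format = "gmt",
                              background = geneIds(em))
    enr <- if (!is.null(terms))
        .stage("enrichment",
               enrichMany(geneSets(diffClusters), terms))
    else NULL

    sigFull <- if (length(geneSets(diffClusters)))
        .stage("signature", buildSignature(diffClusters)) else NULL
    sigReduced <- NULL
    if (!is.null(sigFull) && !is.null(config$sharedTargets)) {
        st <- config$sharedTargets
        sigReduced <- .stage("signature", suppressWarnings(
            reduceSharedTargets(sigFull,
                                geneSets(terms)[[st[1]]],
                                geneSets(terms)[[st[2]]],
                                names = st)))
    }

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeExpressionMatrix(em, file.path(outDir, "normalized.tsv"))
    cl <- geneSets(diffClusters)
    utils::write.table(
        data.frame(gene = unlist(cl, use.names = FALSE),
                   cluster = rep(names(cl), lengths(cl))),
        file.path(outDir, "clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(diffClusters@collective,
                       file.path(outDir, "collective_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(diffs))
        utils::write.table(diffs[[nm]]$table,
                           file.path(outDir,
                                     paste0("differential_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enr))
        utils::write.table(enr, file.path(outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sigFull))
        writeSignature(sigFull, file.path(outDir, "signature_full.tsv"))
    if (!is.null(sigReduced))
        writeSignature(sigReduced,
                       file.path(outDir, "signature_reduced.tsv"))

    if (is.null(names(contrasts)))
        names(contrasts) <- vapply(contrasts, function(ct)
            paste0(ct[1], ".vs.", ct[2]), character(1))
    report <- list(
        stage = "discovery",
        seed = seed,
        n_genes = nrow(em),
        n_samples = ncol(em),
        cluster_count = length(cl),
        cluster_sizes = as.list(lengths(cl)),
        cluster_patterns = as.list(diffClusters@patterns),
        collective_p = stats::setNames(
            as.list(diffClusters@collective$p),
            paste(diffClusters@collective$cluster,
                  diffClusters@collective$contrast, sep = ":")),
        differential_counts = lapply(diffs, function(d)
            list(up = length(d$up), down = length(d$down))),
        signature_size = if (is.null(sigFull)) 0L
                         else length(sigFull@genes),
        reduced_signature_size = if (is.null(sigReduced)) 0L
                                 else length(sigReduced@genes),
        outputs = as.list(list.files(outDir)))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}

#' Project a signature onto an external cohort and test the branches
#'
#' @param config a list (or path to JSON) with elements:
#'   \describe{
#'     \item{external}{an [ExpressionMatrix-class] or path to a TSV
#'       (log2 scale).}
#'     \item{signature}{a [Signature-class], a character vector of
#'       genes, or a path to a signature TSV.}
#'     \item{excludeSamples}{sample ids excluded from clustering and
#'       statistics (e.g. controls).}
#'     \item{fdr}{branch-differential FDR threshold (default 0.01).}
#'     \item{seed}{integer (default 1).}
#'   }
#' @param outDir output directory.
#' @return the report, invisibly (also written to
#'   \code{<outDir>/projection_report.json}).
#' @export
runProjection <- function(config, outDir) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    set.seed(seed)
    em <- .stage("input", {
        m <- config$external
        if (is.character(m)) m <- readExpressionMatrix(m, "tsv")
        m
    })
    sig <- .stage("input", {
        s <- config$signature
        if (is.character(s) && length(s) == 1L && file.exists(s))
            s <- readSignature(s)
        s
    })
    excl <- if (is.null(config$excludeSamples)) character(0)
            else config$excludeSamples
    fdr <- if (is.null(config$fdr)) 0.01 else config$fdr

    cls <- .stage("projection", projectSignature(em, sig, excl))
    bd <- .stage("branch_differential",
                 branchDifferential(em, cls, fdrThreshold = fdr))

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
        data.frame(sample = names(branches(cls)),
                   branch = unname(branches(cls))),
        file.path(outDir, "classification.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(bd$table,
                       file.path(outDir, "branch_differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    b <- branches(cls)
    report <- list(
        stage = "projection",
        seed = seed,
        n_genes = nrow(em),
        n_samples = ncol(em),
        match_rate = cls@matchRate,
        matched_genes = length(cls@matchedGenes),
        branch_sizes = list(LB = sum(b == "LB"), RB = sum(b == "RB"),
                            excluded = sum(b == "excluded")),
        differential_counts = list(up_in_LB = length(bd$up),
                                   down_in_LB = length(bd$down)),
        fdr = fdr,
        outputs = as.list(list.files(outDir)))
    jsonlite::write_json(report,
                         file.path(outDir, "projection_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Validate a pipeline report against the bundled schema
#'
#' Structural check of the JSON reports written by [runDiscovery()] and
#' [runProjection()]: required keys present, values of the declared type.
#'
#' @param report a report list or path to a report JSON file.
#' @param schema path to a schema file (default: the bundled one
#'   matching the report's \code{stage}).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validateReport <- function(report, schema = NULL) {
    if (is.character(report))
        report <- jsonlite::read_json(report, simplifyVector = FALSE)
    if (is.null(schema))
        schema <- system.file("extdata",
                              paste0("report-schema-", report$stage,
                                     ".json"),
                              package = "mirSig", mustWork = TRUE)
    sch <- jsonlite::read_json(schema, simplifyVector = FALSE)
    for (key in names(sch$properties)) {
        prop <- sch$properties[[key]]
        req <- key %in% unlist(sch$required)
        if (is.null(report[[key]])) {
            if (req) stop("report lacks required key '", key, "'")
            next
        }
        val <- report[[key]]
        ok <- switch(prop$type,
            string = is.character(val) || (is.list(val) &&
                     all(vapply(val, is.character, logical(1)))),
            number = is.numeric(val),
            integer = is.numeric(val) && all(unlist(val) ==
                      round(unlist(val))),
            object = is.list(val),
            array = is.list(val) || is.vector(val),
            TRUE)
        if (!ok)
            stop("report key '", key, "' is not of type '", prop$type,
                 "'")
    }
    invisible(TRUE)
}
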