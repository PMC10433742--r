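#' Read an expression matrix from disk
#'
#' Two formats are supported: a plain tab-delimited table (first column =
#' gene/probe id, remaining columns numeric, header row of sample ids),
#' and a GEO series-matrix text export, whose \code{!}-prefixed metadata
#' lines are parsed into per-sample annotations and whose numeric table
#' (between the \code{!series_matrix_table_begin} /
#' \code{!series_matrix_table_end} markers) becomes the values. Non-numeric
#' cells are a parse error naming the offending line, never a silent
#' coercion.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"series_matrix"}.
#' @param groups optional per-sample group labels (named by sample id or
#'   positional).
#' @return an [ExpressionMatrix-class]; for series-matrix input, sample
#'   annotations are kept in \code{colData()}.
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "series_matrix"),
                                 groups = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("input file not found: ", path)
    if (format == "tsv") {
        df <- utils::read.delim(path, header = TRUE, sep = "\t",
                                quote = "", check.names = FALSE,
                                stringsAsFactors = FALSE,
                                colClasses = "character")
        .matrixFromTable(df, path, headerLines = 1L, groups = groups)
    } else {
        lines <- readLines(path)
        b <- grep("^!series_matrix_table_begin", lines)
        e <- grep("^!series_matrix_table_end", lines)
        if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
            stop("malformed series-matrix file: table markers not found ",
                 "in ", path)
        tbl <- utils::read.delim(text = lines[(b + 1L):(e - 1L)],
                                 header = TRUE, sep = "\t", quote = "\"",
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
        em <- .matrixFromTable(tbl, path, headerLines = b + 1L,
                               groups = groups)
        meta <- grep("^!Sample_", lines[seq_len(b - 1L)], value = TRUE)
        cd <- SummarizedExperiment::colData(em)
        for (ln in meta) {
            f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
            f <- gsub("^\"|\"$", "", f)
            if (length(f) == ncol(em) + 1L) {
                key <- sub("^!Sample_", "", f[1])
                if (!key %in% colnames(cd))
                    cd[[key]] <- f[-1]
            }
        }
        SummarizedExperiment::colData(em) <- cd
        em
    }
}

.matrixFromTable <- function(df, path, headerLines, groups) {
    if (ncol(df) < 2L)
        stop("expression table in ", path, " has no sample columns")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate gene/probe identifiers in ", path, ": ",
             paste(utils::head(unique(ids[duplicated(ids)]), 5),
                   collapse = ", "))
    if (anyDuplicated(colnames(df)[-1]))
        stop("duplicate sample identifiers in ", path)
    V <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                dimnames = list(ids, colnames(df)[-1]))
    for (j in 2:ncol(df)) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) & !(df[[j]] %in% c("NA", "")))
        if (length(bad))
            stop("non-numeric value '", df[[j]][bad[1]], "' at line ",
                 bad[1] + headerLines, ", column '", colnames(df)[j],
                 "' of ", path)
        if (any(is.na(v)))
            stop("missing value at line ", which(is.na(v))[1] +
                 headerLines, " of ", path)
        V[, j - 1L] <- v
    }
    if (!is.null(groups) && !is.null(names(groups)))
        groups <- groups[colnames(V)]
    ExpressionMatrix(V, groups = groups)
}

#' Write an expression matrix as a tab-delimited table
#'
#' Period decimal separator, full double precision (readers roundtrip
#' losslessly well beyond 6 significant digits).
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path) {
    V <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    df <- data.frame(gene = rownames(V),
                     format(V, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' Probes with no gene assignment are dropped (and counted in a message).
#' The default rule keeps, for each gene, the probe with the highest mean
#' expression; \code{"mean"} averages all probes of a gene instead.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix with probe
#'   rownames.
#' @param probe2gene named character vector, probe id -> gene symbol
#'   (NA/"" = unassigned).
#' @param method \code{"maxMean"} (default) or \code{"mean"}.
#' @return an [ExpressionMatrix-class] with unique gene rownames.
#' @export
collapseProbesToGenes <- function(x, probe2gene,
                                  method = c("maxMean", "mean")) {
    method <- match.arg(method)
    isEM <- is(x, "ExpressionMatrix")
    V <- if (isEM) exprValues(x) else as.matrix(x)
    g <- probe2gene[rownames(V)]
    keep <- !is.na(g) & g != ""
    nd <- sum(!keep)
    if (nd > 0)
        message(nd, " probes without gene assignment dropped")
    V <- V[keep, , drop = FALSE]
    g <- g[keep]
    if (nrow(V) == 0L)
        stop("no probe maps to a gene: collapse produced an empty matrix")
    if (method == "maxMean") {
        mns <- rowMeans(V)
        ord <- order(g, -mns)
        sel <- ord[!duplicated(g[ord])]
        sel <- sort(sel)               # preserve input probe order
        out <- V[sel, , drop = FALSE]
        rownames(out) <- g[sel]
    } else {
        out <- rowsum(V, group = g)
        out <- out / as.vector(table(g)[rownames(out)])
    }
    grps <- if (isEM) sampleGroups(x) else NULL
    ExpressionMatrix(out, groups = grps)
}

#' Read gene sets (GMT or one-symbol-per-line list)
#'
#' GMT rows are (set name, description, members...). A list file becomes a
#' single set named after the file. Empty sets are retained with a
#' warning. Duplicated symbols within a set are removed.
#'
#' @param path input file.
#' @param format \code{"gmt"} or \code{"list"}.
#' @param background optional background universe; defaults to the union
#'   of all sets.
#' @return a [TargetCollection-class].
#' @export
readGeneSets <- function(path, format = c("gmt", "list"),
                         background = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("gene-set file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (format == "gmt") {
        sets <- list()
        for (ln in lines) {
            f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
            if (length(f) < 2L)
                stop("malformed GMT row (need name and description): ", ln)
            members <- unique(f[-(1:2)])
            members <- members[nzchar(members)]
            if (length(members) == 0L)
                warning("empty gene set '", f[1], "' retained")
            sets[[f[1]]] <- members
        }
    } else {
        nm <- sub("\\.[^.]*$", "", basename(path))
        sets <- stats::setNames(list(unique(trimws(lines))), nm)
    }
    if (is.null(background))
        background <- unique(unlist(sets, use.names = FALSE))
    TargetCollection(sets, background = background)
}

#' Write a TargetCollection as GMT
#'
#' @param x a [TargetCollection-class].
#' @param path output file.
#' @param descriptions optional per-set description column (default
#'   "na").
#' @return invisibly, \code{path}.
#' @export
writeGeneSets <- function(x, path, descriptions = NULL) {
    stopifnot(is(x, "TargetCollection"))
    sets <- geneSets(x)
    if (is.null(descriptions))
        descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write clustered output in the Cluster 3.0 CDT/GTR/ATR dialect
#'
#' The CDT lists genes in gene-tree leaf order (and samples in sample-tree
#' leaf order when a sample tree is given); the GTR/ATR list the merges as
#' \code{NODEnX} rows joining \code{GENE}/\code{ARRY} ids with similarity
#' scores \code{1 - merge distance}.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix.
#' @param geneTree \code{hclust} over the genes (from
#'   [averageLinkage()]).
#' @param sampleTree optional \code{hclust} over the samples.
#' @param pathPrefix output prefix; writes \code{<prefix>.cdt},
#'   \code{<prefix>.gtr} and, when a sample tree is given,
#'   \code{<prefix>.atr}.
#' @return invisibly, the named vector of written paths.
#' @export
writeClusteredOutput <- function(x, geneTree, sampleTree = NULL,
                                 pathPrefix) {
    V <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    if (length(geneTree$order) != nrow(V))
        stop("gene tree size does not match the matrix")
    if (!is.null(sampleTree) && length(sampleTree$order) != ncol(V))
        stop("sample tree size does not match the matrix")
    paths <- c(cdt = paste0(pathPrefix, ".cdt"),
               gtr = paste0(pathPrefix, ".gtr"))
    .writeTreeFile(geneTree, "GENE", paths["gtr"])
    if (!is.null(sampleTree)) {
        paths["atr"] <- paste0(pathPrefix, ".atr")
        .writeTreeFile(sampleTree, "ARRY", paths["atr"])
    }
    gord <- geneTree$order
    sord <- if (is.null(sampleTree)) seq_len(ncol(V)) else
        sampleTree$order
    con <- file(paths["cdt"], "w")
    on.exit(close(con))
    writeLines(paste(c("GID", "UNIQID", "NAME", "GWEIGHT",
                       colnames(V)[sord]), collapse = "\t"), con)
    if (!is.null(sampleTree))
        writeLines(paste(c("AID", "", "", "",
                           sprintf("ARRY%dX", sord - 1L)),
                         collapse = "\t"), con)
    writeLines(paste(c("EWEIGHT", "", "", "",
                       rep("1", ncol(V))), collapse = "\t"), con)
    for (i in gord)
        writeLines(paste(c(sprintf("GENE%dX", i - 1L), rownames(V)[i],
                           rownames(V)[i], "1",
                           format(V[i, sord], digits = 15,
                                  trim = TRUE, scientific = FALSE)),
                         collapse = "\t"), con)
    invisible(paths)
}

.writeTreeFile <- function(tree, kind, path) {
    nodeName <- function(v) ifelse(v < 0, sprintf("%s%dX", kind, -v - 1L),
                                   sprintf("NODE%dX", v))
    m <- tree$merge
    lines <- vapply(seq_len(nrow(m)), function(i)
        paste(c(sprintf("NODE%dX", i), nodeName(m[i, 1]),
                nodeName(m[i, 2]),
                format(1 - tree$height[i], digits = 15, trim = TRUE,
                       scientific = FALSE)),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
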