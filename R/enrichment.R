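#' Observed/Expected fold-enrichment of a term in a gene list
#'
#' Observed is the frequency of the term's genes in the list, Expected is
#' the term's background frequency on the whole chip; the fold-enrichment
#' is their ratio. A one-sided Fisher exact test (hypergeometric tail)
#' validates the enrichment; depletion shows as fold < 1 and can be tested
#' with \code{alternative = "less"}. List and term are intersected with
#' the background before counting.
#'
#' @param listGenes character vector, the gene list (e.g. a cluster).
#' @param termGenes character vector, the term/target set.
#' @param background character vector, the chip universe.
#' @param alternative \code{"greater"} (enrichment, default),
#'   \code{"less"} or \code{"two.sided"}.
#' @return one-row \code{data.frame}: \code{k} (term genes in list),
#'   \code{m} (list size on chip), \code{K} (term size on chip), \code{N}
#'   (chip size), \code{observed} (k/m), \code{expected} (K/N),
#'   \code{fold}, \code{p}.
#' @export
foldEnrichment <- function(listGenes, termGenes, background,
                           alternative = c("greater", "less",
                                           "two.sided")) {
    alternative <- match.arg(alternative)
    if (length(background) == 0L)
        stop("background must be non-empty")
    bg <- unique(background)
    lst <- intersect(unique(listGenes), bg)
    trm <- intersect(unique(termGenes), bg)
    if (length(lst) == 0L)
        stop("gene list has no overlap with the background")
    N <- length(bg)
    m <- length(lst)
    K <- length(trm)
    k <- length(intersect(lst, trm))
    obs <- k / m
    expd <- K / N
    fold <- if (k == 0 || K == 0) 0 else obs / expd
    p <- switch(alternative,
        greater = stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE),
        less = stats::phyper(k, K, N - K, m),
        two.sided = stats::fisher.test(
            matrix(c(k, m - k, K - k, N - m - K + k), 2),
            alternative = "two.sided")$p.value)
    data.frame(k = k, m = m, K = K, N = N, observed = obs,
               expected = expd, fold = fold, p = p)
}

#' Enrichment of many gene lists in many term sets
#'
#' One row per (list, term) pair, plus an automatically added
#' \code{"outside"} list (background minus the union of the supplied
#' lists), so depletion outside the clusters is visible alongside
#' enrichment within them. BH FDR is computed across all emitted rows.
#'
#' @param lists named list of character vectors (e.g. the clusters).
#' @param terms a [TargetCollection-class]; its background is the chip
#'   universe.
#' @param alternative passed to [foldEnrichment()].
#' @param addOutside add the complement list (default TRUE).
#' @return \code{data.frame} with columns \code{list}, \code{term}, the
#'   [foldEnrichment()] columns, and \code{q}.
#' @export
enrichMany <- function(lists, terms,
                       alternative = c("greater", "less", "two.sided"),
                       addOutside = TRUE) {
    alternative <- match.arg(alternative)
    stopifnot(is(terms, "TargetCollection"))
    bg <- geneBackground(terms)
    lists <- lapply(lists, function(s) intersect(unique(s), bg))
    if (addOutside)
        lists <- c(lists,
                   list(outside = setdiff(bg, unlist(lists,
                                                     use.names = FALSE))))
    rows <- list()
    for (ln in names(lists)) {
        if (length(lists[[ln]]) == 0L)
            next
        for (tn in names(geneSets(terms))) {
            r <- foldEnrichment(lists[[ln]], geneSets(terms)[[tn]], bg,
                                alternative = alternative)
            rows[[length(rows) + 1L]] <-
                cbind(data.frame(list = ln, term = tn,
                                 stringsAsFactors = FALSE), r)
        }
    }
    if (!length(rows))
        return(data.frame(list = character(0), term = character(0),
                          k = integer(0), m = integer(0), K = integer(0),
                          N = integer(0), observed = numeric(0),
                          expected = numeric(0), fold = numeric(0),
                          p = numeric(0), q = numeric(0)))
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    rownames(out) <- NULL
    out
}

#' Coverage of a term by a signature
#'
#' Percentage of the term's genes (on the chip) that fall inside the
#' signature: \code{100 * |term & signature & background| / |term &
#' background|}.
#'
#' @param termGenes character vector, the term/target set.
#' @param signatureGenes character vector (or [Signature-class]).
#' @param background character vector, the chip universe.
#' @return a percentage in \code{[0, 100]}.
#' @export
coverageFraction <- function(termGenes, signatureGenes, background) {
    if (is(signatureGenes, "Signature"))
        signatureGenes <- signatureGenes@genes
    trm <- intersect(unique(termGenes), unique(background))
    if (length(trm) == 0L)
        stop("term has no overlap with the background")
    100 * length(intersect(trm, unique(signatureGenes))) / length(trm)
}
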