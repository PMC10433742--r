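#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-inverse-chi-square prior of the moderated-t model to
#' per-gene residual variances by moment matching of log-variances: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, the prior degrees of
#' freedom solve \eqn{\psi'(d_0/2) = \overline{(e_g - \bar e)^2\,G/(G-1) -
#' \psi'(d_g/2)}} (digamma \eqn{\psi}, trigamma \eqn{\psi'}), and
#' \eqn{\log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2)}. If the
#' right-hand side is not positive the observed spread of log-variances is
#' no larger than expected under a single variance and \code{d0 = Inf},
#' \code{s0Sq = exp(mean(e))}. The trigamma inversion uses a monotone
#' Newton iteration to \code{|delta| < 1e-8}.
#'
#' @param variances per-gene residual variances \eqn{s_g^2} (>= 0; exact
#'   zeros are offset to half the smallest positive value, with a
#'   message).
#' @param dfs residual degrees of freedom, a scalar or one value per
#'   gene.
#' @return an [EBPrior-class].
#' @export
estimateEBPrior <- function(variances, dfs) {
    s2 <- as.numeric(variances)
    if (length(s2) < 2L)
        stop("need at least 2 variances")
    d <- rep_len(as.numeric(dfs), length(s2))
    ok <- d >= 1 & !is.na(s2)
    s2 <- s2[ok]
    d <- d[ok]
    G <- length(s2)
    if (G < 10L)
        warning("fewer than 10 genes with df >= 1; prior estimate is weak")
    if (any(s2 < 0))
        stop("variances must be non-negative")
    nz <- sum(s2 == 0)
    if (nz > 0) {
        if (all(s2 == 0))
            stop("all variances are zero")
        s2[s2 == 0] <- min(s2[s2 > 0]) / 2
        message(nz, " zero variances offset to half the smallest positive")
    }
    if (stats::var(s2) == 0)           # all variances identical
        return(EBPrior(d0 = Inf, s0Sq = s2[1]))
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    target <- mean((e - ebar)^2 * G / (G - 1) - trigamma(d / 2))
    if (target <= 0)
        return(EBPrior(d0 = Inf, s0Sq = exp(ebar)))
    half_d0 <- .trigammaInverse(target)
    d0 <- 2 * half_d0
    s0 <- exp(ebar + digamma(half_d0) - log(half_d0))
    EBPrior(d0 = d0, s0Sq = s0)
}

# Solve trigamma(x) = y for x > 0 by Newton iteration on the monotone
# decreasing trigamma; derivative is psigamma(x, 2). Converges for all
# y > 0 from the large-x asymptotic start x ~ 1/y + 1/2.
.trigammaInverse <- function(y) {
    if (y <= 0)
        return(Inf)
    if (y > 1e7)
        return(1 / sqrt(y))
    x <- 0.5 + 1 / y
    for (i in 1:60) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2)
        x <- x + dif
        if (abs(dif) < 1e-8)
            break
    }
    x
}

#' Gene-wise moderated t-test table for a two-group contrast
#'
#' For every gene, the pooled residual variance \eqn{s_g^2} (with
#' \eqn{d_g = n_A + n_B - 2} df) is shrunk towards the chip-wide prior:
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}; the
#' moderated statistic \eqn{t_g = (\bar x_A - \bar x_B) / (\tilde s_g
#' \sqrt{1/n_A + 1/n_B})} is referred to a Student t distribution with
#' \eqn{d_g + d_0} df (standard normal for \eqn{d_0 = \infty}). With
#' \code{d0 = 0} the statistic reduces exactly to the classical
#' pooled-variance two-sample t.
#'
#' @param x an [ExpressionMatrix-class] with group labels (log2 scale).
#' @param groupA,groupB group labels; the log2 fold change is
#'   \code{meanA - meanB}.
#' @param prior optional [EBPrior-class]; estimated from this matrix via
#'   [estimateEBPrior()] when missing. Supply \code{EBPrior} with
#'   \code{d0 = 0} semantics via \code{prior = NULL, d0 = 0} is not
#'   allowed by the class; use the \code{d0}/\code{s0Sq} arguments
#'   instead to force a degenerate prior.
#' @param d0,s0Sq optional scalar overrides of the prior (e.g.
#'   \code{d0 = 0} for the classical t); ignored when \code{prior} is
#'   supplied.
#' @return a \code{data.frame} (one row per gene): \code{gene},
#'   \code{lfc} (log2 fold change), \code{s2} (residual variance),
#'   \code{df} (residual df), \code{s2_post} (posterior variance),
#'   \code{t} (moderated t), \code{p} (two-sided), \code{q} (BH FDR).
#'   The prior used is attached as \code{attr(, "prior")} (a list with
#'   \code{d0}, \code{s0Sq}).
#' @export
moderatedTTable <- function(x, groupA, groupB, prior = NULL, d0 = NULL,
                            s0Sq = NULL) {
    grp <- sampleGroups(x)
    if (is.null(grp))
        stop("expression matrix carries no group labels")
    sa <- names(grp)[grp == groupA]
    sb <- names(grp)[grp == groupB]
    nA <- length(sa)
    nB <- length(sb)
    if (nA < 2L || nB < 2L)
        stop("both groups need at least 2 samples")
    V <- exprValues(x)
    A <- V[, sa, drop = FALSE]
    B <- V[, sb, drop = FALSE]
    mA <- rowMeans(A)
    mB <- rowMeans(B)
    dg <- nA + nB - 2
    s2 <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / dg
    if (!is.null(prior)) {
        stopifnot(is(prior, "EBPrior"))
        p0 <- prior@d0
        pv <- prior@s0Sq
    } else if (!is.null(d0)) {
        p0 <- d0
        pv <- if (!is.null(s0Sq)) s0Sq else 1   # unused when d0 = 0
        if (p0 > 0 && is.null(s0Sq))
            stop("s0Sq required when d0 > 0 is forced")
    } else {
        est <- estimateEBPrior(s2, dg)
        p0 <- est@d0
        pv <- est@s0Sq
    }
    s2post <- if (is.infinite(p0)) rep(pv, length(s2))
              else if (p0 == 0) s2
              else (p0 * pv + dg * s2) / (p0 + dg)
    se <- sqrt(s2post * (1 / nA + 1 / nB))
    lfc <- mA - mB
    t <- ifelse(se == 0, ifelse(lfc == 0, 0, sign(lfc) * Inf), lfc / se)
    dfTotal <- dg + p0
    p <- if (is.infinite(dfTotal)) 2 * stats::pnorm(-abs(t))
         else 2 * stats::pt(-abs(t), df = dfTotal)
    p[t == 0 & se == 0] <- 1
    tab <- data.frame(gene = rownames(V), lfc = lfc, s2 = s2, df = dg,
                      s2_post = s2post, t = t, p = p,
                      q = bhAdjust(p), row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(tab, "prior") <- list(d0 = p0, s0Sq = pv)
    tab
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and mapped
#' back to input order. \code{NA} p-values receive \code{NA} q-values and
#' are excluded from the test count \eqn{m}.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]} (NA
#'   allowed).
#' @return q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
    p <- as.numeric(pvalues)
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

#' Threshold a differential table into up/down gene sets
#'
#' A gene is called up if \code{q < fdrThreshold} and its log2 fold change
#' exceeds \code{log2(foldThreshold)}; down symmetrically. With
#' \code{foldThreshold = 1} only the FDR filter applies (genes need a
#' non-zero fold change for a direction).
#'
#' @param table a differential table from [moderatedTTable()].
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @param foldThreshold fold-change cutoff on the anti-logged scale
#'   (default 2, i.e. |log2 FC| > 1).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
selectDifferential <- function(table, fdrThreshold = 0.05,
                               foldThreshold = 2) {
    if (fdrThreshold <= 0 || foldThreshold <= 0)
        stop("thresholds must be positive")
    lth <- base::log2(foldThreshold)
    sig <- !is.na(table$q) & table$q < fdrThreshold
    list(up = table$gene[sig & table$lfc > lth],
         down = table$gene[sig & table$lfc < -lth])
}

#' Venn overlap counts between two contrasts' up/down gene sets
#'
#' @param upA,downA,upB,downB character vectors of unique gene symbols.
#' @return list of counts: \code{up_up} (up in both), \code{down_down},
#'   \code{discordant} (up in one contrast, down in the other),
#'   \code{exclusive_A}, \code{exclusive_B}.
#' @export
vennOverlap <- function(upA, downA, upB, downB) {
    upA <- unique(upA); downA <- unique(downA)
    upB <- unique(upB); downB <- unique(downB)
    selA <- union(upA, downA)
    selB <- union(upB, downB)
    list(up_up = length(intersect(upA, upB)),
         down_down = length(intersect(downA, downB)),
         discordant = length(intersect(upA, downB)) +
                      length(intersect(downA, upB)),
         exclusive_A = length(setdiff(selA, selB)),
         exclusive_B = length(setdiff(selB, selA)))
}
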