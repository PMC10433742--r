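#' Median reference profile
#'
#' Element-wise median across samples, on the scale of the input. The
#' reference profile is the target of the LOWESS trend correction.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix with >= 2
#'   samples.
#' @return named numeric vector, one median per gene.
#' @export
medianReference <- function(x) {
    V <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    if (ncol(V) < 2L)
        stop("need at least 2 samples to form a median reference")
    apply(V, 1L, stats::median)
}

#' Robust locally weighted scatterplot smoothing (LOWESS)
#'
#' Locally linear fit with tricube weights and robustifying iterations
#' (Cleveland's method, via \code{stats::lowess}), evaluated back at every
#' input abscissa. For speed on chip-sized inputs the fit is computed on a
#' downsampled anchor grid and linearly interpolated; the anchor spacing is
#' 1/1000 of the abscissa range, which changes fitted values by far less
#' than the fit tolerance of the normalization contract.
#'
#' @param x abscissa values (length >= 3).
#' @param y ordinate values, same length.
#' @param span fraction of points in each local window, in (0, 1].
#' @param iterations robustifying iterations (default 3).
#' @return numeric vector of fitted values at each \code{x}, in input
#'   order.
#' @export
lowessFit <- function(x, y, span = 0.4, iterations = 3) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal lengths")
    if (length(x) < 3L)
        stop("need at least 3 points")
    if (span <= 0 || span > 1)
        stop("'span' must lie in (0, 1]")
    if (floor(span * length(x)) < 2L)
        stop("'span' leaves local windows with fewer than 2 points")
    rng <- range(x)
    delta <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 1000 else 0
    fit <- stats::lowess(x, y, f = span, iter = iterations, delta = delta)
    if (rng[2] == rng[1])
        return(rep(fit$y[1], length(x)))
    stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
}

#' LOWESS normalization against the median reference profile
#'
#' For every sample j, the intensity-dependent trend of the deviation
#' \code{x_j - reference} as a function of the reference is estimated by
#' [lowessFit()] and subtracted. This removes smooth nonlinear effects
#' such as background offsets or saturation. After correction, a re-fitted
#' trend is flat to within ~0.05 (log2 units) for chip-sized inputs.
#'
#' Because subtracting the trends moves the per-gene medians, the
#' correction is iterated against the updated reference until the fitted
#' trend amplitude falls below \code{tol} (a fixed-point refinement), up
#' to \code{maxPasses} passes.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix (>= 3 genes),
#'   conventionally on the log2 scale.
#' @param span,iterations passed to [lowessFit()].
#' @param maxPasses maximum correction passes (default 3).
#' @param tol trend amplitude below which the correction is considered
#'   converged (default 0.02 log2 units).
#' @return an object of the same class as \code{x} with the per-sample
#'   trends removed.
#' @export
normalizeToReference <- function(x, span = 0.4, iterations = 3,
                                 maxPasses = 3, tol = 0.02) {
    isEM <- is(x, "ExpressionMatrix")
    V <- if (isEM) exprValues(x) else as.matrix(x)
    if (nrow(V) < 3L)
        stop("need at least 3 genes for trend estimation")
    out <- V
    for (pass in seq_len(maxPasses)) {
        ref <- medianReference(out)
        amp <- 0
        for (j in seq_len(ncol(out))) {
            trend <- lowessFit(ref, out[, j] - ref, span = span,
                               iterations = iterations)
            amp <- max(amp, max(abs(trend)))
            out[, j] <- out[, j] - trend
        }
        if (amp < tol)
            break
    }
    if (isEM) ExpressionMatrix(out, groups = sampleGroups(x)) else out
}

#' Log2 transform and gene-median centering
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix.
#' @param log2 apply \code{log2} first (values must be strictly
#'   positive); set FALSE for data already on the log scale.
#' @param center \code{"median"} (default; every output row has median
#'   exactly 0), \code{"mean"}, or \code{"none"}.
#' @return transformed object of the same class as \code{x}.
#' @export
log2AndCenter <- function(x, log2 = TRUE,
                          center = c("median", "mean", "none")) {
    center <- match.arg(center)
    isEM <- is(x, "ExpressionMatrix")
    V <- if (isEM) exprValues(x) else as.matrix(x)
    if (log2) {
        bad <- rowSums(V <= 0) > 0
        if (any(bad))
            stop("non-positive values with log2 enabled in genes: ",
                 paste(utils::head(rownames(V)[bad], 10), collapse = ", "),
                 if (sum(bad) > 10) ", ...")
        V <- base::log2(V)
    }
    if (center == "median")
        V <- V - apply(V, 1L, stats::median)
    else if (center == "mean")
        V <- V - rowMeans(V)
    if (isEM) ExpressionMatrix(V, groups = sampleGroups(x)) else V
}
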