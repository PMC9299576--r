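#' Principal component analysis of sample profiles
#'
#' Columns are centered (no variance scaling by default, matching the usual
#' convention for motif-percentage matrices) and the scores are computed by
#' singular value decomposition of the centered matrix. With all components
#' kept, scores times rotation reproduces the centered data.
#'
#' @param mat samples x features numeric matrix (e.g. log2(TPM+1) genes or
#'   256 motif percentages).
#' @param nComponents number of components to return (default all).
#' @param scale. also scale columns to unit variance.
#' @return list with `scores` (samples x components), `rotation` (features
#'   x components), `sdev` and `explained` (fraction of variance per
#'   component, non-increasing).
#' @export
pcaProfiles <- function(mat, nComponents = NULL, scale. = FALSE) {
    mat <- as.matrix(mat)
    if (nrow(mat) < 2 || ncol(mat) < 2)
        stop("need at least 2 samples and 2 features")
    ctr <- scale(mat, center = TRUE, scale = scale.)
    if (all(abs(ctr) < 1e-12))
        warning("constant matrix: all components have zero variance")
    sv <- svd(ctr)
    sdev <- sv$d / sqrt(max(1, nrow(mat) - 1))
    k <- if (is.null(nComponents)) length(sv$d)
         else min(nComponents, length(sv$d))
    scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
    dimnames(scores) <- list(rownames(mat),
                             paste0("PC", seq_along(sv$d)))
    rotation <- sv$v
    dimnames(rotation) <- list(colnames(mat),
                               paste0("PC", seq_along(sv$d)))
    expl <- if (sum(sdev^2) > 0) sdev^2 / sum(sdev^2)
            else rep(0, length(sdev))
    list(scores = scores[, seq_len(k), drop = FALSE],
         rotation = rotation[, seq_len(k), drop = FALSE],
         sdev = sdev[seq_len(k)], explained = expl[seq_len(k)])
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform of r
#' on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return list(r, p, n).
#' @export
pearsonCor <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("need equal-length vectors with n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant input")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return "" / "*" / "**" / "***" for p below .05, .01, .001.
#' @export
sigStars <- function(p) {
    vapply(p, function(pp) {
        if (is.na(pp)) return(NA_character_)
        if (pp < 0.001) "***" else if (pp < 0.01) "**"
        else if (pp < 0.05) "*" else ""
    }, character(1))
}

#' Wilcoxon rank-sum test between two groups
#'
#' Exact two-sided p for small samples (both groups at most 20, no ties),
#' normal approximation otherwise.
#'
#' @param g1,g2 numeric vectors, each of length >= 2.
#' @return data.frame(comparison, statistic, p, stars).
#' @export
rankSumTest <- function(g1, g2) {
    stopifnot(length(g1) >= 2, length(g2) >= 2)
    ties <- anyDuplicated(c(g1, g2)) > 0
    exact <- length(g1) <= 20 && length(g2) <= 20 && !ties
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = exact,
                                              correct = !exact))
    data.frame(comparison = "rank_sum", statistic = unname(wt$statistic),
               p = wt$p.value, stars = sigStars(wt$p.value),
               stringsAsFactors = FALSE)
}

#' Matched (paired) two-tailed t test
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return data.frame(comparison, statistic, p, stars).
#' @export
pairedTTest <- function(x, y) {
    if (length(x) != length(y))
        stop("paired test needs equal-length vectors")
    d <- x - y
    if (stats::sd(d) == 0)
        stop("paired differences are constant; t statistic undefined")
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(comparison = "paired_t", statistic = unname(tt$statistic),
               p = tt$p.value, stars = sigStars(tt$p.value),
               stringsAsFactors = FALSE)
}
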