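#' F-score of a single feature
#'
#' Ranks how well one feature separates the two classes.  The default
#' `"ratio"` variant is the statistic this package's frozen feature set
#' was selected with: the absolute ratio of the between-class mean
#' difference to the difference of the class standard deviations,
#' `| (mean+ - mean-) / (sd+ - sd-) |`, with sample (n-1) standard
#' deviations.  The `"classical"` variant is the Chen-Lin F-score,
#' `(mean+ - m)^2 + (mean- - m)^2` over the sum of within-class
#' variances, with `m` the pooled mean.
#'
#' When the two class standard deviations coincide (within 1e-12) but
#' the means differ, the ratio variant is undefined and returns the
#' sentinel `Inf`, which sorts above every finite score; with equal
#' means the score is 0 under either variant.
#'
#' @param posValues,negValues numeric vectors of the feature in the true
#'   and false class (each of length >= 2)
#' @param variant `"ratio"` (default) or `"classical"`
#' @return a nonnegative number, possibly `Inf` (ratio variant sentinel)
#' @examples
#' fScore(c(1.5, 2.5), c(0.5, 1.5))             # means 2 vs 1
#' @export
fScore <- function(posValues, negValues, variant = c("ratio", "classical")) {
    variant <- match.arg(variant)
    if (length(posValues) < 2L || length(negValues) < 2L)
        stop("need at least 2 values per class")
    mp <- mean(posValues); mn <- mean(negValues)
    if (variant == "ratio") {
        sp <- sd(posValues); sn <- sd(negValues)
        if (abs(sp - sn) < 1e-12)
            return(if (abs(mp - mn) < 1e-12) 0 else Inf)
        abs((mp - mn) / (sp - sn))
    } else {
        m <- mean(c(posValues, negValues))
        denom <- sum((posValues - mp)^2) / (length(posValues) - 1L) +
                 sum((negValues - mn)^2) / (length(negValues) - 1L)
        num <- (mp - m)^2 + (mn - m)^2
        if (denom < 1e-300)
            return(if (num < 1e-300) 0 else Inf)
        num / denom
    }
}

#' Rank features by F-score and select those above a threshold
#'
#' Computes the F-score of every column of a feature matrix and flags
#' features with a finite score at or above the threshold (the
#' selection rule is inclusive, `F >= threshold`).  Features returning
#' the `Inf` sentinel (undefined ratio: equal class spreads with unequal
#' means) are ranked on top but never auto-selected; they are reported
#' with a warning so the analyst can decide.
#'
#' @param mat numeric feature matrix (windows x named features), e.g.
#'   from [encodeWindows()]
#' @param labels class labels parallel to the rows (`"true"`/`"false"`
#'   factor, character or logical with `TRUE` = true site)
#' @param threshold selection threshold (default 1.25, the operating
#'   point the frozen 49-feature set was selected at)
#' @param variant passed to [fScore()]
#' @return data.frame sorted by decreasing F with columns `feature`,
#'   `F`, `meanTrue`, `meanFalse`, `sdTrue`, `sdFalse`, `selected`;
#'   the threshold and variant are stored as attributes
#' @seealso [asManifest()] to turn the selection into a feature-set
#'   manifest
#' @export
selectFeatures <- function(mat, labels, threshold = 1.25,
                           variant = c("ratio", "classical")) {
    variant <- match.arg(variant)
    if (is.logical(labels)) labels <- ifelse(labels, "true", "false")
    labels <- as.character(labels)
    pos <- labels == "true"
    if (!any(pos) || all(pos))
        stop("both classes must be present")
    if (is.null(colnames(mat))) stop("feature matrix columns must be named")
    stats <- apply(mat, 2L, function(v)
        c(F = fScore(v[pos], v[!pos], variant),
          meanTrue = mean(v[pos]), meanFalse = mean(v[!pos]),
          sdTrue = sd(v[pos]), sdFalse = sd(v[!pos])))
    out <- data.frame(feature = colnames(mat), t(stats),
                      stringsAsFactors = FALSE, row.names = NULL)
    out$selected <- is.finite(out$F) & out$F >= threshold
    if (any(!is.finite(out$F)))
        warning(sprintf(paste0("%d feature(s) have an undefined (sentinel) ",
                               "F-score and were not auto-selected: %s"),
                        sum(!is.finite(out$F)),
                        paste(head(out$feature[!is.finite(out$F)], 5L),
                              collapse = ", ")))
    out <- out[order(-out$F, out$feature), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "threshold") <- threshold
    attr(out, "variant") <- variant
    out
}

#' Convert an F-score selection into a custom feature manifest
#'
#' @param fscoreTable the data.frame returned by [selectFeatures()]
#' @return a `custom` [FeatureSetManifest-class] of the selected
#'   features, in decreasing-F order
#' @export
asManifest <- function(fscoreTable) {
    featureManifest("custom",
        featureNames = fscoreTable$feature[fscoreTable$selected],
        note = sprintf("F-score selection, threshold %g, variant %s",
                       attr(fscoreTable, "threshold"),
                       attr(fscoreTable, "variant")))
}

#' Write an F-score table as a delimited file
#'
#' Tab-separated, sorted by descending F as returned by
#' [selectFeatures()]; reloadable into a manifest via [readManifest()]
#' after [writeManifest()], or re-read with [read.table()].
#'
#' @param fscoreTable data.frame from [selectFeatures()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFScoreTable <- function(fscoreTable, path) {
    write.table(fscoreTable, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
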