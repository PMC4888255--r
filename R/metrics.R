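.check_binary <- function(scores, labels) {
    if (is.logical(labels)) labels <- ifelse(labels, "true", "false")
    labels <- as.character(labels)
    if (length(labels) != length(scores))
        stop("scores and labels must have the same length")
    if (!all(labels %in% c("true", "false")))
        stop("labels must be 'true'/'false' (or logical)")
    labels == "true"
}

# cumulative confusion counts along the sweep of distinct scores
# (descending); all instances sharing a score change class together
.sweep_counts <- function(scores, pos) {
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; p <- pos[o]
    last <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
    data.frame(threshold = s[last],
               TP = cumsum(p)[last],
               FP = cumsum(!p)[last])
}

#' ROC curve over the exact threshold sweep
#'
#' Sweeps the distinct observed scores as thresholds (each tie group
#' changes classification together) and returns the false positive rate
#' and true positive rate at every cutoff, with the (0, 0) and (1, 1)
#' endpoints.
#'
#' @param scores numeric classifier scores, larger = more positive
#' @param labels `"true"`/`"false"` labels (or logical, `TRUE` =
#'   positive) parallel to `scores`
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold (`Inf`/`-Inf` sentinels give the endpoints)
#' @export
rocCurve <- function(scores, labels) {
    pos <- .check_binary(scores, labels)
    nP <- sum(pos); nN <- sum(!pos)
    if (nP == 0L || nN == 0L)
        stop("both classes must be present to compute a ROC curve")
    cc <- .sweep_counts(scores, pos)
    data.frame(threshold = c(Inf, cc$threshold),
               fpr = c(0, cc$FP / nN),
               tpr = c(0, cc$TP / nP))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal area under the exact threshold-sweep ROC curve of
#' [rocCurve()]: `sum_i { tpr * d(fpr) + 1/2 d(tpr) d(fpr) }`.  This
#' equals the Mann-Whitney statistic (fraction of (positive, negative)
#' pairs ranked concordantly, ties counted 1/2).
#'
#' @inheritParams rocCurve
#' @return area in `[0, 1]`
#' @examples
#' aucROC(c(0.9, 0.8, 0.7, 0.6), c("true", "false", "true", "false"))
#' @export
aucROC <- function(scores, labels) {
    rc <- rocCurve(scores, labels)
    n <- nrow(rc)
    sum((rc$tpr[-n] + rc$tpr[-1]) / 2 * diff(rc$fpr))
}

# achievable PR points plus the (TP = 0, FP = 0) anchor
.pr_points <- function(scores, pos) {
    cc <- .sweep_counts(scores, pos)
    data.frame(TP = c(0, cc$TP), FP = c(0, cc$FP))
}

#' Precision-recall curve with Davis-Goadrich interpolation
#'
#' Returns the achievable PR points of the threshold sweep together with
#' the non-linearly interpolated points between them: between adjacent
#' achievable points the true positives are stepped one at a time and
#' the false positives grow proportionally (the local skew), so
#' precision between achievable points follows
#' `x / (x + FP_a + s (x - TP_a))` rather than a straight line.
#'
#' @inheritParams rocCurve
#' @return data.frame with columns `recall`, `precision`, `TP`, `FP`,
#'   recall nondecreasing
#' @export
prCurve <- function(scores, labels) {
    pos <- .check_binary(scores, labels)
    P <- sum(pos)
    if (P == 0L) stop("at least one positive instance is required")
    pts <- .pr_points(scores, pos)
    out <- list()
    for (seg in seq_len(nrow(pts) - 1L)) {
        TPa <- pts$TP[seg]; FPa <- pts$FP[seg]
        TPb <- pts$TP[seg + 1L]; FPb <- pts$FP[seg + 1L]
        if (TPb == TPa) {     # recall unchanged; keep the endpoint only
            out[[seg]] <- data.frame(TP = TPb, FP = FPb)
            next
        }
        s <- (FPb - FPa) / (TPb - TPa)
        x <- seq(TPa + 1L, TPb)
        out[[seg]] <- data.frame(TP = x, FP = FPa + s * (x - TPa))
    }
    pts <- do.call(rbind, out)
    pts <- pts[pts$TP > 0, , drop = FALSE]   # precision undefined at TP=0
    data.frame(recall = pts$TP / P,
               precision = pts$TP / (pts$TP + pts$FP),
               TP = pts$TP, FP = pts$FP)
}

#' Area under the precision-recall curve (Davis-Goadrich)
#'
#' Integrates precision over recall with the Davis-Goadrich non-linear
#' interpolation between achievable points.  Within a segment from
#' `(TP_a, FP_a)` to `(TP_b, FP_b)` the interpolated precision is
#' `p(x) = x / (x (1 + s) + c)` with `s` the local skew
#' `(FP_b - FP_a) / (TP_b - TP_a)` and `c = FP_a - s TP_a`; the segment
#' area is the exact integral of `p(x) / P` over `x` in `[TP_a, TP_b]`,
#' so no grid approximation is involved.  The curve is anchored at
#' `(TP, FP) = (0, 0)`: with all scores tied this yields the constant-
#' precision curve at the class prevalence, whose area is the prevalence.
#'
#' @inheritParams rocCurve
#' @return area in `(0, 1]`
#' @examples
#' aucPR(c(0.9, 0.8, 0.7, 0.6), c("true", "false", "true", "false"))
#' @export
aucPR <- function(scores, labels) {
    pos <- .check_binary(scores, labels)
    P <- sum(pos)
    if (P == 0L) stop("at least one positive instance is required")
    pts <- .pr_points(scores, pos)
    area <- 0
    for (seg in seq_len(nrow(pts) - 1L)) {
        TPa <- pts$TP[seg]; FPa <- pts$FP[seg]
        TPb <- pts$TP[seg + 1L]; FPb <- pts$FP[seg + 1L]
        if (TPb == TPa) next
        s <- (FPb - FPa) / (TPb - TPa)
        a <- 1 + s
        c0 <- FPa - s * TPa
        # integral of x / (a x + c0) dx = x/a - (c0/a^2) log(a x + c0)
        F <- function(x) {
            v <- x / a
            if (abs(c0) > 1e-300) v <- v - (c0 / a^2) * log(a * x + c0)
            v
        }
        area <- area + (F(TPb) - F(TPa)) / P
    }
    area
}

#' Write a ROC or PR curve as a delimited table
#'
#' @param curve data.frame from [rocCurve()] or [prCurve()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCurve <- function(curve, path) {
    write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
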