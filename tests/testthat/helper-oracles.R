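# Independent oracles used to check the package's implementations.
# Each is written as a direct transcription of the defining computation
# (pair counting, fine-grid interpolation, substring enumeration) and
# shares no code with the implementation under test.

# AUC-ROC as the Mann-Whitney pair statistic: fraction of
# (positive, negative) pairs ranked concordantly, ties counted 1/2.
oracle_auc_pairs <- function(scores, labels) {
    pos <- scores[labels == "true"]
    neg <- scores[labels == "false"]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# achievable (TP, FP) points of the threshold sweep, by direct counting
oracle_pr_points <- function(scores, labels) {
    pos <- labels == "true"
    ts <- sort(unique(scores), decreasing = TRUE)
    data.frame(TP = vapply(ts, function(t) sum(pos & scores >= t), 0),
               FP = vapply(ts, function(t) sum(!pos & scores >= t), 0))
}

# AUC-PR by fine-grid Davis-Goadrich interpolation: between adjacent
# achievable points (anchored at TP = FP = 0) the true positives are
# stepped on a fine grid with proportional false positives, and the
# precision-over-recall integral is taken by trapezoid on that grid.
oracle_auc_pr_grid <- function(scores, labels, steps = 20000L) {
    pts <- oracle_pr_points(scores, labels)
    pts <- rbind(data.frame(TP = 0, FP = 0), pts)
    P <- sum(labels == "true")
    area <- 0
    for (k in seq_len(nrow(pts) - 1L)) {
        dTP <- pts$TP[k + 1L] - pts$TP[k]
        if (dTP == 0) next
        s <- (pts$FP[k + 1L] - pts$FP[k]) / dTP
        x <- seq(pts$TP[k], pts$TP[k + 1L], length.out = steps)
        prec <- x / (x + pts$FP[k] + s * (x - pts$TP[k]))
        prec[x == 0] <- 1 / (1 + s)   # limit from the right
        recall <- x / P
        area <- area + sum((prec[-1] + prec[-steps]) / 2 * diff(recall))
    }
    area
}

# overlapping k-mer counts by explicit substring enumeration; levels in
# lexicographic A<C<G<T order, built independently with expand.grid
oracle_kmer_counts <- function(seq, k) {
    L <- nchar(seq)
    kmers <- substring(seq, 1:(L - k + 1), k:L)
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
    lvls <- apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste,
                  collapse = "")
    table(factor(kmers, levels = lvls))
}

# all valid GT window starts in a sequence, by explicit enumeration
oracle_gt_starts <- function(seq, L, g) {
    starts <- integer(0)
    for (i in seq_len(max(nchar(seq) - 1L, 0L))) {
        if (substr(seq, i, i + 1L) != "GT") next
        st <- i - g + 1L
        if (st >= 1L && st + L - 1L <= nchar(seq)) starts <- c(starts, st)
    }
    starts
}

random_score_instance <- function(n, tie_prob = 0.3) {
    scores <- if (runif(1) < tie_prob)
        sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    else runif(n)
    labels <- sample(c("true", "false"), n, replace = TRUE)
    # ensure both classes present
    labels[1] <- "true"; labels[2] <- "false"
    list(scores = scores, labels = labels)
}

random_window_set <- function(n, L = 15L, g = 9L, label = NULL) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    m[, g] <- "G"; m[, g + 1L] <- "T"
    SpliceWindowSet(apply(m, 1L, paste, collapse = ""),
                    geometry = WindowGeometry(L, g), label = label)
}
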