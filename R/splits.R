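#' Assemble repeated balanced/imbalanced evaluation sets
#'
#' Builds the repeated cross-validation design used to evaluate the
#' classifier: `nSets` independent data sets, each drawn by seeded random
#' subsampling (without replacement) of the pooled windows at an exact
#' `ratio[1]:ratio[2]` true:false ratio, each set then partitioned into
#' `nFolds` class-stratified folds so every window of a set appears in
#' the test partition of exactly one fold.
#'
#' Set sizes are maximal under the ratio: with `u = min(floor(nTrue /
#' ratio[1]), floor(nFalse / ratio[2]))`, each set holds `u * ratio[1]`
#' true and `u * ratio[2]` false windows.  A balanced (1:1) design over
#' 2796 true and 90923 false windows therefore uses all 2796 true sites
#' per set with a fresh random subset of 2796 false sites, and a 1:19
#' design over 500 true and 9500 false windows uses all of both.
#'
#' @param trueWindows,falseWindows [SpliceWindowSet-class] objects holding
#'   the two classes (labels are overwritten with `true` / `false`)
#' @param ratio length-2 integer vector, true:false parts (default 1:1)
#' @param nSets number of independently subsampled sets (default 10)
#' @param nFolds folds per set (default 5, must be >= 2)
#' @param seed integer seed; the design is byte-identical across runs for
#'   a fixed seed
#' @return an [EvalDesign-class]
#' @examples
#' w <- generateWindows(nTrue = 30, nFalse = 60, seed = 1)
#' assembleEvalSets(w[siteLabels(w) == "true"],
#'                  w[siteLabels(w) == "false"],
#'                  ratio = c(1, 2), nSets = 2, nFolds = 5, seed = 7)
#' @export
assembleEvalSets <- function(trueWindows, falseWindows, ratio = c(1L, 1L),
                             nSets = 10L, nFolds = 5L, seed = 1L) {
    stopifnot(is(trueWindows, "SpliceWindowSet"),
              is(falseWindows, "SpliceWindowSet"))
    ratio <- as.integer(ratio)
    nSets <- as.integer(nSets); nFolds <- as.integer(nFolds)
    if (length(ratio) != 2L || any(ratio < 1L))
        stop("ratio must be two positive integers c(true, false)")
    if (nFolds < 2L) stop("nFolds must be >= 2")

    trueWindows@label <- factor(rep("true", length(trueWindows)),
                                levels = c("true", "false"))
    falseWindows@label <- factor(rep("false", length(falseWindows)),
                                 levels = c("true", "false"))
    pool <- c(trueWindows, falseWindows)
    nT <- length(trueWindows); nF <- length(falseWindows)
    unit <- min(nT %/% ratio[1], nF %/% ratio[2])
    if (unit < nFolds)
        stop(sprintf(paste0("insufficient windows for ratio %d:%d with %d ",
                            "folds: have %d true and %d false, need at ",
                            "least %d true and %d false"),
                     ratio[1], ratio[2], nFolds, nT, nF,
                     ratio[1] * nFolds, ratio[2] * nFolds))
    nTset <- unit * ratio[1]
    nFset <- unit * ratio[2]

    idxT <- seq_len(nT)
    idxF <- nT + seq_len(nF)
    membership <- with_seed(seed, lapply(seq_len(nSets), function(s) {
        pickT <- sample(idxT, nTset)
        pickF <- sample(idxF, nFset)
        # stratified fold assignment: each class permuted, folds dealt
        # round-robin so every fold preserves the set's class ratio
        foldT <- rep_len(seq_len(nFolds), nTset)[sample.int(nTset)]
        foldF <- rep_len(seq_len(nFolds), nFset)[sample.int(nFset)]
        df <- data.frame(index = c(pickT, pickF), fold = c(foldT, foldF))
        df[order(df$index), , drop = FALSE]
    }))

    new("EvalDesign", windows = pool, membership = membership,
        ratio = ratio, nFolds = nFolds, seed = as.integer(seed))
}

#' @rdname EvalDesign
#' @param design an `EvalDesign`
#' @param set set index in `1..nSets`
#' @param fold fold index in `1..nFolds`
#' @return `splitWindows` returns `list(train =, test =)` of
#'   [SpliceWindowSet-class] objects: the given fold as the test
#'   partition, all remaining folds of the set as training
#' @export
setMethod("splitWindows", "EvalDesign", function(design, set, fold) {
    m <- design@membership[[set]]
    list(train = design@windows[m$index[m$fold != fold]],
         test  = design@windows[m$index[m$fold == fold]])
})

#' @rdname EvalDesign
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname EvalDesign
#' @param x an `EvalDesign`
#' @export
setMethod("nSets", "EvalDesign", function(x) length(x@membership))

#' @rdname EvalDesign
#' @export
setGeneric("nFolds", function(x) standardGeneric("nFolds"))

#' @rdname EvalDesign
#' @export
setMethod("nFolds", "EvalDesign", function(x) x@nFolds)

setMethod("show", "EvalDesign", function(object) {
    sizes <- table(siteLabels(object@windows[object@membership[[1]]$index]))
    cat(sprintf(
        "EvalDesign: %d set(s) x %d fold(s), ratio %d:%d, seed %d\n",
        nSets(object), object@nFolds, object@ratio[1], object@ratio[2],
        object@seed))
    cat(sprintf("  each set: %d true + %d false window(s)\n",
                sizes["true"], sizes["false"]))
})

#' Write an evaluation design manifest
#'
#' Plain-text table with one row per (set, window): columns `set`,
#' `fold`, `role` and `windowId`, where `fold` is the fold in which the
#' window is tested (it trains in all other folds of the set).
#'
#' @param design an [EvalDesign-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeDesignManifest <- function(design, path) {
    rows <- do.call(rbind, lapply(seq_along(design@membership), function(s) {
        m <- design@membership[[s]]
        data.frame(set = s, fold = m$fold, role = "test",
                   windowId = sourceIds(design@windows)[m$index])
    }))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
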