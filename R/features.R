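.POSITIONAL_NAMES <- c("wmm_true", "wmm_diff", "ss_true", "ss_diff")
.DEPENDENCY_NAMES <- c("wam_true", "wam_diff", "sae_true", "sae_diff")

.kmer_names <- function(k) {
    prefix <- c("di", "tri", "tetra")[k - 1L]
    paste(prefix,
          Biostrings::mkAllStrings(DNA_BASES4, width = k), sep = "_")
}

# The frozen 49-feature set retained by F-score filtering (threshold
# 1.25) on the human HS3D donor benchmark: all 8 model-based scores plus
# 14 di-, 15 tri- and 12 tetramer compositions.  Shipped verbatim so
# cross-species prediction reuses the same features without re-running
# selection.
.SELECTED49 <- c(
    .POSITIONAL_NAMES, .DEPENDENCY_NAMES,
    paste0("di_", c("AA", "AC", "AG", "CA", "CC", "CT", "GA", "GC", "GG",
                    "GT", "TA", "TC", "TG", "TT")),
    paste0("tri_", c("AAG", "AGG", "AGT", "CAG", "GAG", "GGG", "GGT",
                     "GTA", "GTC", "GTG", "TAA", "TGA", "TGC", "TGG",
                     "TGT")),
    paste0("tetra_", c("AAGG", "AGGT", "CAGG", "GAGG", "GGGT", "GGTA",
                       "GGTG", "GTAA", "GTGA", "GTGG", "TAAG", "TGAG")))

#' Construct a feature-set manifest
#'
#' @param id `"full344"` (all 4 + 4 + 16 + 64 + 256 features),
#'   `"selected49"` (the frozen F-score-selected subset), or `"custom"`
#'   together with `featureNames`
#' @param featureNames ordered feature names, required for `custom`
#' @param note provenance note stored with the manifest
#' @return a [FeatureSetManifest-class]
#' @examples
#' length(featureNames(featureManifest("full344")))    # 344
#' length(featureNames(featureManifest("selected49"))) # 49
#' @export
featureManifest <- function(id = c("selected49", "full344", "custom"),
                            featureNames = NULL, note = "") {
    id <- match.arg(id)
    names_ <- switch(id,
        full344 = c(.POSITIONAL_NAMES, .DEPENDENCY_NAMES,
                    .kmer_names(2L), .kmer_names(3L), .kmer_names(4L)),
        selected49 = .SELECTED49,
        custom = {
            if (is.null(featureNames))
                stop("custom manifests require featureNames")
            as.character(featureNames)
        })
    if (!nzchar(note))
        note <- switch(id,
            full344 = "all positional, dependency and k-mer composition features",
            selected49 = "frozen F-score-selected feature set (threshold 1.25, human donor benchmark)",
            "user-defined feature set")
    new("FeatureSetManifest", id = id, featureNames = names_, note = note)
}

#' @rdname FeatureSetManifest
#' @export
setMethod("featureNames", "FeatureSetManifest", function(x) x@featureNames)

#' @rdname FeatureSetManifest
#' @export
setMethod("manifestId", "FeatureSetManifest", function(x) x@id)

#' @rdname FeatureSetManifest
#' @export
setMethod("length", "FeatureSetManifest",
          function(x) length(x@featureNames))

setMethod("show", "FeatureSetManifest", function(object) {
    cat(sprintf("FeatureSetManifest '%s': %d feature(s)\n  %s\n",
                object@id, length(object@featureNames), object@note))
})

#' Write / read a feature-set manifest as a plain-text name list
#'
#' One feature name per line, with `#`-prefixed comment lines recording
#' the id and provenance note.
#'
#' @param manifest a [FeatureSetManifest-class]
#' @param path file path
#' @return `writeManifest` returns `path` invisibly; `readManifest`
#'   returns the reloaded [FeatureSetManifest-class]
#' @export
writeManifest <- function(manifest, path) {
    writeLines(c(sprintf("# id: %s", manifest@id),
                 sprintf("# note: %s", manifest@note),
                 manifest@featureNames), path)
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    lines <- readLines(path)
    id <- sub("^# id: ", "", grep("^# id:", lines, value = TRUE)[1])
    note <- sub("^# note: ", "", grep("^# note:", lines, value = TRUE)[1])
    new("FeatureSetManifest", id = id,
        featureNames = lines[!grepl("^#", lines) & nzchar(lines)],
        note = note)
}

# n x L matrix of per-window probabilities looked up from a positional
# model; m is the integer window matrix
.lookup_pos <- function(m, prob) {
    L <- ncol(m)
    matrix(prob[cbind(as.vector(m), rep(seq_len(L), each = nrow(m)))],
           nrow(m), L)
}

.check_L <- function(x, L, what) {
    if (geometry(x)@windowLength != L)
        stop(sprintf("window length %d does not match the %s model (L = %d)",
                     geometry(x)@windowLength, what, L))
}

#' Positional (weight-matrix and Shapiro-Senapathy style) features
#'
#' For each window with bases `a_1..a_L`, computes four scores from the
#' per-position frequency models of the two classes:
#' \describe{
#'   \item{wmm_true}{`sum_i log2 pt(a_i)` - the weight-matrix-model log
#'     score under the true-site model}
#'   \item{wmm_diff}{`wmm_true - sum_i log2 pf(a_i)` - the log-odds-style
#'     difference against the false-site model}
#'   \item{ss_true}{`100 * (sum_i pt(a_i) - M) / (M - N)` with M, N the
#'     extremal sums of the true model - a min-max-normalised positional
#'     score in the Shapiro-Senapathy family (0 at the per-position
#'     consensus, negative otherwise)}
#'   \item{ss_diff}{the difference of that quantity between the true and
#'     false models}
#' }
#'
#' `ssVariant = "classical"` replaces the numerator by `sum_i p(a_i) - N`
#' (the classical Shapiro-Senapathy form, 100 at consensus, 0 at the
#' anti-consensus); the default `"deviation"` form is the one the rest of
#' the package is calibrated to.
#'
#' @param x a [SpliceWindowSet-class]
#' @param trueModel,falseModel [PositionalFrequencyModel-class] objects
#'   fitted on true and false sites at the same window length
#' @param ssVariant `"deviation"` (default) or `"classical"`
#' @return numeric matrix, one row per window, columns `wmm_true`,
#'   `wmm_diff`, `ss_true`, `ss_diff`
#' @export
positionalFeatures <- function(x, trueModel, falseModel,
                               ssVariant = c("deviation", "classical")) {
    ssVariant <- match.arg(ssVariant)
    L <- ncol(trueModel@prob)
    .check_L(x, L, "positional")
    for (mod in list(trueModel, falseModel))
        if (mod@M - mod@N < 1e-12)
            stop(sprintf("degenerate positional model ('%s' class): M == N",
                         mod@classTag))
    m <- .window_int_matrix(x)
    pt <- .lookup_pos(m, trueModel@prob)
    pf <- .lookup_pos(m, falseModel@prob)
    if (any(pt == 0) || any(pf == 0))
        stop(paste("zero frequency encountered; refit the models with a",
                   "positive pseudocount"))
    ss <- function(sumP, mod)
        if (ssVariant == "deviation")
            100 * (sumP - mod@M) / (mod@M - mod@N)
        else
            100 * (sumP - mod@N) / (mod@M - mod@N)
    wmm_t <- rowSums(log2(pt))
    wmm_f <- rowSums(log2(pf))
    ss_t <- ss(rowSums(pt), trueModel)
    ss_f <- ss(rowSums(pf), falseModel)
    out <- cbind(wmm_true = wmm_t, wmm_diff = wmm_t - wmm_f,
                 ss_true = ss_t, ss_diff = ss_t - ss_f)
    rownames(out) <- sourceIds(x)
    out
}

# rowwise sums of q and log2 q over all ordered position pairs
.dep_sums <- function(m, q) {
    n <- nrow(m); L <- ncol(m)
    sumQ <- numeric(n); sumLog <- numeric(n)
    for (j in seq_len(L)) {
        off_j <- 16L * L * (j - 1L)
        bj <- 4L * (m[, j] - 1L)
        for (i in seq_len(L)) {
            if (i == j) next
            v <- q[m[, i] + bj + 16L * (i - 1L) + off_j]
            sumQ <- sumQ + v
            sumLog <- sumLog + log2(v)
        }
    }
    list(q = sumQ, log = sumLog)
}

#' Dependency (weight-array and SAE style) features
#'
#' For each window, sums the pairwise conditional frequencies
#' `q(a_i at i | a_j at j)` over all `L(L-1)` ordered position pairs
#' under the true- and false-site dependency models and derives:
#' \describe{
#'   \item{wam_true}{`sum_(i,j) log2 qt` - weight-array-model style log
#'     score under the true-site model}
#'   \item{wam_diff}{`wam_true` minus the same sum under the false model}
#'   \item{sae_true}{`2L(L-1) - 2 * sum_(i,j) qt` - a sum-of-absolute-
#'     error style dependency score (0 when every conditional equals 1)}
#'   \item{sae_diff}{`2 * sum qf - 2 * sum qt`}
#' }
#'
#' @param x a [SpliceWindowSet-class]
#' @param trueDep,falseDep [DependencyFrequencyModel-class] objects for
#'   the two classes at the same window length
#' @return numeric matrix, one row per window, columns `wam_true`,
#'   `wam_diff`, `sae_true`, `sae_diff`
#' @export
dependencyFeatures <- function(x, trueDep, falseDep) {
    L <- dim(trueDep@condProb)[3]
    .check_L(x, L, "dependency")
    m <- .window_int_matrix(x)
    st <- .dep_sums(m, trueDep@condProb)
    sf <- .dep_sums(m, falseDep@condProb)
    if (any(!is.finite(st$log)) || any(!is.finite(sf$log)))
        stop(paste("zero conditional frequency encountered; refit the",
                   "models with a positive pseudocount"))
    out <- cbind(wam_true = st$log, wam_diff = st$log - sf$log,
                 sae_true = 2 * L * (L - 1) - 2 * st$q,
                 sae_diff = 2 * sf$q - 2 * st$q)
    rownames(out) <- sourceIds(x)
    out
}

#' Overlapping k-mer composition features
#'
#' Counts every length-k substring of each window by shifting one
#' position at a time and divides by the number of windows, `L - k + 1`,
#' so each k-mer block is a probability vector over the `4^k` possible
#' k-mers.
#'
#' @param x a [SpliceWindowSet-class]
#' @param k k-mer length: 2 (di-), 3 (tri-) or 4 (tetramers)
#' @return numeric matrix, one row per window, `4^k` columns named
#'   `di_AA`, `tri_AAA`, `tetra_AAAA`, ...
#' @export
compositionalFeatures <- function(x, k) {
    k <- as.integer(k)
    if (!k %in% 2:4) stop("k must be 2, 3 or 4")
    L <- geometry(x)@windowLength
    if (L < k) stop("window length must be >= k")
    counts <- Biostrings::oligonucleotideFrequency(windowSequences(x),
                                                   width = k)
    out <- counts / (L - k + 1L)
    colnames(out) <- .kmer_names(k)
    rownames(out) <- sourceIds(x)
    out
}

#' Fit the four frequency models used for encoding
#'
#' Convenience wrapper fitting the true- and false-class positional and
#' dependency models from one labelled window set.
#'
#' @param windows labelled [SpliceWindowSet-class] containing both classes
#' @param pseudocount smoothing constant passed to the estimators
#' @return named list `posTrue`, `posFalse`, `depTrue`, `depFalse`
#' @export
fitFrequencyModels <- function(windows, pseudocount = 1) {
    lab <- siteLabels(windows)
    if (!all(c("true", "false") %in% lab))
        stop("need labelled windows of both classes")
    wt <- windows[!is.na(lab) & lab == "true"]
    wf <- windows[!is.na(lab) & lab == "false"]
    list(posTrue  = estimatePositional(wt, pseudocount, "true"),
         posFalse = estimatePositional(wf, pseudocount, "false"),
         depTrue  = estimateDependency(wt, pseudocount, "true"),
         depFalse = estimateDependency(wf, pseudocount, "false"))
}

#' Encode windows into a named feature matrix
#'
#' Maps each window to the features named by the manifest: model-based
#' positional and dependency scores (computed against the supplied
#' frequency models) and k-mer composition frequencies.  Only the blocks
#' a manifest actually references are computed.  Columns appear exactly
#' in manifest order, so feature matrices are reproducible
#' column-for-column.
#'
#' @param x a [SpliceWindowSet-class]
#' @param models the list returned by [fitFrequencyModels()]
#' @param manifest a [FeatureSetManifest-class] (default the frozen
#'   49-feature set)
#' @param ssVariant passed to [positionalFeatures()]
#' @return numeric matrix, one row per window, one column per manifest
#'   feature
#' @examples
#' w <- generateWindows(nTrue = 20, nFalse = 20, seed = 1)
#' models <- fitFrequencyModels(w)
#' dim(encodeWindows(w, models, featureManifest("full344")))  # 40 x 344
#' @export
encodeWindows <- function(x, models, manifest = featureManifest(),
                          ssVariant = c("deviation", "classical")) {
    ssVariant <- match.arg(ssVariant)
    wanted <- featureNames(manifest)
    blocks <- list()
    if (any(wanted %in% .POSITIONAL_NAMES))
        blocks$pos <- positionalFeatures(x, models$posTrue, models$posFalse,
                                         ssVariant)
    if (any(wanted %in% .DEPENDENCY_NAMES))
        blocks$dep <- dependencyFeatures(x, models$depTrue, models$depFalse)
    for (k in 2:4)
        if (any(startsWith(wanted, c("di_", "tri_", "tetra_")[k - 1L])))
            blocks[[paste0("k", k)]] <- compositionalFeatures(x, k)
    all <- do.call(cbind, blocks)
    missing <- setdiff(wanted, colnames(all))
    if (length(missing) > 0L)
        stop(sprintf("manifest references unknown feature(s): %s",
                     paste(head(missing, 5L), collapse = ", ")))
    out <- all[, wanted, drop = FALSE]
    rownames(out) <- sourceIds(x)
    out
}

#' Write a feature matrix as a delimited table
#'
#' Tab-separated, header row of feature names, one row per window id.
#'
#' @param mat matrix returned by [encodeWindows()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFeatureMatrix <- function(mat, path) {
    df <- data.frame(windowId = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
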