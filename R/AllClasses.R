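#' @import methods
#' @importFrom stats predict sd quantile setNames runif
#' @importFrom utils head read.table write.table
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement vmatchPattern oligonucleotideFrequency mkAllStrings
#' @importFrom BiocGenerics start width
#' @importFrom e1071 svm
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Window geometry of a donor splice-site motif
#'
#' A donor splice-site window is a fixed-length nucleotide string with the
#' near-invariant intron-start dimer GT at a declared position:
#' `gtOffset` is the 1-based position of the conserved G and the T sits at
#' `gtOffset + 1`.  The default geometry used throughout the package is a
#' 15 nt window with GT at positions 9-10 (8 nt of exon context, 5 nt of
#' intron context beyond the dimer), the geometry of the NN269 benchmark.
#'
#' @slot windowLength single integer, window length in nucleotides (>= 4)
#' @slot gtOffset single integer, 1-based position of the conserved G;
#'   must satisfy `2 <= gtOffset <= windowLength - 1` so that at least one
#'   nucleotide flanks the dimer on each side
#'
#' @seealso [WindowGeometry()] for the user constructor
#' @exportClass WindowGeometry
setClass("WindowGeometry",
    representation(windowLength = "integer", gtOffset = "integer"),
    prototype(windowLength = 15L, gtOffset = 9L))

setValidity("WindowGeometry", function(object) {
    L <- object@windowLength
    g <- object@gtOffset
    if (length(L) != 1L || length(g) != 1L || is.na(L) || is.na(g))
        return("windowLength and gtOffset must be single non-NA integers")
    if (L < 4L)
        return("windowLength must be >= 4")
    if (g < 2L || g > L - 1L)
        return("gtOffset must satisfy 2 <= gtOffset <= windowLength - 1")
    TRUE
})

#' A set of donor splice-site windows
#'
#' Container for fixed-length candidate or labelled splice-site windows.
#' Sequences are stored as a [Biostrings::DNAStringSet] whose widths all
#' equal the geometry's window length; every window carries the conserved
#' GT dimer at the geometry's offset and is restricted to the unambiguous
#' alphabet A/C/G/T.
#'
#' @slot sequences [Biostrings::DNAStringSet] of windows, all of the
#'   geometry's width
#' @slot label factor with levels `true`/`false` (NA = unlabelled)
#' @slot sourceId character, free-text identifier of the source record
#' @slot sourceCoord integer, 1-based inclusive start of the window on its
#'   source sequence (forward strand); NA when unknown
#' @slot geometry a [WindowGeometry-class]
#' @slot rejections data.frame describing records/windows that were read
#'   but rejected (columns `id`, `reason`); kept so loaders never drop
#'   records silently
#'
#' @seealso [SpliceWindowSet()], [readWindows()], [scanCandidates()],
#'   [generateWindows()]
#' @exportClass SpliceWindowSet
setClass("SpliceWindowSet",
    representation(
        sequences   = "DNAStringSet",
        label       = "factor",
        sourceId    = "character",
        sourceCoord = "integer",
        geometry    = "WindowGeometry",
        rejections  = "data.frame"))

setValidity("SpliceWindowSet", function(object) {
    n <- length(object@sequences)
    if (length(object@label) != n || length(object@sourceId) != n ||
        length(object@sourceCoord) != n)
        return("label, sourceId and sourceCoord must match length(sequences)")
    if (!identical(levels(object@label), c("true", "false")))
        return("label must be a factor with levels c('true','false')")
    L <- object@geometry@windowLength
    g <- object@geometry@gtOffset
    if (n > 0L) {
        if (any(Biostrings::width(object@sequences) != L))
            return(sprintf("all windows must have width %d", L))
        seqs <- as.character(object@sequences)
        if (any(grepl("[^ACGT]", seqs)))
            return("windows must contain only A/C/G/T")
        if (any(substr(seqs, g, g + 1L) != "GT"))
            return(sprintf("all windows must carry GT at positions %d-%d",
                           g, g + 1L))
    }
    TRUE
})

#' Per-position nucleotide frequency model
#'
#' Position weight matrix estimated from one class of splice-site windows:
#' `prob[b, i]` is the (optionally pseudocount-smoothed) frequency of base
#' b at window position i.  `M` and `N` are the sums over positions of the
#' per-position maximum and minimum frequencies; they normalise the
#' Shapiro-Senapathy-style positional scores.
#'
#' @slot classTag `"true"` or `"false"` - the class the model was fitted on
#' @slot prob 4 x L numeric matrix, rows A/C/G/T, columns positions;
#'   each column sums to 1
#' @slot M,N numeric, sums of per-position maximum / minimum frequencies
#' @slot pseudocount the additive smoothing constant used at count level
#' @slot nTrain number of training windows
#'
#' @seealso [estimatePositional()]
#' @exportClass PositionalFrequencyModel
setClass("PositionalFrequencyModel",
    representation(
        classTag    = "character",
        prob        = "matrix",
        M           = "numeric",
        N           = "numeric",
        pseudocount = "numeric",
        nTrain      = "integer"))

setValidity("PositionalFrequencyModel", function(object) {
    p <- object@prob
    if (!identical(rownames(p), DNA_BASES4))
        return("prob must have rows named A,C,G,T")
    if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-9))
        return("each column of prob must be a probability vector")
    if (object@N > object@M + 1e-12)
        return("N must not exceed M")
    TRUE
})

#' Pairwise conditional nucleotide frequency model
#'
#' Conditional frequencies over all ordered position pairs of a window:
#' `condProb[a, b, i, j]` is the frequency of base a at position i among
#' training windows carrying base b at position j (i != j).  These drive
#' the weight-array and sum-of-absolute-error style dependency scores.
#'
#' @slot classTag `"true"` or `"false"`
#' @slot condProb 4 x 4 x L x L numeric array indexed
#'   `[a, b, i, j]`; the diagonal slices i == j are NA
#' @slot pseudocount additive smoothing constant used at count level
#' @slot nTrain number of training windows
#'
#' @seealso [estimateDependency()]
#' @exportClass DependencyFrequencyModel
setClass("DependencyFrequencyModel",
    representation(
        classTag    = "character",
        condProb    = "array",
        pseudocount = "numeric",
        nTrain      = "integer"))

setValidity("DependencyFrequencyModel", function(object) {
    d <- dim(object@condProb)
    if (length(d) != 4L || d[1] != 4L || d[2] != 4L || d[3] != d[4])
        return("condProb must be a 4 x 4 x L x L array")
    TRUE
})

#' Ordered feature-set manifest
#'
#' Fixes the identity and order of the features a window is encoded into,
#' so that feature matrices are reproducible column-for-column.  Two
#' manifests ship with the package: `full344` (4 positional + 4 dependency
#' + 16 + 64 + 256 k-mer compositions) and `selected49`, the frozen
#' 49-feature subset retained by F-score filtering on the human HS3D
#' benchmark (4 positional + 4 dependency + 14 di- + 15 tri- + 12
#' tetramer compositions).
#'
#' @slot id manifest identifier (`full344`, `selected49` or `custom`)
#' @slot featureNames ordered character vector of unique feature names
#' @slot note free-text provenance note
#'
#' @seealso [featureManifest()]
#' @exportClass FeatureSetManifest
setClass("FeatureSetManifest",
    representation(id = "character", featureNames = "character",
                   note = "character"))

setValidity("FeatureSetManifest", function(object) {
    if (anyDuplicated(object@featureNames))
        return("featureNames must be unique")
    TRUE
})

#' Classifier configuration
#'
#' Bundles the tunable parameters of the splice-site SVM.  Defaults follow
#' the method's published operating point: RBF kernel with gamma = 0.2,
#' cost 1, probability output, z-score feature standardisation fitted on
#' training data, and the frozen 49-feature manifest.
#'
#' @slot kernel SVM kernel (`radial`, `linear`, `polynomial`, `sigmoid`)
#' @slot gamma positive RBF kernel width
#' @slot cost positive soft-margin cost C
#' @slot scaling `"zscore"` (per-feature standardisation fitted on the
#'   training split) or `"none"`
#' @slot featureSet manifest id or a [FeatureSetManifest-class]
#' @slot pseudocount smoothing constant for the frequency models
#' @slot modelScope `"fold"` (frequency models re-estimated inside each
#'   training fold; leakage-safe default) or `"global"` (fitted once on
#'   the full window set before splitting)
#' @slot seed integer seed controlling SVM probability calibration and any
#'   other stochastic step
#'
#' @seealso [svmConfig()], [trainSpliceSVM()], [crossValidate()]
#' @exportClass SvmConfig
setClass("SvmConfig",
    representation(
        kernel      = "character",
        gamma       = "numeric",
        cost        = "numeric",
        scaling     = "character",
        featureSet  = "ANY",
        pseudocount = "numeric",
        modelScope  = "character",
        seed        = "integer"))

setValidity("SvmConfig", function(object) {
    if (object@gamma <= 0) return("gamma must be > 0")
    if (object@cost <= 0) return("cost must be > 0")
    if (!object@scaling %in% c("zscore", "none"))
        return("scaling must be 'zscore' or 'none'")
    if (!object@modelScope %in% c("fold", "global"))
        return("modelScope must be 'fold' or 'global'")
    TRUE
})

#' Trained splice-site SVM
#'
#' Everything needed to score new candidate windows: the fitted SVM, the
#' feature manifest, the four frequency models used for encoding (true and
#' false positional, true and false dependency), and the feature scaling
#' learned from the training data.
#'
#' @slot fit fitted [e1071::svm] object
#' @slot manifest [FeatureSetManifest-class] used for encoding
#' @slot posModels list of `true`/`false` [PositionalFrequencyModel-class]
#' @slot depModels list of `true`/`false` [DependencyFrequencyModel-class]
#' @slot center,scale named numeric vectors of the z-score parameters
#'   (zero-length when scaling = "none")
#' @slot config the [SvmConfig-class] used
#' @slot geometry the [WindowGeometry-class] the model expects
#' @slot nTrain named integer, training windows per class
#'
#' @seealso [trainSpliceSVM()], [predict,SpliceSVMModel-method]
#' @exportClass SpliceSVMModel
setClass("SpliceSVMModel",
    representation(
        fit      = "ANY",
        manifest = "FeatureSetManifest",
        posModels = "list",
        depModels = "list",
        center   = "numeric",
        scale    = "numeric",
        config   = "SvmConfig",
        geometry = "WindowGeometry",
        nTrain   = "integer"))

#' Evaluation design: repeated subsampled sets with stratified folds
#'
#' The repeated cross-validation protocol: `nSets` independent data sets
#' are drawn by seeded subsampling of the pooled windows at an exact
#' true:false ratio, and each set is partitioned into `nFolds`
#' class-stratified folds, each fold serving once as the test partition.
#'
#' @slot windows the pooled labelled [SpliceWindowSet-class]
#' @slot membership list (one element per set) of data.frames with columns
#'   `index` (into `windows`) and `fold`
#' @slot ratio integer vector `c(true, false)` parts
#' @slot nFolds number of folds per set
#' @slot seed the seed the design was built from
#'
#' @seealso [assembleEvalSets()], [splitWindows()], [crossValidate()]
#' @exportClass EvalDesign
setClass("EvalDesign",
    representation(
        windows    = "SpliceWindowSet",
        membership = "list",
        ratio      = "integer",
        nFolds     = "integer",
        seed       = "integer"))

#' Cross-validation result
#'
#' Per-(set, fold) AUC-ROC and AUC-PR together with their arithmetic means
#' over all evaluated folds.
#'
#' @slot perFold data.frame with columns `set`, `fold`, `aucROC`, `aucPR`,
#'   `nTest`, `nPos`
#' @slot summary named numeric: mean `aucROC` and `aucPR` over folds
#' @slot config the [SvmConfig-class] used
#'
#' @seealso [crossValidate()]
#' @exportClass EvalResult
setClass("EvalResult",
    representation(perFold = "data.frame", summary = "numeric",
                   config = "SvmConfig"))
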