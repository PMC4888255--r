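#' Construct a classifier configuration
#'
#' @param kernel SVM kernel, default `"radial"` (RBF)
#' @param gamma RBF kernel width, default 0.2 (the method's published
#'   operating point, at which held-out AUC-ROC stabilises)
#' @param cost soft-margin cost C, default 1
#' @param scaling `"zscore"` (default: per-feature standardisation with
#'   parameters fitted on the training split, so the log-score features
#'   and the `[0, 1]` composition features enter the RBF kernel on a
#'   common scale) or `"none"`
#' @param featureSet manifest id (`"selected49"`/`"full344"`) or a
#'   [FeatureSetManifest-class]
#' @param pseudocount smoothing constant for the frequency models
#' @param modelScope `"fold"` (default, leakage-safe: frequency models
#'   are re-estimated inside every training fold of a cross-validation)
#'   or `"global"` (models fitted once on the pooled windows before
#'   splitting, for comparison)
#' @param seed integer seed for the SVM's internal probability
#'   calibration (and any other stochastic step)
#' @return an [SvmConfig-class]
#' @export
svmConfig <- function(kernel = "radial", gamma = 0.2, cost = 1,
                      scaling = c("zscore", "none"),
                      featureSet = "selected49", pseudocount = 1,
                      modelScope = c("fold", "global"), seed = 1L) {
    new("SvmConfig", kernel = kernel, gamma = as.numeric(gamma),
        cost = as.numeric(cost), scaling = match.arg(scaling),
        featureSet = featureSet, pseudocount = as.numeric(pseudocount),
        modelScope = match.arg(modelScope), seed = as.integer(seed))
}

setMethod("show", "SvmConfig", function(object) {
    fs <- if (is(object@featureSet, "FeatureSetManifest"))
        manifestId(object@featureSet) else object@featureSet
    cat(sprintf(paste0("SvmConfig: kernel=%s gamma=%g cost=%g scaling=%s ",
                       "featureSet=%s pseudocount=%g modelScope=%s seed=%d\n"),
                object@kernel, object@gamma, object@cost, object@scaling,
                fs, object@pseudocount, object@modelScope, object@seed))
})

.resolve_manifest <- function(featureSet) {
    if (is(featureSet, "FeatureSetManifest")) featureSet
    else featureManifest(featureSet)
}

# fit/apply z-score parameters; constant features pass through unscaled
.fit_scaler <- function(mat) {
    ctr <- colMeans(mat)
    scl <- apply(mat, 2L, sd)
    flat <- !is.finite(scl) | scl < 1e-12
    if (any(flat)) {
        warning(sprintf("%d constant feature(s) passed through unscaled: %s",
                        sum(flat),
                        paste(head(colnames(mat)[flat], 5L),
                              collapse = ", ")))
        ctr[flat] <- 0; scl[flat] <- 1
    }
    list(center = ctr, scale = scl)
}

.apply_scaler <- function(mat, center, scale) {
    if (length(center) == 0L) return(mat)
    sweep(sweep(mat, 2L, center, "-"), 2L, scale, "/")
}

#' Train the donor splice-site SVM
#'
#' Fits the full pipeline on a labelled window set: the four frequency
#' models (true/false positional and dependency) are estimated from the
#' training windows, every window is encoded per the configured feature
#' manifest, features are optionally z-scored with training-fitted
#' parameters, and an SVM with probability output is fitted with the
#' configured kernel, gamma and cost.  Deterministic given
#' `config@seed`.
#'
#' @param windows labelled [SpliceWindowSet-class] containing both
#'   classes
#' @param config an [SvmConfig-class] (default [svmConfig()])
#' @return a [SpliceSVMModel-class]
#' @examples
#' w <- generateWindows(nTrue = 60, nFalse = 60, seed = 3)
#' fit <- trainSpliceSVM(w)
#' predict(fit, w[1:2])
#' @export
trainSpliceSVM <- function(windows, config = svmConfig()) {
    lab <- siteLabels(windows)
    if (!all(c("true", "false") %in% lab))
        stop("training requires windows of both classes")
    manifest <- .resolve_manifest(config@featureSet)
    models <- fitFrequencyModels(windows, config@pseudocount)
    feats <- encodeWindows(windows, models, manifest)
    if (config@scaling == "zscore") {
        sc <- .fit_scaler(feats)
        feats <- .apply_scaler(feats, sc$center, sc$scale)
    } else sc <- list(center = numeric(0), scale = numeric(0))
    y <- factor(as.character(lab), levels = c("true", "false"))
    fit <- with_seed(config@seed,
        e1071::svm(feats, y, kernel = config@kernel, gamma = config@gamma,
                   cost = config@cost, probability = TRUE, scale = FALSE))
    new("SpliceSVMModel", fit = fit, manifest = manifest,
        posModels = models[c("posTrue", "posFalse")],
        depModels = models[c("depTrue", "depFalse")],
        center = sc$center, scale = sc$scale, config = config,
        geometry = geometry(windows),
        nTrain = c(true = sum(lab == "true", na.rm = TRUE),
                   false = sum(lab == "false", na.rm = TRUE)))
}

setMethod("show", "SpliceSVMModel", function(object) {
    cat(sprintf(paste0("SpliceSVMModel: %s kernel, gamma=%g, cost=%g, ",
                       "%d feature(s) [%s]\n  trained on %d true + %d ",
                       "false window(s) (%d nt, GT at %d-%d)\n"),
                object@config@kernel, object@config@gamma,
                object@config@cost, length(object@manifest),
                manifestId(object@manifest), object@nTrain["true"],
                object@nTrain["false"], object@geometry@windowLength,
                object@geometry@gtOffset, object@geometry@gtOffset + 1L))
})

#' Score candidate windows with a trained model
#'
#' Encodes the windows with the model's stored frequency models, applies
#' the stored feature scaling and returns the SVM's probability that
#' each window is a true donor site, together with the binary call at
#' the 0.5 threshold.  Output rows follow input order.
#'
#' @param object a [SpliceSVMModel-class]
#' @param newdata a [SpliceWindowSet-class] with the model's geometry
#' @param ... ignored
#' @return data.frame with columns `sourceId`, `sourceCoord`, `window`,
#'   `probability`, `call` (`"true"` when probability > 0.5)
#' @export
setMethod("predict", "SpliceSVMModel", function(object, newdata, ...) {
    stopifnot(is(newdata, "SpliceWindowSet"))
    g <- object@geometry
    gn <- geometry(newdata)
    if (gn@windowLength != g@windowLength || gn@gtOffset != g@gtOffset)
        stop(sprintf(
            "window geometry (%d, %d) does not match the model's (%d, %d)",
            gn@windowLength, gn@gtOffset, g@windowLength, g@gtOffset))
    if (length(newdata) == 0L)
        return(data.frame(sourceId = character(0),
                          sourceCoord = integer(0), window = character(0),
                          probability = numeric(0), call = character(0)))
    models <- c(object@posModels, object@depModels)
    feats <- encodeWindows(newdata, models, object@manifest)
    feats <- .apply_scaler(feats, object@center, object@scale)
    pred <- predict(object@fit, feats, probability = TRUE)
    prob <- attr(pred, "probabilities")[, "true"]
    data.frame(sourceId = sourceIds(newdata),
               sourceCoord = sourceCoords(newdata),
               window = as.character(windowSequences(newdata)),
               probability = as.numeric(prob),
               call = ifelse(prob > 0.5, "true", "false"),
               row.names = NULL)
})

#' Run the repeated cross-validation protocol
#'
#' For every (set, fold) of the design, trains the full pipeline on the
#' four training folds (with `modelScope = "fold"`, the default, the
#' frequency models and the feature scaler are re-fitted from those
#' training windows only, so no information from the test partition
#' leaks into the encoding) and computes AUC-ROC and AUC-PR on the
#' held-out fold.  A 10-set x fivefold design therefore yields 50 metric
#' pairs, whose arithmetic means form the summary.
#'
#' Folds whose test partition contains a single class cannot be scored;
#' they are flagged with a warning, reported with NA metrics and
#' excluded from the means.
#'
#' @param design an [EvalDesign-class] from [assembleEvalSets()]
#' @param config an [SvmConfig-class]
#' @return an [EvalResult-class]
#' @export
crossValidate <- function(design, config = svmConfig()) {
    globalModels <- if (config@modelScope == "global")
        fitFrequencyModels(design@windows, config@pseudocount) else NULL
    manifest <- .resolve_manifest(config@featureSet)
    rows <- list()
    for (s in seq_len(nSets(design))) {
        for (f in seq_len(design@nFolds)) {
            sp <- splitWindows(design, s, f)
            testLab <- as.character(siteLabels(sp$test))
            if (length(unique(testLab)) < 2L) {
                warning(sprintf(
                    "set %d fold %d: single-class test partition, excluded",
                    s, f))
                rows[[length(rows) + 1L]] <- data.frame(
                    set = s, fold = f, aucROC = NA_real_, aucPR = NA_real_,
                    nTest = length(sp$test), nPos = sum(testLab == "true"))
                next
            }
            if (is.null(globalModels)) {
                fit <- trainSpliceSVM(sp$train, config)
                pr <- predict(fit, sp$test)$probability
            } else {
                # global scope: frequency models (and scaler inputs) come
                # from the pooled windows; only the SVM is fold-specific
                trFeats <- encodeWindows(sp$train, globalModels, manifest)
                teFeats <- encodeWindows(sp$test, globalModels, manifest)
                if (config@scaling == "zscore") {
                    sc <- .fit_scaler(trFeats)
                    trFeats <- .apply_scaler(trFeats, sc$center, sc$scale)
                    teFeats <- .apply_scaler(teFeats, sc$center, sc$scale)
                }
                y <- factor(as.character(siteLabels(sp$train)),
                            levels = c("true", "false"))
                fit <- with_seed(config@seed,
                    e1071::svm(trFeats, y, kernel = config@kernel,
                               gamma = config@gamma, cost = config@cost,
                               probability = TRUE, scale = FALSE))
                pred <- predict(fit, teFeats, probability = TRUE)
                pr <- attr(pred, "probabilities")[, "true"]
            }
            rows[[length(rows) + 1L]] <- data.frame(
                set = s, fold = f,
                aucROC = aucROC(pr, testLab), aucPR = aucPR(pr, testLab),
                nTest = length(sp$test), nPos = sum(testLab == "true"))
        }
    }
    perFold <- do.call(rbind, rows)
    new("EvalResult", perFold = perFold,
        summary = c(aucROC = mean(perFold$aucROC, na.rm = TRUE),
                    aucPR = mean(perFold$aucPR, na.rm = TRUE)),
        config = config)
}

#' @rdname EvalResult
#' @param x an `EvalResult`
#' @return `perFold` returns the per-(set, fold) metric data.frame
#' @export
setMethod("perFold", "EvalResult", function(x) x@perFold)

setMethod("show", "EvalResult", function(object) {
    ok <- !is.na(object@perFold$aucROC)
    cat(sprintf(paste0("EvalResult over %d fold evaluation(s)",
                       "%s\n  mean AUC-ROC = %.4f, mean AUC-PR = %.4f\n"),
                nrow(object@perFold),
                if (all(ok)) "" else sprintf(" (%d excluded)", sum(!ok)),
                object@summary["aucROC"], object@summary["aucPR"]))
})

#' Write a cross-validation result as a delimited table
#'
#' One row per (set, fold) plus a `summary` row holding the means.
#'
#' @param result an [EvalResult-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeEvalResult <- function(result, path) {
    pf <- perFold(result)
    pf$set <- as.character(pf$set); pf$fold <- as.character(pf$fold)
    pf <- rbind(pf, data.frame(set = "summary", fold = "mean",
                               aucROC = result@summary["aucROC"],
                               aucPR = result@summary["aucPR"],
                               nTest = NA, nPos = NA))
    write.table(pf, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Save / load a trained model archive
#'
#' Serialises the complete [SpliceSVMModel-class] (frequency models,
#' manifest, scaler, SVM state and configuration) to a single file;
#' reloading yields identical predictions.
#'
#' @param model a [SpliceSVMModel-class]
#' @param path archive file path
#' @return `saveModel` returns `path` invisibly; `loadModel` the model
#' @export
saveModel <- function(model, path) {
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    model <- readRDS(path)
    if (!is(model, "SpliceSVMModel"))
        stop(sprintf("'%s' does not contain a SpliceSVMModel", path))
    model
}
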