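.check_model_input <- function(windows) {
    if (!is(windows, "SpliceWindowSet") || length(windows) == 0L)
        stop("need a non-empty SpliceWindowSet")
    lab <- unique(as.character(siteLabels(windows)))
    lab <- lab[!is.na(lab)]
    if (length(lab) > 1L)
        stop("training windows must all belong to one class")
    if (length(lab) == 0L) lab <- NA_character_
    lab
}

#' Estimate the per-position nucleotide frequency model
#'
#' Counts nucleotides per window position over one class of training
#' windows and converts them to (optionally smoothed) frequencies:
#' `p(base at i) = (count + pseudocount) / (n + 4 * pseudocount)`.
#' The extremal sums M (sum over positions of the highest per-position
#' frequency) and N (sum of the lowest) are computed from the smoothed
#' matrix; they normalise the Shapiro-Senapathy-style scores.
#'
#' The default pseudocount of 1 keeps all downstream log2 scores finite;
#' with `pseudocount = 0` the model is the raw relative-frequency matrix.
#'
#' @param windows single-class [SpliceWindowSet-class]
#' @param pseudocount nonnegative additive smoothing constant (default 1)
#' @param classTag override for the stored class tag (defaults to the
#'   windows' label)
#' @return a [PositionalFrequencyModel-class]
#' @examples
#' w <- SpliceWindowSet(c("AAAAAAAAGTAAAAA", "CCCCCCCCGTCCCCC"),
#'                      label = "true")
#' m <- estimatePositional(w, pseudocount = 0)
#' positionalProbs(m)["G", 9]   # 1: GT is conserved
#' @export
estimatePositional <- function(windows, pseudocount = 1, classTag = NULL) {
    lab <- .check_model_input(windows)
    if (pseudocount < 0) stop("pseudocount must be nonnegative")
    if (is.null(classTag)) classTag <- lab
    m <- .window_int_matrix(windows)
    n <- nrow(m); L <- ncol(m)
    counts <- vapply(seq_len(L), function(i) tabulate(m[, i], 4L),
                     integer(4L))
    p <- (counts + pseudocount) / (n + 4 * pseudocount)
    dimnames(p) <- list(DNA_BASES4, NULL)
    new("PositionalFrequencyModel", classTag = as.character(classTag),
        prob = p,
        M = sum(apply(p, 2L, max)), N = sum(apply(p, 2L, min)),
        pseudocount = as.numeric(pseudocount), nTrain = n)
}

#' Estimate the pairwise conditional frequency model
#'
#' For every ordered position pair (i, j), i != j, estimates the
#' conditional frequency of each base at i given each base at j:
#' `q(a at i | b at j) = (count(a at i, b at j) + pseudocount) /
#' (count(b at j) + 4 * pseudocount)`.  When a conditioning base was
#' never observed at j and the pseudocount is 0, the conditional is
#' defined as the uniform 1/4 (the maximum-entropy convention, which
#' keeps downstream log scores finite).
#'
#' @inheritParams estimatePositional
#' @return a [DependencyFrequencyModel-class]
#' @examples
#' w <- SpliceWindowSet(c("AAAAAAAAGTAAAAA", "ACAAAAAAGTAAAAA"),
#'                      label = "true")
#' d <- estimateDependency(w, pseudocount = 0)
#' conditionalProbs(d)["C", "A", 2, 1]   # P(C at 2 | A at 1) = 0.5
#' @export
estimateDependency <- function(windows, pseudocount = 1, classTag = NULL) {
    lab <- .check_model_input(windows)
    if (pseudocount < 0) stop("pseudocount must be nonnegative")
    if (is.null(classTag)) classTag <- lab
    m <- .window_int_matrix(windows)
    n <- nrow(m); L <- ncol(m)
    q <- array(NA_real_, dim = c(4L, 4L, L, L),
               dimnames = list(DNA_BASES4, DNA_BASES4, NULL, NULL))
    for (j in seq_len(L)) {
        countB <- tabulate(m[, j], 4L)
        for (i in seq_len(L)) {
            if (i == j) next
            joint <- matrix(tabulate(m[, i] + 4L * (m[, j] - 1L), 16L),
                            4L, 4L)
            denom <- countB + 4 * pseudocount
            qq <- sweep(joint + pseudocount, 2L, denom, "/")
            if (pseudocount == 0 && any(countB == 0L))
                qq[, countB == 0L] <- 0.25
            q[, , i, j] <- qq
        }
    }
    new("DependencyFrequencyModel", classTag = as.character(classTag),
        condProb = q, pseudocount = as.numeric(pseudocount), nTrain = n)
}

#' @rdname PositionalFrequencyModel
#' @param x a `PositionalFrequencyModel`
#' @return `positionalProbs` returns the 4 x L frequency matrix;
#'   `extremalSums` the named vector `c(M =, N =)`
#' @export
positionalProbs <- function(x) x@prob

#' @rdname PositionalFrequencyModel
#' @export
extremalSums <- function(x) c(M = x@M, N = x@N)

#' @rdname DependencyFrequencyModel
#' @param x a `DependencyFrequencyModel`
#' @return `conditionalProbs` returns the 4 x 4 x L x L array
#'   `[a, b, i, j] = P(a at i | b at j)`
#' @export
conditionalProbs <- function(x) x@condProb

setMethod("show", "PositionalFrequencyModel", function(object) {
    cat(sprintf(paste0("PositionalFrequencyModel (%s class): L = %d, ",
                       "n = %d, pseudocount = %g\n  M = %.4f, N = %.4f\n"),
                object@classTag, ncol(object@prob), object@nTrain,
                object@pseudocount, object@M, object@N))
})

setMethod("show", "DependencyFrequencyModel", function(object) {
    L <- dim(object@condProb)[3]
    cat(sprintf(paste0("DependencyFrequencyModel (%s class): L = %d ",
                       "(%d ordered pairs), n = %d, pseudocount = %g\n"),
                object@classTag, L, L * (L - 1L), object@nTrain,
                object@pseudocount))
})

.fmt_num <- function(x) sprintf("%.17g", x)

#' Serialise a frequency model to a plain-text table
#'
#' Positional models are written as a position x A/C/G/T table,
#' dependency models as one row per (i, j, conditioning base) holding the
#' four conditional frequencies; a `#`-prefixed header records class tag,
#' length, pseudocount and training size.  Values are written with 17
#' significant digits, so [readFrequencyModel()] round-trips exactly.
#'
#' @param model a [PositionalFrequencyModel-class] or
#'   [DependencyFrequencyModel-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFrequencyModel <- function(model, path) {
    con <- file(path, "w"); on.exit(close(con))
    if (is(model, "PositionalFrequencyModel")) {
        L <- ncol(model@prob)
        writeLines(c("# spliceSVM frequency model",
                     "# type: positional",
                     sprintf("# classTag: %s", model@classTag),
                     sprintf("# L: %d", L),
                     sprintf("# pseudocount: %s", .fmt_num(model@pseudocount)),
                     sprintf("# nTrain: %d", model@nTrain),
                     paste(c("position", DNA_BASES4), collapse = "\t")), con)
        for (i in seq_len(L))
            writeLines(paste(c(i, .fmt_num(model@prob[, i])),
                             collapse = "\t"), con)
    } else if (is(model, "DependencyFrequencyModel")) {
        L <- dim(model@condProb)[3]
        writeLines(c("# spliceSVM frequency model",
                     "# type: dependency",
                     sprintf("# classTag: %s", model@classTag),
                     sprintf("# L: %d", L),
                     sprintf("# pseudocount: %s", .fmt_num(model@pseudocount)),
                     sprintf("# nTrain: %d", model@nTrain),
                     paste(c("i", "j", "given", DNA_BASES4),
                           collapse = "\t")), con)
        for (j in seq_len(L)) for (i in seq_len(L)) {
            if (i == j) next
            for (b in seq_len(4L))
                writeLines(paste(c(i, j, DNA_BASES4[b],
                                   .fmt_num(model@condProb[, b, i, j])),
                                 collapse = "\t"), con)
        }
    } else stop("not a frequency model")
    invisible(path)
}

#' Read a frequency model written by [writeFrequencyModel()]
#'
#' @param path input file
#' @return the deserialised model, identical to the one written
#' @export
readFrequencyModel <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    getv <- function(key) sub(sprintf("^# %s: ", key), "",
                              grep(sprintf("^# %s:", key), hdr, value = TRUE))
    type <- getv("type")
    L <- as.integer(getv("L"))
    pc <- as.numeric(getv("pseudocount"))
    nTrain <- as.integer(getv("nTrain"))
    classTag <- getv("classTag")
    body <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
    if (type == "positional") {
        p <- t(as.matrix(body[, DNA_BASES4]))
        dimnames(p) <- list(DNA_BASES4, NULL)
        new("PositionalFrequencyModel", classTag = classTag, prob = p,
            M = sum(apply(p, 2L, max)), N = sum(apply(p, 2L, min)),
            pseudocount = pc, nTrain = nTrain)
    } else {
        q <- array(NA_real_, dim = c(4L, 4L, L, L),
                   dimnames = list(DNA_BASES4, DNA_BASES4, NULL, NULL))
        bidx <- match(body$given, DNA_BASES4)
        vals <- as.matrix(body[, DNA_BASES4])
        for (r in seq_len(nrow(body)))
            q[, bidx[r], body$i[r], body$j[r]] <- vals[r, ]
        new("DependencyFrequencyModel", classTag = classTag, condProb = q,
            pseudocount = pc, nTrain = nTrain)
    }
}
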