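#' Construct a window geometry
#'
#' @param windowLength window length in nucleotides (default 15)
#' @param gtOffset 1-based position of the conserved G of the GT dimer
#'   (default 9, so the dimer occupies positions 9-10)
#' @return a [WindowGeometry-class]
#' @examples
#' WindowGeometry()          # 15 nt, GT at 9-10
#' WindowGeometry(38, 9)     # UCSC-derived 38 nt windows
#' @export
WindowGeometry <- function(windowLength = 15L, gtOffset = 9L) {
    new("WindowGeometry",
        windowLength = as.integer(windowLength),
        gtOffset = as.integer(gtOffset))
}

setMethod("show", "WindowGeometry", function(object) {
    cat(sprintf("WindowGeometry: %d nt, conserved GT at positions %d-%d\n",
                object@windowLength, object@gtOffset, object@gtOffset + 1L))
})

.as_label_factor <- function(label, n) {
    if (is.null(label)) label <- rep(NA_character_, n)
    if (length(label) == 1L && n != 1L) label <- rep(label, n)
    factor(as.character(label), levels = c("true", "false"))
}

.empty_rejections <- function() {
    data.frame(id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
}

#' Construct a set of splice-site windows
#'
#' @param sequences a [Biostrings::DNAStringSet] or character vector of
#'   equal-length windows over A/C/G/T carrying GT at the geometry offset
#' @param geometry a [WindowGeometry-class]
#' @param label optional class labels (`"true"`, `"false"` or NA),
#'   recycled if of length one
#' @param sourceId optional per-window source identifiers (defaults to
#'   sequence names, then `window_<i>`)
#' @param sourceCoord optional 1-based inclusive start coordinates of each
#'   window on its source sequence
#' @param rejections a data.frame of rejected records (`id`, `reason`);
#'   loaders fill this so rejected input is visible, never silently lost
#' @return a [SpliceWindowSet-class]
#' @examples
#' SpliceWindowSet(c("AAAAAAAAGTAAAAA", "CCCCCCCCGTCCCCC"),
#'                 label = c("true", "false"))
#' @export
SpliceWindowSet <- function(sequences, geometry = WindowGeometry(),
                            label = NULL, sourceId = NULL,
                            sourceCoord = NULL, rejections = NULL) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(sequences)
    n <- length(sequences)
    if (is.null(sourceId)) {
        sourceId <- names(sequences)
        if (is.null(sourceId)) sourceId <- sprintf("window_%d", seq_len(n))
    }
    if (is.null(sourceCoord)) sourceCoord <- rep(NA_integer_, n)
    if (is.null(rejections)) rejections <- .empty_rejections()
    new("SpliceWindowSet",
        sequences = sequences,
        label = .as_label_factor(label, n),
        sourceId = as.character(sourceId),
        sourceCoord = as.integer(sourceCoord),
        geometry = geometry,
        rejections = rejections)
}

#' @rdname SpliceWindowSet
#' @export
setMethod("windowSequences", "SpliceWindowSet", function(x) x@sequences)

#' @rdname SpliceWindowSet
#' @export
setMethod("siteLabels", "SpliceWindowSet", function(x) x@label)

#' @rdname SpliceWindowSet
#' @export
setMethod("sourceIds", "SpliceWindowSet", function(x) x@sourceId)

#' @rdname SpliceWindowSet
#' @export
setMethod("sourceCoords", "SpliceWindowSet", function(x) x@sourceCoord)

#' @rdname SpliceWindowSet
#' @export
setMethod("geometry", "SpliceWindowSet", function(x) x@geometry)

#' @rdname SpliceWindowSet
#' @export
setMethod("rejections", "SpliceWindowSet", function(x) x@rejections)

#' @rdname SpliceWindowSet
#' @export
setMethod("length", "SpliceWindowSet", function(x) length(x@sequences))

#' @rdname SpliceWindowSet
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "SpliceWindowSet", function(x, i, j, ..., drop = FALSE) {
    new("SpliceWindowSet",
        sequences = x@sequences[i],
        label = x@label[i],
        sourceId = x@sourceId[i],
        sourceCoord = x@sourceCoord[i],
        geometry = x@geometry,
        rejections = x@rejections)
})

setMethod("show", "SpliceWindowSet", function(object) {
    n <- length(object)
    tab <- table(object@label, useNA = "ifany")
    cat(sprintf("SpliceWindowSet of %d window(s) (%d nt, GT at %d-%d)\n",
                n, object@geometry@windowLength, object@geometry@gtOffset,
                object@geometry@gtOffset + 1L))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
    if (nrow(object@rejections) > 0L)
        cat(sprintf("  %d rejected record(s); see rejections()\n",
                    nrow(object@rejections)))
    if (n > 0L) {
        k <- head(seq_len(n), 3L)
        for (i in k)
            cat(sprintf("  %s %s\n", as.character(object@sequences[[i]]),
                        object@sourceId[i]))
        if (n > 3L) cat("  ...\n")
    }
})

#' Combine splice-window sets sharing a geometry
#'
#' @param x,... `SpliceWindowSet` objects with identical geometry
#' @return a single concatenated [SpliceWindowSet-class]
#' @export
setMethod("c", "SpliceWindowSet", function(x, ...) {
    others <- list(...)
    for (y in others) {
        stopifnot(is(y, "SpliceWindowSet"))
        if (!identical(y@geometry@windowLength, x@geometry@windowLength) ||
            !identical(y@geometry@gtOffset, x@geometry@gtOffset))
            stop("cannot combine SpliceWindowSets with different geometries")
    }
    all <- c(list(x), others)
    new("SpliceWindowSet",
        sequences = do.call(c, lapply(all, slot, "sequences")),
        label = factor(unlist(lapply(all, function(w)
            as.character(w@label))), levels = c("true", "false")),
        sourceId = unlist(lapply(all, slot, "sourceId")),
        sourceCoord = unlist(lapply(all, slot, "sourceCoord")),
        geometry = x@geometry,
        rejections = do.call(rbind, lapply(all, slot, "rejections")))
})

# integer (1..4) matrix view of the windows, n x L; the workhorse layout
# for frequency-model fitting and feature lookup
.window_int_matrix <- function(x) {
    seqs <- as.character(windowSequences(x))
    L <- geometry(x)@windowLength
    m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      DNA_BASES4),
                nrow = length(seqs), ncol = L, byrow = TRUE)
    m
}
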