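.default_consensus <- function(geometry) {
    L <- geometry@windowLength
    g <- geometry@gtOffset
    # canonical donor context: exon ends ...CAG, intron starts GTAAGT
    exon <- paste(rep("A", g - 1L), collapse = "")
    if (g - 1L >= 3L)
        substr(exon, g - 3L, g - 1L) <- "CAG"
    intron <- paste(rep("A", L - g - 1L), collapse = "")
    if (nchar(intron) > 0L) {
        fill <- substr("AAGT", 1L, nchar(intron))
        substr(intron, 1L, nchar(fill)) <- fill
    }
    paste0(exon, "GT", intron)
}

#' Generate labelled synthetic donor-site windows
#'
#' Draws windows of the given geometry with a controllable signal
#' strength, so the full pipeline can be exercised and calibrated
#' without external data.  True sites are drawn position-independently
#' from a position weight matrix: at every non-GT position the consensus
#' nucleotide appears with probability `conservation` and the remaining
#' mass is split over the other three bases in proportion to
#' `background`; the conserved GT is forced at the geometry's offset.
#' False sites are drawn from `background` alone, again with GT forced
#' (they emulate the non-functional GT dimers a scanner encounters).  At
#' `conservation = 0.25` with uniform background the two classes are
#' distributionally identical - the null case.
#'
#' The default consensus embeds the canonical donor context (exon ends
#' `...CAG`, intron starts `GTAAGT`) at the geometry's offsets.
#'
#' Optionally, `dependentPair = c(i, j)` plants a pairwise dependency in
#' the true class: with probability `dependencyStrength` the base drawn
#' at position i is copied to position j.  This gives the pairwise
#' dependency scores signal beyond what the positional models capture.
#'
#' @param nTrue,nFalse number of true / false windows
#' @param geometry a [WindowGeometry-class]
#' @param conservation probability mass on the consensus nucleotide at
#'   each non-GT position of the true-site PWM, in `[0.25, 1]`
#'   (default 0.85, a strongly conserved donor motif)
#' @param consensus optional explicit consensus window (must carry GT at
#'   the geometry offset)
#' @param background nucleotide distribution (length-4, A/C/G/T order)
#'   for false sites and for the non-consensus mass; default uniform
#' @param seed integer seed; output is deterministic given the seed
#' @param dependentPair optional pair of non-GT positions `c(i, j)`
#' @param dependencyStrength copy probability for the planted pair
#' @return a labelled [SpliceWindowSet-class] with `nTrue + nFalse`
#'   windows (true first)
#' @examples
#' w <- generateWindows(nTrue = 5, nFalse = 5, conservation = 1, seed = 1)
#' unique(as.character(windowSequences(w)[siteLabels(w) == "true"]))
#' @export
generateWindows <- function(nTrue, nFalse, geometry = WindowGeometry(),
                            conservation = 0.85, consensus = NULL,
                            background = rep(0.25, 4), seed = 1L,
                            dependentPair = NULL,
                            dependencyStrength = 0.9) {
    if (conservation < 0.25 || conservation > 1)
        stop("conservation must lie in [0.25, 1]")
    if (length(background) != 4L || any(background < 0) ||
        sum(background) <= 0)
        stop("background must be 4 nonnegative weights")
    background <- background / sum(background)
    L <- geometry@windowLength
    g <- geometry@gtOffset
    if (is.null(consensus)) consensus <- .default_consensus(geometry)
    consensus <- toupper(consensus)
    if (nchar(consensus) != L || substr(consensus, g, g + 1L) != "GT" ||
        grepl("[^ACGT]", consensus))
        stop("consensus must be an ACGT window with GT at the geometry offset")
    consIdx <- match(strsplit(consensus, "")[[1]], DNA_BASES4)
    if (!is.null(dependentPair)) {
        dependentPair <- as.integer(dependentPair)
        if (length(dependentPair) != 2L ||
            any(dependentPair %in% c(g, g + 1L)) ||
            any(dependentPair < 1L | dependentPair > L))
            stop("dependentPair must be two non-GT positions")
    }

    draw <- with_seed(seed, {
        tmat <- matrix(0L, nTrue, L)
        fmat <- matrix(0L, nFalse, L)
        for (i in seq_len(L)) {
            if (i == g) { tmat[, i] <- 3L; fmat[, i] <- 3L; next }
            if (i == g + 1L) { tmat[, i] <- 4L; fmat[, i] <- 4L; next }
            others <- background
            others[consIdx[i]] <- 0
            probs <- if (sum(others) > 0)
                (1 - conservation) * others / sum(others)
            else rep(0, 4)
            probs[consIdx[i]] <- 1 - sum(probs)
            if (nTrue > 0L)
                tmat[, i] <- sample.int(4L, nTrue, replace = TRUE,
                                        prob = probs)
            if (nFalse > 0L)
                fmat[, i] <- sample.int(4L, nFalse, replace = TRUE,
                                        prob = background)
        }
        if (!is.null(dependentPair) && nTrue > 0L) {
            copy <- runif(nTrue) < dependencyStrength
            tmat[copy, dependentPair[2L]] <- tmat[copy, dependentPair[1L]]
        }
        list(t = tmat, f = fmat)
    })
    to_seq <- function(m) apply(m, 1L, function(r)
        paste(DNA_BASES4[r], collapse = ""))
    seqs <- c(if (nTrue > 0L) to_seq(draw$t), if (nFalse > 0L) to_seq(draw$f))
    SpliceWindowSet(seqs, geometry = geometry,
                    label = rep(c("true", "false"), c(nTrue, nFalse)),
                    sourceId = c(sprintf("true_%04d", seq_len(nTrue)),
                                 sprintf("false_%04d", seq_len(nFalse))))
}

#' Generate balanced/imbalanced evaluation files on disk
#'
#' Writes, for each requested true:false ratio, a FASTA file of labelled
#' windows (labels and coordinates in the headers, readable back with
#' [readWindows()]) and a tab-separated label manifest.  Mirrors the
#' balanced (1:1) and imbalanced (1:5, 1:19) evaluation designs.
#'
#' @param dir output directory (created if needed)
#' @param ratios list of length-2 integer vectors, e.g.
#'   `list(c(1, 1), c(1, 5), c(1, 19))`
#' @param nTrue number of true windows per ratio (false count is
#'   `nTrue / ratio[1] * ratio[2]`)
#' @param geometry,conservation,consensus,background passed to
#'   [generateWindows()]
#' @param seed integer seed; file contents are reproducible given the
#'   seed (each ratio uses an offset sub-seed)
#' @return data.frame with columns `ratio`, `fasta`, `manifest`,
#'   `nTrue`, `nFalse`
#' @export
generateEvalSuite <- function(dir,
                              ratios = list(c(1L, 1L), c(1L, 5L),
                                            c(1L, 19L)),
                              nTrue = 500L,
                              geometry = WindowGeometry(),
                              conservation = 0.85, consensus = NULL,
                              background = rep(0.25, 4), seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(seq_along(ratios), function(k) {
        r <- as.integer(ratios[[k]])
        if (length(r) != 2L || any(r < 1L))
            stop("each ratio must be two positive integers")
        nT <- as.integer(nTrue)
        if (nT %% r[1] != 0L)
            stop(sprintf("nTrue = %d is not a multiple of ratio part %d",
                         nT, r[1]))
        nF <- nT %/% r[1] * r[2]
        w <- generateWindows(nT, nF, geometry = geometry,
                             conservation = conservation,
                             consensus = consensus,
                             background = background,
                             seed = seed + k - 1L)
        tag <- sprintf("%dto%d", r[1], r[2])
        fasta <- file.path(dir, sprintf("windows_%s.fasta", tag))
        manifest <- file.path(dir, sprintf("labels_%s.tsv", tag))
        writeWindowsFasta(w, fasta)
        write.table(data.frame(windowId = sourceIds(w),
                               label = as.character(siteLabels(w))),
                    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
        data.frame(ratio = tag, fasta = fasta, manifest = manifest,
                   nTrue = nT, nFalse = nF, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
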