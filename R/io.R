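.IUPAC_RE <- "[^ACGTRYSWKMBDHVN]"

# profile -> where the conserved G sits in the *record* (NA = use the
# geometry's own offset, i.e. records are already window-sized)
.PROFILES <- list(
    fasta = list(recordGt = NA_integer_, recordLen = NA_integer_),
    plain = list(recordGt = NA_integer_, recordLen = NA_integer_),
    hs3d  = list(recordGt = 71L, recordLen = 140L),
    nn269 = list(recordGt = 9L,  recordLen = 15L),
    ucsc  = list(recordGt = 9L,  recordLen = 38L))

.read_plain_records <- function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    lines <- toupper(trimws(lines))[keep]
    bad <- grep(.IUPAC_RE, lines)
    if (length(bad) > 0L)
        stop(sprintf("parse error in '%s': line %d contains non-nucleotide characters",
                     path, which(keep)[bad[1]]))
    names(lines) <- sprintf("record_%d", seq_along(lines))
    lines
}

.read_fasta_records <- function(path) {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
        error = function(e)
            stop(sprintf("parse error in FASTA '%s': %s", path,
                         conditionMessage(e)), call. = FALSE))
    recs <- toupper(as.character(set))
    if (is.null(names(recs)) || any(!nzchar(names(recs))))
        names(recs) <- sprintf("record_%d", seq_along(recs))
    recs
}

# parse ">id|start|label" headers written by writeWindowsFasta()
.parse_headers <- function(ids) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    has3 <- vapply(parts, length, 1L) == 3L
    lab <- rep(NA_character_, length(ids))
    coord <- rep(NA_integer_, length(ids))
    id <- ids
    if (any(has3)) {
        id[has3] <- vapply(parts[has3], `[`, "", 1L)
        coord[has3] <- suppressWarnings(
            as.integer(vapply(parts[has3], `[`, "", 2L)))
        lab3 <- vapply(parts[has3], `[`, "", 3L)
        lab[has3] <- ifelse(lab3 %in% c("true", "false"), lab3, NA)
    }
    list(id = id, coord = coord, label = lab)
}

#' Read labelled or unlabelled splice-site windows from a file
#'
#' Reads windows from FASTA or one-sequence-per-line files, cutting the
#' window of `geometry@windowLength` so that the record's conserved G
#' lands at `geometry@gtOffset`.  Format profiles declare where the
#' conserved dimer sits in the *record*: `hs3d` expects 140 nt records
#' with GT at 71-72, `nn269` 15 nt records with GT at 9-10, `ucsc` 38 nt
#' records with GT at 9-10; `fasta` and `plain` expect records already
#' carrying GT at the geometry's own offset.  With the default (15, 9)
#' geometry an `hs3d` record therefore yields its subsequence 63..77.
#'
#' Records violating the GT invariant, too short to contain the window,
#' or containing ambiguity codes inside the window are rejected with a
#' reason and reported via [rejections()]; they are never silently
#' dropped.  Characters outside the IUPAC nucleotide alphabet abort with
#' a parse error naming the offending record.
#'
#' FASTA headers of the form `id|start|label` (as written by
#' [writeWindowsFasta()]) are parsed back into source ids, coordinates
#' and labels; otherwise `label` applies to all records.
#'
#' @param path input file
#' @param geometry target [WindowGeometry-class]
#' @param profile one of `"fasta"`, `"plain"`, `"hs3d"`, `"nn269"`,
#'   `"ucsc"`
#' @param label optional class label (`"true"`/`"false"`) applied to all
#'   records that do not carry one in their header
#' @return a [SpliceWindowSet-class]; rejected records are listed in
#'   `rejections(x)`
#' @seealso [scanCandidates()] to enumerate GT candidates in raw FASTA
#' @export
readWindows <- function(path, geometry = WindowGeometry(),
                        profile = c("fasta", "plain", "hs3d", "nn269",
                                    "ucsc"),
                        label = NULL) {
    profile <- match.arg(profile)
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path))
    prof <- .PROFILES[[profile]]

    is_fasta <- if (profile == "fasta") TRUE
        else if (profile == "plain") FALSE
        else startsWith(readLines(path, n = 1L), ">")
    recs <- if (is_fasta) .read_fasta_records(path)
            else .read_plain_records(path)

    hdr <- .parse_headers(names(recs))
    labels <- hdr$label
    if (!is.null(label)) labels[is.na(labels)] <- label

    L <- geometry@windowLength
    g <- geometry@gtOffset
    recordGt <- if (is.na(prof$recordGt)) g else prof$recordGt
    start <- recordGt - g + 1L
    end <- start + L - 1L

    keep <- logical(length(recs))
    reasons <- character(length(recs))
    windows <- character(length(recs))
    for (k in seq_along(recs)) {
        s <- recs[[k]]
        if (start < 1L || nchar(s) < end) {
            reasons[k] <- sprintf(
                "record too short (%d nt) to contain window %d..%d",
                nchar(s), start, end)
            next
        }
        w <- substr(s, start, end)
        if (substr(w, g, g + 1L) != "GT") {
            reasons[k] <- sprintf("no GT at window positions %d-%d (found '%s')",
                                  g, g + 1L, substr(w, g, g + 1L))
            next
        }
        if (grepl("[^ACGT]", w)) {
            reasons[k] <- "non-ACGT character inside window"
            next
        }
        keep[k] <- TRUE
        windows[k] <- w
    }

    rej <- data.frame(id = hdr$id[!keep], reason = reasons[!keep],
                      stringsAsFactors = FALSE)
    if (nrow(rej) > 0L)
        .msg("readWindows: rejected %d of %d record(s); see rejections()",
             nrow(rej), length(recs))

    coord <- hdr$coord[keep]
    coord[is.na(coord)] <- start
    SpliceWindowSet(windows[keep], geometry = geometry,
                    label = labels[keep], sourceId = hdr$id[keep],
                    sourceCoord = coord, rejections = rej)
}

#' Scan FASTA sequences for candidate donor-site windows
#'
#' Enumerates every occurrence of the dimer GT on the forward strand that
#' has at least `gtOffset - 1` nucleotides upstream of the G and
#' `windowLength - gtOffset - 1` downstream of the T, and extracts the
#' corresponding window.  Windows overlapping a non-ACGT character are
#' skipped and reported via [rejections()].  Output is ordered by record
#' and then by coordinate; `sourceCoord` holds the 1-based inclusive
#' window start, so `substr(record, start, start + L - 1)` reproduces the
#' window exactly.
#'
#' With `reverseStrand = TRUE` the reverse complement of each record is
#' scanned as well; those windows carry `sourceId` suffixed with `/rc`
#' and coordinates in the reverse-complement frame.
#'
#' @param x path to a FASTA file, or a [Biostrings::DNAStringSet]
#' @param geometry target [WindowGeometry-class]
#' @param reverseStrand also scan the reverse complement (default FALSE)
#' @return a [SpliceWindowSet-class] of unlabelled candidate windows
#' @examples
#' fa <- Biostrings::DNAStringSet(c(chr = "AAAAAAAAGTAAAAAAAAA"))
#' scanCandidates(fa)
#' @export
scanCandidates <- function(x, geometry = WindowGeometry(),
                           reverseStrand = FALSE) {
    if (is.character(x)) {
        recs <- Biostrings::DNAStringSet(.read_fasta_records(x))
    } else {
        recs <- x
        if (is.null(names(recs)))
            names(recs) <- sprintf("record_%d", seq_along(recs))
    }
    if (reverseStrand) {
        rc <- Biostrings::reverseComplement(recs)
        names(rc) <- paste0(names(recs), "/rc")
        recs <- c(recs, rc)
    }
    L <- geometry@windowLength
    g <- geometry@gtOffset

    out_seq <- character(0); out_id <- character(0); out_coord <- integer(0)
    rej <- .empty_rejections()
    if (length(recs) > 0L) {
        hits <- Biostrings::vmatchPattern("GT", recs, fixed = TRUE)
        for (k in seq_along(recs)) {
            s <- toupper(as.character(recs[[k]]))
            gpos <- BiocGenerics::start(hits[[k]])
            starts <- gpos - g + 1L
            ok <- starts >= 1L & (starts + L - 1L) <= nchar(s)
            starts <- starts[ok]
            if (length(starts) == 0L) next
            w <- substring(s, starts, starts + L - 1L)
            clean <- !grepl("[^ACGT]", w)
            if (any(!clean)) {
                rej <- rbind(rej, data.frame(
                    id = sprintf("%s:%d", names(recs)[k], starts[!clean]),
                    reason = "window overlaps a non-ACGT character",
                    stringsAsFactors = FALSE))
            }
            out_seq <- c(out_seq, w[clean])
            out_id <- c(out_id, rep(names(recs)[k], sum(clean)))
            out_coord <- c(out_coord, starts[clean])
        }
    }
    if (nrow(rej) > 0L)
        .msg("scanCandidates: skipped %d window(s) overlapping ambiguity codes",
             nrow(rej))
    SpliceWindowSet(Biostrings::DNAStringSet(out_seq), geometry = geometry,
                    sourceId = out_id, sourceCoord = out_coord,
                    rejections = rej)
}

#' Write a window set as FASTA with `id|start|label` headers
#'
#' The serialisation round-trips through [readWindows()] with
#' `profile = "fasta"`: labels and coordinates are restored from the
#' headers.
#'
#' @param x a [SpliceWindowSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeWindowsFasta <- function(x, path) {
    seqs <- windowSequences(x)
    names(seqs) <- sprintf("%s|%s|%s", sourceIds(x),
                           ifelse(is.na(sourceCoords(x)), "NA",
                                  sourceCoords(x)),
                           ifelse(is.na(siteLabels(x)), "NA",
                                  as.character(siteLabels(x))))
    Biostrings::writeXStringSet(seqs, path, width = 80L)
    invisible(path)
}
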