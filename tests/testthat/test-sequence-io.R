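test_that("long-record profiles cut the window so the GT lands at the offset", {
    # 140 nt record with G,T at 71,72: the (15, 9) window must be
    # positions 63..77 of the record
    rec <- paste(rep("A", 140), collapse = "")
    substr(rec, 71, 72) <- "GT"
    substr(rec, 63, 63) <- "C"   # marker at expected window start
    substr(rec, 77, 77) <- "C"   # marker at expected window end
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(rec, path)
    w <- readWindows(path, profile = "hs3d", label = "true")
    expect_equal(length(w), 1L)
    expect_equal(as.character(windowSequences(w))[1], substr(rec, 63, 77))
    expect_equal(sourceCoords(w), 63L)
    expect_equal(as.character(siteLabels(w)), "true")
})

test_that("window-sized records pass through unchanged and GT violations are rejected, not dropped silently", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("AAAAAAAAGTAAAAA",    # valid
                 "AAAAAAAAGAAAAAA",    # GA at 9-10: invariant violation
                 "AAAANAAAGTAAAAA"),   # ambiguity code inside window
               path)
    expect_message(w <- readWindows(path, profile = "nn269"),
                   "rejected 2 of 3")
    expect_equal(as.character(windowSequences(w)), "AAAAAAAAGTAAAAA")
    rej <- rejections(w)
    expect_equal(nrow(rej), 2L)
    expect_match(rej$reason[1], "no GT")
    expect_match(rej$reason[2], "non-ACGT")
})

test_that("files with non-nucleotide characters abort with a parse error naming the record", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("AAAAAAAAGTAAAAA", "AAAA1AAAGTAAAAA"), path)
    expect_error(readWindows(path, profile = "plain"), "line 2")
})

test_that("the candidate scanner enumerates exactly the flank-valid GT dimers", {
    # no GT at all
    fa <- Biostrings::DNAStringSet(c(r1 = "AAAAAAAA"))
    expect_equal(length(scanCandidates(fa)), 0L)
    # 20 nt, single GT at 9-10: one window spanning 1..15
    s2 <- "AAAAAAAAGTAAAAAAAAAA"
    w2 <- scanCandidates(Biostrings::DNAStringSet(c(r = s2)))
    expect_equal(length(w2), 1L)
    expect_equal(sourceCoords(w2), 1L)
    expect_equal(as.character(windowSequences(w2))[1], substr(s2, 1, 15))
    # 17 nt with GT at 9-10 and 11-12: windows at starts 1 and 3
    s3 <- "AAAAAAAAGTGTAAAAA"
    w3 <- scanCandidates(Biostrings::DNAStringSet(c(r = s3)))
    expect_equal(sourceCoords(w3), c(1L, 3L))
})

test_that("scanning is coordinate-exact and GT-invariant on random sequences", {
    set.seed(42)
    g <- WindowGeometry(15, 9)
    for (rep in 1:20) {
        s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                   collapse = "")
        w <- scanCandidates(Biostrings::DNAStringSet(c(rec = s)), g)
        expect_equal(sourceCoords(w), oracle_gt_starts(s, 15L, 9L))
        if (length(w) == 0L) next
        seqs <- as.character(windowSequences(w))
        # re-slicing the source at sourceCoord reproduces each window
        expect_equal(seqs, substring(s, sourceCoords(w),
                                     sourceCoords(w) + 14L))
        expect_true(all(substr(seqs, 9, 10) == "GT"))
    }
})

test_that("windows overlapping ambiguity codes are skipped with a log entry", {
    fa <- Biostrings::DNAStringSet(c(r = "AAAAAAAAGTAANAAAAAAAAGTAAAAA"))
    expect_message(w <- scanCandidates(fa), "skipped")
    # first GT (pos 9) overlaps the N at 13; second GT (pos 22) is clean
    expect_equal(sourceCoords(w), 14L)
    expect_equal(nrow(rejections(w)), 1L)
})

test_that("FASTA round-trip preserves sequences, labels and coordinates", {
    w <- generateWindows(nTrue = 8, nFalse = 8, seed = 4)
    path <- withr::local_tempfile(fileext = ".fasta")
    writeWindowsFasta(w, path)
    back <- readWindows(path, profile = "fasta")
    expect_equal(as.character(windowSequences(back)),
                 as.character(windowSequences(w)))
    expect_equal(as.character(siteLabels(back)),
                 as.character(siteLabels(w)))
    expect_equal(sourceIds(back), sourceIds(w))
})

test_that("evaluation sets honor the ratio exactly and partition each set across folds", {
    w <- generateWindows(nTrue = 10, nFalse = 10, seed = 2)
    tw <- w[siteLabels(w) == "true"]; fw <- w[siteLabels(w) == "false"]
    d <- assembleEvalSets(tw, fw, ratio = c(1, 1), nSets = 1, nFolds = 5,
                          seed = 9)
    m <- d@membership[[1]]
    # every window of the set tested exactly once; folds of 4
    expect_equal(sort(table(m$fold)), sort(rep(4L, 5)), ignore_attr = TRUE)
    expect_equal(anyDuplicated(m$index), 0L)
    for (f in 1:5) {
        sp <- splitWindows(d, 1, f)
        expect_equal(length(sp$test), 4L)
        expect_equal(length(sp$train), 16L)
        # stratified: each fold preserves the 1:1 ratio
        expect_equal(sum(siteLabels(sp$test) == "true"), 2L)
        # train/test disjoint
        expect_length(intersect(sourceIds(sp$train), sourceIds(sp$test)), 0)
    }
})

test_that("imbalanced designs size sets as ratio multiples of the available windows", {
    w <- generateWindows(nTrue = 50, nFalse = 950, seed = 5)
    tw <- w[siteLabels(w) == "true"]; fw <- w[siteLabels(w) == "false"]
    d <- assembleEvalSets(tw, fw, ratio = c(1, 19), nSets = 3, nFolds = 5,
                          seed = 1)
    for (s in 1:3) {
        lab <- siteLabels(d@windows[d@membership[[s]]$index])
        expect_equal(sum(lab == "true"), 50L)
        expect_equal(sum(lab == "false"), 950L)
    }
    expect_error(assembleEvalSets(tw[1:3], fw, ratio = c(1, 1),
                                  nFolds = 5, seed = 1),
                 "insufficient")
})

test_that("set assembly is deterministic in the seed and varies across seeds", {
    w <- generateWindows(nTrue = 100, nFalse = 200, seed = 8)
    tw <- w[siteLabels(w) == "true"]; fw <- w[siteLabels(w) == "false"]
    d1 <- assembleEvalSets(tw, fw, nSets = 2, nFolds = 5, seed = 33)
    d2 <- assembleEvalSets(tw, fw, nSets = 2, nFolds = 5, seed = 33)
    d3 <- assembleEvalSets(tw, fw, nSets = 2, nFolds = 5, seed = 34)
    expect_identical(d1@membership, d2@membership)
    expect_false(identical(d1@membership, d3@membership))
})
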