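two_windows <- function()
    SpliceWindowSet(c("AAAAAAAAGTAAAAA", "CCCCCCCCGTCCCCC"), label = "true")

test_that("positional frequencies, M and N match direct counting", {
    m <- estimatePositional(two_windows(), pseudocount = 0)
    p <- positionalProbs(m)
    expect_equal(unname(p["A", 1]), 0.5)
    expect_equal(unname(p["C", 1]), 0.5)
    expect_equal(unname(p["G", 9]), 1)
    expect_equal(unname(p["T", 10]), 1)
    # 13 half-half columns contribute max 0.5 each, the GT columns 1 each
    expect_equal(unname(extremalSums(m)["M"]), 13 * 0.5 + 2)
    expect_equal(unname(extremalSums(m)["N"]), 0)
})

test_that("a single training window gives a 0/1 model with M = L, N = 0", {
    m <- estimatePositional(two_windows()[1], pseudocount = 0)
    expect_true(all(positionalProbs(m) %in% c(0, 1)))
    expect_equal(unname(extremalSums(m)["M"]), 15)
    expect_equal(unname(extremalSums(m)["N"]), 0)
})

test_that("additive smoothing enters at count level", {
    m <- estimatePositional(two_windows(), pseudocount = 1)
    expect_equal(unname(positionalProbs(m)["A", 1]), (1 + 1) / (2 + 4))
})

test_that("conditional frequencies match direct pair counting", {
    w <- SpliceWindowSet(c("AAAAAAAAGTAAAAA", "ACAAAAAAGTAAAAA"),
                         label = "true")
    d <- estimateDependency(w, pseudocount = 0)
    q <- conditionalProbs(d)
    expect_equal(q["C", "A", 2, 1], 0.5)   # A at 1 in both, C at 2 once
    expect_equal(q["A", "C", 3, 2], 1)     # C at 2 only in window 2
    # single-window model: q = 1 at every observed pair
    d1 <- estimateDependency(w[1], pseudocount = 0)
    q1 <- conditionalProbs(d1)
    expect_equal(q1["A", "A", 1, 2], 1)
    expect_equal(q1["G", "T", 9, 10], 1)
})

test_that("unobserved conditioning bases fall back to the uniform 1/4", {
    w <- two_windows()[1]   # all-A flanks: C, G, T never occur at pos 1
    d <- estimateDependency(w, pseudocount = 0)
    expect_equal(unname(conditionalProbs(d)[, "C", 2, 1]), rep(0.25, 4))
})

test_that("models are column-stochastic and exchangeable on random training sets", {
    set.seed(7)
    for (rep in 1:5) {
        w <- random_window_set(30, label = "true")
        pc <- sample(c(0, 0.5, 1), 1)
        m <- estimatePositional(w, pc)
        expect_true(all(abs(colSums(positionalProbs(m)) - 1) < 1e-9))
        d <- estimateDependency(w, pc)
        q <- conditionalProbs(d)
        L <- 15L
        for (j in c(1L, 5L, 14L)) for (i in c(2L, 9L)) {
            if (i == j) next
            cs <- colSums(q[, , i, j])
            # columns with support (or any pseudocount) sum to one
            expect_true(all(abs(cs - 1) < 1e-9))
        }
        # permutation of training windows leaves the estimates unchanged
        perm <- sample(length(w))
        expect_equal(positionalProbs(estimatePositional(w[perm], pc)),
                     positionalProbs(m))
        expect_equal(conditionalProbs(estimateDependency(w[perm], pc)), q)
    }
})

test_that("the conserved GT columns are degenerate under a pseudocount-0 model", {
    w <- random_window_set(40, label = "true")
    m <- estimatePositional(w, pseudocount = 0)
    expect_equal(unname(positionalProbs(m)["G", 9]), 1)
    expect_equal(unname(positionalProbs(m)["T", 10]), 1)
})

test_that("estimation rejects empty, mixed-length and mixed-class input", {
    w <- two_windows()
    expect_error(estimatePositional(w[0]), "non-empty")
    mixed <- SpliceWindowSet(c("AAAAAAAAGTAAAAA", "CCCCCCCCGTCCCCC"),
                             label = c("true", "false"))
    expect_error(estimatePositional(mixed), "one class")
    expect_error(estimatePositional(w, pseudocount = -1), "nonnegative")
})

test_that("plain-text model serialisation round-trips exactly", {
    w <- random_window_set(25, label = "true")
    pos <- estimatePositional(w, pseudocount = 1)
    dep <- estimateDependency(w, pseudocount = 1)
    fp <- withr::local_tempfile(fileext = ".tsv")
    fd <- withr::local_tempfile(fileext = ".tsv")
    writeFrequencyModel(pos, fp)
    writeFrequencyModel(dep, fd)
    pos2 <- readFrequencyModel(fp)
    dep2 <- readFrequencyModel(fd)
    expect_identical(positionalProbs(pos2), positionalProbs(pos))
    expect_identical(extremalSums(pos2), extremalSums(pos))
    expect_identical(pos2@nTrain, pos@nTrain)
    expect_identical(conditionalProbs(dep2), conditionalProbs(dep))
    expect_identical(dep2@classTag, dep@classTag)
})
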