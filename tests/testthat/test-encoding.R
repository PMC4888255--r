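test_that("a consensus window scores 0 on WMM and SS under its own model", {
    w <- SpliceWindowSet("AAAAAAAAGTAAAAA")
    m <- estimatePositional(SpliceWindowSet(c("AAAAAAAAGTAAAAA",
                                              "CCCCCCCCGTCCCCC")),
                            pseudocount = 0, classTag = "true")
    pf <- positionalFeatures(w, m, m)
    # every p(a_i) is the column max (consensus), so sum p = M and the
    # min-max normalised score is 0; note logs of 0.5 make wmm negative
    expect_equal(unname(pf[1, "ss_true"]), 0)
    expect_equal(unname(pf[1, "ss_diff"]), 0)
    expect_equal(unname(pf[1, "wmm_diff"]), 0)
    # single-sequence model: all matched frequencies are 1
    m1 <- estimatePositional(w, pseudocount = 0, classTag = "true")
    pf1 <- positionalFeatures(w, m1, m)
    expect_equal(unname(pf1[1, "wmm_true"]), 0)
    expect_equal(unname(pf1[1, "ss_true"]), 0)
})

test_that("the WMM log score is the hand-computed sum of log2 frequencies", {
    # two informative positions with p = 0.5 and 0.25; the conserved GT
    # columns have p = 1 and contribute log2(1) = 0, so the score is
    # log2 0.5 + log2 0.25 = -3
    g <- WindowGeometry(4, 3)
    train <- SpliceWindowSet(c("AAGT", "AAGT", "ACGT", "CGGT"),
                             geometry = g, label = "true")
    m <- estimatePositional(train, pseudocount = 0)
    expect_equal(unname(positionalProbs(m)["A", 1]), 0.75)
    expect_equal(unname(positionalProbs(m)["C", 2]), 0.25)
    pf <- positionalFeatures(SpliceWindowSet("ACGT", geometry = g), m, m)
    expect_equal(unname(pf[1, "wmm_true"]), log2(0.75) + log2(0.25))
    m@prob[, 1] <- c(0.5, 0.5, 0, 0)   # p(A_1) = 0.5, p(C_2) = 0.25
    pf2 <- positionalFeatures(SpliceWindowSet("ACGT", geometry = g), m, m)
    expect_equal(unname(pf2[1, "wmm_true"]), -3)
})

test_that("positional scores follow the printed min-max deviation form with a classical variant behind a flag", {
    set.seed(31)
    wt <- random_window_set(40, label = "true")
    m <- estimatePositional(wt, pseudocount = 1)
    pf <- positionalFeatures(wt, m, m)
    # deviation form: 0 at consensus, negative otherwise
    expect_true(all(pf[, "ss_true"] <= 1e-9))
    cl <- positionalFeatures(wt, m, m, ssVariant = "classical")
    # classical Shapiro-Senapathy: shifted by 100 relative to deviation
    expect_equal(unname(cl[, "ss_true"] - pf[, "ss_true"]),
                 rep(100, length(wt)))
})

test_that("dependency features are zero in the degenerate one-window case", {
    w <- SpliceWindowSet("ACGCAGGCGTAAGTC")
    d1 <- estimateDependency(w, 0, "true")
    df <- dependencyFeatures(w, d1, d1)
    expect_equal(unname(df[1, "wam_true"]), 0)   # all q = 1
    expect_equal(unname(df[1, "sae_true"]), 0)   # 2L(L-1) - 2L(L-1)
    expect_equal(unname(df[1, "wam_diff"]), 0)
    expect_equal(unname(df[1, "sae_diff"]), 0)
})

test_that("the SAE score equals 2L(L-1) - 2 sum q (210 under an all-0.5 model at L = 15)", {
    w <- SpliceWindowSet("AAAAAAAAGTAAAAA")
    d <- estimateDependency(w, 0, "true")
    d@condProb[] <- 0.5            # synthetic all-0.5 conditional model
    df <- dependencyFeatures(w, d, d)
    # sum q over 210 ordered pairs = 105; 2*15*14 - 2*105 = 210
    expect_equal(unname(df[1, "sae_true"]), 210)
    expect_equal(unname(df[1, "wam_true"]), -210)  # 210 logs of 0.5
})

test_that("difference features vanish when the class models coincide and flip sign when swapped", {
    set.seed(13)
    w <- random_window_set(25)
    wt <- random_window_set(30, label = "true")
    wf <- random_window_set(30, label = "false")
    mt <- estimatePositional(wt, 1); mf <- estimatePositional(wf, 1)
    dt <- estimateDependency(wt, 1); df_ <- estimateDependency(wf, 1)
    same_p <- positionalFeatures(w, mt, mt)
    same_d <- dependencyFeatures(w, dt, dt)
    expect_equal(unname(same_p[, "wmm_diff"]), rep(0, 25))
    expect_equal(unname(same_p[, "ss_diff"]), rep(0, 25))
    expect_equal(unname(same_d[, "wam_diff"]), rep(0, 25))
    expect_equal(unname(same_d[, "sae_diff"]), rep(0, 25))
    ab_p <- positionalFeatures(w, mt, mf); ba_p <- positionalFeatures(w, mf, mt)
    ab_d <- dependencyFeatures(w, dt, df_); ba_d <- dependencyFeatures(w, df_, dt)
    expect_equal(ab_p[, "wmm_diff"], -ba_p[, "wmm_diff"])
    expect_equal(ab_p[, "ss_diff"], -ba_p[, "ss_diff"])
    expect_equal(ab_d[, "wam_diff"], -ba_d[, "wam_diff"])
    expect_equal(ab_d[, "sae_diff"], -ba_d[, "sae_diff"])
    # true-only features ignore the false model entirely
    expect_equal(ab_p[, c("wmm_true", "ss_true")],
                 positionalFeatures(w, mt, mf)[, c("wmm_true", "ss_true")])
})

test_that("k-mer compositions match brute-force substring counting", {
    w1 <- SpliceWindowSet("AAAAAAAAGTAAAAA")
    di <- compositionalFeatures(w1, 2)
    expect_equal(unname(di[1, "di_AA"]), 11 / 14)
    expect_equal(unname(di[1, "di_AG"]), 1 / 14)
    expect_equal(unname(di[1, "di_GT"]), 1 / 14)
    expect_equal(unname(di[1, "di_TA"]), 1 / 14)
    expect_equal(sum(di[1, ] != 0), 4)
    tet <- compositionalFeatures(w1, 4)
    expect_equal(unname(tet[1, "tetra_AAAA"]), 7 / 12)
    expect_equal(unname(tet[1, c("tetra_AAAG", "tetra_AAGT", "tetra_AGTA",
                                 "tetra_GTAA", "tetra_TAAA")]),
                 rep(1 / 12, 5))
    # homopolymer check
    hp <- SpliceWindowSet("AAAAAAAAGTAAAAA")
    expect_equal(sum(compositionalFeatures(hp, 3)[1, ]), 1)
    # property: every block matches the oracle and sums to 1
    set.seed(99)
    w <- random_window_set(10)
    for (k in 2:4) {
        cf <- compositionalFeatures(w, k)
        expect_equal(unname(rowSums(cf)), rep(1, 10))
        for (i in c(1L, 7L)) {
            s <- as.character(windowSequences(w))[i]
            expect_equal(unname(cf[i, ]),
                         unname(as.vector(oracle_kmer_counts(s, k))) /
                             (15 - k + 1))
        }
    }
})

test_that("the encoder emits manifests exactly: 344 full features, 49 frozen features", {
    w <- generateWindows(nTrue = 15, nFalse = 15, seed = 6)
    models <- fitFrequencyModels(w)
    full <- encodeWindows(w, models, featureManifest("full344"))
    expect_equal(ncol(full), 344L)
    expect_equal(sum(startsWith(colnames(full), "tetra_")), 256L)
    expect_equal(sum(startsWith(colnames(full), "tri_")), 64L)
    expect_equal(sum(startsWith(colnames(full), "di_")), 16L)
    red <- encodeWindows(w, models, featureManifest("selected49"))
    expect_equal(ncol(red), 49L)
    expect_equal(sum(startsWith(colnames(red), "di_")), 14L)
    expect_equal(sum(startsWith(colnames(red), "tri_")), 15L)
    expect_equal(sum(startsWith(colnames(red), "tetra_")), 12L)
    # the reduced encoding is a column subset of the full one
    expect_equal(full[, colnames(red)], red)
    # determinism
    expect_identical(encodeWindows(w, models, featureManifest("selected49")),
                     red)
    # unknown feature names are a configuration error
    bad <- featureManifest("custom", featureNames = c("wmm_true", "hexa_A"))
    expect_error(encodeWindows(w, models, bad), "unknown feature")
})

test_that("degenerate or unsmoothed models are rejected with advice", {
    w <- SpliceWindowSet("AAAAAAAAGTAAAAA")
    wt <- random_window_set(10, label = "true")
    m0 <- estimatePositional(wt, 0)
    expect_error(positionalFeatures(w, m0, m0), "pseudocount")
    flat <- m0
    flat@prob[] <- 0.25; flat@M <- 15 * 0.25; flat@N <- 15 * 0.25
    expect_error(positionalFeatures(w, flat, flat), "degenerate")
})
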