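makeTruth <- function(nMips = 10L, nDecoys = 10L) {
    data.frame(
        id = c(sprintf("mip%d", seq_len(nMips)),
               sprintf("dec%d", seq_len(nDecoys)), "tfA"),
        class = c(rep("true_mip_tier1", nMips),
                  rep("decoy_random", nDecoys), "tf"),
        expected_targets = c(rep("tfA", nMips), rep("-", nDecoys), "-"))
}

makePredictions <- function(ids, targets = "tfA") {
    S4Vectors::DataFrame(
        mip_id = ids, mip_length = rep(100L, length(ids)),
        target_tfs = IRanges::CharacterList(as.list(rep(targets,
                                                        length(ids)))),
        target_lengths = IRanges::IntegerList(as.list(rep(400L,
                                                          length(ids)))),
        domains = IRanges::CharacterList(rep(list(character(0L)),
                                             length(ids))),
        tier = rep("tier1", length(ids)))
}

test_that("recall, precision and target accuracy follow their definitions", {
    truth <- makeTruth()
    perfect <- evaluatePredictions(makePredictions(sprintf("mip%d", 1:10)),
                                   truth)
    r <- as.list(perfect)
    expect_identical(r$recall, 1)
    expect_identical(r$precision, 1)
    expect_identical(r$target_accuracy, 1)

    half <- evaluatePredictions(
        makePredictions(c(sprintf("mip%d", 1:5), sprintf("dec%d", 1:5))),
        truth)
    expect_identical(half@recall, 0.5)
    expect_identical(half@precision, 0.5)
    expect_identical(unname(half@classCounts[c("true_mip_tier1",
                                               "decoy_random")]),
                     c(5L, 5L))

    # wrong targets hurt target accuracy but not precision
    wrong <- evaluatePredictions(
        makePredictions(sprintf("mip%d", 1:10), targets = "tfZZZ"), truth)
    expect_identical(wrong@precision, 1)
    expect_identical(wrong@targetAccuracy, 0)
})

test_that("zero predictions leave precision undefined, not zero", {
    rep0 <- evaluatePredictions(makePredictions(character(0L)), makeTruth())
    expect_identical(rep0@recall, 0)
    expect_true(is.na(rep0@precision))
    expect_true(is.na(rep0@targetAccuracy))
})

test_that("unlabeled prediction ids are a hard error", {
    expect_error(evaluatePredictions(makePredictions("phantom"), makeTruth()),
                 "phantom")
})

test_that("evaluation is invariant to prediction order", {
    truth <- makeTruth()
    ids <- c(sprintf("mip%d", 1:6), sprintf("dec%d", 1:3))
    a <- evaluatePredictions(makePredictions(ids), truth)
    b <- evaluatePredictions(makePredictions(rev(ids)), truth)
    expect_identical(as.list(a), as.list(b))
})

test_that("a single-point sweep matches a direct pipeline run", {
    fix <- smallFixture()
    sw <- sweepThresholds(fix, 1e-7, 0.5, 0.1)
    expect_identical(nrow(sw$grid), 1L)
    pred <- runPipeline(fixtureProteome(fix), fixtureTfs(fix),
                        fixtureUnwanted(fix), mipConfig(), builtinBackend(),
                        fixtureLibrary(fix))
    direct <- evaluatePredictions(pred, fixtureTruth(fix))
    expect_identical(sw$grid$recall, direct@recall)
    expect_identical(sw$grid$n_predictions, direct@nPredictions)
    expect_identical(sw$selected, sw$grid[1L, ])
})

test_that("re-thresholded sweep equals naive full runs over a small grid", {
    fix <- smallFixture()
    e1s <- c(1e-12, 1e-7)
    e2s <- c(0.05, 0.5)
    sw <- sweepThresholds(fix, e1s, e2s, 0.1)
    for (i in seq_len(nrow(sw$grid))) {
        cfg <- mipConfig(tier1Cutoff = sw$grid$e1[i],
                         tier2Cutoff = sw$grid$e2[i],
                         reverseCutoff = sw$grid$e3[i])
        pred <- runPipeline(fixtureProteome(fix), fixtureTfs(fix),
                            fixtureUnwanted(fix), cfg, builtinBackend(),
                            fixtureLibrary(fix))
        direct <- evaluatePredictions(pred, fixtureTruth(fix))
        expect_identical(sw$grid$recall[i], direct@recall, info = i)
        expect_identical(sw$grid$n_predictions[i], direct@nPredictions,
                         info = i)
    }
})

test_that("the selected row maximizes recall at the most stringent cutoffs", {
    fix <- defaultFixture()
    sw <- sweepThresholds(fix)
    grid <- sw$grid
    expect_identical(sw$selected$recall, max(grid$recall))
    best <- grid[grid$recall == max(grid$recall), ]
    best <- best[order(best$e1, best$e2, best$e3), ]
    expect_identical(sw$selected, best[1L, ])
    # the fixture is built so the defaults already recall everything
    expect_identical(sw$selected$recall, 1)
    expect_error(sweepThresholds(fix, c(1e-4, 1e-7), 0.5, 0.1), "ascending")
})
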