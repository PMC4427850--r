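test_that("self-alignment score equals the diagonal substitution sum", {
    sch <- scoringScheme()
    s <- "HEAGAWGHEE"
    res <- smithWaterman(s, s, sch)
    letters <- strsplit(s, "", fixed = TRUE)[[1L]]
    expect_identical(res$score,
                     as.integer(sum(diag(sch@matrix[letters, letters]))))
    expect_identical(c(res$qstart, res$qend), c(1L, 10L))
    expect_identical(res$identity, 1)
})

test_that("all-negative pairs give score zero and an empty alignment", {
    res <- smithWaterman("AAAA", "WWWW")
    expect_identical(res$score, 0L)
    expect_true(is.na(res$qstart))
    expect_error(smithWaterman("", "MKV"), "non-empty")
})

test_that("alignment scores match the naive full-DP oracle on random pairs", {
    sch <- scoringScheme()
    set.seed(202)
    for (i in 1:40) {
        a <- randomProtein(sample(5:50, 1L))
        b <- randomProtein(sample(5:50, 1L))
        expect_identical(smithWaterman(a, b, sch)$score,
                         as.integer(swOracle(a, b, sch@matrix)),
                         info = paste("pair", i))
    }
})

test_that("alignment score is symmetric under a symmetric matrix", {
    set.seed(303)
    for (i in 1:10) {
        a <- randomProtein(40L)
        b <- randomProtein(40L)
        expect_identical(smithWaterman(a, b)$score, smithWaterman(b, a)$score)
    }
})

test_that("E-values follow the Karlin-Altschul formula", {
    sch <- scoringScheme()
    # direct arithmetic: E = K * m * n * exp(-lambda * S)
    expect_equal(evalueOf(40, 100, 10000, sch),
                 0.041 * 100 * 10000 * exp(-0.267 * 40))
    # at lambda * S = log(K * m * n) the E-value is exactly 1
    s0 <- log(sch@K * 100 * 10000) / sch@lambda
    expect_equal(evalueOf(s0, 100, 10000, sch), 1)
    # doubling the database doubles E; E is strictly decreasing in score
    expect_equal(evalueOf(40, 100, 20000, sch),
                 2 * evalueOf(40, 100, 10000, sch))
    expect_true(all(diff(evalueOf(1:100, 100, 10000, sch)) < 0))
    expect_error(evalueOf(40, 0, 10000, sch), "positive")
})

test_that("search reports an exact database copy of the query", {
    set.seed(404)
    q <- randomProtein(300L)
    queries <- Proteome(c(tfA = q))
    db <- Proteome(c(copyA = q, junk1 = randomProtein(250L),
                     junk2 = randomProtein(250L)))
    hits <- searchProteins(queries, db, cutoff = 1e-7)
    expect_true(any(hits$query == "tfA" & hits$subject == "copyA"))
    expect_error(searchProteins(queries, Proteome(), 1e-7), "empty database")
})

test_that("random 50-aa queries almost never hit unrelated databases", {
    set.seed(505)
    db <- Proteome(stats::setNames(
        vapply(1:5, function(i) randomProtein(200L), character(1L)),
        paste0("d", 1:5)))
    clean <- 0L
    for (trial in 1:20) {
        q <- Proteome(c(q1 = randomProtein(50L)))
        hits <- searchProteins(q, db, cutoff = 1e-7)
        if (nrow(hits) == 0L)
            clean <- clean + 1L
    }
    expect_gte(clean, 19L)
})

test_that("hit sets grow monotonically with the cutoff", {
    fix <- smallFixture()
    tfs <- fixtureTfs(fix)
    db <- partitionByLength(fixtureProteome(fix), 550L)
    strict <- searchProteins(tfs, db, 1e-7)
    loose <- searchProteins(tfs, db, 0.5)
    key <- function(h) paste(h$query, h$subject)
    expect_true(all(key(strict) %in% key(loose)))
    expect_true(all(loose$evalue <= 0.5))
    # deterministic ordering: query, then evalue ascending, then subject
    expect_false(is.unsorted(loose$evalue[loose$query == loose$query[1L]]))
})

test_that("precomputed backends replay hits and reject unknown ids", {
    fix <- smallFixture()
    tabs <- pipelineSearchTables(fix)
    backend <- precomputedBackend(tabs$forward, tabs$small, tabs$reverse)
    expect_silent(validateBackend(backend, fixtureProteome(fix),
                                  fixtureTfs(fix)))
    ghost <- tabs$forward
    ghost$subject[1L] <- "ghost"
    bad <- precomputedBackend(ghost, tabs$small, tabs$reverse)
    expect_error(validateBackend(bad, fixtureProteome(fix), fixtureTfs(fix)),
                 "ghost")
    # replay filters by cutoff and by membership in the requested sets
    replay <- backendSearch(backend, "forward", fixtureTfs(fix),
                            partitionByLength(fixtureProteome(fix), 550L),
                            cutoff = 1e-30)
    expect_true(all(replay$evalue <= 1e-30))
})

test_that("an empty precomputed backend yields zero predictions", {
    fix <- smallFixture()
    f <- withr::local_tempfile(lines = character())
    backend <- precomputedBackend(f, f, f)
    pred <- runPipeline(fixtureProteome(fix), fixtureTfs(fix),
                        fixtureUnwanted(fix), mipConfig(), backend,
                        fixtureLibrary(fix))
    expect_identical(nrow(pred), 0L)
})
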