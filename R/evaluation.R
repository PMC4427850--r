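#' Evaluation report for predictions against ground truth
#'
#' @slot recall fraction of planted miPs recovered (\code{NA} when none
#'   were planted).
#' @slot precision fraction of predictions labeled as true miPs
#'   (\code{NA} when there are no predictions: undefined, not zero).
#' @slot targetAccuracy fraction of recovered miPs whose reported target
#'   set intersects the expected targets (\code{NA} when none were
#'   recovered). Reported separately from precision: a recovered miP
#'   with a wrong target list still counts for precision.
#' @slot classCounts integer vector counting predictions per truth class.
#' @slot nPredictions,nPlanted,nRecovered integer counts.
#' @exportClass EvalReport
setClass("EvalReport", representation(
    recall = "numeric", precision = "numeric", targetAccuracy = "numeric",
    classCounts = "integer", nPredictions = "integer", nPlanted = "integer",
    nRecovered = "integer"))

setMethod("show", "EvalReport", function(object) {
    fmt <- function(x) if (is.na(x)) "-" else sprintf("%.3f", x)
    cat("EvalReport: recall ", fmt(object@recall), " (",
        object@nRecovered, "/", object@nPlanted, " planted miPs), precision ",
        fmt(object@precision), ", target accuracy ",
        fmt(object@targetAccuracy), "\n", sep = "")
    cat("  predictions by truth class:\n")
    print(object@classCounts[object@classCounts > 0L])
    invisible(NULL)
})

#' @rdname evaluatePredictions
#' @param x an \linkS4class{EvalReport}.
#' @param ... ignored.
#' @export
setMethod("as.list", "EvalReport", function(x, ...) {
    list(recall = x@recall, precision = x@precision,
         target_accuracy = x@targetAccuracy, class_counts = x@classCounts,
         n_predictions = x@nPredictions, n_planted = x@nPlanted,
         n_recovered = x@nRecovered)
})

#' Score predictions against a fixture's ground truth
#'
#' A planted miP counts as recovered iff its id appears among the
#' predictions; precision counts any prediction whose truth label is a
#' true-miP class, regardless of its reported targets (target
#' correctness is reported separately as target accuracy). Predictions
#' whose id carries no truth label are a hard error. The result is
#' invariant to prediction order.
#'
#' @param predictions a prediction \code{DataFrame} from [runPipeline()]
#'   or [readPredictions()].
#' @param truth a ground-truth data.frame (see
#'   \linkS4class{MipFixture}).
#' @return an \linkS4class{EvalReport}; extract numbers with
#'   \code{as.list()}.
#' @export
evaluatePredictions <- function(predictions, truth) {
    predIds <- predictions$mip_id
    unknown <- setdiff(predIds, truth$id)
    if (length(unknown))
        stop("prediction id(s) missing from ground truth: ",
             paste(unknown, collapse = ", "))
    trueClasses <- c("true_mip_tier1", "true_mip_tier2")
    planted <- truth$id[truth$class %in% trueClasses]
    recovered <- intersect(planted, predIds)
    classOf <- truth$class[match(predIds, truth$id)]
    counts <- table(factor(classOf, levels = TRUTH_CLASSES))
    nPred <- length(predIds)

    targetOk <- NA
    if (length(recovered)) {
        expected <- strsplit(truth$expected_targets[match(recovered,
                                                          truth$id)],
                             ";", fixed = TRUE)
        predTargets <- as.list(predictions$target_tfs[match(recovered,
                                                            predIds)])
        targetOk <- mean(mapply(function(e, p) length(intersect(e, p)) > 0L,
                                expected, predTargets))
    }
    new("EvalReport",
        recall = if (length(planted)) length(recovered) / length(planted)
                 else NA_real_,
        precision = if (nPred) sum(classOf %in% trueClasses) / nPred
                    else NA_real_,
        targetAccuracy = as.numeric(targetOk),
        classCounts = stats::setNames(as.integer(counts), names(counts)),
        nPredictions = nPred, nPlanted = length(planted),
        nRecovered = length(recovered))
}

#' Sweep E-value cutoff combinations and select defaults by recall
#'
#' Runs the pipeline over the Cartesian grid of stringent-tier,
#' permissive-tier and reverse-search cutoffs on a benchmark fixture and
#' scores each combination against the ground truth. The three searches
#' are computed once at the loosest cutoff of each axis and replayed
#' through the precomputed backend, so the sweep is a re-thresholding
#' pass, not repeated alignment (equivalent to independent full runs,
#' since a hit table at a stricter cutoff is exactly the loose table
#' filtered). The selected row follows the recall-driven calibration
#' rule: among rows achieving maximal recall, the most stringent
#' (smallest) cutoffs, ties broken lexicographically by (tier1, tier2,
#' reverse).
#'
#' @param fixture a \linkS4class{MipFixture}.
#' @param tier1Cutoffs,tier2Cutoffs,reverseCutoffs ascending E-value
#'   vectors; every tier-1 value must be \code{<=} every tier-2 value so
#'   each grid point is a valid configuration.
#' @param config base \linkS4class{MipConfig} supplying the non-swept
#'   parameters.
#' @param scheme \linkS4class{ScoringScheme} for the search engine.
#' @return a list with \code{grid} (data.frame of e1, e2, e3, recall,
#'   precision, n_predictions, sorted by (e1, e2, e3)) and
#'   \code{selected} (the chosen row).
#' @export
sweepThresholds <- function(fixture,
                            tier1Cutoffs = c(1e-10, 1e-7, 1e-4),
                            tier2Cutoffs = c(0.05, 0.5, 1),
                            reverseCutoffs = c(0.01, 0.1, 0.5),
                            config = mipConfig(),
                            scheme = scoringScheme()) {
    for (ax in list(tier1Cutoffs, tier2Cutoffs, reverseCutoffs))
        if (length(ax) == 0L || is.unsorted(ax, strictly = TRUE))
            stop("cutoff axes must be non-empty and strictly ascending")
    proteome <- fixture@proteome
    tfs <- fixture@tfs
    looseCfg <- mipConfig(
        maxMipLength = config@maxMipLength,
        smallProteinLength = config@smallProteinLength,
        tier1Cutoff = max(tier1Cutoffs), tier2Cutoff = max(tier2Cutoffs),
        reverseCutoff = max(reverseCutoffs),
        lengthRatio = config@lengthRatio)
    p550 <- partitionByLength(proteome, config@maxMipLength)
    p200 <- partitionByLength(proteome, config@smallProteinLength)
    fwd <- searchProteins(tfs, p550, looseCfg@tier1Cutoff, scheme)
    small <- searchProteins(tfs, p200, looseCfg@tier2Cutoff, scheme)
    subjects <- setdiff(unique(small$subject), proteinIds(tfs))
    rev <- if (length(subjects))
        searchProteins(proteome[subjects], tfs, looseCfg@reverseCutoff,
                       scheme)
    else .emptyHits()
    backend <- precomputedBackend(fwd, small, rev)

    rows <- list()
    for (e1 in tier1Cutoffs)
        for (e2 in tier2Cutoffs)
            for (e3 in reverseCutoffs) {
                cfg <- mipConfig(
                    maxMipLength = config@maxMipLength,
                    smallProteinLength = config@smallProteinLength,
                    tier1Cutoff = e1, tier2Cutoff = e2, reverseCutoff = e3,
                    lengthRatio = config@lengthRatio)
                pred <- runPipeline(proteome, tfs, fixture@unwanted, cfg,
                                    backend, fixture@library)
                rep <- evaluatePredictions(pred, fixture@truth)
                rows[[length(rows) + 1L]] <- data.frame(
                    e1 = e1, e2 = e2, e3 = e3, recall = rep@recall,
                    precision = rep@precision,
                    n_predictions = rep@nPredictions)
            }
    grid <- do.call(rbind, rows)
    best <- grid[grid$recall == max(grid$recall), , drop = FALSE]
    best <- best[order(best$e1, best$e2, best$e3), , drop = FALSE]
    list(grid = grid, selected = best[1L, , drop = FALSE])
}
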