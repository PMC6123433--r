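## Shared learnability runs (synthetic cohort -> encode -> train ->
## score). Study conditions: 50 specimens per class, stratified 60/40
## specimen-level split, default generator effect, 50 epochs of 100
## patches (100 px windows) with dihedral augmentation.
##
## Only seed 1 is cached with its model and training features (the
## patch-group direction test reuses them); other seeds return bare
## metrics so three runs fit comfortably in memory.

.learnCache <- new.env(parent = emptyenv())

runLearnability <- function(seed) {
    key <- as.character(seed)
    if (!is.null(.learnCache[[key]])) return(.learnCache[[key]])
    cohort <- generateCohort(50, generatorConfig(), seed = seed)
    feats <- lapply(cohort, encodeSnapshot)
    rm(cohort)
    sp <- splitCohort(feats, trainFraction = 0.6, seed = seed,
                      stratify = TRUE)
    trainF <- feats[sp$train]
    testF <- feats[sp$test]
    rm(feats)
    model <- buildNetwork(networkConfig(), seed = seed)
    tc <- trainConfig(patchSize = 100, patchesPerEpoch = 100,
                      batchSize = 25, epochs = 45, epochsPhase2 = 5,
                      lr = 1e-3, valFraction = 0.2, valEvery = 10,
                      seed = seed)
    model <- trainNetwork(model, trainF, config = tc)
    scores <- scoreSpecimens(model, testF)
    dnnAuc <- rocAuc(scores$score, scores$label)
    ## logistic baseline on intra-patch moments of 5000 training
    ## patches, sampled in chunks so the patches are never all in
    ## memory at once
    chunks <- lapply(seq_len(10), function(i) {
        ps <- sampleTrainingPatches(trainF, 500, patchSize = 64,
                                    seed = seed * 100L + i,
                                    augment = FALSE)
        cbind(patchStatsTable(ps),
              label = vapply(ps, erLabel, integer(1)))
    })
    baseStats <- do.call(rbind, chunks)
    rm(chunks)
    baseline <- logisticBaselineTrain(NULL, labels = baseStats$label,
                                      stats = baseStats)
    baseScores <- vapply(testF, function(f)
        logisticBaselineScore(baseline, f, patchSize = 64), numeric(1))
    baseLabels <- vapply(testF, erLabel, integer(1))
    ok <- !is.na(baseScores)
    baseAuc <- rocAuc(baseScores[ok], baseLabels[ok])
    out <- list(scores = scores, dnnAuc = dnnAuc, baseAuc = baseAuc,
                seed = seed)
    if (seed == 1) {
        out$model <- model
        out$trainFeatures <- trainF
        .learnCache[[key]] <- out
    }
    rm(trainF, testF, model, baseline)
    gc(verbose = FALSE)
    out
}
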