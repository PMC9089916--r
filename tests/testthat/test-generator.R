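test_that("gene universes are disjoint and flag markers and mito genes", {
    u <- buildGeneUniverse(generatorConfig())
    expect_length(u$rat$gene, 1000)
    expect_length(u$mouse$gene, 1000)
    expect_length(intersect(u$rat$gene, u$mouse$gene), 0)
    markers <- unique(unlist(markerPanels()))
    expect_setequal(u$rat$gene[u$rat$is_marker], markers)
    expect_identical(sum(u$rat$is_mito), 13L)
    expect_identical(sum(u$mouse$is_mito), 13L)
})

test_that("a universe too small for the shipped gene sets is rejected", {
    expect_error(buildGeneUniverse(generatorConfig(nGenesPerSpecies = 10)),
                 "smaller")
})

test_that("same config and seed give bit-identical simulations", {
    cfg <- generatorConfig(nGenesPerSpecies = 100, treatments = "fresh",
                           replicatesPerArm = 1, cellsPerReplicate = 60,
                           seed = 7)
    s1 <- simulateExperiment(cfg)
    s2 <- simulateExperiment(cfg)
    expect_identical(as.matrix(ratCounts(s1)), as.matrix(ratCounts(s2)))
    expect_identical(as.matrix(mouseCounts(s1)), as.matrix(mouseCounts(s2)))
    expect_identical(as.data.frame(simTruth(s1)),
                     as.data.frame(simTruth(s2)))
    s3 <- simulateExperiment(generatorConfig(nGenesPerSpecies = 100,
        treatments = "fresh", replicatesPerArm = 1,
        cellsPerReplicate = 60, seed = 8))
    expect_false(identical(as.matrix(ratCounts(s1)),
                           as.matrix(ratCounts(s3))))
})

test_that("zero ambient rate leaves wrong-species genes empty", {
    sim <- tinySim(seed = 3, ambientRate = 0)
    expect_identical(sum(mouseCounts(sim)), 0)
    simM <- tinySim(seed = 3, ambientRate = 0, mouseFraction = 1)
    expect_identical(sum(ratCounts(simM)), 0)
})

test_that("per-cell totals decompose into rat plus mouse counts", {
    sim <- tinySim(seed = 5, ambientRate = 0.05)
    tot <- colSums(ratCounts(sim)) + colSums(mouseCounts(sim))
    expect_identical(tot,
        colSums(rbind(ratCounts(sim), mouseCounts(sim))))
    # own-species share is >= 1 - ambient in expectation
    own <- colSums(ratCounts(sim)) / pmax(tot, 1)
    expect_gt(mean(own), 1 - 0.05 - 0.01)
})

test_that("marker genes are elevated in their own stage", {
    sim <- tinySim(seed = 9, cells = 1500, propConcentration = Inf,
                   selection = "epcam")
    truth <- as.data.frame(simTruth(sim))
    norm <- normalizeCpmLog(ratCounts(sim))
    for (st in c("SSC", "elongating spermatid")) {
        g <- markerPanels()[[st]]
        inStage <- truth$stage == st
        expect_gt(sum(inStage), 4)
        expect_gt(mean(as.matrix(norm[g, inStage, drop = FALSE])),
                  mean(as.matrix(norm[g, !inStage, drop = FALSE])))
    }
})

test_that("planted Prm1 suppression is realized in group means", {
    # two arms, round-spermatid heavy, ~500 cells/group: the empirical
    # fresh/long-frozen mean ratio of the Prm1 analog is within 15% of
    # the planted 2.8-fold
    w <- c(0.01, 0.01, 0.01, 0.05, 0.12, 0.75, 0.05)
    sim <- simulateExperiment(generatorConfig(
        nGenesPerSpecies = 150,
        treatments = c("transplanted_fresh", "transplanted_long_frozen"),
        effects = list(
            transplanted_fresh = treatmentEffects()$fresh,
            transplanted_long_frozen =
                treatmentEffects()$transplanted_long_frozen),
        replicatesPerArm = 1, cellsPerReplicate = 700,
        stageWeights = w, propConcentration = Inf, seed = 21))
    truth <- as.data.frame(simTruth(sim))
    cpm <- expm1(normalizeCpmLog(ratCounts(sim)))
    rs <- truth$stage == "round spermatid"
    mF <- mean(cpm["Prm1", rs & truth$treatment == "transplanted_fresh"])
    mL <- mean(cpm["Prm1", rs &
                           truth$treatment == "transplanted_long_frozen"])
    expect_gt(sum(rs & truth$treatment == "transplanted_fresh"), 300)
    expect_lt(abs(mF / mL - 2.8) / 2.8, 0.15)
})

test_that("generated stage proportions match the configured weights", {
    cfg <- generatorConfig(nGenesPerSpecies = 100, treatments = "fresh",
                           replicatesPerArm = 1,
                           cellsPerReplicate = 10000,
                           propConcentration = Inf, seed = 17)
    truth <- as.data.frame(simTruth(simulateExperiment(cfg)))
    obs <- table(factor(truth$stage, levels = germCellStages()))
    gof <- stats::chisq.test(obs, p = cfg@stageWeights)
    expect_gt(gof$p.value, 0.01)
})

test_that("EpCAM enrichment raises early-stage fractions, identity cases unchanged", {
    sim <- tinySim(seed = 13, cells = 2000)
    truth <- simTruth(sim)
    early <- c("SSC", "progenitor", "differentiating spermatogonia")
    preFrac <- mean(truth$stage %in% early)

    cfg10 <- generatorConfig(epcamFactor = 10, seed = 13)
    post <- applyEpcamEnrichment(truth, cfg10)
    expect_identical(nrow(post), nrow(truth))
    expect_gt(mean(post$stage %in% early), preFrac)

    cfg1 <- generatorConfig(epcamFactor = 1, seed = 13)
    expect_identical(applyEpcamEnrichment(truth, cfg1), truth)

    lateOnly <- truth[!truth$stage %in% early, ]
    expect_identical(applyEpcamEnrichment(lateOnly, cfg10), lateOnly)
})

test_that("epcam selection shifts the generator's own sampling weights", {
    cfgE <- generatorConfig(nGenesPerSpecies = 100,
                            treatments = "fresh", replicatesPerArm = 1,
                            cellsPerReplicate = 3000,
                            selection = "epcam",
                            propConcentration = Inf, seed = 31)
    truthE <- as.data.frame(simTruth(simulateExperiment(cfgE)))
    early <- c("SSC", "progenitor", "differentiating spermatogonia")
    expect_gt(mean(truthE$stage %in% early), 0.4)
})

test_that("degenerate configurations are rejected", {
    expect_error(generatorConfig(cellsPerReplicate = 0), "positive")
    expect_error(generatorConfig(ambientRate = 1.2))
    expect_error(generatorConfig(epcamFactor = 0.5))
})
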