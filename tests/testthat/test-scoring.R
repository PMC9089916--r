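normToy <- function(nGenes = 50, nCells = 30, seed = 14) {
    set.seed(seed)
    m <- matrix(rpois(nGenes * nCells, 8), nGenes,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                paste0("c", seq_len(nCells))))
    normalizeCpmLog(m)
}

test_that("module score of the whole gene universe is exactly zero", {
    norm <- normToy()
    sc <- moduleScore(norm, rownames(norm), n_bins = 5, n_ctrl = 100,
                      seed = 2)
    expect_true(all(abs(sc) < 1e-12))
})

test_that("module score is seed-deterministic and shift invariant", {
    norm <- as.matrix(normToy())
    prog <- rownames(norm)[1:8]
    s1 <- moduleScore(norm, prog, n_bins = 5, seed = 3)
    s2 <- moduleScore(norm, prog, n_bins = 5, seed = 3)
    expect_identical(s1, s2)
    # adding a constant to a cell's profile cancels in the difference
    shifted <- norm
    shifted[, 1] <- shifted[, 1] + 3.7
    s3 <- moduleScore(shifted, prog, n_bins = 5, seed = 3)
    expect_equal(s3[1], s1[1] + 0, tolerance = 1e-10)
    expect_error(moduleScore(norm, c(prog, "nope"), seed = 3), "nope")
})

test_that("cells with planted program induction score higher", {
    # default-size universe: expression bins then hold non-program
    # genes to serve as controls
    sim <- simulateExperiment(generatorConfig(
        treatments = "long_frozen",
        replicatesPerArm = 1, cellsPerReplicate = 400,
        effects = list(long_frozen = list(
            stress_fold = 1, stage_prop_shift = numeric(),
            spermatid_fold_down = numeric(),
            apoptotic_fraction = 0.3)),
        seed = 44))
    truth <- as.data.frame(simTruth(sim))
    norm <- normalizeCpmLog(ratCounts(sim))
    sc <- moduleScore(norm, proapoptoticGenes(), seed = 44)
    expect_gt(median(sc[truth$apoptotic]), median(sc[!truth$apoptotic]))
    # and the classifier separates them far better than chance
    flag <- classifyApoptotic(sc)$flag
    expect_gt(mean(flag[truth$apoptotic]), 0.9)
})

test_that("apoptotic flag is strict at the cutoff and monotone in it", {
    sc <- c(a = 0.2, b = 0.1, c = 0.05, d = -0.3)
    flag <- classifyApoptotic(sc)$flag
    expect_identical(unname(flag), c(TRUE, FALSE, FALSE, FALSE))
    fracs <- vapply(c(0, 0.05, 0.1, 0.3), function(ct)
        mean(classifyApoptotic(sc, cutoff = ct)$flag), numeric(1))
    expect_true(all(diff(fracs) <= 0))
    ann <- data.frame(barcode = names(sc),
                      replicate = c("r1", "r1", "r1", "r2"),
                      cell_type = "SSC")
    out <- classifyApoptotic(sc, annotations = ann)
    r1 <- out$fractions[out$fractions$replicate == "r1", ]
    expect_equal(r1$apoptotic_fraction, 1 / 3)
    expect_equal(r1$n_cells, 3)
})

test_that("cell-type proportions are row-normalised hand counts", {
    ann <- data.frame(
        barcode = paste0("c", 1:10),
        treatment = rep(c("fresh", "frozen"), c(4, 6)),
        replicate = rep(c("r1", "r2", "r3"), c(4, 3, 3)),
        cell_type = c("SSC", "SSC", "round spermatid", "SSC",
                      "SSC", "round spermatid", "round spermatid",
                      "SSC", "SSC", "SSC"))
    pt <- celltypeProportions(ann)
    expect_equal(rowSums(pt[, germCellStages()]), rep(1, 3))
    r1 <- pt[pt$replicate == "r1", ]
    expect_equal(r1$SSC, 0.75)
    expect_equal(r1[["round spermatid"]], 0.25)
    expect_equal(pt$treatment[pt$replicate == "r3"], "frozen")
    annNA <- ann; annNA$cell_type[1] <- NA
    expect_error(celltypeProportions(annNA), "cell type")
})

test_that("one-way ANOVA matches the closed-form sums of squares", {
    props <- data.frame(
        treatment = rep(c("a", "b"), each = 3),
        replicate = paste0("r", 1:6),
        SSC = c(0.10, 0.12, 0.11, 0.20, 0.22, 0.21),
        other = rep(0.5, 6))
    res <- anovaPerCelltype(props, types = c("SSC", "other"))
    y <- props$SSC
    ssb <- 3 * sum((tapply(y, props$treatment, mean) - mean(y))^2)
    ssw <- sum((y - ave(y, props$treatment))^2)
    fHand <- (ssb / 1) / (ssw / 4)
    expect_equal(res$F[res$cell_type == "SSC"], fHand, tolerance = 1e-10)
    expect_equal(res$p_value[res$cell_type == "SSC"],
                 stats::pf(fHand, 1, 4, lower.tail = FALSE),
                 tolerance = 1e-10)
    # identical proportions across treatments: F = 0, p = 1
    expect_equal(res$F[res$cell_type == "other"], 0)
    expect_equal(res$p_value[res$cell_type == "other"], 1)
    expect_error(anovaPerCelltype(props[1:4, ], types = "SSC"),
                 ">= 2 replicates")
    expect_error(anovaPerCelltype(props[1:3, ], types = "SSC"),
                 "two treatments")
})

test_that("planted SSC proportion shifts are detected by the ANOVA", {
    # +0.10 SSC shift, 3 replicates per arm, replicate noise ~2pp
    hits <- 0L
    nsim <- 40L
    for (i in seq_len(nsim)) {
        sim <- simulateExperiment(generatorConfig(
            nGenesPerSpecies = 100,
            treatments = c("transplanted_fresh",
                           "transplanted_long_frozen"),
            replicatesPerArm = 3, cellsPerReplicate = 250,
            seed = 2000 + i))
        truth <- as.data.frame(simTruth(sim))
        truth$cell_type <- truth$stage
        props <- celltypeProportions(truth)
        res <- anovaPerCelltype(props, types = "SSC")
        if (res$p_value < 0.05) hits <- hits + 1L
    }
    expect_gte(hits / nsim, 0.9)
})
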