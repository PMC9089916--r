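# Independent oracles used across the suite. These re-state the target
# computations from their definitions, by routes unrelated to the
# package implementation.

# species call by direct evaluation of the margin inequality
oracleSpeciesCall <- function(rat, mouse, margin = 0.05) {
    if (rat > (1 + margin) * mouse) return("rat")
    if (mouse > (1 + margin) * rat) return("mouse")
    "unknown"
}

# Benjamini-Hochberg by brute force: for each p, the minimum over the
# tail ranks of p_(j) * m / j, capped at 1
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    sorted <- p[ord]
    adj <- vapply(seq_len(m), function(i)
        min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
    out <- numeric(m)
    out[ord] <- adj
    out
}

# PERMANOVA pseudo-F recomputed from group membership sums (double loop,
# no shared code with the package)
oracleF <- function(d, labels) {
    n <- nrow(d)
    a <- length(unique(labels))
    sst <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (g in unique(labels)) {
        idx <- which(labels == g)
        s <- 0
        if (length(idx) > 1)
            for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
        ssw <- ssw + s / length(idx)
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# small fast simulation for module-level tests
tinySim <- function(seed = 1, treatments = "fresh", reps = 1,
                    cells = 120, genes = 100, ...) {
    simulateExperiment(generatorConfig(
        nGenesPerSpecies = genes, treatments = treatments,
        replicatesPerArm = reps, cellsPerReplicate = cells,
        seed = seed, ...))
}

# two-species toy DualSpeciesCounts with prescribed per-cell totals
toyDual <- function(ratTotals, mouseTotals) {
    n <- length(ratTotals)
    bc <- paste0("bc", seq_len(n))
    rat <- matrix(0, 2, n, dimnames = list(c("Etv5", "RatGene0001"), bc))
    mouse <- matrix(0, 2, n,
                    dimnames = list(c("MouseGene0001", "MouseGene0002"), bc))
    rat[1, ] <- ratTotals
    mouse[1, ] <- mouseTotals
    DualSpeciesCounts(rat, mouse)
}
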