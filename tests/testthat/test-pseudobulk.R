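toyNorm <- function() {
    m <- matrix(c(1, 2,   # c1 (rep1, SSC)
                  3, 4,   # c2 (rep1, SSC)
                  5, 6,   # c3 (rep2, SSC)
                  9, 9),  # c4 (rep2, other type)
                nrow = 2, dimnames = list(c("g1", "g2"),
                                          paste0("c", 1:4)))
    ann <- data.frame(barcode = paste0("c", 1:4),
                      cell_type = c("SSC", "SSC", "SSC", "round spermatid"),
                      replicate = c("r1", "r1", "r2", "r2"),
                      treatment = c("fresh", "fresh", "frozen", "frozen"))
    list(m = m, ann = ann)
}

test_that("pseudobulk rows are member-cell means with cell counts", {
    toy <- toyNorm()
    pb <- pseudobulk(toy$m, toy$ann, "SSC")
    expect_equal(pb$matrix["r1", ], c(g1 = 2, g2 = 3))  # mean of c1, c2
    expect_equal(pb$matrix["r2", ], c(g1 = 5, g2 = 6))  # single cell
    expect_equal(pb$samples$n_cells, c(2, 1))
    expect_identical(pb$samples$treatment, c("fresh", "frozen"))
    # a replicate without cells of the type is dropped with a warning
    expect_warning(pb2 <- pseudobulk(toy$m, toy$ann, "round spermatid"),
                   "no")
    expect_identical(rownames(pb2$matrix), "r2")
    expect_error(suppressWarnings(pseudobulk(toy$m, toy$ann, "missing")),
                 "no replicate")
})

test_that("pseudobulk PCA matches an eigendecomposition oracle", {
    set.seed(4)
    x <- matrix(rnorm(50), nrow = 5)
    res <- pcaPseudobulk(x)
    ev <- eigen(stats::cov(x))
    expect_equal(sort(res$variance_pct, decreasing = TRUE),
                 res$variance_pct)
    expect_equal(res$variance_pct[1:4],
                 100 * ev$values[1:4] / sum(ev$values), tolerance = 1e-8)
    # coordinates agree up to per-axis sign
    ctr <- sweep(x, 2, colMeans(x))
    oracle <- ctr %*% ev$vectors[, 1:4]
    for (j in 1:4)
        expect_equal(abs(res$coordinates[, j]), abs(oracle[, j]),
                     ignore_attr = TRUE, tolerance = 1e-8)
    # identical rows coincide, constant matrix does not fail
    same <- rbind(c(1, 2), c(1, 2))
    expect_equal(pcaPseudobulk(same)$coordinates[1, ],
                 pcaPseudobulk(same)$coordinates[2, ])
})

test_that("distance matrix is euclidean and matches brute force", {
    m <- rbind(a = c(0, 0), b = c(3, 4))
    d <- distanceMatrix(m)
    expect_equal(d["a", "b"], 5)
    expect_equal(diag(d), c(a = 0, b = 0))
    set.seed(9)
    x <- matrix(rnorm(48), nrow = 6)
    d <- distanceMatrix(x)
    for (i in 1:6) for (j in 1:6)
        expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)),
                     tolerance = 1e-12)
    expect_error(distanceMatrix(rbind(c(1, NA), c(0, 0))), "finite")
})

test_that("permanova is scale invariant and label-permutation invariant", {
    set.seed(2)
    x <- matrix(rnorm(60), nrow = 6)
    g <- rep(c("a", "b"), each = 3)
    d <- distanceMatrix(x)
    r1 <- permanova(d, g, n_permutations = 99, seed = 5)
    r2 <- permanova(d * 7, g, n_permutations = 99, seed = 5)
    expect_equal(r1$pseudo_F, r2$pseudo_F)
    expect_equal(r1$p_value, r2$p_value)
    # permuting rows together with labels leaves the exhaustive p
    # unchanged (the random-permutation p is only equal in distribution)
    perm <- c(4, 2, 6, 1, 3, 5)
    e1 <- permanova(d, g, exhaustive = TRUE)
    e3 <- permanova(d[perm, perm], g[perm], exhaustive = TRUE)
    expect_equal(e1$pseudo_F, e3$pseudo_F)
    expect_equal(e1$p_value, e3$p_value)
    expect_error(permanova(d, rep("a", 6)), "two groups")
    expect_error(permanova(d, g, n_permutations = 0), ">= 1")
})

test_that("pseudo-F agrees with vegan's adonis2 on random data", {
    set.seed(8)
    x <- matrix(rnorm(80), nrow = 8)
    g <- rep(c("a", "b"), each = 4)
    ours <- permanova(distanceMatrix(x), g, n_permutations = 99, seed = 1)
    ref <- vegan::adonis2(stats::dist(x) ~ g, permutations = 999)
    expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("a planted two-SD group shift drives p to its permutation floor", {
    # 3+3 rows admit only 10 distinct relabelings, so the add-one p
    # cannot drop below ~0.1 no matter how strong the shift; the planted
    # signal must pin the median at that floor
    set.seed(33)
    pvals <- replicate(100, {
        base <- matrix(rnorm(6 * 20), nrow = 6)
        base[4:6, ] <- base[4:6, ] + 2      # +2 pooled SDs per gene
        permanova(distanceMatrix(base), rep(c("a", "b"), each = 3),
                  n_permutations = 199,
                  seed = sample.int(1e6, 1))$p_value
    })
    expect_lte(median(pvals), 0.12)
    # with one extra replicate per group the same shift is conclusive
    set.seed(34)
    pvals8 <- replicate(100, {
        base <- matrix(rnorm(8 * 20), nrow = 8)
        base[5:8, ] <- base[5:8, ] + 2
        permanova(distanceMatrix(base), rep(c("a", "b"), each = 4),
                  n_permutations = 199,
                  seed = sample.int(1e6, 1))$p_value
    })
    expect_lt(median(pvals8), 0.1)
})

test_that("pooled designs map treatments to groups and reject gaps", {
    g <- pooledGroupDesign(rep(c("fresh", "short_frozen", "long_frozen"),
                               each = 3))
    expect_identical(table(g)[["fresh"]], 3L)
    expect_identical(table(g)[["frozen"]], 6L)
    expect_identical(
        pooledGroupDesign(c("a", "b"), list(a = "a", b = "b")),
        c("a", "b"))
    expect_error(pooledGroupDesign(c("fresh", "odd")), "not covered")
    expect_error(pooledGroupDesign("fresh",
        list(g1 = "fresh", g2 = "fresh")), "more than one")
})
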