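#' Per-cell quality-control metrics
#'
#' @param counts genes x cells count matrix (sparse or dense) with gene
#'   rownames and barcode colnames.
#' @param mito_genes character vector of mitochondrial gene names (a
#'   subset of the rownames; genes absent from the matrix are an error).
#' @return data.frame with columns \code{barcode}, \code{n_genes} (genes
#'   with at least one UMI), \code{n_umi}, \code{pct_mito}
#'   (mitochondrial UMIs as a percentage of total; 0 for an all-zero
#'   cell).
#' @export
qcMetrics <- function(counts, mito_genes = ratMitoGenes()) {
    if (length(dim(counts)) != 2L || ncol(counts) == 0L)
        stop("counts must be a nonempty genes x cells matrix",
             call. = FALSE)
    missing <- setdiff(mito_genes, rownames(counts))
    if (length(missing))
        stop("mitochondrial genes absent from matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    nUmi <- as.numeric(colSums(counts))
    nGenes <- as.numeric(colSums(counts > 0))
    mito <- as.numeric(colSums(counts[mito_genes, , drop = FALSE]))
    pct <- ifelse(nUmi > 0, 100 * mito / nUmi, 0)
    data.frame(barcode = colnames(counts), n_genes = nGenes,
               n_umi = nUmi, pct_mito = pct, row.names = NULL)
}

#' Filter low-quality cells
#'
#' A cell is removed iff its mitochondrial percentage is strictly above
#' \code{mito_max} (cells at exactly the threshold are kept) or it falls
#' below the detected-genes or UMI floors.
#'
#' @param metrics data.frame from [qcMetrics()].
#' @param mito_max maximum mitochondrial percentage (default 20).
#' @param min_genes minimum detected genes (default 200).
#' @param min_umi minimum UMI count (default 500).
#' @return character vector of kept barcodes.
#' @export
filterCells <- function(metrics, mito_max = 20, min_genes = 200,
                        min_umi = 500) {
    .assertSingleNumber(mito_max, "mito_max", lo = 0)
    .assertSingleNumber(min_genes, "min_genes", lo = 0)
    .assertSingleNumber(min_umi, "min_umi", lo = 0)
    keep <- metrics$pct_mito <= mito_max &
        metrics$n_genes >= min_genes &
        metrics$n_umi >= min_umi
    metrics$barcode[keep]
}

#' Counts-per-million log normalisation
#'
#' Scales each cell to one million UMIs and applies log(1 + x). Cells
#' with zero total stay all-zero; the zero pattern of the matrix is
#' preserved exactly.
#'
#' @param counts genes x cells count matrix.
#' @return genes x cells matrix of log1p(CPM), same class family
#'   (sparse in, sparse out).
#' @export
normalizeCpmLog <- function(counts) {
    if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
    tot <- colSums(counts)
    scale <- ifelse(tot > 0, 1e6 / tot, 0)
    if (is(counts, "sparseMatrix")) {
        out <- as(as(counts, "dMatrix"), "CsparseMatrix")
        out@x <- log1p(out@x * rep.int(scale, diff(out@p)))
        out
    } else {
        log1p(sweep(counts, 2L, scale, "*"))
    }
}

#' Unsupervised clustering of cells
#'
#' Centroid-based clustering (k-means with multiple starts) on the top
#' principal components of the normalised matrix. Deterministic under a
#' fixed seed.
#'
#' @param normalized genes x cells log-normalised matrix.
#' @param k number of clusters (default 14: two centroids per expected
#'   state, merged afterwards by marker-panel labelling).
#' @param seed integer seed.
#' @param n_pcs number of principal components used (default 10, capped
#'   at the available dimensions).
#' @return integer vector of cluster labels named by barcode.
#' @export
clusterCells <- function(normalized, k = 14, seed = 1, n_pcs = 10) {
    n <- ncol(normalized)
    if (k < 1) stop("k must be >= 1", call. = FALSE)
    if (k > n) stop("k exceeds the number of cells", call. = FALSE)
    if (k == 1)
        return(stats::setNames(rep(1L, n), colnames(normalized)))
    x <- as.matrix(Matrix::t(normalized))
    n_pcs <- min(n_pcs, n - 1L, ncol(x))
    withSeed(seed, {
        pc <- stats::prcomp(x, rank. = n_pcs, center = TRUE,
                            scale. = FALSE)
        km <- stats::kmeans(pc$x, centers = k, nstart = 25,
                            iter.max = 100)
        stats::setNames(as.integer(km$cluster), colnames(normalized))
    })
}

#' Per-cell marker-panel scores
#'
#' The score of a cell for a panel is the mean log-normalised expression
#' of the panel's genes in that cell.
#'
#' @param normalized genes x cells log-normalised matrix.
#' @param panels named list of marker gene vectors, default
#'   [markerPanels()].
#' @return cells x panels numeric matrix.
#' @export
scoreMarkerPanels <- function(normalized, panels = markerPanels()) {
    for (nm in names(panels)) {
        missing <- setdiff(panels[[nm]], rownames(normalized))
        if (length(missing))
            stop("panel '", nm, "' gene(s) absent from matrix: ",
                 paste(missing, collapse = ", "), call. = FALSE)
    }
    scores <- vapply(panels, function(g)
        as.numeric(colSums(normalized[g, , drop = FALSE])) / length(g),
        numeric(ncol(normalized)))
    if (is.null(dim(scores)))
        scores <- matrix(scores, nrow = 1,
                         dimnames = list(NULL, names(panels)))
    rownames(scores) <- colnames(normalized)
    scores
}

#' Label clusters (and their cells) by the best-scoring marker panel
#'
#' Each cluster is assigned the panel with the highest mean score over
#' its member cells; all cells inherit their cluster's label. Ties are
#' broken by the canonical stage order (earlier stage wins).
#'
#' @param clusters cluster labels, one per cell (as from
#'   [clusterCells()]).
#' @param panel_scores cells x panels score matrix from
#'   [scoreMarkerPanels()], rows aligned with \code{clusters}.
#' @return character vector of cell-type labels, one per cell.
#' @export
annotateCells <- function(clusters, panel_scores) {
    if (length(clusters) != nrow(panel_scores))
        stop("one score row per cell required", call. = FALSE)
    types <- colnames(panel_scores)
    out <- character(length(clusters))
    for (cl in unique(clusters)) {
        idx <- clusters == cl
        m <- colMeans(panel_scores[idx, , drop = FALSE])
        out[idx] <- types[which.max(m)]  # which.max: first (earliest) on tie
    }
    out
}

#' Linear pseudotime along the first principal component
#'
#' A deliberately simple trajectory: cells are projected on the first
#' principal component of the log-normalised matrix and rescaled to
#' [0, 1]. The axis is oriented so that cells in the top decile of the
#' start gene's expression (undifferentiated spermatogonia for Etv5) sit
#' below 0.5 on average, making pseudotime increase along
#' differentiation.
#'
#' @param normalized genes x cells log-normalised matrix (>= 2 cells).
#' @param start_gene gene anchoring the origin (default "Etv5").
#' @return numeric vector in [0, 1], named by barcode.
#' @export
linearPseudotime <- function(normalized, start_gene = "Etv5") {
    if (ncol(normalized) < 2L)
        stop("pseudotime needs at least two cells", call. = FALSE)
    if (!start_gene %in% rownames(normalized))
        stop("start gene '", start_gene, "' absent from matrix",
             call. = FALSE)
    pc1 <- stats::prcomp(as.matrix(Matrix::t(normalized)), rank. = 1,
                         center = TRUE)$x[, 1]
    rng <- range(pc1)
    pt <- if (diff(rng) > 0) (pc1 - rng[1]) / diff(rng)
          else rep(0.5, length(pc1))
    expr <- as.numeric(normalized[start_gene, ])
    hi <- expr >= stats::quantile(expr, 0.9)
    if (any(hi) && mean(pt[hi]) > 0.5) pt <- 1 - pt
    stats::setNames(pt, colnames(normalized))
}
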