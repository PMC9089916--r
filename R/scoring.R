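#' Gene-program module score with binned control genes
#'
#' For each cell, the score is the mean log-normalised expression of the
#' program genes minus the mean over a control gene set. Controls are
#' matched for expression level: all genes are ranked by their average
#' expression across cells and cut into \code{n_bins} equal-frequency
#' bins, and for each program gene up to \code{n_ctrl} control genes are
#' sampled (without replacement) from the non-program genes of the
#' program gene's own bin; the union of these samples forms the control
#' set. This makes the score
#' robust to depth and baseline expression differences. The control
#' sampling is the only stochastic step and is fully determined by
#' \code{seed}.
#'
#' @param normalized genes x cells log-normalised matrix.
#' @param program character vector of program genes (all must be
#'   present).
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per program gene (default 100;
#'   capped at the bin size).
#' @param seed integer seed for control sampling.
#' @return numeric score per cell, named by barcode.
#' @examples
#' m <- matrix(rpois(600, 5), 30,
#'     dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
#' norm <- normalizeCpmLog(m)
#' head(moduleScore(norm, c("g1", "g2", "g3"), n_bins = 5))
#' @export
moduleScore <- function(normalized, program, n_bins = 25, n_ctrl = 100,
                        seed = 1) {
    if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
    missing <- setdiff(program, rownames(normalized))
    if (length(missing))
        stop("program gene(s) absent from matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    program <- unique(program)
    avg <- Matrix::rowMeans(normalized)
    # equal-frequency bins of average expression
    bins <- ceiling(rank(avg, ties.method = "first") * n_bins /
                    length(avg))
    names(bins) <- rownames(normalized)
    ctrl <- withSeed(seed, {
        unique(unlist(lapply(program, function(g) {
            pool <- setdiff(names(bins)[bins == bins[g]], program)
            # a program spanning its whole bin falls back to the bin
            # itself (score contributions then cancel exactly)
            if (!length(pool)) pool <- names(bins)[bins == bins[g]]
            sample(pool, min(n_ctrl, length(pool)))
        })))
    })
    progMean <- as.numeric(
        Matrix::colSums(normalized[program, , drop = FALSE])) /
        length(program)
    ctrlMean <- as.numeric(
        Matrix::colSums(normalized[ctrl, , drop = FALSE])) /
        length(ctrl)
    stats::setNames(progMean - ctrlMean, colnames(normalized))
}

#' Classify cells as apoptotic by module-score cutoff
#'
#' A cell is flagged apoptotic iff its score is strictly greater than
#' the cutoff (a score exactly at the cutoff is not flagged).
#'
#' @param scores per-cell scores (as from [moduleScore()]).
#' @param cutoff score threshold (default 0.1).
#' @param annotations optional per-cell data.frame with \code{barcode},
#'   \code{replicate}, \code{cell_type}; when given, per-(replicate,
#'   cell type) apoptotic fractions are also returned.
#' @return list with \code{flag} (logical per cell) and, when
#'   annotations are given, \code{fractions} (data.frame: replicate,
#'   cell_type, n_cells, apoptotic_fraction).
#' @export
classifyApoptotic <- function(scores, cutoff = 0.1, annotations = NULL) {
    flag <- scores > cutoff
    out <- list(flag = flag)
    if (!is.null(annotations)) {
        m <- match(names(scores), annotations$barcode)
        if (anyNA(m))
            stop("annotations missing for some barcodes", call. = FALSE)
        ann <- annotations[m, , drop = FALSE]
        agg <- stats::aggregate(flag,
            by = list(replicate = ann$replicate,
                      cell_type = ann$cell_type),
            FUN = function(x) c(n = length(x), frac = mean(x)))
        out$fractions <- data.frame(replicate = agg$replicate,
                                    cell_type = agg$cell_type,
                                    n_cells = agg$x[, "n"],
                                    apoptotic_fraction = agg$x[, "frac"])
    }
    out
}

#' Per-replicate cell-type composition
#'
#' @param annotations per-cell data.frame with \code{treatment},
#'   \code{replicate}, \code{cell_type} (every cell typed).
#' @param types cell-type column order (default the canonical stage
#'   order).
#' @return data.frame with one row per (treatment, replicate) and one
#'   fraction column per cell type; fractions in each row sum to 1.
#' @export
celltypeProportions <- function(annotations, types = germCellStages()) {
    if (any(is.na(annotations$cell_type)))
        stop("every cell must have a cell type", call. = FALSE)
    tab <- table(annotations$replicate,
                 factor(annotations$cell_type, levels = types))
    if (any(rowSums(tab) == 0))
        stop("empty replicate in annotations", call. = FALSE)
    frac <- sweep(unclass(tab), 1L, rowSums(tab), "/")
    reps <- rownames(frac)
    tr <- annotations$treatment[match(reps, annotations$replicate)]
    data.frame(treatment = tr, replicate = reps,
               frac, check.names = FALSE, row.names = NULL)
}

#' One-way ANOVA of cell-type proportions across treatments
#'
#' Fits, separately for each cell type, a fixed-effects one-way ANOVA of
#' the per-replicate proportion on treatment, on the untransformed
#' proportion scale.
#'
#' @param proportions data.frame from [celltypeProportions()].
#' @param types cell types to test (default: all proportion columns).
#' @return data.frame with one row per cell type: \code{cell_type},
#'   \code{F}, \code{p_value}, \code{df_between}, \code{df_within}.
#' @export
anovaPerCelltype <- function(proportions, types = NULL) {
    if (is.null(types))
        types <- setdiff(colnames(proportions),
                         c("treatment", "replicate"))
    counts <- table(proportions$treatment)
    if (length(counts) < 2L)
        stop("need at least two treatments", call. = FALSE)
    if (any(counts < 2L))
        stop("every treatment needs >= 2 replicates", call. = FALSE)
    res <- lapply(types, function(ct) {
        y <- proportions[[ct]]
        tr <- factor(proportions$treatment)
        if (stats::var(y) == 0) {
            # identical proportions everywhere: no effect, by convention
            return(data.frame(cell_type = ct, F = 0, p_value = 1,
                              df_between = nlevels(tr) - 1L,
                              df_within = length(y) - nlevels(tr)))
        }
        fit <- stats::aov(y ~ tr)
        s <- summary(fit)[[1]]
        data.frame(cell_type = ct, F = s[1, "F value"],
                   p_value = s[1, "Pr(>F)"],
                   df_between = s[1, "Df"], df_within = s[2, "Df"])
    })
    do.call(rbind, res)
}
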