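#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Compares two treatment groups within one cell type, pooling cells
#' across replicates. For each gene, a two-sided Wilcoxon rank-sum test
#' is run on the log-normalised values (normal approximation with
#' continuity and tie correction; the exact distribution is used when
#' the smaller group has fewer than 8 cells and there are no ties).
#' The fold change is computed on the CPM scale as
#' log2((mean_A + 1) / (mean_B + 1)); the +1 pseudocount keeps
#' low-expression genes stable.
#'
#' @param normalized genes x cells log-normalised matrix (log1p of CPM).
#' @param annotations per-cell data.frame with \code{barcode},
#'   \code{treatment}, \code{cell_type}.
#' @param group_A,group_B treatment labels being compared (A over B).
#' @param cell_type restrict to this cell type; \code{NULL} uses all
#'   cells.
#' @param fc_min,padj_max significance cutoffs forwarded to
#'   [applyDegCutoffs()].
#' @return data.frame with one row per gene: \code{gene}, \code{mean_A},
#'   \code{mean_B} (CPM scale), \code{log2_fold_change}, \code{p_value},
#'   \code{p_adjusted}, \code{significant}.
#' @export
wilcoxonDE <- function(normalized, annotations, group_A, group_B,
                       cell_type = NULL, fc_min = 1.5, padj_max = 0.05) {
    m <- match(colnames(normalized), annotations$barcode)
    if (anyNA(m))
        stop("annotations missing for some barcodes", call. = FALSE)
    ann <- annotations[m, , drop = FALSE]
    inType <- if (is.null(cell_type)) rep(TRUE, nrow(ann))
              else !is.na(ann$cell_type) & ann$cell_type == cell_type
    idxA <- which(inType & ann$treatment == group_A)
    idxB <- which(inType & ann$treatment == group_B)
    if (!length(idxA) || !length(idxB))
        stop("both groups must contain cells",
             if (!is.null(cell_type)) paste0(" of type '", cell_type, "'"),
             call. = FALSE)
    A <- as.matrix(normalized[, idxA, drop = FALSE])
    B <- as.matrix(normalized[, idxB, drop = FALSE])
    exact <- min(ncol(A), ncol(B)) < 8L
    p <- vapply(seq_len(nrow(A)), function(i) {
        a <- A[i, ]; b <- B[i, ]
        if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
        suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE)$p.value)
    }, numeric(1))
    meanA <- rowMeans(expm1(A))
    meanB <- rowMeans(expm1(B))
    res <- data.frame(gene = rownames(normalized),
                      mean_A = meanA, mean_B = meanB,
                      log2_fold_change = log2((meanA + 1) / (meanB + 1)),
                      p_value = p, row.names = NULL)
    res$p_adjusted <- bhAdjust(res$p_value)
    applyDegCutoffs(res, fc_min = fc_min, padj_max = padj_max)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure (monotone
#' after sorting, capped at 1), controlling the false discovery rate.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p_values) {
    if (!is.numeric(p_values) || anyNA(p_values) ||
        any(p_values < 0 | p_values > 1))
        stop("p-values must be numeric in [0, 1]", call. = FALSE)
    stats::p.adjust(p_values, method = "BH")
}

#' Flag significant genes by fold-change and FDR cutoffs
#'
#' A gene is significant iff |log2 fold change| >= log2(fc_min) and
#' adjusted p <= padj_max; both thresholds are inclusive (a minimum
#' 1.5-fold change corresponds to |log2FC| >= 0.585).
#'
#' @param results data.frame with \code{log2_fold_change} and
#'   \code{p_adjusted} columns (as from [wilcoxonDE()]).
#' @param fc_min minimum fold change (default 1.5).
#' @param padj_max maximum adjusted p (default 0.05).
#' @return \code{results} with a logical \code{significant} column.
#' @export
applyDegCutoffs <- function(results, fc_min = 1.5, padj_max = 0.05) {
    if (nrow(results) == 0L) {
        results$significant <- logical(0)
        return(results)
    }
    results$significant <-
        abs(results$log2_fold_change) >= log2(fc_min) - 1e-12 &
        results$p_adjusted <= padj_max
    results
}

#' Exclusive region counts of several gene sets (Euler-diagram counts)
#'
#' Counts the members of every exclusive region of the Venn/Euler
#' partition of two or more sets; the regions partition the union.
#'
#' @param sets named list of >= 2 character vectors.
#' @return named integer vector; names encode region membership as
#'   set names joined by "&" (e.g. "A", "A&B").
#' @examples
#' overlapSets(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
overlapSets <- function(sets) {
    if (length(sets) < 2L)
        stop("need at least two sets", call. = FALSE)
    if (is.null(names(sets)))
        names(sets) <- paste0("set", seq_along(sets))
    all_members <- unique(unlist(sets, use.names = FALSE))
    membership <- vapply(sets, function(s) all_members %in% s,
                         logical(length(all_members)))
    if (is.null(dim(membership)))
        membership <- matrix(membership, nrow = length(all_members))
    patterns <- apply(membership, 1L, function(row)
        paste(names(sets)[row], collapse = "&"))
    counts <- table(patterns)
    stats::setNames(as.integer(counts), names(counts))
}
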