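#' Pseudobulk a cell type to per-replicate mean expression profiles
#'
#' Averages the log-normalised expression of all cells of a given cell
#' type within each replicate, producing one observation per biological
#' replicate for sample-level statistics. Replicates contributing no
#' cells of the type are omitted with a warning.
#'
#' @param normalized genes x cells log-normalised matrix.
#' @param annotations data.frame with one row per cell (aligned with the
#'   matrix columns via \code{barcode}) holding \code{cell_type},
#'   \code{replicate} and \code{treatment}.
#' @param cell_type the cell type to aggregate (default "SSC"). Use
#'   \code{NULL} to aggregate all cells per replicate.
#' @return list with \code{matrix} (replicates x genes mean expression),
#'   and \code{samples} (data.frame: replicate, treatment, n_cells).
#' @export
pseudobulk <- function(normalized, annotations, cell_type = "SSC") {
    m <- match(colnames(normalized), annotations$barcode)
    if (anyNA(m))
        stop("annotations missing for some barcodes", call. = FALSE)
    ann <- annotations[m, , drop = FALSE]
    keep <- if (is.null(cell_type)) rep(TRUE, nrow(ann))
            else !is.na(ann$cell_type) & ann$cell_type == cell_type
    reps <- unique(ann$replicate)
    rows <- list(); info <- list()
    for (r in reps) {
        idx <- which(keep & ann$replicate == r)
        if (!length(idx)) {
            warning("replicate '", r, "' has no '", cell_type,
                    "' cells; row omitted", call. = FALSE)
            next
        }
        rows[[r]] <- as.numeric(
            Matrix::rowSums(normalized[, idx, drop = FALSE])) /
            length(idx)
        info[[r]] <- data.frame(replicate = r,
                                treatment = ann$treatment[idx[1]],
                                n_cells = length(idx))
    }
    if (!length(rows))
        stop("no replicate contains cells of type '", cell_type, "'",
             call. = FALSE)
    mat <- do.call(rbind, rows)
    colnames(mat) <- rownames(normalized)
    list(matrix = mat, samples = do.call(rbind, c(info,
                                                  make.row.names = FALSE)))
}

#' PCA of pseudobulk profiles
#'
#' Row-centred principal component analysis of a samples x genes matrix.
#'
#' @param pb_matrix samples x genes matrix (e.g. \code{pseudobulk()$matrix}).
#' @return list with \code{coordinates} (samples x components) and
#'   \code{variance_pct} (percent variance per component, nonincreasing).
#' @export
pcaPseudobulk <- function(pb_matrix) {
    if (nrow(pb_matrix) < 2L)
        stop("PCA needs at least two samples", call. = FALSE)
    pc <- stats::prcomp(pb_matrix, center = TRUE, scale. = FALSE)
    tot <- sum(pc$sdev^2)
    varPct <- if (tot > 0) 100 * pc$sdev^2 / tot else rep(0, length(pc$sdev))
    list(coordinates = pc$x, variance_pct = varPct)
}

#' Euclidean distance matrix between pseudobulk samples
#'
#' @param pb_matrix samples x genes matrix; must be finite.
#' @param metric currently "euclidean".
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
distanceMatrix <- function(pb_matrix, metric = "euclidean") {
    metric <- match.arg(metric)
    if (nrow(pb_matrix) < 2L)
        stop("need at least two samples", call. = FALSE)
    if (!all(is.finite(pb_matrix)))
        stop("non-finite values in pseudobulk matrix", call. = FALSE)
    as.matrix(stats::dist(pb_matrix, method = metric))
}

# pseudo-F from a squared-distance matrix and integer group codes
.pseudoF <- function(d2, groups) {
    N <- nrow(d2)
    a <- length(unique(groups))
    ssTotal <- sum(d2[upper.tri(d2)]) / N
    ssWithin <- 0
    for (g in unique(groups)) {
        idx <- which(groups == g)
        if (length(idx) > 1L) {
            sub <- d2[idx, idx]
            ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
        }
    }
    ((ssTotal - ssWithin) / (a - 1)) / (ssWithin / (N - a))
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Tests whether between-group dissimilarities exceed within-group
#' dissimilarities. The pseudo-F is computed directly from the distance
#' matrix: SS_total = sum of squared distances over all pairs divided by
#' N; SS_within = the same sum restricted to within-group pairs, each
#' group divided by its size; F = ((SS_total - SS_within)/(a - 1)) /
#' (SS_within/(N - a)). The null distribution comes from random
#' relabelings of the samples; the p-value uses the add-one convention
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations), so p is never 0.
#' With \code{exhaustive = TRUE} all n! label permutations are enumerated
#' instead and p is the exact fraction (identity included) with
#' F_perm >= F_obs.
#'
#' @param distances symmetric distance matrix (as from
#'   [distanceMatrix()]).
#' @param group_labels group label per sample (>= 2 groups).
#' @param n_permutations number of random permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all permutations (feasible for small N).
#' @return list with \code{pseudo_F}, \code{p_value},
#'   \code{n_permutations}, \code{group_sizes}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), nrow = 6)
#' permanova(distanceMatrix(x), rep(c("a", "b"), each = 3),
#'           n_permutations = 199, seed = 1)
#' @export
permanova <- function(distances, group_labels, n_permutations = 1000,
                      seed = 1, exhaustive = FALSE) {
    groups <- as.character(group_labels)
    N <- nrow(distances)
    if (length(groups) != N)
        stop("one group label per sample required", call. = FALSE)
    if (length(unique(groups)) < 2L)
        stop("PERMANOVA needs at least two groups", call. = FALSE)
    if (!exhaustive && n_permutations < 1)
        stop("n_permutations must be >= 1", call. = FALSE)
    d2 <- distances^2
    fObs <- .pseudoF(d2, groups)
    if (exhaustive) {
        perms <- .allPermutations(N)
        fPerm <- vapply(perms, function(p) .pseudoF(d2, groups[p]),
                        numeric(1))
        p <- mean(fPerm >= fObs - 1e-12)
        nPerm <- length(perms)
    } else {
        fPerm <- withSeed(seed, vapply(seq_len(n_permutations),
            function(i) .pseudoF(d2, groups[sample.int(N)]), numeric(1)))
        p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + n_permutations)
        nPerm <- n_permutations
    }
    list(pseudo_F = fObs, p_value = p, n_permutations = nPerm,
         group_sizes = table(groups))
}

# all permutations of seq_len(n) as a list (n <= 8 guarded)
.allPermutations <- function(n) {
    if (n > 8L) stop("exhaustive enumeration limited to N <= 8",
                     call. = FALSE)
    if (n == 1L) return(list(1L))
    sub <- .allPermutations(n - 1L)
    out <- vector("list", n * length(sub))
    k <- 0L
    for (p in sub) for (pos in seq_len(n)) {
        k <- k + 1L
        out[[k]] <- append(p, n, after = pos - 1L)
    }
    out
}

#' Pool treatment arms into analysis groups
#'
#' Maps each sample's treatment to a pooled group label, e.g. comparing
#' fresh against short- and long-frozen combined.
#'
#' @param treatments treatment label per sample.
#' @param pooling_spec named list, group name -> character vector of
#'   treatments it absorbs. Every observed treatment must be covered by
#'   exactly one group.
#' @return character vector of group labels aligned with
#'   \code{treatments}.
#' @examples
#' pooledGroupDesign(c("fresh", "short_frozen", "long_frozen"),
#'     list(fresh = "fresh",
#'          frozen = c("short_frozen", "long_frozen")))
#' @export
pooledGroupDesign <- function(treatments,
                              pooling_spec = list(
                                  fresh = "fresh",
                                  frozen = c("short_frozen",
                                             "long_frozen"))) {
    flat <- unlist(pooling_spec, use.names = FALSE)
    if (anyDuplicated(flat))
        stop("a treatment maps to more than one pooled group",
             call. = FALSE)
    unmapped <- setdiff(unique(treatments), flat)
    if (length(unmapped))
        stop("treatment(s) not covered by pooling spec: ",
             paste(unmapped, collapse = ", "), call. = FALSE)
    lut <- rep(names(pooling_spec), lengths(pooling_spec))
    names(lut) <- flat
    unname(lut[as.character(treatments)])
}
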