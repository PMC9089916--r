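#' Assign species by the dual-genome UMI-margin rule
#'
#' A cell is called for a species when its UMI total on that species'
#' reference exceeds the other species' total by more than the margin:
#' rat iff \code{rat_umi > (1 + margin) * mouse_umi}, mouse symmetrically,
#' otherwise unknown. The comparison is strict, so ties (including 0/0)
#' are unknown. Vectorised over cells.
#'
#' @param rat_umi,mouse_umi nonnegative UMI totals (vectors of equal
#'   length).
#' @param margin nonnegative margin fraction (default 0.05, i.e. one
#'   total must be more than 5\% higher than the other).
#' @return character vector of calls in \{"rat", "mouse", "unknown"\}.
#' @examples
#' assignSpecies(c(1000, 100, 105, 106), c(0, 100, 100, 100))
#' @export
assignSpecies <- function(rat_umi, mouse_umi, margin = 0.05) {
    if (length(rat_umi) != length(mouse_umi))
        stop("rat_umi and mouse_umi must have equal length", call. = FALSE)
    if (any(rat_umi < 0, na.rm = TRUE) || any(mouse_umi < 0, na.rm = TRUE))
        stop("UMI totals must be nonnegative", call. = FALSE)
    .assertSingleNumber(margin, "margin", lo = 0)
    call <- rep("unknown", length(rat_umi))
    call[rat_umi > (1 + margin) * mouse_umi] <- "rat"
    call[mouse_umi > (1 + margin) * rat_umi] <- "mouse"
    call
}

#' Species calls for every barcode of a dual-species experiment
#'
#' Sums UMIs over all genes of each reference (mitochondrial genes
#' included) and applies [assignSpecies()] per barcode.
#'
#' @param counts a [DualSpeciesCounts-class] object (or a
#'   [GermCellSim-class], whose counts are used).
#' @param margin margin fraction, default 0.05.
#' @return data.frame with columns \code{barcode}, \code{rat_umi},
#'   \code{mouse_umi}, \code{call}.
#' @export
assignAllSpecies <- function(counts, margin = 0.05) {
    if (is(counts, "GermCellSim")) counts <- counts@counts
    if (!is(counts, "DualSpeciesCounts"))
        stop("counts must be a DualSpeciesCounts object", call. = FALSE)
    ratTot <- colSums(ratCounts(counts))
    mouseTot <- colSums(mouseCounts(counts))
    data.frame(barcode = barcodes(counts),
               rat_umi = as.numeric(ratTot),
               mouse_umi = as.numeric(mouseTot),
               call = assignSpecies(ratTot, mouseTot, margin),
               row.names = NULL)
}

#' Evaluate species calls against ground truth
#'
#' @param calls data.frame from [assignAllSpecies()].
#' @param truth per-cell ground truth with columns \code{barcode} and
#'   \code{species} covering every called barcode.
#' @return list with \code{accuracy} (correct-species calls over all
#'   cells; unknowns count as incorrect), \code{unknown_rate}, and
#'   \code{confusion} (true species x call contingency table).
#' @examples
#' calls <- data.frame(barcode = c("a", "b"),
#'     call = c("rat", "unknown"))
#' truth <- data.frame(barcode = c("a", "b"),
#'     species = c("rat", "rat"))
#' evaluateAssignment(calls, truth)$accuracy  # 0.5
#' @export
evaluateAssignment <- function(calls, truth) {
    m <- match(calls$barcode, truth$barcode)
    if (anyNA(m))
        stop("truth is missing ", sum(is.na(m)), " barcode(s)",
             call. = FALSE)
    trueSp <- truth$species[m]
    confusion <- table(truth = factor(trueSp,
                                      levels = c("rat", "mouse")),
                       call = factor(calls$call,
                                     levels = c("rat", "mouse", "unknown")))
    list(accuracy = mean(calls$call == trueSp),
         unknown_rate = mean(calls$call == "unknown"),
         confusion = confusion)
}
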