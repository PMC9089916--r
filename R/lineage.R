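#' Construct a LineageModel
#'
#' The default model encodes the textbook rat division scheme: nine mitotic
#' doublings from a single SSC through progenitor and differentiating
#' spermatogonia to type B (an approximately 500-fold expansion), one
#' further doubling into preleptotene spermatocytes, and meiosis yielding
#' four spermatids per entering spermatocyte -- 2^10 x 4 / 2 = 4,096
#' spermatids per founding stem cell.
#'
#' @param doublingsToB mitotic doublings from one SSC to type B (default 9).
#' @param progenitorDoublings how many of those occur in the progenitor
#'   phase (default 3; the remaining 6 are differentiating divisions).
#' @param doublingsBToPrelep doublings from type B into preleptotene
#'   spermatocytes (default 1).
#' @param meioticYield spermatids per spermatocyte entering meiosis
#'   (default 4).
#' @param stageNames the seven ordered stage labels.
#' @return a [LineageModel-class] object.
#' @examples
#' idealLineageCounts(lineageModel())
#' @export
lineageModel <- function(doublingsToB = 9L, progenitorDoublings = 3L,
                         doublingsBToPrelep = 1L, meioticYield = 4L,
                         stageNames = germCellStages()) {
    as_count <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
            stop(nm, " must be a single nonnegative integer", call. = FALSE)
        as.integer(x)
    }
    new("LineageModel",
        stageNames = stageNames,
        doublingsToB = as_count(doublingsToB, "doublingsToB"),
        progenitorDoublings = as_count(progenitorDoublings,
                                       "progenitorDoublings"),
        doublingsBToPrelep = as_count(doublingsBToPrelep,
                                      "doublingsBToPrelep"),
        meioticYield = as_count(meioticYield, "meioticYield"))
}

#' Ideal per-stage cell counts from one stem cell
#'
#' Propagates the division arithmetic of a [LineageModel-class]: the SSC
#' count is 1; the progenitor stage holds 2^progenitorDoublings cells; the
#' differentiating-spermatogonia stage ends at type B with 2^doublingsToB
#' cells; both spermatocyte stages hold 2^(doublingsToB +
#' doublingsBToPrelep) cells; and each spermatid stage holds that number
#' times the meiotic yield, since meiosis converts each spermatocyte into
#' \code{meioticYield} spermatids. With the defaults, 1,024 spermatocytes
#' x 4 = 4,096 spermatids.
#'
#' @param model a [LineageModel-class] object.
#' @return named integer vector of ideal counts, one per stage in order.
#' @examples
#' idealLineageCounts(lineageModel())["elongating spermatid"]  # 4096
#' @export
setMethod("idealLineageCounts", "LineageModel", function(model) {
    nB <- 2^model@doublingsToB
    nPrelep <- nB * 2^model@doublingsBToPrelep
    nSptd <- nPrelep * model@meioticYield
    counts <- c(1,
                2^model@progenitorDoublings,
                nB,
                nPrelep,
                nPrelep,
                nSptd,
                nSptd)
    names(counts) <- model@stageNames
    storage.mode(counts) <- "integer"
    counts
})
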