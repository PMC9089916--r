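#' @rdname DualSpeciesCounts-class
#' @param x a \code{DualSpeciesCounts} or \code{GermCellSim} object.
#' @export
setGeneric("ratCounts", function(x) standardGeneric("ratCounts"))

#' @rdname DualSpeciesCounts-class
#' @export
setGeneric("mouseCounts", function(x) standardGeneric("mouseCounts"))

#' @rdname DualSpeciesCounts-class
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname GermCellSim-class
#' @param x a \code{GermCellSim} object.
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname GermCellSim-class
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname idealLineageCounts
#' @export
setGeneric("idealLineageCounts",
    function(model) standardGeneric("idealLineageCounts"))

setMethod("ratCounts", "DualSpeciesCounts", function(x) x@rat)
setMethod("mouseCounts", "DualSpeciesCounts", function(x) x@mouse)
setMethod("barcodes", "DualSpeciesCounts", function(x) colnames(x@rat))

setMethod("ratCounts", "GermCellSim", function(x) x@counts@rat)
setMethod("mouseCounts", "GermCellSim", function(x) x@counts@mouse)
setMethod("barcodes", "GermCellSim", function(x) colnames(x@counts@rat))
setMethod("simTruth", "GermCellSim", function(x) x@truth)
setMethod("simConfig", "GermCellSim", function(x) x@config)

setMethod("show", "DualSpeciesCounts", function(object) {
    cat("DualSpeciesCounts:", ncol(object@rat), "cells\n")
    cat("  rat genes:  ", nrow(object@rat),
        " (", sum(object@rat), " UMIs)\n", sep = "")
    cat("  mouse genes:", nrow(object@mouse),
        " (", sum(object@mouse), " UMIs)\n", sep = "")
})

setMethod("show", "GermCellSim", function(object) {
    cat("GermCellSim:", ncol(object@counts@rat), "cells,",
        length(object@config@treatments), "treatment arm(s)\n")
    tab <- table(object@truth$species)
    cat("  species: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  seed:", object@config@seed, "\n")
})

setMethod("show", "LineageModel", function(object) {
    cat("LineageModel: ", object@doublingsToB, " doublings to type B, ",
        object@doublingsBToPrelep, " to preleptotene, meiotic yield ",
        object@meioticYield, "\n", sep = "")
    print(idealLineageCounts(object))
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig:", object@nGenesPerSpecies, "genes/species;",
        length(object@treatments), "arm(s) x", object@replicatesPerArm,
        "replicates x", object@cellsPerReplicate, "cells\n")
    cat("  arms:", paste(object@treatments, collapse = ", "), "\n")
    cat("  depth ", object@meanUmisPerCell, " UMIs, dispersion ",
        object@dispersion, ", ambient ", object@ambientRate,
        ", selection ", object@selection, ", seed ", object@seed, "\n",
        sep = "")
})

#' Construct a DualSpeciesCounts object
#'
#' @param rat,mouse genes x cells count matrices (coerced to sparse) with
#'   identical barcodes as colnames and disjoint gene names as rownames.
#' @return a [DualSpeciesCounts-class] object.
#' @examples
#' rat <- matrix(c(5L, 0L, 3L, 1L), 2, dimnames = list(c("Etv5", "Kit"),
#'     c("bc1", "bc2")))
#' mouse <- matrix(0L, 2, 2, dimnames = list(c("mGene1", "mGene2"),
#'     c("bc1", "bc2")))
#' DualSpeciesCounts(rat, mouse)
#' @export
DualSpeciesCounts <- function(rat, mouse) {
    new("DualSpeciesCounts",
        rat = as(as(as(rat, "dMatrix"), "generalMatrix"), "CsparseMatrix"),
        mouse = as(as(as(mouse, "dMatrix"), "generalMatrix"), "CsparseMatrix"))
}
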