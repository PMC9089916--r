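#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t readMM writeMM sparseMatrix
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' DualSpeciesCounts: paired UMI count matrices from a barnyard experiment
#'
#' Container for a single-cell UMI experiment aligned against two reference
#' gene universes (rat and mouse). Both matrices are genes x cells, share the
#' same barcodes in the same order, and carry disjoint gene names.
#'
#' @slot rat sparse integer matrix, rat-aligned genes x cells.
#' @slot mouse sparse integer matrix, mouse-aligned genes x cells.
#'
#' @seealso [DualSpeciesCounts()], [ratCounts()], [mouseCounts()],
#'   [barcodes()], [assignAllSpecies()]
#' @export
setClass("DualSpeciesCounts",
    representation(rat = "dgCMatrix", mouse = "dgCMatrix"))

setValidity("DualSpeciesCounts", function(object) {
    msgs <- character()
    if (!identical(colnames(object@rat), colnames(object@mouse)))
        msgs <- c(msgs, "rat and mouse matrices must share barcodes (colnames), in order")
    if (is.null(rownames(object@rat)) || is.null(rownames(object@mouse)))
        msgs <- c(msgs, "gene names (rownames) are required on both matrices")
    if (length(intersect(rownames(object@rat), rownames(object@mouse))) > 0L)
        msgs <- c(msgs, "rat and mouse gene namespaces must be disjoint")
    if (any(object@rat@x < 0) || any(object@mouse@x < 0))
        msgs <- c(msgs, "counts must be nonnegative")
    if (length(msgs)) msgs else TRUE
})

#' LineageModel: division arithmetic of the spermatogenic lineage
#'
#' Encodes the idealised clonal expansion from one spermatogonial stem cell
#' (SSC) to spermatids: mitotic doublings through progenitor and
#' differentiating spermatogonia up to type B, one further doubling into
#' preleptotene spermatocytes, and a meiotic yield of spermatids per
#' spermatocyte entering meiosis.
#'
#' @slot stageNames ordered labels of the seven germ-cell stages.
#' @slot doublingsToB integer, mitotic doublings from one SSC to type B.
#' @slot progenitorDoublings integer, how many of those doublings occur in
#'   the undifferentiated progenitor phase (the rest are differentiating
#'   spermatogonia divisions). Used only to place per-stage ideal counts.
#' @slot doublingsBToPrelep integer, doublings from type B into preleptotene.
#' @slot meioticYield integer, spermatids produced per spermatocyte
#'   entering meiosis.
#'
#' @seealso [lineageModel()], [idealLineageCounts()]
#' @export
setClass("LineageModel",
    representation(stageNames = "character",
                   doublingsToB = "integer",
                   progenitorDoublings = "integer",
                   doublingsBToPrelep = "integer",
                   meioticYield = "integer"))

setValidity("LineageModel", function(object) {
    msgs <- character()
    if (length(object@stageNames) != 7L)
        msgs <- c(msgs, "exactly seven stage names required")
    for (s in c("doublingsToB", "progenitorDoublings", "doublingsBToPrelep")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0L)
            msgs <- c(msgs, paste0(s, " must be a single nonnegative integer"))
    }
    if (object@progenitorDoublings > object@doublingsToB)
        msgs <- c(msgs, "progenitorDoublings cannot exceed doublingsToB")
    if (length(object@meioticYield) != 1L || is.na(object@meioticYield) ||
        object@meioticYield < 1L)
        msgs <- c(msgs, "meioticYield must be a positive integer")
    if (length(msgs)) msgs else TRUE
})

#' GeneratorConfig: parameters of the dual-species UMI count simulator
#'
#' Holds every knob of the synthetic experiment: gene universe size, marker
#' panels, experimental design (treatment arms x replicates x cells),
#' sequencing depth and gamma-Poisson noise, cross-species ambient
#' contamination, mitochondrial load, EpCAM-style early-stage enrichment,
#' and the planted per-arm effects (stress-program induction, cell-type
#' proportion shifts, transition-protein/protamine suppression, apoptotic
#' fractions). See [generatorConfig()] for defaults and presets.
#'
#' @slot nGenesPerSpecies integer, genes per species universe.
#' @slot markerPanels named list, cell type -> marker gene vector.
#' @slot treatments character, arm labels.
#' @slot replicatesPerArm integer.
#' @slot cellsPerReplicate integer.
#' @slot meanUmisPerCell numeric, mean UMI library size.
#' @slot libSizeSdLog numeric, lognormal sd of library sizes (log scale).
#' @slot dispersion numeric, gamma-Poisson dispersion shared across genes.
#' @slot ambientRate numeric in [0,1), expected fraction of each cell's
#'   library drawn from the other species' expression profile.
#' @slot mitoShape numeric length 2, Beta shape parameters of the per-cell
#'   mitochondrial fraction.
#' @slot epcamFactor numeric >= 1, multiplier on early-stage sampling
#'   weights when \code{selection == "epcam"}.
#' @slot selection "unselected" or "epcam".
#' @slot stageWeights named numeric length 7, baseline stage sampling
#'   weights for unselected cells.
#' @slot propConcentration numeric, Dirichlet concentration controlling
#'   replicate-to-replicate variability of stage proportions
#'   (\code{Inf} = none).
#' @slot markerFold numeric, expression boost of a marker gene in its own
#'   stage.
#' @slot progressionFold numeric, boost of transition-protein/protamine
#'   genes in round spermatids (they peak in elongating spermatids).
#' @slot stageStepSd numeric, per-gene sd of the random-walk log-expression
#'   drift between adjacent stages (gives stages broad, ordered
#'   transcriptomic signatures).
#' @slot effects named list, one entry per treatment arm; each a list with
#'   elements \code{stress_fold}, \code{stage_prop_shift},
#'   \code{spermatid_fold_down}, \code{apoptotic_fraction}.
#' @slot mouseFraction numeric in [0,1], fraction of cells that are truly
#'   mouse (endogenous germ cells escaping ablation); 0 for pure-rat runs.
#' @slot seed integer.
#'
#' @export
setClass("GeneratorConfig",
    representation(nGenesPerSpecies = "integer",
                   markerPanels = "list",
                   treatments = "character",
                   replicatesPerArm = "integer",
                   cellsPerReplicate = "integer",
                   meanUmisPerCell = "numeric",
                   libSizeSdLog = "numeric",
                   dispersion = "numeric",
                   ambientRate = "numeric",
                   mitoShape = "numeric",
                   epcamFactor = "numeric",
                   selection = "character",
                   stageWeights = "numeric",
                   propConcentration = "numeric",
                   markerFold = "numeric",
                   progressionFold = "numeric",
                   stageStepSd = "numeric",
                   effects = "list",
                   mouseFraction = "numeric",
                   seed = "integer"))

setValidity("GeneratorConfig", function(object) {
    msgs <- character()
    chkfrac <- function(x, nm, lo = 0, hi = 1) {
        if (length(x) != 1L || is.na(x) || x < lo || x > hi)
            paste0(nm, " must be a single value in [", lo, ",", hi, "]")
        else character()
    }
    msgs <- c(msgs,
        chkfrac(object@ambientRate, "ambientRate", 0, 1 - 1e-9),
        chkfrac(object@mouseFraction, "mouseFraction"))
    if (object@nGenesPerSpecies < 1L)
        msgs <- c(msgs, "nGenesPerSpecies must be positive")
    if (object@cellsPerReplicate < 1L || object@replicatesPerArm < 1L)
        msgs <- c(msgs, "cells and replicates must be positive")
    if (object@meanUmisPerCell <= 0 || object@dispersion <= 0)
        msgs <- c(msgs, "meanUmisPerCell and dispersion must be positive")
    if (object@epcamFactor < 1)
        msgs <- c(msgs, "epcamFactor must be >= 1")
    if (!object@selection %in% c("unselected", "epcam"))
        msgs <- c(msgs, "selection must be 'unselected' or 'epcam'")
    if (length(object@stageWeights) != 7L || any(object@stageWeights < 0))
        msgs <- c(msgs, "stageWeights must be seven nonnegative weights")
    if (any(object@mitoShape <= 0) || length(object@mitoShape) != 2L)
        msgs <- c(msgs, "mitoShape must be two positive Beta shapes")
    if (!all(object@treatments %in% names(object@effects)))
        msgs <- c(msgs, "every treatment needs an entry in effects")
    for (arm in names(object@effects)) {
        ef <- object@effects[[arm]]
        if (!is.null(ef$stress_fold) && any(ef$stress_fold <= 0))
            msgs <- c(msgs, "stress_fold must be strictly positive")
        if (!is.null(ef$spermatid_fold_down) && any(ef$spermatid_fold_down <= 0))
            msgs <- c(msgs, "spermatid_fold_down must be strictly positive")
        if (!is.null(ef$apoptotic_fraction) &&
            (any(ef$apoptotic_fraction < 0) || any(ef$apoptotic_fraction >= 1)))
            msgs <- c(msgs, "apoptotic_fraction must be in [0,1)")
    }
    if (length(msgs)) msgs else TRUE
})

#' GermCellSim: a simulated dual-species experiment with ground truth
#'
#' Returned by [simulateExperiment()]. Bundles the paired count matrices
#' with the per-cell ground-truth annotation (true species, stage,
#' treatment, replicate, apoptotic flag) and the generating configuration.
#' The planted per-(gene, arm, stage) log2 fold-change table is stored in
#' \code{metadata(simTruth(x))$planted_log2fc}.
#'
#' @slot counts a [DualSpeciesCounts-class] object.
#' @slot truth a [S4Vectors::DataFrame] with one row per barcode.
#' @slot config the [GeneratorConfig-class] used.
#'
#' @export
setClass("GermCellSim",
    representation(counts = "DualSpeciesCounts",
                   truth = "DataFrame",
                   config = "GeneratorConfig"))

setValidity("GermCellSim", function(object) {
    if (!identical(object@truth$barcode, barcodes(object@counts)))
        "truth must have exactly one row per barcode, in matrix order"
    else TRUE
})
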