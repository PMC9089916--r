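# Dual-species UMI count simulator.
#
# Counts are gamma-Poisson (negative binomial) per gene with a shared
# dispersion; library sizes are lognormal; each cell devotes an expected
# `ambientRate` fraction of its library to the other species' mean
# expression profile (ambient contamination); per-cell mitochondrial load
# is Beta-distributed. Stages carry broad transcriptomic signatures built
# as a per-gene random walk along the stage order, plus strong boosts of
# the stage's marker genes, so that unsupervised clustering and a linear
# pseudotime behave as they do on real spermatogenesis data.

.APOPTOSIS_FOLD <- 3      # program induction in cells flagged apoptotic
.EARLY_STAGES <- c("SSC", "progenitor", "differentiating spermatogonia")

#' Planted treatment-arm effect presets
#'
#' Named effect bundles for the six experimental arms: fresh, short-frozen
#' and long-frozen cells profiled immediately post-thaw, and the same three
#' treatments profiled after transplantation into recipient testes. Each
#' bundle fixes, relative to the fresh arm: the fold induction of the
#' cryodamage stress program in SSCs (graded short < long), additive
#' cell-type proportion shifts (transplanted long-frozen: SSC fraction up
#' 0.10, elongating-spermatid fraction down 0.10), fold suppression of
#' transition-protein/protamine genes in round spermatids (Prm1 2.8x,
#' Tnp1 2.3x and Tnp2 1.6x down in transplanted long-frozen versus fresh,
#' with intermediate values in the other transplanted arms; Prm2
#' untouched), and the apoptotic-cell fraction.
#'
#' @return named list of per-arm effect lists with elements
#'   \code{stress_fold}, \code{stage_prop_shift},
#'   \code{spermatid_fold_down}, \code{apoptotic_fraction}.
#' @export
treatmentEffects <- function() {
    eff <- function(stress = 1, shift = numeric(), folddown = numeric(),
                    apo = 0.03) {
        list(stress_fold = stress, stage_prop_shift = shift,
             spermatid_fold_down = folddown, apoptotic_fraction = apo)
    }
    list(
        fresh = eff(),
        short_frozen = eff(stress = 1.5, apo = 0.06),
        long_frozen = eff(stress = 2.25, apo = 0.09),
        transplanted_fresh = eff(
            folddown = c(Prm1 = 1.4, Tnp1 = 1.1)),
        transplanted_short_frozen = eff(
            stress = 1.25, apo = 0.05,
            folddown = c(Prm1 = 2.8 / 2.3, Tnp1 = 2.3 / 1.7,
                         Tnp2 = 1.6 / 1.4)),
        transplanted_long_frozen = eff(
            stress = 1.5, apo = 0.07,
            shift = c("SSC" = 0.10, "elongating spermatid" = -0.10),
            folddown = c(Prm1 = 2.8, Tnp1 = 2.3, Tnp2 = 1.6)))
}

#' Construct a GeneratorConfig
#'
#' All arguments have defaults describing the study conditions the package
#' emulates; see the slot documentation of [GeneratorConfig-class] and the
#' methods vignette for the rationale behind each value.
#'
#' @param nGenesPerSpecies genes per species universe (default 1000).
#' @param markerPanels stage marker panels, default [markerPanels()].
#' @param treatments treatment arm labels; each must have a matching entry
#'   in \code{effects} (defaults ship for the six arms of
#'   [treatmentEffects()]).
#' @param replicatesPerArm biological replicates per arm (default 3).
#' @param cellsPerReplicate cells per replicate (default 1000).
#' @param meanUmisPerCell mean UMI library size (default 3000).
#' @param libSizeSdLog lognormal sd of library size (default 0.35).
#' @param dispersion gamma-Poisson dispersion (default 0.3).
#' @param ambientRate expected cross-species ambient fraction
#'   (default 0.01).
#' @param mitoShape Beta shapes of the mitochondrial fraction
#'   (default c(2, 38), mean 5\%).
#' @param epcamFactor early-stage enrichment multiplier used when
#'   \code{selection = "epcam"} (default 10).
#' @param selection "unselected" or "epcam".
#' @param stageWeights baseline stage sampling weights (late-stage heavy,
#'   matching the amplifying divisions of the lineage).
#' @param propConcentration Dirichlet concentration for replicate-level
#'   proportion noise (default 225, about 2 percentage points of sd on a
#'   10\% stage; \code{Inf} disables the noise).
#' @param markerFold marker boost in its own stage (default 50).
#' @param progressionFold boost of Tnp/Prm genes in round spermatids
#'   (default 10; they peak at \code{markerFold} in elongating spermatids).
#' @param stageStepSd per-gene sd of the stage-to-stage log-expression
#'   random walk (default 0.35).
#' @param effects named per-arm effect lists, default
#'   \code{treatmentEffects()[treatments]}.
#' @param mouseFraction fraction of cells that are truly mouse (default 0).
#' @param seed integer RNG seed.
#' @return a [GeneratorConfig-class] object.
#' @examples
#' generatorConfig(cellsPerReplicate = 200, seed = 7)
#' @export
generatorConfig <- function(nGenesPerSpecies = 1000,
                            markerPanels = xenoGerm::markerPanels(),
                            treatments = c("fresh", "short_frozen",
                                           "long_frozen"),
                            replicatesPerArm = 3,
                            cellsPerReplicate = 1000,
                            meanUmisPerCell = 3000,
                            libSizeSdLog = 0.35,
                            dispersion = 0.3,
                            ambientRate = 0.01,
                            mitoShape = c(2, 38),
                            epcamFactor = 10,
                            selection = c("unselected", "epcam"),
                            stageWeights = c(
                                "SSC" = 0.02, "progenitor" = 0.03,
                                "differentiating spermatogonia" = 0.07,
                                "early spermatocyte" = 0.12,
                                "late spermatocyte" = 0.21,
                                "round spermatid" = 0.30,
                                "elongating spermatid" = 0.25),
                            propConcentration = 225,
                            markerFold = 50,
                            progressionFold = 10,
                            stageStepSd = 0.35,
                            effects = NULL,
                            mouseFraction = 0,
                            seed = 1) {
    selection <- match.arg(selection)
    if (is.null(effects)) {
        presets <- treatmentEffects()
        missing <- setdiff(treatments, names(presets))
        if (length(missing))
            stop("no shipped effect preset for arm(s): ",
                 paste(missing, collapse = ", "),
                 "; supply `effects` explicitly", call. = FALSE)
        effects <- presets[treatments]
    }
    if (is.null(names(stageWeights)))
        names(stageWeights) <- germCellStages()
    stageWeights <- stageWeights[germCellStages()]
    stageWeights <- stageWeights / sum(stageWeights)
    new("GeneratorConfig",
        nGenesPerSpecies = as.integer(nGenesPerSpecies),
        markerPanels = markerPanels,
        treatments = as.character(treatments),
        replicatesPerArm = as.integer(replicatesPerArm),
        cellsPerReplicate = as.integer(cellsPerReplicate),
        meanUmisPerCell = as.numeric(meanUmisPerCell),
        libSizeSdLog = as.numeric(libSizeSdLog),
        dispersion = as.numeric(dispersion),
        ambientRate = as.numeric(ambientRate),
        mitoShape = as.numeric(mitoShape),
        epcamFactor = as.numeric(epcamFactor),
        selection = selection,
        stageWeights = stageWeights,
        propConcentration = as.numeric(propConcentration),
        markerFold = as.numeric(markerFold),
        progressionFold = as.numeric(progressionFold),
        stageStepSd = as.numeric(stageStepSd),
        effects = effects,
        mouseFraction = as.numeric(mouseFraction),
        seed = as.integer(seed))
}

#' Build the dual-species gene universe
#'
#' Lays out two disjoint gene namespaces. The rat side carries the marker
#' panel genes, the proapoptotic and stress programs, the 13 mitochondrial
#' protein-coding genes (Mt- prefix) and anonymous filler genes
#' (RatGene0001, ...). The mouse side carries its own mitochondrial set
#' (mMt- prefix) and fillers (MouseGene0001, ...).
#'
#' @param config a [GeneratorConfig-class].
#' @return list with data.frames \code{rat} and \code{mouse}, each with
#'   columns \code{gene}, \code{is_marker}, \code{is_mito}.
#' @examples
#' head(buildGeneUniverse(generatorConfig())$rat)
#' @export
buildGeneUniverse <- function(config) {
    markers <- unique(unlist(config@markerPanels, use.names = FALSE))
    special <- unique(c(markers, proapoptoticGenes(), stressProgramGenes()))
    ratMt <- ratMitoGenes()
    n <- config@nGenesPerSpecies
    if (n < length(special) + length(ratMt))
        stop("nGenesPerSpecies (", n, ") is smaller than the ",
             length(special) + length(ratMt),
             " marker/program/mitochondrial genes", call. = FALSE)
    nFill <- n - length(special) - length(ratMt)
    ratGenes <- c(special, ratMt,
                  if (nFill) sprintf("RatGene%04d", seq_len(nFill)))
    mouseMt <- mouseMitoGenes()
    mFill <- n - length(mouseMt)
    mouseGenes <- c(mouseMt, sprintf("MouseGene%04d", seq_len(mFill)))
    if (anyDuplicated(ratGenes) || anyDuplicated(mouseGenes) ||
        length(intersect(ratGenes, mouseGenes)))
        stop("gene namespace collision", call. = FALSE)
    list(rat = data.frame(gene = ratGenes,
                          is_marker = ratGenes %in% markers,
                          is_mito = ratGenes %in% ratMt),
         mouse = data.frame(gene = mouseGenes,
                            is_marker = FALSE,
                            is_mito = mouseGenes %in% mouseMt))
}

# Stage-resolved expression profiles (proportions) for both species.
# Deterministic given config seed. Mitochondrial genes are excluded from
# the stage profiles (their share is set per cell) and returned separately.
.expressionProfiles <- function(config, universe) {
    stages <- germCellStages()
    rat <- universe$rat
    withSeed(childSeed(config@seed, "profiles"), {
        base <- stats::rlnorm(nrow(rat), meanlog = 0, sdlog = 1)
        names(base) <- rat$gene
        # markers and shipped programs get stable, comfortably detectable
        # baseline expression
        markers <- unique(unlist(config@markerPanels, use.names = FALSE))
        base[markers] <- 5
        base[proapoptoticGenes()] <- 5
        base[stressProgramGenes()] <- 5
        base[rat$is_mito] <- 0
        # broad stage signatures: per-gene random walk along the lineage;
        # the shipped gene programs are kept stage-flat so that the
        # planted arm effects are their only systematic signal
        steps <- matrix(stats::rnorm(nrow(rat) * (length(stages) - 1L),
                                     sd = config@stageStepSd),
                        nrow = nrow(rat))
        steps[rat$gene %in% c(proapoptoticGenes(),
                              stressProgramGenes()), ] <- 0
        logfc <- cbind(0, t(apply(steps, 1L, cumsum)))
        prof <- base * exp(logfc)
        dimnames(prof) <- list(rat$gene, stages)
        # marker boosts in their own stage
        for (st in stages)
            prof[config@markerPanels[[st]], st] <-
                prof[config@markerPanels[[st]], st] * config@markerFold
        # transition proteins/protamines already rise in round spermatids
        progression <- intersect(c("Tnp1", "Tnp2", "Prm1", "Prm2"),
                                 rat$gene)
        prof[progression, "round spermatid"] <-
            prof[progression, "round spermatid"] * config@progressionFold
        prof <- sweep(prof, 2L, colSums(prof), "/")
        mouseBase <- stats::rlnorm(nrow(universe$mouse), sdlog = 1)
        names(mouseBase) <- universe$mouse$gene
        mouseBase[universe$mouse$is_mito] <- 0
        mouseBase <- mouseBase / sum(mouseBase)
        ratMito <- stats::rlnorm(sum(rat$is_mito), sdlog = 0.5)
        ratMito <- ratMito / sum(ratMito)
        names(ratMito) <- rat$gene[rat$is_mito]
        mouseMito <- stats::rlnorm(sum(universe$mouse$is_mito), sdlog = 0.5)
        mouseMito <- mouseMito / sum(mouseMito)
        names(mouseMito) <- universe$mouse$gene[universe$mouse$is_mito]
        list(ratStage = prof, ratMito = ratMito,
             mouseBase = mouseBase, mouseMito = mouseMito)
    })
}

# Scale the weights of `genes` in one profile column so that their
# *normalised* proportions change by exactly `folds` (compositional
# correction: naive scaling plus renormalisation would attenuate the
# realised fold by the change in the column total).
.plantFolds <- function(col, genes, folds) {
    w <- col[genes]
    Z <- sum(col)
    A <- sum(w) / Z
    C <- sum(w * folds) / Z
    if (C >= 1)
        stop("planted folds would exceed the whole library", call. = FALSE)
    s <- (1 - A) / (1 - C)
    col[genes] <- w * s * folds
    col
}

# Apply an arm's planted expression effects to the stage profile matrix,
# renormalising columns. Planted folds are exact on the CPM scale.
# Returns the adjusted matrix plus the planted log2 fold-change records
# (relative to the fresh arm).
.applyArmEffects <- function(prof, effect, apoptotic = FALSE) {
    planted <- data.frame(gene = character(), stage = character(),
                          log2fc = numeric())
    sf <- effect$stress_fold
    if (!is.null(sf) && sf != 1) {
        sg <- intersect(stressProgramGenes(), rownames(prof))
        prof[, "SSC"] <- .plantFolds(prof[, "SSC"], sg,
                                     rep(sf, length(sg)))
        planted <- rbind(planted, data.frame(gene = sg, stage = "SSC",
                                             log2fc = log2(sf)))
    }
    fd <- effect$spermatid_fold_down
    if (length(fd)) {
        g <- intersect(names(fd), rownames(prof))
        prof[, "round spermatid"] <-
            .plantFolds(prof[, "round spermatid"], g, 1 / fd[g])
        planted <- rbind(planted,
                         data.frame(gene = g, stage = "round spermatid",
                                    log2fc = -log2(unname(fd[g]))))
    }
    if (apoptotic) {
        # qualitative induction (the contract is a higher module score,
        # not an exact fold), so plain scaling + renormalisation is fine
        ag <- intersect(proapoptoticGenes(), rownames(prof))
        prof[ag, ] <- prof[ag, ] * .APOPTOSIS_FOLD
    }
    list(prof = sweep(prof, 2L, colSums(prof), "/"), planted = planted)
}

# Stage sampling weights for one arm (selection + planted shift applied).
.armStageWeights <- function(config, effect) {
    w <- config@stageWeights
    if (config@selection == "epcam") {
        w[.EARLY_STAGES] <- w[.EARLY_STAGES] * config@epcamFactor
        w <- w / sum(w)
    }
    shift <- effect$stage_prop_shift
    if (length(shift)) {
        w[names(shift)] <- pmax(w[names(shift)] + shift, 1e-6)
        w <- w / sum(w)
    }
    w
}

# Negative-binomial draw for a dense mean matrix, in cell blocks.
.nbDraw <- function(mu, size) {
    x <- stats::rnbinom(length(mu), size = size, mu = mu)
    dim(x) <- dim(mu)
    dimnames(x) <- dimnames(mu)
    x
}

#' Simulate a dual-species germ-cell scRNA-seq experiment
#'
#' Generates seeded paired UMI count matrices (rat- and mouse-aligned) for
#' every treatment arm and replicate of the configuration, together with
#' the per-cell ground truth. See the package vignette for the generative
#' model.
#'
#' @param config a [GeneratorConfig-class].
#' @return a [GermCellSim-class] object.
#' @examples
#' sim <- simulateExperiment(generatorConfig(treatments = "fresh",
#'     replicatesPerArm = 1, cellsPerReplicate = 50, seed = 1))
#' sim
#' @export
simulateExperiment <- function(config) {
    validObject(config)
    if (config@cellsPerReplicate < 1L || config@nGenesPerSpecies < 1L)
        stop("need at least one cell and one gene", call. = FALSE)
    universe <- buildGeneUniverse(config)
    profiles <- .expressionProfiles(config, universe)
    stages <- germCellStages()
    r <- config@ambientRate
    size <- 1 / config@dispersion
    nRatGenes <- nrow(universe$rat)
    nMouseGenes <- nrow(universe$mouse)
    ratMitoIdx <- which(universe$rat$is_mito)
    mouseMitoIdx <- which(universe$mouse$is_mito)
    # average rat profile (ambient source seen by mouse cells)
    ratAvg <- as.numeric(profiles$ratStage %*% config@stageWeights)
    names(ratAvg) <- rownames(profiles$ratStage)

    plantedAll <- data.frame(gene = character(), arm = character(),
                             stage = character(), log2fc = numeric())
    ratBlocks <- list(); mouseBlocks <- list(); truthBlocks <- list()

    withSeed(config@seed, {
        for (arm in config@treatments) {
            effect <- config@effects[[arm]]
            w <- .armStageWeights(config, effect)
            adj <- .applyArmEffects(profiles$ratStage, effect)
            adjApo <- .applyArmEffects(profiles$ratStage, effect,
                                       apoptotic = TRUE)
            if (nrow(adj$planted))
                plantedAll <- rbind(plantedAll,
                                    cbind(adj$planted[, "gene", drop = FALSE],
                                          arm = arm,
                                          adj$planted[, c("stage", "log2fc")]))
            for (rep_i in seq_len(config@replicatesPerArm)) {
                n <- config@cellsPerReplicate
                wRep <- w
                if (is.finite(config@propConcentration)) {
                    g <- stats::rgamma(length(w),
                                       shape = w * config@propConcentration)
                    wRep <- g / sum(g)
                }
                nMouse <- round(config@mouseFraction * n)
                isMouse <- rep(FALSE, n)
                if (nMouse > 0)
                    isMouse[sample.int(n, nMouse)] <- TRUE
                stage <- rep(NA_character_, n)
                stage[!isMouse] <- sample(stages, n - nMouse,
                                          replace = TRUE, prob = wRep)
                apoFrac <- effect$apoptotic_fraction
                if (is.null(apoFrac)) apoFrac <- 0
                apo <- !isMouse & stats::runif(n) < apoFrac
                lib <- stats::rlnorm(n,
                    meanlog = log(config@meanUmisPerCell) -
                        config@libSizeSdLog^2 / 2,
                    sdlog = config@libSizeSdLog)
                mitoF <- stats::rbeta(n, config@mitoShape[1],
                                      config@mitoShape[2])
                bc <- sprintf("%s_rep%d_cell%04d", arm, rep_i, seq_len(n))

                # expected rat-gene means, genes x cells
                muRat <- matrix(0, nRatGenes, n,
                                dimnames = list(universe$rat$gene, bc))
                muMouse <- matrix(0, nMouseGenes, n,
                                  dimnames = list(universe$mouse$gene, bc))
                ratIdx <- which(!isMouse)
                if (length(ratIdx)) {
                    P <- adj$prof[, stage[ratIdx], drop = FALSE]
                    if (any(apo[ratIdx]))
                        P[, apo[ratIdx]] <-
                            adjApo$prof[, stage[ratIdx][apo[ratIdx]],
                                        drop = FALSE]
                    own <- lib[ratIdx] * (1 - r)
                    muRat[, ratIdx] <-
                        sweep(P, 2L, own * (1 - mitoF[ratIdx]), "*")
                    muRat[ratMitoIdx, ratIdx] <-
                        muRat[ratMitoIdx, ratIdx] +
                        outer(profiles$ratMito, own * mitoF[ratIdx])
                    muMouse[, ratIdx] <-
                        outer(profiles$mouseBase, lib[ratIdx] * r)
                }
                mouIdx <- which(isMouse)
                if (length(mouIdx)) {
                    own <- lib[mouIdx] * (1 - r)
                    muMouse[, mouIdx] <-
                        outer(profiles$mouseBase,
                              own * (1 - mitoF[mouIdx]))
                    muMouse[mouseMitoIdx, mouIdx] <-
                        muMouse[mouseMitoIdx, mouIdx] +
                        outer(profiles$mouseMito, own * mitoF[mouIdx])
                    muRat[, mouIdx] <- outer(ratAvg, lib[mouIdx] * r)
                }
                ratBlocks[[length(ratBlocks) + 1L]] <-
                    Matrix(.nbDraw(muRat, size), sparse = TRUE)
                mouseBlocks[[length(mouseBlocks) + 1L]] <-
                    Matrix(.nbDraw(muMouse, size), sparse = TRUE)
                truthBlocks[[length(truthBlocks) + 1L]] <- DataFrame(
                    barcode = bc,
                    species = ifelse(isMouse, "mouse", "rat"),
                    stage = stage,
                    treatment = arm,
                    replicate = sprintf("%s_rep%d", arm, rep_i),
                    apoptotic = apo,
                    mito_fraction = mitoF,
                    lib_size = lib)
            }
        }
    })
    ratMat <- do.call(cbind, ratBlocks)
    mouseMat <- do.call(cbind, mouseBlocks)
    truth <- do.call(rbind, truthBlocks)
    metadata(truth)$planted_log2fc <- plantedAll
    new("GermCellSim",
        counts = DualSpeciesCounts(ratMat, mouseMat),
        truth = truth,
        config = config)
}

#' Resample a cell population with EpCAM-style early-stage enrichment
#'
#' Emulates magnetic enrichment for an early-stage surface marker:
#' sampling weights of SSC, progenitor and differentiating-spermatogonia
#' cells are multiplied by \code{config@epcamFactor} and the population is
#' resampled (with replacement) to its original size. A population
#' containing no early-stage cells, or a factor of exactly 1, is returned
#' unchanged.
#'
#' @param truth per-cell ground truth (rows of [simTruth()]).
#' @param config a [GeneratorConfig-class]; only \code{epcamFactor} is
#'   used.
#' @return a DataFrame of the same number of rows.
#' @export
applyEpcamEnrichment <- function(truth, config) {
    factor <- config@epcamFactor
    if (factor < 1)
        stop("enrichment factor must be >= 1", call. = FALSE)
    early <- !is.na(truth$stage) & truth$stage %in% .EARLY_STAGES
    if (factor == 1 || !any(early))
        return(truth)
    w <- ifelse(early, factor, 1)
    idx <- withSeed(childSeed(config@seed, "epcam"),
                    sample.int(nrow(truth), nrow(truth),
                               replace = TRUE, prob = w))
    truth[idx, , drop = FALSE]
}

#' Simulate the pure-species validation experiment
#'
#' Generates pure-rat and pure-mouse cell populations under identical
#' settings, the design used to validate the species-assignment margin
#' rule: every cell's true species is known, and the only wrong-species
#' signal is ambient contamination.
#'
#' @param nRat,nMouse number of pure rat / pure mouse cells.
#' @param ambientRate cross-species ambient fraction (default 0.01).
#' @param seed integer seed.
#' @param ... further arguments passed to [generatorConfig()].
#' @return a [GermCellSim-class] object with \code{nRat + nMouse} cells.
#' @examples
#' sim <- simulateSpeciesValidation(100, 100, seed = 1)
#' table(simTruth(sim)$species)
#' @export
simulateSpeciesValidation <- function(nRat = 10000, nMouse = 10000,
                                      ambientRate = 0.01, seed = 1, ...) {
    n <- nRat + nMouse
    config <- generatorConfig(treatments = "fresh", replicatesPerArm = 1,
                              cellsPerReplicate = n,
                              ambientRate = ambientRate,
                              mouseFraction = nMouse / n,
                              seed = seed, ...)
    simulateExperiment(config)
}
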