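#' Run the full dual-species germ-cell analysis pipeline
#'
#' Orchestrates every stage on a simulated (or supplied) experiment:
#' species assignment and rat-cell selection, QC filtering, CPM log
#' normalisation, clustering and marker-panel cell typing, linear
#' pseudotime, SSC pseudobulk PCA + PERMANOVA, pairwise differential
#' expression with DEG-set overlaps, apoptosis module scoring, and
#' cell-type proportion ANOVA. Stages that need a design the data cannot
#' support (e.g. PERMANOVA with a single arm) are skipped and recorded
#' as such in the report. The whole run is deterministic given the
#' configuration seed.
#'
#' @param x a [GeneratorConfig-class] (the experiment is simulated) or a
#'   ready [GermCellSim-class].
#' @param margin species-assignment margin (default 0.05).
#' @param mito_max,min_genes,min_umi QC thresholds (defaults 20\%, 200,
#'   500).
#' @param k number of clusters (default 14).
#' @param fc_min,padj_max DEG cutoffs (defaults 1.5, 0.05).
#' @param module_cutoff apoptosis score cutoff (default 0.1).
#' @param n_permutations PERMANOVA permutations (default 1000).
#' @param permanova_cell_type cell type pseudobulked for PERMANOVA
#'   (default "SSC").
#' @param pooling_spec pooled-group design for PERMANOVA; default pools
#'   any arms containing "frozen" against the rest when possible,
#'   otherwise treatments are used as-is.
#' @param de_cell_type cell type(s) for the DE comparisons (default "SSC");
#'   one report section per type.
#' @param out_dir optional directory; when given, annotations, DEG
#'   tables, proportions (TSV) and the report (JSON) are written there.
#' @param enable_de set \code{FALSE} to skip the DE stage.
#' @return a list report with one element per executed stage.
#' @examples
#' cfg <- generatorConfig(treatments = c("fresh", "long_frozen"),
#'     replicatesPerArm = 2, cellsPerReplicate = 150,
#'     nGenesPerSpecies = 200, seed = 42)
#' rep <- runPipeline(cfg)
#' names(rep)
#' @export
runPipeline <- function(x, margin = 0.05, mito_max = 20,
                        min_genes = 200, min_umi = 500, k = 14,
                        fc_min = 1.5, padj_max = 0.05,
                        module_cutoff = 0.1, n_permutations = 1000,
                        permanova_cell_type = "SSC",
                        pooling_spec = NULL, de_cell_type = "SSC",
                        out_dir = NULL, enable_de = TRUE) {
    sim <- if (is(x, "GeneratorConfig")) simulateExperiment(x) else x
    if (!is(sim, "GermCellSim"))
        stop("[input] x must be a GeneratorConfig or GermCellSim",
             call. = FALSE)
    seed <- simConfig(sim)@seed
    truth <- as.data.frame(simTruth(sim))
    report <- list(config = list(seed = seed, margin = margin,
                                 mito_max = mito_max,
                                 min_genes = min_genes,
                                 min_umi = min_umi, k = k,
                                 fc_min = fc_min, padj_max = padj_max,
                                 module_cutoff = module_cutoff,
                                 n_permutations = n_permutations))

    ## species assignment: keep rat cells only
    calls <- assignAllSpecies(sim, margin = margin)
    report$species <- evaluateAssignment(calls, truth)
    ratBc <- calls$barcode[calls$call == "rat"]
    counts <- ratCounts(sim)[, ratBc, drop = FALSE]

    ## QC
    metrics <- qcMetrics(counts, ratMitoGenes())
    kept <- filterCells(metrics, mito_max = mito_max,
                        min_genes = min_genes, min_umi = min_umi)
    report$qc <- list(n_rat_cells = length(ratBc),
                      n_kept = length(kept),
                      n_removed = length(ratBc) - length(kept))
    if (length(kept) < 2L)
        stop("[qc] fewer than two cells survive filtering",
             call. = FALSE)
    counts <- counts[, kept, drop = FALSE]

    ## normalisation, clustering, typing, pseudotime
    normalized <- normalizeCpmLog(counts)
    clusters <- clusterCells(normalized, k = min(k, ncol(normalized)),
                             seed = seed)
    scores <- scoreMarkerPanels(normalized,
                                simConfig(sim)@markerPanels)
    cellType <- annotateCells(clusters, scores)
    pt <- linearPseudotime(normalized)
    idx <- match(kept, truth$barcode)
    annotations <- data.frame(
        barcode = kept,
        species = "rat",
        n_genes = metrics$n_genes[match(kept, metrics$barcode)],
        n_umi = metrics$n_umi[match(kept, metrics$barcode)],
        pct_mito = metrics$pct_mito[match(kept, metrics$barcode)],
        cluster = as.integer(clusters),
        cell_type = cellType,
        pseudotime = as.numeric(pt),
        treatment = truth$treatment[idx],
        replicate = truth$replicate[idx],
        row.names = NULL)
    report$typing <- list(
        type_counts = table(annotations$cell_type),
        accuracy_vs_truth = mean(cellType == truth$stage[idx],
                                 na.rm = TRUE))

    ## pseudobulk PCA + PERMANOVA on the SSC compartment
    arms <- unique(annotations$treatment)
    report$permanova <- tryCatch({
        pb <- suppressWarnings(
            pseudobulk(normalized, annotations, permanova_cell_type))
        pca <- pcaPseudobulk(pb$matrix)
        if (is.null(pooling_spec)) {
            frozen <- grep("frozen", arms, value = TRUE)
            pooling_spec <- if (length(frozen) && length(frozen) < length(arms))
                list(fresh = setdiff(arms, frozen), frozen = frozen)
            else stats::setNames(as.list(arms), arms)
        }
        groups <- pooledGroupDesign(pb$samples$treatment, pooling_spec)
        pm <- if (length(unique(groups)) >= 2L)
            permanova(distanceMatrix(pb$matrix), groups,
                      n_permutations = n_permutations, seed = seed)
        else list(skipped = "fewer than two pooled groups")
        c(pm, list(variance_pct = pca$variance_pct,
                   samples = pb$samples))
    }, error = function(e) list(skipped = conditionMessage(e)))

    ## differential expression: every arm versus the first, per cell type
    if (enable_de && length(arms) >= 2L) {
        ref <- arms[1]
        report$de <- list()
        for (ct in de_cell_type) {
            degs <- list()
            for (arm in arms[-1]) {
                res <- tryCatch(
                    wilcoxonDE(normalized, annotations, arm, ref,
                               cell_type = ct,
                               fc_min = fc_min, padj_max = padj_max),
                    error = function(e) NULL)
                if (!is.null(res))
                    degs[[paste0(arm, "_vs_", ref)]] <- res
            }
            section <- list(
                deg_counts = vapply(degs, function(d)
                    sum(d$significant), integer(1)),
                tables = degs)
            if (length(degs) >= 2L)
                section$overlap <- overlapSets(
                    lapply(degs, function(d) d$gene[d$significant]))
            report$de[[ct]] <- section
        }
    }

    ## apoptosis module score and classification
    report$apoptosis <- tryCatch({
        sc <- moduleScore(normalized, proapoptoticGenes(),
                          seed = seed)
        cls <- classifyApoptotic(sc, cutoff = module_cutoff,
                                 annotations = annotations)
        list(n_apoptotic = sum(cls$flag), fractions = cls$fractions)
    }, error = function(e) list(skipped = conditionMessage(e)))

    ## cell-type proportions and per-type ANOVA
    props <- celltypeProportions(annotations)
    report$proportions <- list(table = props)
    trCounts <- table(unique(props[c("treatment", "replicate")])$treatment)
    if (length(trCounts) >= 2L && all(trCounts >= 2L))
        report$proportions$anova <- anovaPerCelltype(props)

    report$annotations <- annotations
    if (!is.null(out_dir)) .writeReport(report, out_dir)
    report
}

# write the machine-readable outputs of a pipeline run
.writeReport <- function(report, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(d, f) utils::write.table(d, file.path(out_dir, f),
        sep = "\t", quote = FALSE, row.names = FALSE)
    tsv(report$annotations, "annotations.tsv")
    tsv(report$proportions$table, "proportions.tsv")
    for (ct in names(report$de))
        for (nm in names(report$de[[ct]]$tables))
            tsv(report$de[[ct]]$tables[[nm]],
                paste0("deg_", gsub("[^A-Za-z0-9]+", "_", ct),
                       "_", nm, ".tsv"))
    slim <- report
    slim$annotations <- NULL
    for (ct in names(slim$de)) slim$de[[ct]]$tables <- NULL
    slim$species$confusion <- as.data.frame(report$species$confusion)
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(out_dir)
}
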