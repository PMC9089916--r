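#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads \code{matrix.mtx} (genes x cells, integer coordinate format),
#' \code{features.tsv} (gene names, first column) and
#' \code{barcodes.tsv} from a directory and returns a named sparse
#' count matrix. Dimensions are validated against the TSV files and
#' non-integer entries are rejected.
#'
#' @param dir directory holding \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return sparse genes x cells integer count matrix.
#' @export
readCountsMTX <- function(dir) {
    paths <- file.path(dir, c("matrix.mtx", "features.tsv",
                              "barcodes.tsv"))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("missing file(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
    mat <- as(Matrix::readMM(paths[1]), "CsparseMatrix")
    # reject silently truncated coordinate files: the body must hold
    # exactly the declared number of entries
    lines <- readLines(paths[1])
    body <- lines[!startsWith(lines, "%")]
    body <- body[nzchar(trimws(body))]
    declared <- scan(text = body[1], quiet = TRUE)[3]
    if (length(body) - 1L != declared)
        stop("matrix.mtx declares ", declared, " entries but contains ",
             length(body) - 1L, call. = FALSE)
    features <- utils::read.table(paths[2], sep = "\t",
                                  stringsAsFactors = FALSE)[, 1]
    bcs <- utils::read.table(paths[3], sep = "\t",
                             stringsAsFactors = FALSE)[, 1]
    if (nrow(mat) != length(features) || ncol(mat) != length(bcs))
        stop("matrix dimensions (", nrow(mat), " x ", ncol(mat),
             ") do not match features (", length(features),
             ") / barcodes (", length(bcs), ")", call. = FALSE)
    if (any(mat@x != round(mat@x)) || any(mat@x < 0))
        stop("counts must be nonnegative integers", call. = FALSE)
    dimnames(mat) <- list(features, bcs)
    mat
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Writes \code{matrix.mtx} (genes x cells coordinate format, 1-based
#' indices), \code{features.tsv} and \code{barcodes.tsv} into a
#' directory (created if needed).
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCountsMTX <- function(counts, dir) {
    if (length(counts) == 0L)
        stop("refusing to write an empty matrix", call. = FALSE)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry gene and barcode names", call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create ", dir, call. = FALSE)
    Matrix::writeMM(as(as(counts, "dMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Write a simulated experiment to disk
#'
#' Emits the standard exchange layout: one MTX triplet per species
#' alignment (\code{rat/}, \code{mouse/}), the ground truth as
#' \code{truth.tsv}, and a flat YAML echo of the generator
#' configuration.
#'
#' @param sim a [GermCellSim-class].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeCountsMTX(ratCounts(sim), file.path(dir, "rat"))
    writeCountsMTX(mouseCounts(sim), file.path(dir, "mouse"))
    utils::write.table(as.data.frame(simTruth(sim)),
                       file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeConfigYaml(simConfig(sim), file.path(dir, "config.yaml"))
    invisible(dir)
}

#' Echo a GeneratorConfig as flat YAML
#'
#' Scalar and vector parameters are written as a flat key/value YAML
#' document; marker panels and effect bundles as nested maps.
#'
#' @param config a [GeneratorConfig-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeConfigYaml <- function(config, path) {
    slots <- slotNames(config)
    values <- lapply(slots, function(s) {
        v <- slot(config, s)
        if (is.numeric(v) && any(!is.finite(v))) v <- as.character(v)
        v
    })
    names(values) <- slots
    yaml::write_yaml(values, path)
    invisible(path)
}

#' Read pipeline thresholds and generator settings from YAML
#'
#' @param path YAML file with flat keys matching [generatorConfig()]
#'   and/or [runPipeline()] arguments.
#' @return named list.
#' @export
readConfigYaml <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    yaml::read_yaml(path)
}
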