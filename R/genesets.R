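#' Canonical germ-cell stage order
#'
#' The seven transcriptional states of spermatogenesis used throughout the
#' package, ordered along differentiation: spermatogonial stem cells (SSC),
#' undifferentiated progenitors, differentiating spermatogonia, early
#' (preleptotene--zygotene) spermatocytes, late (pachytene--secondary)
#' spermatocytes, round spermatids and elongating spermatids.
#'
#' @return character vector of length 7.
#' @export
germCellStages <- function() {
    c("SSC", "progenitor", "differentiating spermatogonia",
      "early spermatocyte", "late spermatocyte",
      "round spermatid", "elongating spermatid")
}

#' Default marker panels for germ-cell typing
#'
#' One gene panel per stage: Etv5/Ret for SSCs; Sall4/Uchl1/Crabp1 for
#' progenitors; Kit for differentiating spermatogonia; Stra8/Mei1 (meiotic
#' entry) plus Sycp3/Tex101 (leptotene/zygotene) for early spermatocytes;
#' Piwil1 for pachytene-dominated late spermatocytes; Acrv1/Catsper3 for
#' round spermatids; transition proteins (Tnp1, Tnp2) and protamines
#' (Prm1, Prm2) for elongating spermatids.
#'
#' @return named list, stage -> character vector of marker genes.
#' @export
markerPanels <- function() {
    list(
        "SSC" = c("Etv5", "Ret"),
        "progenitor" = c("Sall4", "Uchl1", "Crabp1"),
        "differentiating spermatogonia" = "Kit",
        "early spermatocyte" = c("Stra8", "Mei1", "Sycp3", "Tex101"),
        "late spermatocyte" = "Piwil1",
        "round spermatid" = c("Acrv1", "Catsper3"),
        "elongating spermatid" = c("Tnp1", "Tnp2", "Prm1", "Prm2"))
}

#' Proapoptotic gene program
#'
#' The 38-gene proapoptotic program used for per-cell apoptosis module
#' scoring (caspases, Bcl-2 family sensitisers/effectors, death receptors
#' and their adaptors, and apoptotic nucleases).
#'
#' @return character vector of 38 gene symbols.
#' @seealso [moduleScore()], [classifyApoptotic()]
#' @export
proapoptoticGenes <- function() {
    c("Acin1", "Apaf1", "Bad", "Bak1", "Bax", "Bcl2l11", "Bcl2l14", "Bid",
      "Bik", "Bmf", "Bnip3l", "Bok", "Casp2", "Casp3", "Casp6", "Casp7",
      "Casp8", "Casp9", "Casp12", "Dapk1", "Dapk2", "Dapk3", "Dedd",
      "Dffa", "Diablo", "Ercc2", "Ercc3", "Fas", "Faslg", "Foxo3", "Tnf",
      "Tnfrsf10b", "Tnfrsf1a", "Tnfrsf1b", "Tnfsf14", "Tp53", "Tradd",
      "Traf3")
}

#' Cryodamage stress-response program planted by the generator
#'
#' Immediate-early and heat-shock genes whose induction the simulator
#' plants in frozen-arm stem cells, mimicking a cryopreservation stress
#' signature.
#'
#' @return character vector of 20 gene symbols.
#' @export
stressProgramGenes <- function() {
    c("Hspa1a", "Hspa1b", "Hspa5", "Hspa8", "Hsp90aa1", "Hsp90ab1",
      "Dnajb1", "Fos", "Jun", "Junb", "Egr1", "Atf3", "Ier2", "Ier3",
      "Dusp1", "Socs3", "Klf6", "Zfp36", "Btg2", "Ubc")
}

# the 13 protein-coding mitochondrial genes; rat-side names
ratMitoGenes <- function() {
    paste0("Mt-", c("nd1", "nd2", "nd3", "nd4", "nd4l", "nd5", "nd6",
                    "co1", "co2", "co3", "atp6", "atp8", "cytb"))
}

mouseMitoGenes <- function() {
    paste0("mMt-", c("nd1", "nd2", "nd3", "nd4", "nd4l", "nd5", "nd6",
                     "co1", "co2", "co3", "atp6", "atp8", "cytb"))
}
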