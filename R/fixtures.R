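#' Curated ER-alpha/LSD1 interactor-to-miRNA correspondence map
#'
#' Machine-readable transcription of the curated correspondence between
#' immunoprecipitation bait interactors (ER-alpha and LSD1 pulldowns,
#' under-/over-represented after MC3324 treatment of MCF-7 cells) and the
#' differentially expressed miRNAs predicted to target them. One row per
#' (bait block, gene); `mirnas` is semicolon-joined. miRNA identifiers are
#' opaque strings reproduced exactly as curated (including the
#' `miR-181c-5` spelling in the TANC2 row).
#'
#' @return `data.frame` with columns `bait`, `direction` (`down` = bait
#'   interactor under-represented after treatment), `gene_id`, `mirnas`.
#' @seealso [interactorFixtureInputs()] to expand the map into runnable
#'   pipeline inputs.
#' @export
curatedInteractorMap <- function() {
    read.delim(system.file("extdata", "erlsd1_interactor_mirna_map.tsv",
                           package = "mirCascade"),
               stringsAsFactors = FALSE)
}

#' Expand the curated interactor map into overlay inputs
#'
#' Builds a consistent set of integration inputs from
#' [curatedInteractorMap()]: an interactome table (24 h records; the three
#' genes reported as shared ER-alpha *and* LSD1 interactors — TBC1D1,
#' TBC1D9, USP32 — carry records for both baits), a retained consensus
#' table containing every curated (miRNA, gene) pair, a miRNA DE table in
#' which miRNAs from the down blocks are up-regulated and vice versa
#' (anti-correlation), and a gene DE table with the matching fold-change
#' signs.
#'
#' @param sharedGenes genes associated with both baits in the underlying
#'   pulldowns (default the curated trio).
#' @return list with elements `interactome`, `consensus`, `mirnaDe`,
#'   `geneDe`, `map`.
#' @export
interactorFixtureInputs <- function(sharedGenes = c("TBC1D1", "TBC1D9",
                                                    "USP32")) {
    map <- curatedInteractorMap()
    rep <- ifelse(map$direction == "down", "under", "over")
    interactome <- data.frame(bait = map$bait, gene_id = map$gene_id,
                              timepoint_h = 24, representation = rep,
                              log10_intensity = 5, stringsAsFactors = FALSE)
    for (g in sharedGenes) {
        have <- interactome$bait[interactome$gene_id == g]
        for (b in setdiff(c("ERalpha", "LSD1"), have)) {
            interactome <- rbind(interactome, data.frame(
                bait = b, gene_id = g, timepoint_h = 24,
                representation = "under", log10_intensity = 5,
                stringsAsFactors = FALSE))
        }
    }
    interactome <- unique(interactome)

    pairs <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
        data.frame(mirna_id = splitIds(map$mirnas[i])[[1L]],
                   gene_id = map$gene_id[i],
                   direction = map$direction[i], stringsAsFactors = FALSE)
    }))
    pairs <- unique(pairs)
    consensus <- data.frame(mirna_id = pairs$mirna_id,
                            gene_id = pairs$gene_id,
                            hit = 4L, oe_ratio = 2, retained = TRUE,
                            stringsAsFactors = FALSE)
    # anti-correlation: miRNAs listed against down genes are up, and v.v.
    mdir <- tapply(ifelse(pairs$direction == "down", "up", "down"),
                   pairs$mirna_id, function(d) unique(d)[1L])
    mirnaDe <- data.frame(mirna_id = names(mdir),
                          direction = as.character(mdir),
                          stringsAsFactors = FALSE)
    gdir <- tapply(map$direction, map$gene_id, function(d) unique(d)[1L])
    geneDe <- data.frame(gene_id = names(gdir),
                         log2fc = ifelse(gdir == "down", -1, 1),
                         stringsAsFactors = FALSE)
    list(interactome = interactome, consensus = consensus,
         mirnaDe = mirnaDe, geneDe = geneDe, map = map)
}

#' Clinical and IHC features of the 18-patient breast-cancer cohort
#'
#' Transcription of the cohort's printed clinical annotations: cytology,
#' histology, grade, staging, PR percentage (with the verbatim printed
#' value in `pr_raw`; the printed "<5" for PT15 is carried numerically as
#' 4, any value in (1, 5) yields the same receptor classes) and HER2 IHC
#' score. Per-patient ER and Ki67 percentages were reported only
#' graphically and are NOT transcribed: `er_group` carries the published
#' ER-alpha grouping (patients 4, 7, 8, 13 and 14 negative), and `er_pct`
#' is a synthetic placeholder (80 / 0) consistent with that grouping, as
#' the filename records; `ki67_pct` is `NA`.
#'
#' @return `data.frame` with one row per patient.
#' @export
bcPatientTable <- function() {
    read.delim(system.file("extdata", "bc_cohort_ihc_synthetic_er.tsv",
                           package = "mirCascade"),
               stringsAsFactors = FALSE,
               colClasses = c(pr_raw = "character", cytology = "character"))
}
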