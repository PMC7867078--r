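.readTsv <- function(path, required, numeric = character(), what = "table") {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0) stop("empty ", what, " file: ", path)
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"))
    if (!nrow(d)) stop("no data rows in ", what, " file: ", path)
    missing <- setdiff(required, colnames(d))
    if (length(missing))
        stop("missing column(s) in ", path, ": ",
             paste(missing, collapse = ", "))
    for (col in numeric) {
        v <- d[[col]]
        if (is.character(v)) {
            num <- suppressWarnings(as.numeric(v))
            bad <- which(!is.na(v) & is.na(num))
            if (length(bad))
                stop("unparsable numeric in ", path, ", column '", col,
                     "', line ", bad[1L] + 1L, ": '", v[bad[1L]], "'")
            d[[col]] <- num
        }
    }
    message("read ", nrow(d), " rows x ", ncol(d), " cols from ", path)
    d
}

#' Read a CT matrix and sample sheet into a CtExperiment
#'
#' The CT matrix TSV has first column `mirna_id` and one column per
#' sample; missing CT values are empty cells or `NA`. The companion sample
#' sheet has columns `sample_id`, `condition` (`control`/`treated`) and
#' `replicate`.
#'
#' @param ctPath path to the CT matrix TSV.
#' @param samplesPath path to the sample sheet TSV.
#' @param referenceAssays reference assay ids (optional).
#' @return a [CtExperiment-class].
#' @export
readCtMatrix <- function(ctPath, samplesPath, referenceAssays = character()) {
    d <- .readTsv(ctPath, "mirna_id", what = "CT matrix")
    if (anyDuplicated(d$mirna_id))
        stop("duplicate mirna_id in ", ctPath, ": ",
             paste(unique(d$mirna_id[duplicated(d$mirna_id)]),
                   collapse = ", "))
    ss <- .readTsv(samplesPath, c("sample_id", "condition", "replicate"),
                   numeric = "replicate", what = "sample sheet")
    bad <- setdiff(unique(ss$condition), c("control", "treated"))
    if (length(bad))
        stop("unknown condition label(s) in ", samplesPath, ": ",
             paste(bad, collapse = ", "))
    ct <- as.matrix(d[, setdiff(colnames(d), "mirna_id"), drop = FALSE])
    if (!is.numeric(ct)) stop("non-numeric CT values in ", ctPath)
    rownames(ct) <- d$mirna_id
    missing <- setdiff(ss$sample_id, colnames(ct))
    if (length(missing))
        stop("sample(s) in sheet but not in CT matrix: ",
             paste(missing, collapse = ", "))
    ct <- ct[, ss$sample_id, drop = FALSE]
    CtExperiment(ct, ss$condition, ss$replicate, referenceAssays)
}

#' Read a per-tool miRNA target prediction table
#' @param path TSV with columns `tool`, `mirna_id`, `gene_id`.
#' @return validated `data.frame`.
#' @export
readPredictionTable <- function(path)
    .readTsv(path, c("tool", "mirna_id", "gene_id"), what = "prediction")

#' Read a validated miRNA-gene pair table
#' @param path TSV with columns `mirna_id`, `gene_id`.
#' @return validated `data.frame`.
#' @export
readValidatedPairs <- function(path)
    .readTsv(path, c("mirna_id", "gene_id"), what = "validated pairs")

#' Read a transcriptome DE table
#' @param path TSV with columns `gene_id`, `log2fc`.
#' @return validated `data.frame`.
#' @export
readGeneDeTable <- function(path)
    .readTsv(path, c("gene_id", "log2fc"), numeric = "log2fc",
             what = "gene DE")

#' Read a bait interactome table
#' @param path TSV with columns `bait`, `gene_id`, `timepoint_h`,
#'   `representation`, `log10_intensity`.
#' @return validated `data.frame`.
#' @export
readInteractomeTable <- function(path) {
    d <- .readTsv(path, c("bait", "gene_id", "timepoint_h",
                          "representation"),
                  numeric = "timepoint_h", what = "interactome")
    bad <- setdiff(unique(d$representation), c("under", "over"))
    if (length(bad))
        stop("unknown representation label(s) in ", path, ": ",
             paste(bad, collapse = ", "))
    if (anyDuplicated(d[, c("bait", "gene_id", "timepoint_h")]))
        stop("duplicate (bait, gene, timepoint) record(s) in ", path)
    d
}

#' Read a paired-cohort measurement table
#' @param path TSV with columns `patient_id`, `tissue`, `treatment`,
#'   `mirna_id`, `value`.
#' @return validated `data.frame`.
#' @export
readCohortTable <- function(path) {
    d <- .readTsv(path, c("patient_id", "tissue", "treatment", "value"),
                  numeric = "value", what = "cohort")
    bad <- setdiff(unique(d$tissue), c("tumor", "normal"))
    if (length(bad))
        stop("unknown tissue label(s) in ", path, ": ",
             paste(bad, collapse = ", "))
    d
}

#' Read an IHC parameter table
#' @param path TSV with columns `patient_id`, `er_pct`, `pr_pct`,
#'   `ki67_pct`, `her2_score`.
#' @return validated `data.frame`.
#' @export
readIhcTable <- function(path)
    .readTsv(path, c("patient_id", "er_pct", "pr_pct", "ki67_pct",
                     "her2_score"),
             numeric = c("er_pct", "pr_pct", "ki67_pct", "her2_score"),
             what = "IHC")

#' Read a curated miRNA set (one identifier per line)
#' @param path text file, one miRNA id per line.
#' @return character vector.
#' @export
readMirnaSet <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- trimws(readLines(path))
    x[nzchar(x)]
}

#' Read gene sets in GMT format
#'
#' GMT lines are tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, integer(1)) < 3L
    if (any(short))
        stop("GMT line(s) with fewer than 3 fields in ", path, ": line ",
             which(short)[1L])
    setNames(lapply(parts, function(p) unique(trimws(p[-(1:2)]))),
             vapply(parts, `[`, "", 1L))
}

#' Write a table as TSV
#'
#' UTF-8, tab-separated, header row, no quoting, `NA` as empty cell — the
#' format every reader in the package accepts back (round-trip property).
#'
#' @param x `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsvTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}

#' Write bona fide interactors as bait/direction blocks
#'
#' Serializes an [overlayInteractome()] table in the block layout of the
#' curated interactor map: one row per (bait, direction, gene) with
#' semicolon-joined miRNAs.
#'
#' @param bonaFide table from [overlayInteractome()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeInteractorBlocks <- function(bonaFide, path) {
    rows <- do.call(rbind, lapply(seq_len(nrow(bonaFide)), function(i) {
        baits <- splitIds(bonaFide$baits[i])[[1L]]
        data.frame(bait_direction_block = paste(baits,
                                                bonaFide$direction[i],
                                                sep = "_"),
                   gene_id = bonaFide$gene_id[i],
                   mirnas = bonaFide$mirnas[i], stringsAsFactors = FALSE)
    }))
    writeTsvTable(rows[order(rows$bait_direction_block, rows$gene_id), ],
                  path)
}
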