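# Independent brute-force oracles and random-instance generators used by
# the property tests. These deliberately avoid the package's own code
# paths (plain loops and enumeration only).

# count distinct supporting tools (+1 if validated) by direct looping
bruteHits <- function(predictions, validated = NULL) {
    pairs <- unique(predictions[, c("mirna_id", "gene_id")])
    hit <- integer(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        sel <- predictions$mirna_id == pairs$mirna_id[i] &
               predictions$gene_id == pairs$gene_id[i]
        hit[i] <- length(unique(predictions$tool[sel]))
        if (!is.null(validated) &&
            any(validated$mirna_id == pairs$mirna_id[i] &
                validated$gene_id == pairs$gene_id[i]))
            hit[i] <- hit[i] + 1L
    }
    pairs$hit <- hit
    pairs[order(pairs$mirna_id, pairs$gene_id), , drop = FALSE]
}

randomPredictionInstance <- function(nPairs = 30, nTools = 5,
                                     nMirnas = 6, nGenes = 12) {
    data.frame(
        tool = sample(sprintf("t%d", seq_len(nTools)), nPairs, TRUE),
        mirna_id = sample(sprintf("m%d", seq_len(nMirnas)), nPairs, TRUE),
        gene_id = sample(sprintf("g%d", seq_len(nGenes)), nPairs, TRUE),
        stringsAsFactors = FALSE)
}

# exhaustive set-intersection enumeration of the anti-correlation match
bruteAnticorrelated <- function(geneDe, consensus, mirnaDe) {
    mdir <- setNames(mirnaDe$direction, mirnaDe$mirna_id)
    down <- character(); up <- character()
    for (i in seq_len(nrow(geneDe))) {
        g <- geneDe$gene_id[i]
        gdir <- if (geneDe$log2fc[i] < 0) "down" else "up"
        sup <- consensus[consensus$gene_id == g &
                         consensus$retained, , drop = FALSE]
        dirs <- mdir[sup$mirna_id]
        if (gdir == "down" && any(dirs == "up", na.rm = TRUE))
            down <- c(down, g)
        if (gdir == "up" && any(dirs == "down", na.rm = TRUE))
            up <- c(up, g)
    }
    list(down = sort(down), up = sort(up))
}

randomIntegrationInstance <- function(nGenes = 30, nMirnas = 10) {
    genes <- sprintf("g%d", seq_len(nGenes))
    mirnas <- sprintf("m%d", seq_len(nMirnas))
    geneDe <- data.frame(gene_id = genes,
                         log2fc = rnorm(nGenes), stringsAsFactors = FALSE)
    geneDe <- geneDe[geneDe$log2fc != 0, , drop = FALSE]
    nPairs <- sample(10:40, 1)
    consensus <- unique(data.frame(
        mirna_id = sample(mirnas, nPairs, TRUE),
        gene_id = sample(genes, nPairs, TRUE), stringsAsFactors = FALSE))
    consensus$hit <- 4L
    consensus$oe_ratio <- 2
    consensus$retained <- sample(c(TRUE, FALSE), nrow(consensus), TRUE,
                                 prob = c(0.8, 0.2))
    mirnaDe <- data.frame(
        mirna_id = mirnas,
        direction = sample(c("up", "down", "unchanged"), nMirnas, TRUE),
        stringsAsFactors = FALSE)
    list(geneDe = geneDe, consensus = consensus, mirnaDe = mirnaDe)
}

# hypergeometric upper tail by exhaustive enumeration of all draws
bruteHyperUpper <- function(N, K, n, k) {
    draws <- combn(N, n)
    inSet <- seq_len(K)  # first K elements form the set
    overlap <- apply(draws, 2, function(d) sum(d %in% inSet))
    mean(overlap >= k)
}

# a small random CT experiment with known planted classes
randomCtInstance <- function(nAssays = 30) {
    planted <- sample(c("common", "control_only", "treated_only",
                        "undetected"), nAssays, TRUE)
    ids <- sprintf("a%02d", seq_len(nAssays))
    ct <- matrix(runif(nAssays * 4, 20, 30), nrow = nAssays,
                 dimnames = list(ids, c("c1", "c2", "t1", "t2")))
    ct[planted == "control_only", 3:4] <- 40
    ct[planted == "treated_only", 1:2] <- 40
    ct[planted == "undetected", ] <- 40
    list(ct = CtExperiment(ct, c("control", "control",
                                 "treated", "treated")),
         planted = setNames(planted, ids))
}
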