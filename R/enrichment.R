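## SNP-to-gene mapping by a +/-15 kb window and Fisher exact gene-set
## enrichment of "relevant" (P < 0.05) association signals, with BH FDR
## control.

#' Partition SNPs into relevant and non-relevant
#'
#' Relevant SNPs are those with a genomic-control corrected p-value below
#' \code{alpha} (default 0.05, deliberately permissive so that small-effect
#' loci missed by the genome-wide threshold still inform the pathway level).
#'
#' @param result a \linkS4class{GwasResult} with \code{p_gc} populated.
#' @param alpha relevance threshold.
#' @return A list with character vectors \code{relevant} and
#'   \code{nonrelevant} of SNP ids (NA-p SNPs are non-relevant).
#' @export
selectRelevantSnps <- function(result, alpha = 0.05) {
    stopifnot(is(result, "GwasResult"))
    tab <- gwasTable(result)
    if (is.null(tab$p_gc)) stop("apply genomicControl() first")
    rel <- !is.na(tab$p_gc) & tab$p_gc < alpha
    message(sprintf("selectRelevantSnps [%s]: %d relevant / %d non-relevant",
                    gwasTrait(result), sum(rel), sum(!rel)))
    list(relevant = tab$snp_id[rel], nonrelevant = tab$snp_id[!rel])
}

#' Map SNPs to genes with a symmetric window
#'
#' A SNP is assigned to every gene whose interval, extended by \code{window}
#' bp on both sides, contains the SNP position (boundaries inclusive:
#' a SNP exactly \code{window} bp from a gene edge is assigned;
#' multi-assignment is allowed; strand is ignored). Coordinates are handled
#' 1-based inclusive internally, as in the marker map and GRanges.
#'
#' @param snpIds character vector of SNP ids to map.
#' @param geno a \linkS4class{GenotypeData} providing SNP positions; SNPs
#'   with unknown position are skipped (counted in a message).
#' @param genes a \code{GRanges} with a \code{gene_id} metadata column.
#' @param window bp extension on each side (default 15000).
#' @return Character vector of unique gene ids hit by the SNPs.
#' @export
mapSnpsToGenes <- function(snpIds, geno, genes, window = 15000L) {
    stopifnot(is(geno, "GenotypeData"), is(genes, "GenomicRanges"))
    mm <- markerMap(geno)
    mm <- mm[mm$id %in% snpIds, , drop = FALSE]
    unmapped <- is.na(mm$chrom) | is.na(mm$bp)
    if (any(unmapped))
        message(sum(unmapped), " SNP(s) with unknown position skipped")
    mm <- mm[!unmapped, , drop = FALSE]
    if (!nrow(mm)) return(character(0))
    snpGr <- GenomicRanges::GRanges(mm$chrom, IRanges::IRanges(mm$bp, mm$bp))
    ext <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes),
        IRanges::IRanges(pmax(GenomicRanges::start(genes) - window, 1L),
                         GenomicRanges::end(genes) + window))
    hits <- GenomicRanges::findOverlaps(snpGr, ext)
    sort(unique(genes$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Testable gene background
#'
#' The enrichment universe: genes with at least one genotyped SNP within the
#' mapping window. Only such genes can ever be called relevant, so using all
#' annotated genes would inflate enrichment.
#'
#' @param geno a \linkS4class{GenotypeData} (all QC'd SNPs).
#' @param genes a \code{GRanges} with \code{gene_id}.
#' @param window bp window as in \code{\link{mapSnpsToGenes}}.
#' @return Character vector of background gene ids.
#' @export
testableGenes <- function(geno, genes, window = 15000L) {
    mapSnpsToGenes(markerMap(geno)$id, geno, genes, window)
}

#' Filter gene sets by size
#'
#' Retains sets whose size, counted on the testable background, is strictly
#' greater than \code{minSize} and strictly less than \code{maxSize}
#' (defaults 10 and 1000: a 10-gene term is excluded, an 11-gene term kept).
#'
#' @param sets named list of gene-id vectors.
#' @param background character vector of testable gene ids (sets are
#'   intersected with it before counting); NULL counts raw sizes.
#' @param minSize,maxSize strict size bounds.
#' @return The filtered named list (sets restricted to the background).
#' @export
filterGeneSets <- function(sets, background = NULL, minSize = 10L,
                           maxSize = 1000L) {
    if (!is.null(background))
        sets <- lapply(sets, function(s) intersect(s, background))
    sz <- vapply(sets, length, integer(1))
    sets[sz > minSize & sz < maxSize]
}

#' Fisher exact gene-set overrepresentation test
#'
#' For each set, forms the 2x2 table of relevant/non-relevant x in-set/
#' out-of-set genes over the testable background and computes the one-sided
#' (overrepresentation) hypergeometric upper-tail p-value, the sample odds
#' ratio, and Benjamini-Hochberg q-values across all tested sets. Gene ids
#' are case-normalised before matching. An empty relevant list yields p = 1
#' everywhere.
#'
#' @param relevantGenes character vector of relevant gene ids (subset of the
#'   background).
#' @param background character vector: the testable gene universe.
#' @param sets named list of gene-id vectors (already size-filtered).
#' @param fdr q-value threshold for the \code{enriched} flag (default 0.05).
#' @return data.frame: set, k (relevant in set), K (testable in set),
#'   n (relevant total), N (testable total), odds_ratio, p_fisher, q_fdr,
#'   enriched; ordered by p.
#' @export
fisherEnrichment <- function(relevantGenes, background, sets, fdr = 0.05) {
    bg <- unique(toupper(background))
    rel <- intersect(unique(toupper(relevantGenes)), bg)
    N <- length(bg); n <- length(rel)
    out <- lapply(names(sets), function(nm) {
        s <- intersect(unique(toupper(sets[[nm]])), bg)
        K <- length(s); k <- length(intersect(s, rel))
        p <- if (n == 0 || K == 0) 1
             else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        orr <- (k * ((N - K) - (n - k))) / max((n - k) * (K - k), 0)
        if (!is.finite(orr)) orr <- Inf
        data.frame(set = nm, k = k, K = K, n = n, N = N, odds_ratio = orr,
                   p_fisher = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    res$q_fdr <- stats::p.adjust(res$p_fisher, method = "BH")
    res$enriched <- res$q_fdr < fdr
    res <- res[order(res$p_fisher, res$set), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' One-call enrichment for a single trait
#'
#' Convenience wrapper chaining \code{\link{selectRelevantSnps}},
#' \code{\link{mapSnpsToGenes}}, \code{\link{testableGenes}},
#' \code{\link{filterGeneSets}} and \code{\link{fisherEnrichment}}.
#'
#' @param result a \linkS4class{GwasResult} with genomic control applied.
#' @param geno the QC'd \linkS4class{GenotypeData}.
#' @param genes gene annotation \code{GRanges} with \code{gene_id}.
#' @param sets named list of gene sets.
#' @param alpha relevance threshold on p_gc.
#' @param window bp mapping window.
#' @param minSize,maxSize strict term-size bounds.
#' @param fdr q-value threshold.
#' @return The \code{\link{fisherEnrichment}} data.frame.
#' @export
enrichTrait <- function(result, geno, genes, sets, alpha = 0.05,
                        window = 15000L, minSize = 10L, maxSize = 1000L,
                        fdr = 0.05) {
    part <- selectRelevantSnps(result, alpha)
    bg <- testableGenes(geno, genes, window)
    rel <- mapSnpsToGenes(part$relevant, geno, genes, window)
    sets <- filterGeneSets(sets, bg, minSize, maxSize)
    fisherEnrichment(rel, bg, sets, fdr)
}
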