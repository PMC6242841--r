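#' @import methods
NULL


#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("peakLabels", function(x) standardGeneric("peakLabels"))

#' @export
setGeneric("tentativeIds", function(x) standardGeneric("tentativeIds"))

#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @export
setGeneric("grmMethod", function(x) standardGeneric("grmMethod"))

#' @export
setGeneric("gwasTable", function(x) standardGeneric("gwasTable"))

#' @export
setGeneric("gwasLambda", function(x) standardGeneric("gwasLambda"))

#' @export
setGeneric("gwasTrait", function(x) standardGeneric("gwasTrait"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("subNetworks", function(x) standardGeneric("subNetworks"))

#' @export
setGeneric("denseClusters", function(x) standardGeneric("denseClusters"))

## Central S4 containers: genotype panel, spectrometric peak matrix, genomic
## relationship matrix, per-trait association result, and the cross-trait
## effect-similarity network.

#' GenotypeData: a dosage panel with its marker map
#'
#' Holds an animals x SNPs allele-dosage matrix (counts of the A1 allele,
#' values 0/1/2 or NA for missing calls) together with a marker map giving
#' chromosome, physical position (bp, 1-based) and the two alleles per SNP.
#'
#' @slot dosages numeric matrix, animals in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @slot markerMap data.frame with columns \code{id}, \code{chrom}, \code{bp},
#'   \code{a1}, \code{a2}; one row per SNP, ids unique, \code{bp} strictly
#'   increasing within chromosome.
#' @slot sampleIds character vector of animal identifiers.
#' @export
setClass("GenotypeData",
    slots = c(dosages = "matrix", markerMap = "data.frame",
              sampleIds = "character"))

setValidity("GenotypeData", function(object) {
    d <- object@dosages
    mm <- object@markerMap
    msg <- character()
    if (ncol(d) != nrow(mm))
        msg <- c(msg, "ncol(dosages) must equal nrow(markerMap)")
    if (nrow(d) != length(object@sampleIds))
        msg <- c(msg, "nrow(dosages) must equal length(sampleIds)")
    need <- c("id", "chrom", "bp", "a1", "a2")
    if (!all(need %in% names(mm)))
        msg <- c(msg, paste("markerMap needs columns:",
                            paste(need, collapse = ", ")))
    else if (anyDuplicated(mm$id))
        msg <- c(msg, "marker ids must be unique")
    v <- d[!is.na(d)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosages animals x SNPs matrix of A1-allele dosages (0/1/2/NA).
#' @param markerMap data.frame with columns id, chrom, bp, a1, a2.
#' @param sampleIds character vector of animal ids; defaults to rownames of
#'   \code{dosages} or generated ids.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- GenotypeData(matrix(c(0, 1, 2, 1), 2, 2),
#'     data.frame(id = c("s1", "s2"), chrom = "1", bp = c(100L, 200L),
#'                a1 = "A", a2 = "B"))
#' nSnps(g)
#' @export
GenotypeData <- function(dosages, markerMap, sampleIds = NULL) {
    dosages <- as.matrix(dosages)
    if (is.null(sampleIds))
        sampleIds <- rownames(dosages) %||% sprintf("animal_%d",
                                                    seq_len(nrow(dosages)))
    rownames(dosages) <- sampleIds
    colnames(dosages) <- markerMap$id
    markerMap$chrom <- as.character(markerMap$chrom)
    markerMap$bp <- as.numeric(markerMap$bp)
    new("GenotypeData", dosages = dosages,
        markerMap = as.data.frame(markerMap), sampleIds = as.character(sampleIds))
}

#' @describeIn GenotypeData dosage matrix accessor
#' @param x a GenotypeData object
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @describeIn GenotypeData marker map accessor
#' @export
setMethod("markerMap", "GenotypeData", function(x) x@markerMap)

#' @describeIn GenotypeData sample id accessor
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@sampleIds)

#' @describeIn GenotypeData number of animals
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))

#' @describeIn GenotypeData number of SNPs
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosages))

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nSamples(object), "animals x", nSnps(object),
        "SNPs\n")
    miss <- mean(is.na(object@dosages))
    cat(sprintf("  chromosomes: %d | missing calls: %.3f%%\n",
                length(unique(object@markerMap$chrom)), 100 * miss))
})

#' PeakMatrix: PTR-ToF-MS spectrometric peak intensities
#'
#' Animals x peaks matrix of headspace VOC concentrations. Raw matrices are on
#' the ppbv scale (nonnegative); \code{\link{transformPeaks}} converts them to
#' the compositional log scale used for association analysis.
#'
#' @slot intensities numeric matrix, animals x peaks.
#' @slot peakLabels numeric vector of m/z values, one per peak, unique.
#' @slot tentativeIds character vector of tentative compound identifications
#'   (NA when unknown).
#' @slot scale character, "ppbv" or "log" (after transformation).
#' @export
setClass("PeakMatrix",
    slots = c(intensities = "matrix", peakLabels = "numeric",
              tentativeIds = "character", scale = "character"))

setValidity("PeakMatrix", function(object) {
    msg <- character()
    if (ncol(object@intensities) != length(object@peakLabels))
        msg <- c(msg, "one m/z label per peak required")
    if (length(object@tentativeIds) != length(object@peakLabels))
        msg <- c(msg, "one tentative id (possibly NA) per peak required")
    if (anyDuplicated(object@peakLabels))
        msg <- c(msg, "peak m/z labels must be unique")
    if (identical(object@scale, "ppbv")) {
        v <- object@intensities[!is.na(object@intensities)]
        if (length(v) && any(v < 0))
            msg <- c(msg, "ppbv intensities must be nonnegative")
    }
    if (!object@scale %in% c("ppbv", "log"))
        msg <- c(msg, "scale must be 'ppbv' or 'log'")
    if (length(msg)) msg else TRUE
})

#' Construct a PeakMatrix
#'
#' @param intensities animals x peaks matrix (ppbv unless \code{scale="log"}).
#' @param peakLabels numeric m/z values, one per peak.
#' @param tentativeIds optional compound names per peak (NA = unknown).
#' @param scale "ppbv" (default) or "log".
#' @return A \linkS4class{PeakMatrix}.
#' @export
PeakMatrix <- function(intensities, peakLabels,
                       tentativeIds = rep(NA_character_, length(peakLabels)),
                       scale = "ppbv") {
    intensities <- as.matrix(intensities)
    colnames(intensities) <- formatMz(peakLabels)
    new("PeakMatrix", intensities = intensities,
        peakLabels = as.numeric(peakLabels),
        tentativeIds = as.character(tentativeIds), scale = scale)
}

formatMz <- function(mz) sprintf("%.3f", mz)

#' @describeIn PeakMatrix intensity matrix accessor
#' @param x a PeakMatrix object
#' @export
setMethod("intensities", "PeakMatrix", function(x) x@intensities)

#' @describeIn PeakMatrix m/z label accessor
#' @export
setMethod("peakLabels", "PeakMatrix", function(x) x@peakLabels)

#' @describeIn PeakMatrix tentative compound id accessor
#' @export
setMethod("tentativeIds", "PeakMatrix", function(x) x@tentativeIds)

#' @describeIn PeakMatrix number of peaks
#' @export
setMethod("nPeaks", "PeakMatrix", function(x) ncol(x@intensities))

#' @describeIn PeakMatrix number of animals
#' @export
setMethod("nSamples", "PeakMatrix", function(x) nrow(x@intensities))

setMethod("show", "PeakMatrix", function(object) {
    cat("PeakMatrix:", nSamples(object), "animals x", nPeaks(object),
        "peaks [", object@scale, "]\n")
    idd <- sum(!is.na(object@tentativeIds))
    cat(sprintf("  m/z range: %.3f-%.3f | tentatively identified: %d\n",
                min(object@peakLabels), max(object@peakLabels), idd))
})

#' Grm: genomic relationship matrix
#'
#' Pairwise genomic relatedness among animals computed from genome-wide SNPs,
#' either as plain identity-by-state sharing or as the frequency-weighted
#' (VanRaden-type) relationship used for variance-component estimation.
#'
#' @slot matrix symmetric animals x animals numeric matrix.
#' @slot method "freq-weighted" or "plain-ibs".
#' @slot sampleIds character vector of animal ids.
#' @export
setClass("Grm",
    slots = c(matrix = "matrix", method = "character",
              sampleIds = "character"))

setValidity("Grm", function(object) {
    m <- object@matrix
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "GRM must be square")
    else if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "GRM must be symmetric")
    if (nrow(m) != length(object@sampleIds))
        msg <- c(msg, "one sample id per row required")
    if (!object@method %in% c("freq-weighted", "plain-ibs"))
        msg <- c(msg, "method must be 'freq-weighted' or 'plain-ibs'")
    if (length(msg)) msg else TRUE
})

#' @describeIn Grm relationship matrix accessor
#' @param x a Grm object
#' @export
setMethod("grmMatrix", "Grm", function(x) x@matrix)

#' @describeIn Grm construction method accessor
#' @export
setMethod("grmMethod", "Grm", function(x) x@method)

#' @describeIn Grm sample id accessor
#' @export
setMethod("sampleIds", "Grm", function(x) x@sampleIds)

#' @describeIn Grm number of animals
#' @export
setMethod("nSamples", "Grm", function(x) nrow(x@matrix))

setMethod("show", "Grm", function(object) {
    cat("Grm [", object@method, "]:", nSamples(object), "animals\n")
    cat(sprintf("  mean diagonal: %.4f\n", mean(diag(object@matrix))))
})

#' GwasResult: single-trait GRAMMAR-GC association scan
#'
#' Per-SNP association summaries for one trait: allele substitution effect,
#' standard error, raw and genomic-control-corrected chi-square statistics and
#' p-values, minor allele frequency, and the variance explained (2pqa^2).
#'
#' @slot trait character trait label (an m/z string or composition trait name).
#' @slot table data.frame, one row per SNP (see \code{\link{grammarScan}}).
#' @slot lambda numeric genomic-control inflation factor (NA before
#'   \code{\link{genomicControl}}).
#' @slot nAnimals integer number of animals scanned.
#' @export
setClass("GwasResult",
    slots = c(trait = "character", table = "data.frame", lambda = "numeric",
              nAnimals = "integer"))

setValidity("GwasResult", function(object) {
    tab <- object@table
    need <- c("snp_id", "chrom", "bp", "maf", "n_obs", "beta", "se",
              "chi2_raw")
    if (!all(need %in% names(tab)))
        return(paste("table needs columns:", paste(need, collapse = ", ")))
    if (!is.na(object@lambda) && object@lambda <= 0)
        return("lambda must be positive")
    p <- tab$p_gc
    if (!is.null(p) && any(!is.na(p) & (p <= 0 | p > 1)))
        return("p_gc must lie in (0, 1]")
    TRUE
})

#' @describeIn GwasResult per-SNP result table accessor
#' @param x a GwasResult object
#' @export
setMethod("gwasTable", "GwasResult", function(x) x@table)

#' @describeIn GwasResult genomic-control lambda accessor
#' @export
setMethod("gwasLambda", "GwasResult", function(x) x@lambda)

#' @describeIn GwasResult trait label accessor
#' @export
setMethod("gwasTrait", "GwasResult", function(x) x@trait)

setMethod("show", "GwasResult", function(object) {
    tab <- object@table
    cat("GwasResult for trait", object@trait, ":", nrow(tab), "SNPs,",
        object@nAnimals, "animals\n")
    if (!is.na(object@lambda))
        cat(sprintf("  lambda_GC = %.4f | significant: %d\n", object@lambda,
                    sum(tab$significant, na.rm = TRUE)))
    else cat("  genomic control not yet applied\n")
})

#' EffectNetwork: trait-similarity network from SNP effect vectors
#'
#' Traits are nodes; an edge joins two traits whose genome-wide vectors of SNP
#' allele-substitution effects are strongly correlated. Sub-networks are
#' connected components with >= 3 nodes; dense clusters are detected by
#' greedy cohesiveness maximisation (\code{\link{findDenseClusters}}).
#'
#' @slot nodes character vector of trait labels.
#' @slot edges data.frame with columns from, to, r, p, weight (= |r|).
#' @slot graph the underlying igraph object.
#' @slot subnetworks list of character vectors (components with >= 3 nodes).
#' @slot clusters data.frame of detected dense clusters (empty before
#'   \code{\link{findDenseClusters}}).
#' @export
setClass("EffectNetwork",
    slots = c(nodes = "character", edges = "data.frame", graph = "ANY",
              subnetworks = "list", clusters = "data.frame"))

setValidity("EffectNetwork", function(object) {
    e <- object@edges
    need <- c("from", "to", "r", "p", "weight")
    if (nrow(e) && !all(need %in% names(e)))
        return(paste("edges needs columns:", paste(need, collapse = ", ")))
    if (nrow(e) && !all(c(e$from, e$to) %in% object@nodes))
        return("edge endpoints must be nodes")
    TRUE
})

#' @describeIn EffectNetwork node label accessor
#' @param x an EffectNetwork object
#' @export
setMethod("networkNodes", "EffectNetwork", function(x) x@nodes)

#' @describeIn EffectNetwork edge table accessor
#' @export
setMethod("networkEdges", "EffectNetwork", function(x) x@edges)

#' @describeIn EffectNetwork connected components with >= 3 nodes
#' @export
setMethod("subNetworks", "EffectNetwork", function(x) x@subnetworks)

#' @describeIn EffectNetwork detected dense clusters
#' @export
setMethod("denseClusters", "EffectNetwork", function(x) x@clusters)

setMethod("show", "EffectNetwork", function(object) {
    cat("EffectNetwork:", length(object@nodes), "traits,",
        nrow(object@edges), "edges,", length(object@subnetworks),
        "sub-networks (>=3 nodes)\n")
    if (nrow(object@clusters))
        cat("  dense clusters:", nrow(object@clusters), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
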