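## Plain-text interchange: peak matrices and phenotype tables as TSV, gene
## sets as GMT, gene annotation as BED (0-based half-open on disk, 1-based
## inclusive in memory), GRM and variance components as TSV.

#' Write a peak matrix as TSV
#'
#' Layout: first column \code{animal}, then one column per peak headed by its
#' m/z label (3 decimals). A comment line records the intensity scale.
#'
#' @param peaks a \linkS4class{PeakMatrix}.
#' @param file output path.
#' @export
writePeakMatrix <- function(peaks, file) {
    stopifnot(is(peaks, "PeakMatrix"))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste0("# peak intensities, scale=", peaks@scale), con)
    df <- data.frame(animal = rownames(intensities(peaks)) %||%
                         sprintf("animal_%d", seq_len(nSamples(peaks))),
                     intensities(peaks), check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a peak matrix from TSV
#'
#' @param file path written by \code{\link{writePeakMatrix}} (or any TSV with
#'   an \code{animal} column and m/z-labelled numeric columns).
#' @return A \linkS4class{PeakMatrix}.
#' @export
readPeakMatrix <- function(file) {
    first <- readLines(file, n = 1)
    scale <- if (grepl("scale=log", first)) "log" else "ppbv"
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE)
    x <- as.matrix(df[, -1, drop = FALSE])
    rownames(x) <- df[[1]]
    PeakMatrix(x, as.numeric(colnames(x)), scale = scale)
}

#' Write a phenotype/covariate table as TSV
#'
#' Numeric columns are written with 17 significant digits so that doubles
#' round-trip exactly through \code{\link{readPhenotypes}}.
#'
#' @param pheno data.frame (animal, covariates, traits).
#' @param file output path.
#' @export
writePhenotypes <- function(pheno, file) {
    out <- pheno
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read a phenotype/covariate table from TSV
#'
#' Columns \code{herd_date}, \code{parity} and \code{dim_class}, when
#' present, are read back as factors.
#'
#' @param file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(file) {
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (col in intersect(c("herd_date", "parity", "dim_class"), names(df)))
        df[[col]] <- factor(df[[col]])
    df
}

#' Read gene sets from a GMT file
#'
#' @param file GMT path (set name, description, tab-separated gene ids).
#' @return Named list of gene-id vectors.
#' @export
readGmt <- function(file) fgsea::gmtPathways(file)

#' Write gene sets as GMT
#'
#' @param sets named list of gene-id vectors.
#' @param file output path.
#' @param descriptions optional per-set description column (defaults to "na").
#' @export
writeGmt <- function(sets, file, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, file)
}

#' Read gene annotation from BED or GFF3
#'
#' BED input is 0-based half-open on disk and arrives 1-based inclusive in
#' the returned GRanges (rtracklayer converts on read); GFF3 is 1-based
#' inclusive already. The gene id is taken from the BED name column or the
#' GFF3 ID/Name/gene_id attribute.
#'
#' @param file path ending in .bed, .gff, .gff3 (format sniffed from the
#'   extension).
#' @return A \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readGeneAnnotation <- function(file) {
    ext <- tolower(tools::file_ext(file))
    gr <- if (ext == "bed") rtracklayer::import(file, format = "BED")
          else rtracklayer::import(file, format = "GFF3")
    id <- if (!is.null(gr$name)) gr$name
          else if (!is.null(gr$gene_id)) gr$gene_id
          else if (!is.null(gr$ID)) gr$ID
          else sprintf("GENE%05d", seq_along(gr))
    gr$gene_id <- id
    gr
}

#' Write gene annotation as BED
#'
#' @param genes GRanges with \code{gene_id}.
#' @param file output path (.bed; written 0-based half-open).
#' @export
writeGeneAnnotation <- function(genes, file) {
    gr <- genes
    gr$name <- gr$gene_id
    rtracklayer::export(gr, file, format = "BED")
}

#' Write a GRM as square TSV with a sample-id header
#'
#' @param grm a \linkS4class{Grm}.
#' @param file output path.
#' @export
writeGrmTsv <- function(grm, file) {
    utils::write.table(
        data.frame(sample_id = sampleIds(grm), grmMatrix(grm),
                   check.names = FALSE),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write per-trait variance components as TSV
#'
#' @param vcList named list of \code{VarianceComponents}.
#' @param file output path.
#' @export
writeVarianceComponents <- function(vcList, file) {
    df <- do.call(rbind, lapply(names(vcList), function(nm) {
        v <- vcList[[nm]]
        data.frame(trait = nm, sigma_g2 = v$sigma_g2, sigma_e2 = v$sigma_e2,
                   h2 = v$h2, converged = v$converged,
                   stringsAsFactors = FALSE)
    }))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}
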