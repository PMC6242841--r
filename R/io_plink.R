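## PLINK bed/bim/fam binary genotype I/O (SNP-major .bed, magic bytes
## 0x6c 0x1b 0x01). Dosages count the A1 allele: 2-bit codes are
## 0 = hom A1 (dosage 2), 1 = missing, 2 = het, 3 = hom A2 (dosage 0).

.bedMagic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param prefix path prefix; \code{prefix.bed/.bim/.fam} are written.
#' @return Invisibly, the three paths.
#' @export
writePlink <- function(geno, prefix) {
    stopifnot(is(geno, "GenotypeData"))
    d <- dosages(geno); n <- nrow(d); m <- ncol(d)
    mm <- markerMap(geno)
    utils::write.table(
        data.frame(mm$chrom, mm$id, 0,
                   format(mm$bp, scientific = FALSE, trim = TRUE),
                   mm$a1, mm$a2),
        paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    utils::write.table(
        data.frame(sampleIds(geno), sampleIds(geno), 0, 0, 0, -9),
        paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    ## dosage -> 2-bit code
    code <- matrix(1L, n, m)                 # missing
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    pad <- (4 - n %% 4) %% 4
    if (pad) code <- rbind(code, matrix(0L, pad, m))
    dim(code) <- c(4, length(code) / 4)
    bytes <- as.raw(colSums(code * c(1L, 4L, 16L, 64L)))
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(.bedMagic, con)
    writeBin(bytes, con)
    invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a PLINK bed/bim/fam genotype panel
#'
#' Only SNP-major .bed files (the PLINK default) are supported.
#'
#' @param prefix path prefix of the \code{.bed/.bim/.fam} triple.
#' @return A \linkS4class{GenotypeData} with A1-allele dosages.
#' @export
readPlink <- function(prefix) {
    missing <- !file.exists(paste0(prefix, c(".bed", ".bim", ".fam")))
    if (any(missing))
        stop("no PLINK fileset at prefix '", prefix, "' (missing ",
             paste(c(".bed", ".bim", ".fam")[missing], collapse = ", "), ")")
    bim <- utils::read.table(paste0(prefix, ".bim"),
                             col.names = c("chrom", "id", "cm", "bp", "a1",
                                           "a2"),
                             colClasses = c("character", "character",
                                            "numeric", "numeric",
                                            "character", "character"))
    fam <- utils::read.table(paste0(prefix, ".fam"),
                             colClasses = c("character", "character", rep(NA, 4)))
    n <- nrow(fam); m <- nrow(bim)
    bytesPerSnp <- ceiling(n / 4)
    con <- file(paste0(prefix, ".bed"), "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 3)
    if (!identical(magic, .bedMagic))
        stop("not a SNP-major PLINK .bed file (bad magic bytes)")
    raw <- readBin(con, "raw", bytesPerSnp * m)
    if (length(raw) < bytesPerSnp * m) stop("truncated .bed file")
    b <- as.integer(raw)
    code <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                  b %/% 64L)
    dim(code) <- c(4 * bytesPerSnp, m)
    code <- code[seq_len(n), , drop = FALSE]
    d <- matrix(NA_real_, n, m)
    d[code == 0L] <- 2; d[code == 2L] <- 1; d[code == 3L] <- 0
    GenotypeData(d, bim[, c("id", "chrom", "bp", "a1", "a2")], fam[[2]])
}
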