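## Genomic relationship matrices from genome-wide SNP dosages.

#' Compute a genomic relationship matrix
#'
#' Two identity-by-state flavours are available. The frequency-weighted GRM
#' (default, the form used for variance-component estimation) has entries
#' \deqn{G_{ij} = \frac{1}{m}\sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)},}
#' whose diagonal averages ~1 under Hardy-Weinberg. The plain-IBS matrix is
#' the average allele-sharing \eqn{1 - |x_i - x_j|/2} over SNPs. Missing
#' dosages are mean-imputed per SNP for this computation; SNPs that are
#' monomorphic (p of 0 or 1) are excluded from the frequency-weighted sum.
#'
#' @param geno a QC'd \linkS4class{GenotypeData}.
#' @param method "freq-weighted" (default) or "plain-ibs".
#' @return A \linkS4class{Grm}.
#' @export
computeGrm <- function(geno, method = c("freq-weighted", "plain-ibs")) {
    stopifnot(is(geno, "GenotypeData"))
    method <- match.arg(method)
    d <- dosages(geno)
    p <- colMeans(d, na.rm = TRUE) / 2
    if (method == "freq-weighted") {
        keep <- p > 0 & p < 1
        if (!all(keep)) d <- d[, keep, drop = FALSE]
        p <- p[keep]
        z <- sweep(d, 2, 2 * p)
        z[is.na(z)] <- 0                       # mean imputation after centering
        z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
        K <- tcrossprod(z) / ncol(z)
    } else {
        ## plain IBS via indicator cross-products: |xi - xj| summed over SNPs
        A0 <- (d == 0); A1 <- (d == 1); A2 <- (d == 2)
        A0[is.na(A0)] <- FALSE; A1[is.na(A1)] <- FALSE; A2[is.na(A2)] <- FALSE
        storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
        obs <- (!is.na(d)) + 0
        nPairs <- tcrossprod(obs)               # SNPs observed in both animals
        S02 <- tcrossprod(A0, A2); S1 <- tcrossprod(A1, A0 + A2)
        absDiff <- 2 * (S02 + t(S02)) + S1 + t(S1)
        K <- 1 - absDiff / (2 * pmax(nPairs, 1))
    }
    K <- (K + t(K)) / 2
    dimnames(K) <- list(sampleIds(geno), sampleIds(geno))
    new("Grm", matrix = K, method = method, sampleIds = sampleIds(geno))
}
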