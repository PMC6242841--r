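## Genotype quality control: call-rate, MAF and exact Hardy-Weinberg filters,
## applied in that order, with a per-filter removal report.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditioning on the observed allele counts (Wigginton-style):
#' the p-value is the total probability, under HWE, of heterozygote counts at
#' least as improbable as the one observed.
#'
#' @param nAA,nAa,naa genotype counts (vectors are accepted and recycled to a
#'   common length).
#' @return Numeric vector of exact two-sided p-values.
#' @examples
#' hweExact(25, 50, 25)   # perfectly HWE-proportioned, p = 1
#' @export
hweExact <- function(nAA, nAa, naa) {
    mapply(function(a, h, b) {
        n <- a + h + b
        if (n == 0) return(NA_real_)
        nA <- 2 * a + h            # count of the A allele
        rare <- min(nA, 2 * n - nA)
        ## heterozygote count must have the parity of the rare-allele count
        hets <- seq(rare %% 2, rare, by = 2)
        ## log-probability of each possible het count given allele counts
        lp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) -
            lgamma(hets + 1) - lgamma((2 * n - rare - hets) / 2 + 1) +
            hets * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
            lgamma(2 * n + 1)
        pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
        obs <- pr[match(h, hets)]
        min(1, sum(pr[pr <= obs + 1e-12]))
    }, nAA, nAa, naa)
}

#' Genotype quality control
#'
#' Retains SNPs passing, in order: call rate >= \code{callRateMin}, minor
#' allele frequency >= \code{mafMin}, and exact HWE p >=
#' \code{hweAlpha / n} (Bonferroni over the \code{n} SNPs entering the HWE
#' stage). The defaults are the standard 50k-panel thresholds (call rate
#' 0.95, MAF 0.005, HWE alpha 0.001 Bonferroni-corrected). All-missing SNPs
#' are removed by the call-rate filter and never reach the HWE test.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param callRateMin minimum per-SNP call rate.
#' @param mafMin minimum minor allele frequency.
#' @param hweAlpha HWE significance level before Bonferroni correction.
#' @return A list with \code{geno} (filtered \linkS4class{GenotypeData}) and
#'   \code{report} (a \code{QcReport} list: n_snps_in/out, n_samples_in/out,
#'   removed_call_rate, removed_maf, removed_hwe, thresholds).
#' @export
qcGenotypes <- function(geno, callRateMin = 0.95, mafMin = 0.005,
                        hweAlpha = 0.001) {
    stopifnot(is(geno, "GenotypeData"))
    if (nSamples(geno) < 2) stop("need at least 2 samples for genotype QC")
    d <- dosages(geno)
    m0 <- ncol(d)

    cr <- colMeans(!is.na(d))
    keep1 <- cr >= callRateMin
    d1 <- d[, keep1, drop = FALSE]

    p <- colMeans(d1, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep2 <- maf >= mafMin
    d2 <- d1[, keep2, drop = FALSE]

    nAA <- colSums(d2 == 2, na.rm = TRUE)
    nAa <- colSums(d2 == 1, na.rm = TRUE)
    naa <- colSums(d2 == 0, na.rm = TRUE)
    mHwe <- ncol(d2)
    pHwe <- if (mHwe) hweExact(nAA, nAa, naa) else numeric(0)
    keep3 <- is.na(pHwe) | pHwe >= hweAlpha / max(mHwe, 1L)

    keep <- which(keep1)[which(keep2)][keep3]
    out <- GenotypeData(d[, keep, drop = FALSE],
                        markerMap(geno)[keep, , drop = FALSE],
                        sampleIds(geno))
    report <- list(n_snps_in = m0, n_snps_out = length(keep),
                   n_samples_in = nSamples(geno),
                   n_samples_out = nSamples(geno),
                   removed_call_rate = sum(!keep1),
                   removed_maf = sum(!keep2),
                   removed_hwe = sum(!keep3),
                   thresholds = c(call_rate_min = callRateMin,
                                  maf_min = mafMin, hwe_alpha = hweAlpha))
    class(report) <- "QcReport"
    list(geno = out, report = report)
}

#' @export
print.QcReport <- function(x, ...) {
    cat("Genotype QC report\n")
    cat(sprintf("  SNPs: %d in -> %d out (call rate: -%d, MAF: -%d, HWE: -%d)\n",
                x$n_snps_in, x$n_snps_out, x$removed_call_rate,
                x$removed_maf, x$removed_hwe))
    cat(sprintf("  samples: %d in -> %d out\n", x$n_samples_in,
                x$n_samples_out))
    cat(sprintf("  thresholds: call rate >= %g, MAF >= %g, HWE alpha %g (Bonferroni)\n",
                x$thresholds["call_rate_min"], x$thresholds["maf_min"],
                x$thresholds["hwe_alpha"]))
    invisible(x)
}
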