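## Spectrometric peak preprocessing: low-intensity filtering, compositional
## log transform, and isotope-satellite removal.

#' Filter low-intensity peaks
#'
#' Drops peaks whose summary intensity across animals falls below
#' \code{minPpbv} (default 1 ppbv). The summary statistic is the mean by
#' default; the original filtering rule does not state which summary was
#' used, so \code{stat} also offers "median" and "max". Peak order is
#' preserved. An optional exclusion list of m/z labels removes known
#' interfering ions.
#'
#' @param peaks a \linkS4class{PeakMatrix} on the ppbv scale.
#' @param minPpbv intensity threshold in ppbv.
#' @param stat summary statistic: "mean" (default), "median" or "max".
#' @param excludeMz numeric m/z values to drop regardless of intensity
#'   (interfering ions).
#' @return The filtered \linkS4class{PeakMatrix}.
#' @export
filterPeaks <- function(peaks, minPpbv = 1, stat = c("mean", "median", "max"),
                        excludeMz = numeric(0)) {
    stopifnot(is(peaks, "PeakMatrix"))
    stat <- match.arg(stat)
    f <- switch(stat, mean = function(x) mean(x, na.rm = TRUE),
                median = function(x) stats::median(x, na.rm = TRUE),
                max = function(x) max(x, na.rm = TRUE))
    s <- apply(intensities(peaks), 2, f)
    keep <- s >= minPpbv & !(peakLabels(peaks) %in% excludeMz)
    if (!any(keep))
        message("filterPeaks: no peaks survive the ", minPpbv, " ppbv filter")
    PeakMatrix(intensities(peaks)[, keep, drop = FALSE],
               peakLabels(peaks)[keep], tentativeIds(peaks)[keep],
               scale = peaks@scale)
}

#' Compositional log transform of peak intensities
#'
#' Converts each animal's spectrum to fractions of its total intensity,
#' then maps each fraction f to \code{ln((f + 1) * 1e6)}: the "+1" applies to
#' the fraction and the result is strictly positive (a zero peak maps to
#' \code{ln(1e6)}, about 13.8155; a single-peak spectrum maps to
#' \code{ln(2e6)}, about 14.5087). The transform removes the strong positive
#' skewness of raw ppbv intensities and is monotone in the fraction.
#'
#' @param peaks a \linkS4class{PeakMatrix} on the ppbv scale.
#' @return A \linkS4class{PeakMatrix} on the "log" scale.
#' @export
transformPeaks <- function(peaks) {
    stopifnot(is(peaks, "PeakMatrix"))
    x <- intensities(peaks)
    tot <- rowSums(x, na.rm = TRUE)
    if (any(tot == 0))
        stop("animal(s) with all-zero spectrum: fractions undefined (rows ",
             paste(which(tot == 0), collapse = ", "), ")")
    f <- sweep(x, 1, tot, "/")
    PeakMatrix(log((f + 1) * 1e6), peakLabels(peaks), tentativeIds(peaks),
               scale = "log")
}

#' Remove isotope satellite peaks
#'
#' An isotope satellite is a peak sitting one isotope spacing above a parent
#' peak (Delta m/z of +1.00336, the 13C offset, within \code{mzTol}) whose
#' intensities correlate almost perfectly with the parent. For every peak
#' pair with Pearson r > \code{rMin}, correlation-test p < \code{alpha} and,
#' when \code{requireSpacing} (default), a compatible m/z spacing, the
#' higher-m/z member is removed. The spacing gate protects genuinely
#' co-varying compounds from deletion; disable it to apply the correlation
#' rule alone. Constant peaks have undefined correlation and are skipped with
#' a warning.
#'
#' @param peaks a \linkS4class{PeakMatrix}.
#' @param rMin correlation threshold (strict inequality).
#' @param alpha correlation-test significance threshold.
#' @param mzTol tolerance around the 1.00336 isotope spacing.
#' @param requireSpacing apply the m/z-spacing gate (default TRUE).
#' @return A list with \code{peaks} (satellites removed) and \code{removed}
#'   (data.frame: parent_mz, satellite_mz, r, p).
#' @export
removeIsotopes <- function(peaks, rMin = 0.95, alpha = 0.001, mzTol = 0.01,
                           requireSpacing = TRUE) {
    stopifnot(is(peaks, "PeakMatrix"))
    if (nPeaks(peaks) < 2) stop("need at least 2 peaks")
    x <- intensities(peaks)
    mz <- peakLabels(peaks)
    sds <- apply(x, 2, stats::sd, na.rm = TRUE)
    if (any(sds == 0, na.rm = TRUE))
        warning("constant peak(s) at m/z ",
                paste(formatMz(mz[which(sds == 0)]), collapse = ", "),
                ": correlation undefined, pairs skipped")
    ord <- order(mz)
    removed <- data.frame(parent_mz = numeric(0), satellite_mz = numeric(0),
                          r = numeric(0), p = numeric(0))
    drop <- logical(length(mz))
    n <- nrow(x)
    for (i in seq_along(ord)) for (j in seq_along(ord)) {
        if (j <= i) next
        a <- ord[i]; b <- ord[j]          # mz[a] < mz[b]: b is the candidate satellite
        if (drop[b]) next
        if (requireSpacing && abs((mz[b] - mz[a]) - 1.00336) > mzTol) next
        if (is.na(sds[a]) || is.na(sds[b]) || sds[a] == 0 || sds[b] == 0) next
        ok <- stats::complete.cases(x[, a], x[, b])
        if (sum(ok) < 3) next
        r <- stats::cor(x[ok, a], x[ok, b])
        if (is.na(r) || !(r > rMin)) next
        df <- sum(ok) - 2
        tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tstat), df)
        if (p < alpha) {
            drop[b] <- TRUE
            removed <- rbind(removed,
                             data.frame(parent_mz = mz[a],
                                        satellite_mz = mz[b], r = r, p = p))
        }
    }
    list(peaks = PeakMatrix(x[, !drop, drop = FALSE], mz[!drop],
                            tentativeIds(peaks)[!drop], scale = peaks@scale),
         removed = removed)
}
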