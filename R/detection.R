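#' Score gene detection by signal-to-noise ratio
#'
#' Each cell's signal-to-noise ratio is the raw count divided by that
#' sample's own background threshold, snr_gs = raw_gs / theta_s. An
#' endogenous gene is scored detected when its SNR strictly exceeds `cutoff`
#' in at least `minFraction` of the samples of at least one group
#' (`scope = "any_group"`, the default, so group-specific genes survive) or
#' of all samples (`scope = "all_samples"`). Only Endogenous probes are
#' filtered; Housekeeping/Negative/Positive probes carry `NA` flags.
#'
#' Both the counts and theta are on the raw scale: background is defined on
#' raw negative-control counts, so mixing normalized signal with a raw
#' threshold would be incoherent.
#'
#' @param x an [NCounterSet-class].
#' @param background a [BackgroundProfile-class].
#' @param cutoff SNR threshold, strict inequality (default 3).
#' @param minFraction fraction of samples that must pass (default 0.5).
#' @param scope `"any_group"` or `"all_samples"`. `"any_group"` requires
#'   group labels on `x`.
#' @return a [DetectionResult-class].
#' @export
scoreDetection <- function(x, background, cutoff = 3, minFraction = 0.5,
                           scope = c("any_group", "all_samples")) {
    stopifnot(is(x, "NCounterSet"), is(background, "BackgroundProfile"))
    scope <- match.arg(scope)
    th <- theta(background)[colnames(x)]
    cnt <- assay(x, "counts")
    if (any(th == 0)) {
        warning("theta = 0 in sample(s): ",
                paste(colnames(x)[th == 0], collapse = ", "),
                "; SNR is Inf for nonzero counts there")
        snr <- sweep(cnt, 2, th, `/`)
        snr[, th == 0][cnt[, th == 0, drop = FALSE] == 0] <- 0
    } else snr <- sweep(cnt, 2, th, `/`)

    pass <- snr > cutoff
    isEnd <- codeClass(x) == "Endogenous"
    det <- setNames(rep(NA, nrow(x)), rownames(x))
    if (scope == "all_samples") {
        det[isEnd] <- rowMeans(pass[isEnd, , drop = FALSE]) >= minFraction
    } else {
        gr <- sampleGroups(x)
        if (all(is.na(gr)))
            stop("scope = 'any_group' requires sample group labels")
        hit <- rep(FALSE, sum(isEnd))
        for (g in unique(gr[!is.na(gr)])) {
            cols <- which(gr == g)
            hit <- hit | rowMeans(pass[isEnd, cols, drop = FALSE]) >= minFraction
        }
        det[isEnd] <- hit
    }
    new("DetectionResult", snr = snr, detected = det, cutoff = cutoff,
        minFraction = minFraction, scope = scope)
}

#' Write detection scores to TSV
#'
#' @param result a [DetectionResult-class].
#' @param file output path; columns gene, detected flag, per-sample SNR.
#' @return invisibly, the path.
#' @export
writeDetection <- function(result, file) {
    d <- data.frame(gene = rownames(result@snr),
                    detected = result@detected[rownames(result@snr)],
                    result@snr, check.names = FALSE)
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
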