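#' Estimate per-sample background from negative-control probes
#'
#' For each sample the background threshold is the mean plus two sample
#' standard deviations (n-1 denominator) of the negative-control raw counts:
#' theta_s = mean(neg_s) + 2 * SD(neg_s). Raw counts are used throughout;
#' detection and housekeeping screening compare raw counts against theta_s.
#'
#' @param x an [NCounterSet-class] with at least 2 Negative probes.
#' @param nsd number of standard deviations above the mean (default 2).
#' @return a [BackgroundProfile-class].
#' @examples
#' cnt <- matrix(rep(1:8, 2), ncol = 2,
#'               dimnames = list(paste0("NEG_", LETTERS[1:8]), c("s1", "s2")))
#' nc <- NCounterSet(cnt, rep("Negative", 8))
#' theta(estimateBackground(nc))  # 4.5 + 2*sqrt(6) per sample
#' @export
estimateBackground <- function(x, nsd = 2) {
    stopifnot(is(x, "NCounterSet"))
    neg <- assay(x, "counts")[codeClass(x) == "Negative", , drop = FALSE]
    if (nrow(neg) < 2L)
        stop("background estimation requires >= 2 negative-control probes, got ",
             nrow(neg))
    m <- colMeans(neg)
    s <- apply(neg, 2, sd)
    th <- m + nsd * s
    if (any(colSums(neg) == 0))
        warning("all negative counts are zero in sample(s): ",
                paste(colnames(neg)[colSums(neg) == 0], collapse = ", "),
                "; theta = 0 there")
    new("BackgroundProfile", sampleId = colnames(x), mean = unname(m),
        sd = unname(s), theta = unname(th), nNegative = nrow(neg))
}

#' Screen housekeeping genes against background
#'
#' A housekeeping gene passes the screen only if its raw count exceeds
#' `k * theta_s` in every sample; genes "close to background" fail and are
#' excluded from normalization, but are flagged, never dropped from the
#' matrix. The default k = 3 reuses the platform's signal-to-noise detection
#' cutoff.
#'
#' @param x an [NCounterSet-class] with >= 1 Housekeeping probe.
#' @param background a [BackgroundProfile-class] for the same samples.
#' @param k multiple of theta_s a housekeeping count must exceed (strict)
#'   in every sample; default 3.
#' @return an [HkAssessment-class] with pass flags (stability and panel
#'   slots empty until [genormStability()] / [selectHkPanel()] are run).
#' @export
screenHousekeeping <- function(x, background, k = 3) {
    stopifnot(is(x, "NCounterSet"), is(background, "BackgroundProfile"))
    hk <- assay(x, "counts")[codeClass(x) == "Housekeeping", , drop = FALSE]
    if (!nrow(hk)) stop("no Housekeeping probes in this set")
    th <- theta(background)[colnames(hk)]
    pass <- apply(sweep(hk, 2, k * th, `>`), 1, all)
    new("HkAssessment", genes = rownames(hk), passesBackground = pass,
        stabilityM = setNames(rep(NA_real_, nrow(hk)), rownames(hk)),
        corMatrix = matrix(numeric(0), 0, 0), panel = character(0))
}

.log2counts <- function(x, genes) {
    cnt <- assay(x, "counts")[genes, , drop = FALSE]
    log2(cnt + (if (any(cnt == 0)) 1 else 0))
}

#' geNorm gene-stability measure M
#'
#' For each candidate reference gene j, M_j is the arithmetic mean over all
#' other candidates k of the standard deviation across samples of the
#' pairwise log2 expression ratio log2(x_j) - log2(x_k). Lower M means more
#' stable. Counts of zero get a pseudocount of 1 before the log.
#'
#' @param x an [NCounterSet-class].
#' @param genes candidate reference genes (default: all Housekeeping
#'   probes); at least 3 are required (M for 2 genes is left undefined).
#' @return named numeric vector of M values.
#' @seealso [genormRank()] for the iterative-elimination stability ranking.
#' @export
genormStability <- function(x, genes = housekeepingNames(x)) {
    stopifnot(is(x, "NCounterSet"))
    if (length(genes) < 3L)
        stop("geNorm M requires >= 3 candidate genes, got ", length(genes))
    lg <- .log2counts(x, genes)
    m <- vapply(seq_along(genes), function(j) {
        mean(vapply(seq_along(genes)[-j], function(k)
            sd(lg[j, ] - lg[k, ]), 0))
    }, 0)
    setNames(m, genes)
}

#' geNorm iterative-elimination ranking
#'
#' Repeatedly removes the least stable gene (highest M, ties broken by gene
#' name) and recomputes M on the remainder, until 3 genes are left. The
#' returned ranking lists genes from least to most stable; the final 3 share
#' the top stability rank.
#'
#' @inheritParams genormStability
#' @return data.frame with columns `gene`, `elimination_order` (1 = first
#'   removed, i.e. least stable), and `M_at_elimination`.
#' @export
genormRank <- function(x, genes = housekeepingNames(x)) {
    remaining <- sort(genes)
    out <- data.frame(gene = character(0), elimination_order = integer(0),
                      M_at_elimination = numeric(0))
    step <- 0L
    while (length(remaining) > 3L) {
        M <- genormStability(x, remaining)
        worst <- names(M)[order(-M, names(M))][1L]
        step <- step + 1L
        out <- rbind(out, data.frame(gene = worst, elimination_order = step,
                                     M_at_elimination = unname(M[worst])))
        remaining <- setdiff(remaining, worst)
    }
    M <- genormStability(x, remaining)
    rbind(out, data.frame(gene = names(sort(M, decreasing = TRUE)),
                          elimination_order = NA_integer_,
                          M_at_elimination = unname(sort(M, decreasing = TRUE))))
}

#' Fill an HkAssessment with stability and correlation
#'
#' Convenience wrapper: computes geNorm M and the pairwise Pearson
#' correlation matrix on log2(count + 1) for the genes passing the
#' background screen.
#'
#' @param x an [NCounterSet-class].
#' @param assessment an [HkAssessment-class] from [screenHousekeeping()].
#' @return the updated [HkAssessment-class].
#' @export
assessHousekeeping <- function(x, assessment) {
    pass <- passingHk(assessment)
    if (length(pass) >= 3L) {
        M <- genormStability(x, pass)
        assessment@stabilityM[names(M)] <- M
    }
    if (length(pass) >= 2L)
        assessment@corMatrix <- cor(t(log2(
            assay(x, "counts")[pass, , drop = FALSE] + 1)))
    validObject(assessment)
    assessment
}

#' Select a housekeeping normalization panel by pairwise correlation
#'
#' Emulates the manual selection of a small reference panel with robust
#' signal and good mutual correlation: among all subsets of `panelSize`
#' genes passing the background screen, picks the one maximizing the minimum
#' pairwise Pearson r on log2(count + 1), subject to that minimum being at
#' least `minR`. Ties are broken by lower mean geNorm M, then
#' lexicographically by sorted gene names.
#'
#' @param x an [NCounterSet-class].
#' @param assessment an [HkAssessment-class] (screen flags required; M used
#'   for tie-breaks when available).
#' @param minR minimum acceptable pairwise correlation (default 0.8).
#' @param panelSize number of genes to select (default 4).
#' @return the [HkAssessment-class] with the `panel` slot filled (access
#'   with [hkPanel()]).
#' @export
selectHkPanel <- function(x, assessment, minR = 0.8, panelSize = 4L) {
    stopifnot(minR > 0, minR <= 1)
    pass <- passingHk(assessment)
    if (length(pass) < panelSize)
        stop("only ", length(pass), " housekeeping genes pass background; ",
             "cannot select a panel of ", panelSize)
    lg <- log2(assay(x, "counts")[pass, , drop = FALSE] + 1)
    r <- cor(t(lg))
    M <- assessment@stabilityM[pass]
    if (all(is.na(M)) && length(pass) >= 3L)
        M <- genormStability(x, pass)
    subsets <- combn(sort(pass), panelSize, simplify = FALSE)
    best <- NULL; bestKey <- NULL
    for (sub in subsets) {
        rs <- r[sub, sub]
        minr <- min(rs[upper.tri(rs)])
        meanM <- if (all(is.na(M[sub]))) Inf else mean(M[sub], na.rm = TRUE)
        key <- list(-minr, meanM, paste(sub, collapse = "|"))
        if (is.null(best) ||
            key[[1]] < bestKey[[1]] - 1e-12 ||
            (abs(key[[1]] - bestKey[[1]]) <= 1e-12 &&
             (key[[2]] < bestKey[[2]] - 1e-12 ||
              (abs(key[[2]] - bestKey[[2]]) <= 1e-12 &&
               key[[3]] < bestKey[[3]])))) {
            best <- sub; bestKey <- key
        }
    }
    if (-bestKey[[1]] < minR)
        stop("no ", panelSize, "-gene panel reaches min pairwise r >= ", minR,
             " (best: ", signif(-bestKey[[1]], 3),
             "); lower minR or reduce panelSize")
    assessment@panel <- best
    validObject(assessment)
    assessment
}

#' Write a QC report
#'
#' @param background a [BackgroundProfile-class].
#' @param assessment an [HkAssessment-class].
#' @param dir output directory; writes `background.tsv` and
#'   `housekeeping.tsv`.
#' @return invisibly, the paths written.
#' @export
writeQcReport <- function(background, assessment, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    bg <- data.frame(sample_id = background@sampleId,
                     n_negative = background@nNegative,
                     neg_mean = background@mean, neg_sd = background@sd,
                     theta = background@theta)
    hk <- data.frame(gene = assessment@genes,
                     passes_background = assessment@passesBackground,
                     geNorm_M = assessment@stabilityM[assessment@genes],
                     in_panel = assessment@genes %in% assessment@panel)
    p1 <- file.path(dir, "background.tsv")
    p2 <- file.path(dir, "housekeeping.tsv")
    write.table(bg, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(hk, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(p1, p2))
}
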