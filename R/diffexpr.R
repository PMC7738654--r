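#' Unpaired two-sample t-test for one gene
#'
#' Two-sided unpaired t-test on (log2) expression values. `"student"` is the
#' pooled-variance test with df = n1 + n2 - 2; `"welch"` uses the
#' Satterthwaite approximation. Degenerate inputs are handled explicitly:
#' two constant, equal groups give t = 0, p = 1; two constant, unequal
#' groups give p = 0 with a `zero_variance` attribute.
#'
#' @param case,control numeric vectors (>= 2 finite values each).
#' @param variant `"student"` (default) or `"welch"`.
#' @return named list with `t` and `p` (and attribute `zero_variance` when
#'   both groups were constant).
#' @export
tTestGene <- function(case, control, variant = c("student", "welch")) {
    variant <- match.arg(variant)
    if (length(case) < 2L || length(control) < 2L)
        stop("each group needs >= 2 values")
    if (any(!is.finite(c(case, control))))
        stop("non-finite expression values")
    if (sd(case) == 0 && sd(control) == 0) {
        res <- if (case[1L] == control[1L]) list(t = 0, p = 1)
               else list(t = sign(mean(case) - mean(control)) * Inf, p = 0)
        attr(res, "zero_variance") <- TRUE
        return(res)
    }
    ht <- t.test(case, control, var.equal = (variant == "student"))
    list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Fold change from log2 group means
#'
#' delta is the difference of arithmetic means of the log2 values (case
#' minus control); the linear ratio is R = 2^delta; and the signed fold
#' change follows the reporting convention where down-regulation R < 1 is
#' written as -1/R, so signed FC always lies in (-Inf, -1] or [1, Inf)
#' (e.g. delta = -1 is reported as -2.0).
#'
#' @param case,control numeric vectors of log2-normalized values.
#' @return list with `delta`, `ratio` and `signed_fc`.
#' @export
foldChange <- function(case, control) {
    if (!length(case) || !length(control)) stop("empty group")
    delta <- mean(case) - mean(control)
    R <- 2 ^ delta
    list(delta = delta, ratio = R,
         signed_fc = if (R >= 1) R else -1 / R)
}

#' Differential expression over the detected genes
#'
#' Runs the per-gene unpaired t-test and fold change on log2(normalized + 1)
#' values of the detected endogenous genes, case vs control. With
#' `fcMode = "linear_means"` the ratio is instead computed from the
#' arithmetic means of the linear normalized counts (the log2-mean route is
#' the default; both are offered because published fold changes rarely say
#' which was used).
#'
#' @param x a normalized [NCounterSet-class] with group labels.
#' @param genes genes to test; typically [detectedGenes()] of a
#'   [DetectionResult-class].
#' @param variant t-test variant, see [tTestGene()].
#' @param fcMode `"log2_means"` (default) or `"linear_means"`.
#' @return data.frame with one row per gene: means, `delta`, `ratio`,
#'   `signed_fc`, `t`, `p` (uncorrected, two-sided). Run [callDegs()] to
#'   classify.
#' @export
runDE <- function(x, genes, variant = c("student", "welch"),
                  fcMode = c("log2_means", "linear_means")) {
    variant <- match.arg(variant); fcMode <- match.arg(fcMode)
    stopifnot(is(x, "NCounterSet"))
    if (!"log2" %in% assayNames(x))
        stop("x must be normalized first (normalizeCounts)")
    gr <- sampleGroups(x)
    if (any(is.na(gr)))
        stop("every sample needs a group label before DE: missing for ",
             paste(names(gr)[is.na(gr)], collapse = ", "))
    ic <- gr == "case"; ictl <- gr == "control"
    if (sum(ic) < 2L || sum(ictl) < 2L)
        stop("need >= 2 samples per group")
    lg <- assay(x, "log2")[genes, , drop = FALSE]
    lin <- assay(x, "normalized")[genes, , drop = FALSE]
    rows <- lapply(seq_along(genes), function(i) {
        tv <- tTestGene(lg[i, ic], lg[i, ictl], variant)
        if (fcMode == "log2_means") {
            fc <- foldChange(lg[i, ic], lg[i, ictl])
        } else {
            R <- mean(lin[i, ic]) / mean(lin[i, ictl])
            fc <- list(delta = log2(R), ratio = R,
                       signed_fc = if (R >= 1) R else -1 / R)
        }
        data.frame(gene = genes[i],
                   mean_log2_case = mean(lg[i, ic]),
                   mean_log2_control = mean(lg[i, ictl]),
                   delta = fc$delta, ratio = fc$ratio,
                   signed_fc = fc$signed_fc, t = tv$t, p = tv$p,
                   stringsAsFactors = FALSE)
    })
    de <- do.call(rbind, rows)
    rownames(de) <- NULL
    de
}

#' Classify differentially expressed genes
#'
#' A gene is called `up` when signed FC >= `fcCutoff` and p < `alpha`,
#' `down` when signed FC <= -`fcCutoff` and p < `alpha`, otherwise `ns`.
#' The fold-change boundary is inclusive and the p boundary strict,
#' mirroring the usual "FC of +/-1.5 and uncorrected p < 0.05" definition.
#' Benjamini-Hochberg adjusted p-values can be appended (`correction =
#' "bh"`) without changing the default calls.
#'
#' @param de data.frame from [runDE()].
#' @param fcCutoff signed fold-change magnitude, inclusive (default 1.5).
#' @param alpha p-value threshold, strict (default 0.05); must be in (0,1).
#' @param correction `"none"` (default) or `"bh"` to append `p_adj`.
#' @return the data.frame with a `call` column added; summary counts
#'   (`n_tested`, `n_up`, `n_down`) in `attr(, "summary")`.
#' @export
callDegs <- function(de, fcCutoff = 1.5, alpha = 0.05,
                     correction = c("none", "bh")) {
    correction <- match.arg(correction)
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (fcCutoff < 1) stop("fcCutoff must be >= 1")
    de$call <- "ns"
    de$call[de$signed_fc >= fcCutoff & de$p < alpha] <- "up"
    de$call[de$signed_fc <= -fcCutoff & de$p < alpha] <- "down"
    if (correction == "bh") de$p_adj <- p.adjust(de$p, "BH")
    attr(de, "summary") <- c(n_tested = nrow(de),
                             n_up = sum(de$call == "up"),
                             n_down = sum(de$call == "down"))
    de
}

#' Write the DE table and volcano coordinates
#'
#' @param de classified data.frame from [callDegs()].
#' @param dir output directory; writes `de_table.tsv` (gene, signed FC, p,
#'   delta, t, call) and `volcano.tsv` (gene, log2FC, -log10 p, call).
#' @return invisibly, the paths written.
#' @export
writeDeTables <- function(de, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "de_table.tsv")
    p2 <- file.path(dir, "volcano.tsv")
    write.table(de[order(de$p), ], p1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(volcanoTable(de), p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(p1, p2))
}
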