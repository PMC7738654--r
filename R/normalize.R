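#' Housekeeping normalization
#'
#' Computes per-sample scale factors from a housekeeping panel and rescales
#' the raw counts. With g_s the geometric mean of the panel's raw counts in
#' sample s, the factor is f_s = mean(g) / g_s (arithmetic mean over samples
#' as the fixed reference, nSolver-style), and every count in sample s is
#' multiplied by f_s. After normalization the panel's geometric mean is by
#' construction identical across samples. A `"log2"` assay holding
#' log2(normalized + 1) is added for downstream testing and clustering.
#'
#' @param x an [NCounterSet-class].
#' @param hkPanel character vector of housekeeping genes to normalize
#'   against; all must be present in `x`. Zeros inside the panel trigger a
#'   pseudocount of 1 inside the geometric mean.
#' @return the [NCounterSet-class] with assays `"normalized"` and `"log2"`
#'   added and a `normFactors` data.frame (`sample_id`, `g`, `f`) in
#'   `metadata(x)`.
#' @examples
#' cnt <- matrix(c(100L, 50L, 200L, 100L), 2,
#'               dimnames = list(c("HK_A", "HK_B"), c("s1", "s2")))
#' nc <- NCounterSet(cnt, rep("Housekeeping", 2))
#' normFactors(normalizeCounts(nc, c("HK_A", "HK_B")))$f  # 1.5, 0.75
#' @export
normalizeCounts <- function(x, hkPanel) {
    stopifnot(is(x, "NCounterSet"), length(hkPanel) >= 1L)
    missing <- setdiff(hkPanel, rownames(x))
    if (length(missing))
        stop("housekeeping gene(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    cnt <- assay(x, "counts")
    hk <- cnt[hkPanel, , drop = FALSE]
    if (any(hk == 0)) hk <- hk + 1
    g <- exp(colMeans(log(hk)))
    if (any(g == 0)) stop("zero housekeeping geometric mean in sample(s): ",
                          paste(colnames(x)[g == 0], collapse = ", "))
    f <- mean(g) / g
    norm <- sweep(cnt, 2, f, `*`)
    assay(x, "normalized") <- norm
    assay(x, "log2") <- log2(norm + 1)
    metadata(x)$normFactors <- data.frame(sample_id = colnames(x),
                                          g = unname(g), f = unname(f))
    metadata(x)$hkPanel <- hkPanel
    x
}

#' @rdname normalizeCounts
#' @return `normFactors` returns the factors data.frame (or NULL before
#'   normalization).
#' @export
normFactors <- function(x) metadata(x)$normFactors

#' @rdname normalizeCounts
#' @export
writeNormalized <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "normalized_counts.tsv")
    p2 <- file.path(dir, "norm_factors.tsv")
    d <- data.frame(Name = rownames(x), CodeClass = codeClass(x),
                    assay(x, "normalized"), check.names = FALSE)
    write.table(d, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(normFactors(x), p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(p1, p2))
}
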