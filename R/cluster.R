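#' Unsupervised hierarchical clustering of samples and genes
#'
#' Agglomerative clustering on Euclidean distance of (optionally row
#' z-scaled) log2 expression, for heatmap ordering and for checking whether
#' unsupervised structure separates case from control samples. Gene scaling
#' ("equal variance for all genes") subtracts each gene's mean and divides
#' by its standard deviation; constant genes become all-zero rows and are
#' flagged rather than producing NaN.
#'
#' @param log2mat numeric matrix of log2 values, genes x samples (>= 2 of
#'   each). Any non-finite entry is an error naming the offending cell.
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (ward.D2).
#' @param scaleGenes z-scale each gene row first (default TRUE).
#' @param distance only `"euclidean"` is offered.
#' @return a [ClusterResult-class] with sample and gene trees, leaf orders
#'   and the k = 2 sample partition.
#' @export
clusterExpression <- function(log2mat, linkage = c("average", "complete",
                                                   "ward"),
                              scaleGenes = TRUE,
                              distance = "euclidean") {
    linkage <- match.arg(linkage)
    distance <- match.arg(distance, "euclidean")
    stopifnot(nrow(log2mat) >= 2L, ncol(log2mat) >= 2L)
    bad <- which(!is.finite(log2mat), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-finite value at gene '", rownames(log2mat)[bad[1, 1]],
             "', sample '", colnames(log2mat)[bad[1, 2]], "'")
    constant <- character(0)
    m <- log2mat
    if (scaleGenes) {
        mu <- rowMeans(m)
        s <- apply(m, 1, sd)
        constant <- rownames(m)[s == 0]
        s[s == 0] <- 1
        m <- (m - mu) / s
    }
    method <- c(average = "average", complete = "complete",
                ward = "ward.D2")[[linkage]]
    sampleTree <- hclust(dist(t(m), method = "euclidean"), method = method)
    geneTree <- hclust(dist(m, method = "euclidean"), method = method)
    k2 <- cutree(sampleTree, k = 2)
    new("ClusterResult", scaled = m, sampleTree = sampleTree,
        geneTree = geneTree, sampleClusters = k2,
        constantGenes = constant)
}

#' Adjusted Rand index between two partitions
#'
#' Used to compare the unsupervised k = 2 sample clusters with the known
#' case/control labels (1 = identical partitions up to relabeling).
#'
#' @param a,b equal-length label vectors.
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab))
    si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab)))
    n2 <- comb2(length(a))
    expected <- si * sj / n2
    denom <- (si + sj) / 2 - expected
    if (denom == 0) return(1)
    (sij - expected) / denom
}

#' Volcano-plot coordinate table
#'
#' x = delta (the signed log2 fold change) and y = -log10 p for each tested
#' gene. p = 0 (possible only for degenerate zero-variance genes) is mapped
#' to a capped y with a flag column.
#'
#' @param de data.frame from [runDE()] / [callDegs()].
#' @param yCap y value substituted when p = 0 (default 320, near the
#'   double-precision floor of -log10).
#' @return data.frame with `gene`, `log2fc`, `neg_log10_p`, `capped`, and
#'   `call` when present.
#' @export
volcanoTable <- function(de, yCap = 320) {
    y <- -log10(de$p)
    capped <- !is.finite(y)
    y[capped] <- yCap
    out <- data.frame(gene = de$gene, log2fc = de$delta, neg_log10_p = y,
                      capped = capped, stringsAsFactors = FALSE)
    if (!is.null(de$call)) out$call <- de$call
    out
}

#' Write clustering outputs
#'
#' @param cl a [ClusterResult-class].
#' @param dir output directory; writes the scaled heatmap matrix, leaf
#'   orders and newick-format dendrograms.
#' @return invisibly, the paths written.
#' @export
writeClusterReport <- function(cl, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(dir, c("heatmap_matrix.tsv", "leaf_orders.tsv",
                          "sample_dendrogram.nwk", "gene_dendrogram.nwk"))
    write.table(data.frame(gene = rownames(cl@scaled), cl@scaled,
                           check.names = FALSE),
                p[1], sep = "\t", quote = FALSE, row.names = FALSE)
    lo <- data.frame(
        axis = rep(c("sample", "gene"),
                   c(ncol(cl@scaled), nrow(cl@scaled))),
        position = c(seq_len(ncol(cl@scaled)), seq_len(nrow(cl@scaled))),
        label = c(cl@sampleTree$labels[cl@sampleTree$order],
                  cl@geneTree$labels[cl@geneTree$order]))
    write.table(lo, p[2], sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(.hclustToNewick(cl@sampleTree), p[3])
    writeLines(.hclustToNewick(cl@geneTree), p[4])
    invisible(p)
}

## minimal hclust -> newick serialization (branch lengths = merge heights)
.hclustToNewick <- function(hc) {
    build <- function(i, parentH) {
        if (i < 0)
            return(sprintf("%s:%g", hc$labels[-i], parentH))
        h <- hc$height[i]
        sprintf("(%s,%s):%g", build(hc$merge[i, 1], h),
                build(hc$merge[i, 2], h), parentH - h)
    }
    n <- length(hc$height)
    paste0(sprintf("(%s,%s);",
                   build(hc$merge[n, 1], hc$height[n]),
                   build(hc$merge[n, 2], hc$height[n])))
}
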