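# independent agglomerative oracle for <= 5 leaves: recompute average-linkage
# merges from the raw distance matrix by explicit search.
bruteAverageMerges <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    merged <- list()
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters))
            for (j in seq_len(i - 1)) {
                dd <- mean(d[clusters[[i]], clusters[[j]]])
                if (dd < bestD - 1e-12) { bestD <- dd; best <- c(j, i) }
            }
        heights <- c(heights, bestD)
        merged <- c(merged, list(sort(unlist(clusters[best]))))
        clusters[[best[1]]] <- sort(c(clusters[[best[1]]],
                                      clusters[[best[2]]]))
        clusters[[best[2]]] <- NULL
    }
    list(heights = heights, members = merged)
}

hclustMembers <- function(hc) {
    n <- length(hc$height)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        grab <- function(v) if (v < 0) -v else out[[v]]
        out[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
    }
    out
}

test_that("identical samples are merged first at distance zero", {
    m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 1, 4))
    rownames(m) <- paste0("g", 1:3)
    cl <- clusterExpression(m, scaleGenes = FALSE)
    hc <- cl@sampleTree
    expect_equal(hc$height[1], 0)
    expect_setequal(hc$labels[-hc$merge[1, ]], c("s1", "s2"))
})

test_that("average-linkage merges match a brute-force oracle", {
    set.seed(19)
    for (i in 1:15) {
        ns <- sample(4:5, 1)
        m <- matrix(rnorm(6 * ns), 6, ns,
                    dimnames = list(paste0("g", 1:6), paste0("s", 1:ns)))
        cl <- clusterExpression(m, scaleGenes = FALSE)
        oracle <- bruteAverageMerges(dist(t(m)))
        expect_equal(cl@sampleTree$height, oracle$heights, tolerance = 1e-9)
        expect_equal(hclustMembers(cl@sampleTree), oracle$members)
    }
})

test_that("gene scaling gives zero-mean unit-variance rows; constants flagged", {
    m <- rbind(g1 = c(1, 5, 9, 2), g2 = c(4, 4, 4, 4), g3 = rnorm(4))
    colnames(m) <- paste0("s", 1:4)
    cl <- clusterExpression(m)
    expect_equal(unname(rowMeans(cl@scaled)), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(unname(apply(cl@scaled[c("g1", "g3"), ], 1, sd)), c(1, 1),
                 tolerance = 1e-12)
    expect_equal(unname(cl@scaled["g2", ]), rep(0, 4))
    expect_equal(cl@constantGenes, "g2")
})

test_that("non-finite input is an error naming the cell", {
    m <- matrix(1:6, 2, 3, dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
    m["gB", "s2"] <- NaN
    expect_error(clusterExpression(m), "gene 'gB', sample 's2'")
})

test_that("clustering is invariant to gene order permutation", {
    set.seed(3)
    m <- matrix(rnorm(80), 10, 8,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
    c1 <- clusterExpression(m)
    c2 <- clusterExpression(m[sample(10), ])
    expect_equal(c1@sampleTree$height, c2@sampleTree$height, tolerance = 1e-9)
    expect_equal(sampleClusters(c1), sampleClusters(c2))
})

test_that("strong planted effects separate case from control (ARI = 1)", {
    hits <- vapply(1:20, function(i) {
        cfg <- simConfig(dispersion = 0.01, fc_values = c(2.5, 4, 6),
                         seed = 700L + i)
        sim <- simulateCounterSet(cfg)
        x <- sim$object
        bg <- estimateBackground(x)
        a <- assessHousekeeping(x, screenHousekeeping(x, bg))
        a <- selectHkPanel(x, a)
        x <- normalizeCounts(x, hkPanel(a))
        det <- scoreDetection(x, bg)
        # the DEG-row heatmap input: unsupervised structure among the genes
        # that distinguish the groups (all-gene clustering is additionally
        # driven by per-sample RNA quality, as in real FFPE data)
        de <- callDegs(runDE(x, detectedGenes(det)))
        cl <- clusterExpression(assay(x, "log2")[de$gene[de$call != "ns"], ])
        adjustedRandIndex(sampleClusters(cl),
                          sampleGroups(x)[names(sampleClusters(cl))]) == 1
    }, TRUE)
    expect_gte(mean(hits), 0.95)
})

test_that("adjusted Rand index behaves at its reference points", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
    a <- rep(1:2, each = 10)
    set.seed(8)
    expect_lt(abs(mean(replicate(50,
        adjustedRandIndex(a, sample(a))))), 0.05)
})

test_that("volcano coordinates are delta and -log10 p", {
    de <- data.frame(gene = c("A", "B", "C"),
                     delta = c(1, 0, -2.5),
                     signed_fc = c(2, 1, -5.656854),
                     p = c(0.05, 1, 0))
    v <- volcanoTable(de)
    expect_equal(v$log2fc, de$delta)
    expect_equal(v$neg_log10_p[1], -log10(0.05), tolerance = 1e-9)
    expect_equal(v$neg_log10_p[2], 0)
    expect_equal(v$neg_log10_p[3], 320)  # p = 0 capped
    expect_true(v$capped[3] && !any(v$capped[1:2]))
})

test_that("newick serialization preserves topology and labels", {
    m <- matrix(rnorm(24), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    cl <- clusterExpression(m, scaleGenes = FALSE)
    dir <- withr::local_tempdir()
    writeClusterReport(cl, dir)
    nwk <- readLines(file.path(dir, "sample_dendrogram.nwk"))
    tr <- ape::read.tree(text = nwk)
    expect_setequal(tr$tip.label, paste0("s", 1:6))
    ref <- ape::as.phylo(cl@sampleTree)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ref))), 0)
})
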