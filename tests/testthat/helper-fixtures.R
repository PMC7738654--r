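# Small in-code fixtures shared across test files.

# 3-probe, 2-sample toy set (1 endogenous, 1 housekeeping, 1 negative).
toyCounterSet <- function() {
    cnt <- matrix(c(10L, 250L, 7L, 20L, 300L, 5L), nrow = 3,
                  dimnames = list(c("GENE_A", "HK_1", "NEG_A"),
                                  c("s1", "s2")))
    NCounterSet(cnt, c("Endogenous", "Housekeeping", "Negative"))
}

# A probe table for lane fixtures.
toyProbes <- function(counts = c(10L, 0L, 250L)) {
    data.frame(CodeClass = c("Endogenous", "Negative", "Housekeeping"),
               Name = c("CD4", "NEG_A", "GAPDH"),
               Accession = c("NM_000616", "nil", "NM_002046"),
               Count = counts, stringsAsFactors = FALSE)
}

# NCounterSet with explicit negative-control counts per sample (columns of
# `neg`), plus optional endogenous/housekeeping rows.
setWithNegatives <- function(neg, extra = NULL, extraClass = NULL) {
    neg <- as.matrix(neg)
    rownames(neg) <- paste0("NEG_", LETTERS[seq_len(nrow(neg))])
    cnt <- neg; cls <- rep("Negative", nrow(neg))
    if (!is.null(extra)) {
        cnt <- rbind(as.matrix(extra), neg)
        cls <- c(extraClass, cls)
    }
    colnames(cnt) <- paste0("s", seq_len(ncol(cnt)))
    storage.mode(cnt) <- "integer"
    NCounterSet(cnt, cls)
}

# Independent brute-force geNorm M: direct double loop over pairs.
bruteGenormM <- function(countMat) {
    lg <- log2(countMat + (if (any(countMat == 0)) 1 else 0))
    n <- nrow(lg)
    vapply(seq_len(n), function(j) {
        sds <- sapply(setdiff(seq_len(n), j),
                      function(k) stats::sd(lg[j, ] - lg[k, ]))
        mean(sds)
    }, 0)
}

# Independent pooled-variance t-test from the textbook formula.
bruteStudentT <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
        (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
    list(t = t, p = p)
}

# Exhaustive hypergeometric upper tail: enumerate all size-n draws from a
# universe of size N with K marked elements, count draws with >= k marks.
bruteHyperP <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
    mean(hits)
}
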