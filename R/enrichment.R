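#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated, `name <tab> description
#' <tab> gene1 <tab> gene2 ...`.
#'
#' @param file path to a GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
readGmt <- function(file) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1L],
             ": need name, description and >= 1 gene")
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(names(sets)))
        stop("duplicate gene-set names in GMT")
    sets
}

#' Exact hypergeometric over-representation analysis
#'
#' For a query gene list (e.g. the up-regulated genes) against each set of a
#' collection, computes the upper-tail hypergeometric probability of the
#' observed overlap: with N genes in the universe, K of them in the set, a
#' query of size n and overlap k, p = P(X >= k) for X hypergeometric. The
#' universe defaults to the detected-gene set, which is the background the
#' genes were actually tested on; sets with no member in the universe are
#' skipped with a warning, as are query genes outside the universe.
#'
#' @param query character vector of gene symbols.
#' @param collection named list of gene sets (see [readGmt()]).
#' @param universe character vector of background genes.
#' @param correction `"none"` (default) or `"bh"` to append `p_adj`.
#' @return data.frame sorted by ascending p (ties by term name) with
#'   columns `term`, `K` (set size in universe), `n` (query size), `k`
#'   (overlap), `p`, `neg_log10_p`, `genes` (overlap, comma-separated).
#' @examples
#' sets <- list(T_CELL = c("CD4", "CD8A", "LCK"), OTHER = c("GAPDH", "ACTB"))
#' ora(c("CD4", "LCK"), sets,
#'     universe = c("CD4", "CD8A", "LCK", "GAPDH", "ACTB", "TNF"))
#' @export
ora <- function(query, collection, universe, correction = c("none", "bh")) {
    correction <- match.arg(correction)
    universe <- unique(universe)
    N <- length(universe)
    if (N < 1L) stop("empty universe")
    outside <- setdiff(query, universe)
    if (length(outside))
        warning(length(outside), " query gene(s) outside the universe dropped: ",
                paste(head(outside, 5), collapse = ", "),
                if (length(outside) > 5) ", ...")
    query <- unique(intersect(query, universe))
    n <- length(query)
    if (n == 0L) {
        warning("empty query after intersection with universe")
        return(data.frame(term = character(0), K = integer(0), n = integer(0),
                          k = integer(0), p = numeric(0),
                          neg_log10_p = numeric(0), genes = character(0)))
    }
    rows <- lapply(names(collection), function(nm) {
        set <- intersect(collection[[nm]], universe)
        if (!length(set)) return(NULL)
        ov <- intersect(query, set)
        k <- length(ov); K <- length(set)
        p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = nm, K = K, n = n, k = k, p = p,
                   neg_log10_p = -log10(p),
                   genes = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    skipped <- names(collection)[vapply(rows, is.null, TRUE)]
    if (length(skipped))
        warning("set(s) empty after intersection with universe skipped: ",
                paste(skipped, collapse = ", "))
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(0), K = integer(0), n = integer(0),
                          k = integer(0), p = numeric(0),
                          neg_log10_p = numeric(0), genes = character(0)))
    out <- out[order(out$p, out$term), , drop = FALSE]
    if (correction == "bh") out$p_adj <- p.adjust(out$p, "BH")
    rownames(out) <- NULL
    out
}

#' Shared-annotation gene network
#'
#' A lightweight co-annotation proxy for functional interaction networks:
#' nodes are the query genes and an undirected edge joins two genes when
#' they co-occur in at least `minShared` gene sets; the edge weight is the
#' co-occurrence count. Useful as an in-repo stand-in for database-derived
#' interaction networks, which require external retrieval.
#'
#' @param query character vector of gene symbols.
#' @param collection named list of gene sets.
#' @param minShared minimum number of shared sets for an edge (default 1).
#' @return data.frame with columns `gene1`, `gene2` (gene1 < gene2),
#'   `weight`, sorted by gene pair.
#' @export
sharedTermNetwork <- function(query, collection, minShared = 1L) {
    query <- sort(unique(query))
    if (length(query) < 2L)
        return(data.frame(gene1 = character(0), gene2 = character(0),
                          weight = integer(0)))
    member <- vapply(collection, function(set) query %in% set,
                     logical(length(query)))
    if (is.null(dim(member)))
        member <- matrix(member, nrow = length(query))
    co <- member %*% t(member)
    pairs <- which(upper.tri(co) & co >= minShared, arr.ind = TRUE)
    out <- data.frame(gene1 = query[pairs[, 1L]], gene2 = query[pairs[, 2L]],
                      weight = as.integer(co[pairs]),
                      stringsAsFactors = FALSE)
    out[order(out$gene1, out$gene2), , drop = FALSE]
}
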