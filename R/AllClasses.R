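#' @import methods
#' @importFrom stats sd cor setNames
NULL

.CODE_CLASSES <- c("Endogenous", "Housekeeping", "Negative", "Positive")

#' NCounterSet: probe-by-sample nCounter counts
#'
#' `NCounterSet` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' central container of the package. Rows are codeset probes, columns are
#' samples (lanes). The `"counts"` assay holds raw nonnegative integer counts;
#' normalization adds `"normalized"` and `"log2"` assays. `rowData` carries the
#' probe class (`CodeClass`: Endogenous, Housekeeping, Negative or Positive) and
#' `Accession`; `colData` carries the optional `Group` label (`"case"` /
#' `"control"`) required before differential expression.
#'
#' @slot .. see SummarizedExperiment; no additional slots.
#' @aliases NCounterSet-class
#' @exportClass NCounterSet
setClass("NCounterSet", contains = "SummarizedExperiment")

.validNCounterSet <- function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(!is.finite(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be finite and >= 0")
    }
    if (!"CodeClass" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData column 'CodeClass' is required")
    else {
        cc <- as.character(rowData(object)$CodeClass)
        bad <- setdiff(unique(cc), .CODE_CLASSES)
        if (length(bad))
            msg <- c(msg, paste0("unknown CodeClass value(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe names (rownames) must be present and unique")
    if ("Group" %in% colnames(colData(object))) {
        gr <- as.character(colData(object)$Group)
        bad <- setdiff(unique(gr[!is.na(gr)]), c("case", "control"))
        if (length(bad))
            msg <- c(msg, "Group labels must be 'case' or 'control'")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("NCounterSet", .validNCounterSet)

#' Construct an NCounterSet
#'
#' @param counts integer matrix, probes x samples, with unique rownames and
#'   colnames (sample ids).
#' @param codeClass character vector parallel to rows, each one of
#'   `"Endogenous"`, `"Housekeeping"`, `"Negative"`, `"Positive"`.
#' @param accession optional character vector of probe accessions.
#' @param groups optional named character vector or two-column data.frame
#'   (`sample_id`, `group`) mapping samples to `"case"`/`"control"`.
#'
#' @return an [NCounterSet-class] object.
#' @examples
#' cnt <- matrix(c(10L, 5L, 0L, 20L, 7L, 1L), nrow = 3,
#'               dimnames = list(c("A", "HK1", "NEG_A"), c("s1", "s2")))
#' nc <- NCounterSet(cnt, c("Endogenous", "Housekeeping", "Negative"))
#' codeClass(nc)
#' @export
NCounterSet <- function(counts, codeClass, accession = NULL, groups = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have probe rownames")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    codeClass <- as.character(codeClass)
    if (length(codeClass) != nrow(counts))
        stop("codeClass length must equal nrow(counts)")
    if (is.null(accession)) accession <- rep(NA_character_, nrow(counts))
    rd <- S4Vectors::DataFrame(CodeClass = codeClass, Accession = accession,
                               row.names = rownames(counts))
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rd, colData = cd)
    obj <- new("NCounterSet", se)
    if (!is.null(groups)) sampleGroups(obj) <- groups
    obj
}

setMethod("show", "NCounterSet", function(object) {
    cc <- table(factor(codeClass(object), levels = .CODE_CLASSES))
    cat("NCounterSet:", nrow(object), "probes x", ncol(object), "samples\n")
    cat("  probe classes:",
        paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
    gr <- sampleGroups(object)
    if (!all(is.na(gr)))
        cat("  groups:", sum(gr == "case", na.rm = TRUE), "case /",
            sum(gr == "control", na.rm = TRUE), "control\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' @rdname NCounterSet
#' @param object,x an `NCounterSet`.
#' @export
setGeneric("codeClass", function(x) standardGeneric("codeClass"))

#' @rdname NCounterSet
#' @export
setMethod("codeClass", "NCounterSet", function(x)
    setNames(as.character(rowData(x)$CodeClass), rownames(x)))

#' @rdname NCounterSet
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname NCounterSet
#' @export
setMethod("sampleGroups", "NCounterSet", function(x) {
    if ("Group" %in% colnames(colData(x)))
        setNames(as.character(colData(x)$Group), colnames(x))
    else setNames(rep(NA_character_, ncol(x)), colnames(x))
})

#' @rdname NCounterSet
#' @param value group assignment: named character vector, or data.frame with
#'   columns `sample_id` and `group`.
#' @export
setGeneric("sampleGroups<-", function(x, value) standardGeneric("sampleGroups<-"))

#' @rdname NCounterSet
#' @export
setMethod("sampleGroups<-", "NCounterSet", function(x, value) {
    if (is.data.frame(value)) {
        if (!all(c("sample_id", "group") %in% colnames(value)))
            stop("sample sheet needs columns 'sample_id' and 'group'")
        value <- setNames(as.character(value$group), value$sample_id)
    }
    missing <- setdiff(colnames(x), names(value))
    if (length(missing))
        warning("no group label for sample(s): ", paste(missing, collapse = ", "))
    colData(x)$Group <- unname(value[colnames(x)])
    validObject(x)
    x
})

#' @rdname NCounterSet
#' @param class a probe class to subset on.
#' @return `probesOfClass` returns the `NCounterSet` restricted to one class.
#' @export
probesOfClass <- function(x, class = .CODE_CLASSES) {
    class <- match.arg(class)
    x[codeClass(x) == class, ]
}

#' @rdname NCounterSet
#' @export
housekeepingNames <- function(x) rownames(x)[codeClass(x) == "Housekeeping"]

#' @rdname NCounterSet
#' @export
endogenousNames <- function(x) rownames(x)[codeClass(x) == "Endogenous"]

#' Per-sample background threshold from negative controls
#'
#' Stores, for each sample, the mean and sample (n-1) standard deviation of the
#' negative-control probe counts and the background threshold
#' theta = mean + 2 SD.
#'
#' @slot sampleId character, sample ids.
#' @slot mean,sd,theta numeric per sample.
#' @slot nNegative integer, number of negative probes used.
#' @aliases BackgroundProfile-class
#' @exportClass BackgroundProfile
setClass("BackgroundProfile",
         representation(sampleId = "character", mean = "numeric",
                        sd = "numeric", theta = "numeric",
                        nNegative = "integer"))

setValidity("BackgroundProfile", function(object) {
    msg <- NULL
    n <- length(object@sampleId)
    if (any(lengths(list(object@mean, object@sd, object@theta)) != n))
        msg <- c(msg, "per-sample slots must have equal length")
    if (any(object@theta < object@mean - 1e-12))
        msg <- c(msg, "theta must be >= mean of negative counts")
    if (object@nNegative < 2L)
        msg <- c(msg, "background requires >= 2 negative probes")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "BackgroundProfile", function(object) {
    cat("BackgroundProfile (mean + 2 SD of", object@nNegative,
        "negative controls) for", length(object@sampleId), "samples\n")
    cat("  theta range: [", signif(min(object@theta), 4), ",",
        signif(max(object@theta), 4), "]\n")
})

#' @rdname BackgroundProfile-class
#' @param x a `BackgroundProfile`.
#' @return `theta` returns the named per-sample threshold vector.
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname BackgroundProfile-class
#' @export
setMethod("theta", "BackgroundProfile", function(x)
    setNames(x@theta, x@sampleId))

#' Housekeeping-gene assessment
#'
#' Holds background-screening flags, geNorm stability values M, the pairwise
#' Pearson correlation matrix on log2(count+1), and the selected normalization
#' panel for the housekeeping probes of an [NCounterSet-class].
#'
#' @slot genes character, housekeeping gene names.
#' @slot passesBackground named logical, TRUE if the gene clears k x theta_s in
#'   every sample.
#' @slot stabilityM named numeric, geNorm M (NA until computed).
#' @slot corMatrix pairwise Pearson r on log2 counts (0x0 until computed).
#' @slot panel character, selected normalization panel (possibly empty).
#' @aliases HkAssessment-class
#' @exportClass HkAssessment
setClass("HkAssessment",
         representation(genes = "character", passesBackground = "logical",
                        stabilityM = "numeric", corMatrix = "matrix",
                        panel = "character"))

setValidity("HkAssessment", function(object) {
    msg <- NULL
    if (length(object@passesBackground) != length(object@genes))
        msg <- c(msg, "one pass flag per gene required")
    if (length(object@stabilityM) &&
        any(object@stabilityM < 0, na.rm = TRUE))
        msg <- c(msg, "geNorm M must be nonnegative")
    if (nrow(object@corMatrix) &&
        any(abs(object@corMatrix) > 1 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(object@panel) &&
        !all(object@panel %in% object@genes[object@passesBackground]))
        msg <- c(msg, "panel must be a subset of genes passing background")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "HkAssessment", function(object) {
    cat("HkAssessment:", length(object@genes), "housekeeping genes,",
        sum(object@passesBackground), "pass background screen\n")
    if (any(!is.na(object@stabilityM)))
        cat("  geNorm M range: [",
            signif(min(object@stabilityM, na.rm = TRUE), 4), ",",
            signif(max(object@stabilityM, na.rm = TRUE), 4), "]\n")
    if (length(object@panel))
        cat("  selected panel:", paste(object@panel, collapse = ", "), "\n")
})

#' @rdname HkAssessment-class
#' @param x an `HkAssessment`.
#' @return `passingHk` returns the gene names clearing the background screen.
#' @export
passingHk <- function(x) x@genes[x@passesBackground]

#' @rdname HkAssessment-class
#' @return `stabilityM` returns the named geNorm M vector.
#' @export
stabilityM <- function(x) x@stabilityM

#' @rdname HkAssessment-class
#' @return `hkPanel` returns the selected panel.
#' @export
hkPanel <- function(x) x@panel

#' Signal-to-noise detection result
#'
#' Per-cell signal-to-noise ratios (raw count / sample background threshold)
#' and the per-gene detected flag under the configured rule. Only Endogenous
#' probes are subject to the detection filter; other classes carry `NA` flags.
#'
#' @slot snr genes x samples SNR matrix (all probes).
#' @slot detected named logical per probe (NA for non-endogenous probes).
#' @slot cutoff,minFraction,scope the rule parameters used.
#' @aliases DetectionResult-class
#' @exportClass DetectionResult
setClass("DetectionResult",
         representation(snr = "matrix", detected = "logical",
                        cutoff = "numeric", minFraction = "numeric",
                        scope = "character"))

setValidity("DetectionResult", function(object) {
    msg <- NULL
    if (any(object@snr < 0, na.rm = TRUE))
        msg <- c(msg, "SNR must be nonnegative")
    if (length(object@detected) != nrow(object@snr))
        msg <- c(msg, "one detected flag per probe required")
    if (!object@scope %in% c("any_group", "all_samples"))
        msg <- c(msg, "scope must be 'any_group' or 'all_samples'")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "DetectionResult", function(object) {
    cat("DetectionResult: SNR >", object@cutoff, "in >=",
        object@minFraction * 100, "% of samples (", object@scope, ")\n")
    cat(" ", sum(object@detected, na.rm = TRUE), "of",
        sum(!is.na(object@detected)), "endogenous genes detected\n")
})

#' @rdname DetectionResult-class
#' @param x a `DetectionResult`.
#' @return `detectedGenes` returns the endogenous genes scored as present.
#' @export
detectedGenes <- function(x) names(x@detected)[which(x@detected)]

#' @rdname DetectionResult-class
#' @return `snrMatrix` returns the full SNR matrix.
#' @export
snrMatrix <- function(x) x@snr

#' Hierarchical clustering result
#'
#' Row-scaled log2 matrix, gene and sample dendrograms, and the k = 2 sample
#' partition used to compare unsupervised structure with case/control labels.
#'
#' @slot scaled genes x samples matrix of per-gene z-scaled log2 values
#'   (constant genes set to all-zero and flagged).
#' @slot sampleTree,geneTree `hclust` objects.
#' @slot sampleClusters named integer, cutree at k = 2.
#' @slot constantGenes character, genes whose row was constant before scaling.
#' @aliases ClusterResult-class
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(scaled = "matrix", sampleTree = "ANY",
                        geneTree = "ANY", sampleClusters = "integer",
                        constantGenes = "character"))

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult:", nrow(object@scaled), "genes x",
        ncol(object@scaled), "samples\n")
    cat("  k=2 sample clusters:",
        paste(table(object@sampleClusters), collapse = " / "), "\n")
    if (length(object@constantGenes))
        cat(" ", length(object@constantGenes), "constant gene(s) zeroed\n")
})

#' @rdname ClusterResult-class
#' @param x a `ClusterResult`.
#' @return `sampleClusters` returns the named k = 2 membership vector.
#' @export
setGeneric("sampleClusters", function(x) standardGeneric("sampleClusters"))

#' @rdname ClusterResult-class
#' @export
setMethod("sampleClusters", "ClusterResult", function(x) x@sampleClusters)
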