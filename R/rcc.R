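#' RCC lane file: one sample's reporter code counts
#'
#' The nCounter digital analyzer emits one RCC text file per lane: a set of
#' section-tagged blocks (`<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>`, `<Code_Summary>`) of comma-separated key,value or
#' CodeClass,Name,Accession,Count rows. `RccLane` preserves all attribute
#' sections verbatim (unknown sections round-trip as opaque key/value blocks)
#' plus the ordered probe table.
#'
#' @slot sampleId character scalar, taken from Sample_Attributes `ID` when
#'   present.
#' @slot sections named list of named character vectors, attribute sections in
#'   file order (Code_Summary excluded).
#' @slot probes data.frame with columns CodeClass, Name, Accession, Count, in
#'   file order.
#' @aliases RccLane-class
#' @exportClass RccLane
setClass("RccLane",
         representation(sampleId = "character", sections = "list",
                        probes = "data.frame"))

setValidity("RccLane", function(object) {
    msg <- NULL
    p <- object@probes
    need <- c("CodeClass", "Name", "Accession", "Count")
    if (!all(need %in% colnames(p)))
        msg <- c(msg, "probes must have CodeClass, Name, Accession, Count")
    else {
        if (anyDuplicated(p$Name))
            msg <- c(msg, "probe names must be unique within a lane")
        if (any(!nzchar(p$Name)))
            msg <- c(msg, "probe names must be nonempty")
        if (any(p$Count < 0) || any(p$Count != floor(p$Count)))
            msg <- c(msg, "counts must be nonnegative integers")
        bad <- setdiff(unique(p$CodeClass), .CODE_CLASSES)
        if (length(bad))
            msg <- c(msg, paste0("unknown CodeClass: ", paste(bad, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "RccLane", function(object) {
    cat("RccLane '", object@sampleId, "': ", nrow(object@probes),
        " probes, sections: ", paste(names(object@sections), collapse = ", "),
        "\n", sep = "")
})

#' @rdname RccLane-class
#' @param sampleId sample identifier.
#' @param probes data.frame with columns CodeClass, Name, Accession, Count.
#' @param sections named list of named character vectors (attribute sections);
#'   a `Sample_Attributes` section with `ID = sampleId` is added if absent.
#' @export
RccLane <- function(sampleId, probes, sections = list()) {
    if (!"Sample_Attributes" %in% names(sections))
        sections$Sample_Attributes <- c(ID = sampleId)
    probes$Count <- as.integer(probes$Count)
    new("RccLane", sampleId = as.character(sampleId), sections = sections,
        probes = as.data.frame(probes, stringsAsFactors = FALSE))
}

#' Parse an RCC lane file
#'
#' Reads section-tagged RCC text into an [RccLane-class]. Every
#' `Code_Summary` row becomes one probe record; attribute sections are kept
#' verbatim so that [writeRcc()] round-trips the file.
#'
#' @param file path to an RCC file, or a character vector of lines.
#' @return an [RccLane-class].
#' @examples
#' lane <- RccLane("s1", data.frame(
#'   CodeClass = c("Endogenous", "Negative"), Name = c("CD4", "NEG_A"),
#'   Accession = c("NM_000616", "nil"), Count = c(250L, 7L)))
#' f <- tempfile(fileext = ".rcc")
#' writeRcc(lane, f)
#' identical(rccProbes(parseRcc(f)), rccProbes(lane))
#' @export
parseRcc <- function(file) {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file, warn = FALSE) else as.character(file)
    open_at <- grep("^<[^/][^>]*>\\s*$", lines)
    close_at <- grep("^</[^>]*>\\s*$", lines)
    if (length(open_at) != length(close_at))
        stop("malformed RCC: unbalanced section tags (",
             length(open_at), " open vs ", length(close_at), " close)")
    sections <- list()
    probes <- NULL
    for (i in seq_along(open_at)) {
        o <- open_at[i]; cl <- close_at[i]
        name <- sub("^<([^>]*)>\\s*$", "\\1", lines[o])
        close_name <- sub("^</([^>]*)>\\s*$", "\\1", lines[cl])
        if (cl < o || !identical(name, close_name))
            stop("malformed RCC: section '", name, "' opened at line ", o,
                 " not closed properly (line ", cl, ")")
        body <- lines[seq(o + 1L, length.out = max(cl - o - 1L, 0L))]
        body <- body[nzchar(trimws(body))]
        if (identical(name, "Code_Summary")) {
            probes <- .parseCodeSummary(body, offset = o)
        } else {
            kv <- strsplit(body, ",", fixed = TRUE)
            keys <- vapply(kv, `[`, "", 1L)
            vals <- vapply(kv, function(x)
                paste(x[-1L], collapse = ","), "")
            sections[[name]] <- setNames(vals, keys)
        }
    }
    if (is.null(probes))
        stop("malformed RCC: no <Code_Summary> section")
    sid <- sections[["Sample_Attributes"]]["ID"]
    if (is.na(sid)) sid <- "unknown_sample"
    new("RccLane", sampleId = unname(sid), sections = sections,
        probes = probes)
}

.parseCodeSummary <- function(body, offset = 0L) {
    if (!length(body)) stop("malformed RCC: empty Code_Summary")
    header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
    if (!identical(header[1:4], c("CodeClass", "Name", "Accession", "Count")))
        stop("malformed RCC: Code_Summary header at line ", offset + 1L,
             " must be CodeClass,Name,Accession,Count")
    rows <- strsplit(body[-1L], ",", fixed = TRUE)
    bad_len <- which(lengths(rows) != 4L)
    if (length(bad_len))
        stop("malformed RCC: Code_Summary row at line ",
             offset + 1L + bad_len[1L], " does not have 4 fields")
    m <- do.call(rbind, rows)
    cnt <- suppressWarnings(as.numeric(m[, 4L]))
    bad <- which(is.na(cnt) | cnt != floor(cnt) | cnt < 0)
    if (length(bad))
        stop("non-integer count for probe '", m[bad[1L], 2L], "'")
    dup <- m[duplicated(m[, 2L]), 2L]
    if (length(dup))
        stop("duplicate probe name(s) in Code_Summary: ",
             paste(unique(dup), collapse = ", "))
    data.frame(CodeClass = m[, 1L], Name = m[, 2L], Accession = m[, 3L],
               Count = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Write an RCC lane file
#'
#' Emits section-tagged RCC text such that `parseRcc(writeRcc(lane))` equals
#' `lane`. Attribute sections are written in stored order, followed by
#' `Code_Summary`.
#'
#' @param lane an [RccLane-class].
#' @param file output path or connection.
#' @return invisibly, the lines written.
#' @export
writeRcc <- function(lane, file) {
    stopifnot(is(lane, "RccLane"))
    validObject(lane)
    out <- character(0)
    for (nm in names(lane@sections)) {
        sec <- lane@sections[[nm]]
        out <- c(out, paste0("<", nm, ">"),
                 if (length(sec)) paste0(names(sec), ",", sec),
                 paste0("</", nm, ">"), "")
    }
    p <- lane@probes
    out <- c(out, "<Code_Summary>", "CodeClass,Name,Accession,Count",
             paste(p$CodeClass, p$Name, p$Accession, p$Count, sep = ","),
             "</Code_Summary>")
    writeLines(out, file)
    invisible(out)
}

#' @rdname RccLane-class
#' @param x an `RccLane`.
#' @return `rccProbes` returns the probe data.frame; `rccSections` the
#'   attribute sections.
#' @export
rccProbes <- function(x) x@probes

#' @rdname RccLane-class
#' @export
rccSections <- function(x) x@sections

#' Assemble a multi-lane NCounterSet
#'
#' Stacks RCC lanes sharing an identical probe (name, class) list into a
#' probe-by-sample [NCounterSet-class]. Probe order is taken from the first
#' lane and never silently changed: any mismatch (missing, extra or permuted
#' probes) is a hard error.
#'
#' @param lanes list of [RccLane-class] objects.
#' @param groups optional sample-to-group map (named character vector or
#'   data.frame with `sample_id`, `group`); samples without a label draw a
#'   warning here and an error at differential-expression time.
#' @return an [NCounterSet-class] with columns in lane order.
#' @export
assembleCounterSet <- function(lanes, groups = NULL) {
    stopifnot(length(lanes) >= 1L)
    ref <- lanes[[1L]]@probes
    key <- function(p) paste(p$CodeClass, p$Name, sep = "\r")
    refKey <- key(ref)
    for (i in seq_along(lanes)) {
        k <- key(lanes[[i]]@probes)
        if (!identical(k, refKey)) {
            extra <- setdiff(k, refKey); miss <- setdiff(refKey, k)
            if (length(extra) || length(miss))
                stop("probe set mismatch in lane ", i, ": missing {",
                     paste(sub(".*\r", "", miss), collapse = ", "),
                     "}, extra {",
                     paste(sub(".*\r", "", extra), collapse = ", "), "}")
            stop("probe order differs in lane ", i,
                 "; reordering is never done silently")
        }
    }
    cnt <- vapply(lanes, function(l) l@probes$Count, integer(nrow(ref)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nrow(ref))
    dimnames(cnt) <- list(ref$Name,
                          vapply(lanes, function(l) l@sampleId, ""))
    NCounterSet(cnt, ref$CodeClass, accession = ref$Accession,
                groups = groups)
}

#' Read a directory (or file list) of RCC files into an NCounterSet
#'
#' @param files character vector of RCC paths, or a single directory in which
#'   all `*.RCC`/`*.rcc` files are read in sorted order.
#' @param sampleSheet optional path to a two-column TSV (`sample_id`,
#'   `group`) or a data.frame.
#' @return an [NCounterSet-class].
#' @export
readRccSet <- function(files, sampleSheet = NULL) {
    if (length(files) == 1L && dir.exists(files))
        files <- sort(list.files(files, pattern = "\\.rcc$",
                                 ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no RCC files found")
    lanes <- lapply(files, parseRcc)
    groups <- NULL
    if (!is.null(sampleSheet)) {
        groups <- if (is.character(sampleSheet))
            read.delim(sampleSheet, stringsAsFactors = FALSE) else sampleSheet
    }
    assembleCounterSet(lanes, groups = groups)
}

#' Read/write a plain TSV count matrix
#'
#' The exchange format is a tab-separated table whose first two columns are
#' the probe name and probe class, followed by one column of raw counts per
#' sample (header row = sample ids).
#'
#' @param file path to the TSV.
#' @param groups optional sample-to-group map, as in [assembleCounterSet()].
#' @return `readCountsTsv` returns an [NCounterSet-class].
#' @export
readCountsTsv <- function(file, groups = NULL) {
    d <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 3L)
        stop("count TSV needs probe name, class, and >= 1 sample column")
    cnt <- as.matrix(d[, -(1:2), drop = FALSE])
    storage.mode(cnt) <- "integer"
    rownames(cnt) <- d[[1L]]
    NCounterSet(cnt, d[[2L]], groups = groups)
}

#' @rdname readCountsTsv
#' @param x an [NCounterSet-class].
#' @export
writeCountsTsv <- function(x, file) {
    d <- data.frame(Name = rownames(x), CodeClass = codeClass(x),
                    assay(x, "counts"), check.names = FALSE)
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write one RCC file per sample of an NCounterSet
#'
#' @param x an [NCounterSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeRccSet <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cc <- codeClass(x)
    acc <- rowData(x)$Accession
    acc[is.na(acc)] <- "nil"
    paths <- character(ncol(x))
    for (j in seq_len(ncol(x))) {
        sid <- colnames(x)[j]
        lane <- RccLane(sid, data.frame(
            CodeClass = unname(cc), Name = rownames(x), Accession = acc,
            Count = as.integer(assay(x, "counts")[, j]),
            stringsAsFactors = FALSE),
            sections = list(
                Header = c(FileVersion = "1.7", SoftwareVersion = "synthetic"),
                Sample_Attributes = c(ID = sid),
                Lane_Attributes = c(ID = as.character(j))))
        paths[j] <- file.path(dir, paste0(sid, ".RCC"))
        writeRcc(lane, paths[j])
    }
    invisible(paths)
}
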