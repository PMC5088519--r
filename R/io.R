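#' Read a log2 expression matrix
#'
#' Reads either a plain TSV (first column = feature id, header row of
#' sample ids) or the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` block of a GEO series-matrix file.
#'
#' Deposited series matrices do not always state the logarithm base, so
#' `base` lets the caller declare it; values are converted to log2.
#' A warning is emitted when the value range suggests the matrix is on a
#' linear rather than log scale (maximum > 30).
#'
#' @param path file path.
#' @param design sample design `data.frame` (see
#'   [SleepExpressionSet()]), or path to a design TSV.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @param base logarithm base of the stored values (default 2; use
#'   `exp(1)` for natural log). Values are rescaled to log2.
#' @return a validated [SleepExpressionSet-class].
#' @export
loadExpression <- function(path, design, format = c("tsv", "geo_series_matrix"),
                           base = 2) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    if (format == "geo_series_matrix") {
        i0 <- grep("^!series_matrix_table_begin", lines)
        i1 <- grep("^!series_matrix_table_end", lines)
        if (length(i0) != 1L || length(i1) != 1L || i1 <= i0 + 1L)
            stop("no series-matrix table block found in ", path)
        lines <- lines[(i0 + 1L):(i1 - 1L)]
        lines <- gsub("\"", "", lines, fixed = TRUE)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]][-1L]
    body <- fields[-1L]
    ids <- vapply(body, `[[`, character(1), 1L)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicated feature id(s): ", paste(dup, collapse = ", "))
    ncolm <- length(header)
    vals <- lapply(seq_along(body), function(i) {
        v <- body[[i]][-1L]
        if (length(v) != ncolm)
            stop(sprintf("row %d ('%s') has %d values, expected %d",
                         i, ids[i], length(v), ncolm))
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) & !(v %in% c("NA", "")))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                         v[bad[1L]], ids[i], header[bad[1L]]))
        num
    })
    m <- do.call(rbind, vals)
    dimnames(m) <- list(ids, header)
    if (anyNA(m))
        stop(sum(is.na(m)), " missing value(s) in expression matrix; ",
             "missing entries are rejected, not imputed")
    if (base != 2) m <- m * log2(base)
    if (max(m) > 30)
        warning("maximum expression value ", format(max(m), digits = 4),
                " > 30: values may be on a linear rather than log2 scale")
    if (is.character(design)) design <- loadDesign(design)
    SleepExpressionSet(m, design)
}

#' Write an expression matrix as canonical TSV
#'
#' First column `feature_id`, header row of sample ids, floats formatted
#' with 6 significant digits. The formatting is canonical: writing the
#' result of [loadExpression()] reproduces the file byte for byte.
#'
#' @param x a [SleepExpressionSet-class] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    m <- if (is(x, "SleepExpressionSet")) exprsMatrix(x) else as.matrix(x)
    txt <- apply(m, 2L, function(col) sprintf("%.6g", col))
    if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(m))
    rows <- c(paste(c("feature_id", colnames(m)), collapse = "\t"),
              paste(rownames(m), apply(txt, 1L, paste, collapse = "\t"),
                    sep = "\t"))
    writeLines(rows, path)
    invisible(path)
}

#' Read a sample design table
#'
#' TSV with required columns `sample_id`, `group`, `zt_time`,
#' `replicate_group`, `study`, `platform`.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
loadDesign <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    missing_cols <- setdiff(REQUIRED_DESIGN_COLS, colnames(d))
    if (length(missing_cols))
        stop("design lacks required column(s): ",
             paste(missing_cols, collapse = ", "))
    d$zt_time <- as.numeric(d$zt_time)
    d
}

#' Write a sample design table
#' @param design a design `data.frame`.
#' @param path output path.
#' @export
writeDesign <- function(design, path) {
    utils::write.table(design, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited format: term id, description, then member genes.
#'
#' @param path file path.
#' @param source tag recorded on the collection.
#' @return a [GeneSetCollection-class].
#' @export
loadGMT <- function(path, source = basename(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1L], " has fewer than 3 fields")
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicated term id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- ids
    descs <- stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
    GeneSetCollection(sets, names = descs, source = source)
}

#' Write a GMT gene-set collection
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGMT <- function(gsc, path) {
    lines <- vapply(names(gsc@sets), function(id) {
        paste(c(id, gsc@names[[id]], gsc@sets[[id]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read negative and positive control gene lists
#'
#' The negative-control file holds one feature id per line. The
#' positive-control file is either two-column TSV (contrast label, feature
#' id) or one id per line, in which case the set is filed under the label
#' `"all"` and applies to every contrast.
#'
#' @param neg_path,pos_path file paths; either may be `NULL`.
#' @param dataset optional [SleepExpressionSet-class]; when given, control
#'   ids absent from the dataset are flagged with a warning.
#' @return a [ControlGeneSets-class].
#' @export
loadControls <- function(neg_path = NULL, pos_path = NULL, dataset = NULL) {
    negative <- character()
    positive <- list()
    if (!is.null(neg_path)) {
        negative <- trimws(readLines(neg_path))
        negative <- unique(negative[nzchar(negative)])
    }
    if (!is.null(pos_path)) {
        lines <- trimws(readLines(pos_path))
        lines <- lines[nzchar(lines)]
        if (!length(lines)) {
            warning("positive-control file is empty")
        } else {
            fields <- strsplit(lines, "\t", fixed = TRUE)
            if (all(lengths(fields) >= 2L)) {
                lab <- vapply(fields, `[[`, character(1), 1L)
                gene <- vapply(fields, `[[`, character(1), 2L)
                positive <- split(gene, lab)
            } else {
                positive <- list(all = unique(lines))
            }
        }
    }
    cs <- ControlGeneSets(negative, positive)
    if (!is.null(dataset)) {
        all_ids <- unique(c(negative, unlist(positive, use.names = FALSE)))
        absent <- setdiff(all_ids, featureIds(dataset))
        if (length(absent))
            warning(length(absent), " control id(s) absent from dataset: ",
                    paste(utils::head(absent, 5), collapse = ", "))
    }
    cs
}
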