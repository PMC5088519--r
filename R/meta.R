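#' Harmonize feature identifiers and merge studies
#'
#' Maps platform probesets to a shared gene namespace and inner-joins the
#' studies. The multiple-mapping exclusion is applied in both directions:
#' a probeset mapping to more than one gene is dropped, and a gene hit by
#' more than one probeset within a platform is dropped (for the
#' cross-platform analysis only). Surviving features are renamed to gene
#' ids and the datasets joined on the shared genes; designs are
#' concatenated with their study and platform labels preserved.
#'
#' @param datasets list of [SleepExpressionSet-class] objects, one per
#'   study, under probeset identifiers.
#' @param mapping `data.frame` with columns `probeset_id`, `gene_id`.
#' @return a merged [SleepExpressionSet-class] under gene identifiers.
#' @export
harmonizeDatasets <- function(datasets, mapping) {
    if (length(datasets) < 2) stop("need at least two datasets to merge")
    stopifnot(all(c("probeset_id", "gene_id") %in% colnames(mapping)))
    mapping <- unique(mapping[, c("probeset_id", "gene_id")])
    multi_ps <- names(which(table(mapping$probeset_id) > 1))
    mapping <- mapping[!mapping$probeset_id %in% multi_ps, , drop = FALSE]
    mapped <- lapply(datasets, function(ds) {
        ids <- featureIds(ds)
        map <- mapping[mapping$probeset_id %in% ids, , drop = FALSE]
        # within this platform, genes hit by >1 surviving probeset are
        # multi-mapped and excluded
        multi_g <- names(which(table(map$gene_id) > 1))
        map <- map[!map$gene_id %in% multi_g, , drop = FALSE]
        m <- exprsMatrix(ds)[map$probeset_id, , drop = FALSE]
        rownames(m) <- map$gene_id
        list(m = m, design = sampleDesign(ds))
    })
    shared <- Reduce(intersect, lapply(mapped, function(x) rownames(x$m)))
    if (!length(shared))
        stop("empty gene intersection across datasets after harmonization")
    shared <- sort(shared)
    m <- do.call(cbind, lapply(mapped, function(x) x$m[shared, , drop = FALSE]))
    design <- do.call(rbind, lapply(mapped, function(x) x$design))
    rownames(design) <- NULL
    SleepExpressionSet(m, design)
}

#' Filter features by expression level
#'
#' Keeps features whose log expression exceeds `threshold` in strictly
#' more than `fraction` of the samples.
#'
#' @param dataset a [SleepExpressionSet-class].
#' @param threshold log2 expression cutoff (default 4).
#' @param fraction required fraction of samples (default 0.5, strict).
#' @return the filtered [SleepExpressionSet-class] (a warning is emitted
#'   when nothing survives).
#' @export
filterExpressed <- function(dataset, threshold = 4.0, fraction = 0.5) {
    m <- exprsMatrix(dataset)
    keep <- rowMeans(m > threshold) > fraction
    if (!any(keep))
        warning("no features exceed ", threshold, " in more than ",
                100 * fraction, "% of samples; result is empty")
    SleepExpressionSet(m[keep, , drop = FALSE], sampleDesign(dataset))
}

#' Principal-component report with covariate association
#'
#' Singular value decomposition of the gene-centered sample x gene matrix
#' (log scale, no unit-variance scaling). Reports the variance fraction
#' of each component, per-sample scores, and for each design variable the
#' one-way variance ratio of every component's scores grouped by that
#' variable, naming the variable that best separates each component. The
#' ratio is reported as adjusted R^2 so that a fine-grained variable
#' (e.g. study) is not preferred over a coarser one it nests (e.g.
#' platform) merely by having more levels.
#'
#' @param dataset a [SleepExpressionSet-class] with >= 3 samples.
#' @param n_components number of components to report (default 5).
#' @param variables design columns to test (default group, study,
#'   platform).
#' @return list: `variance_fraction`, `scores` (samples x components),
#'   `association` (`data.frame` component x variable R^2 plus
#'   `best_variable`).
#' @export
pcaReport <- function(dataset, n_components = 5,
                      variables = c("group", "study", "platform")) {
    if (ncol(dataset) < 3) stop("PCA report requires >= 3 samples")
    m <- .rowCenter(exprsMatrix(dataset))
    if (max(abs(m)) == 0) stop("matrix is constant; no variance to decompose")
    sv <- svd(t(m))
    vf <- sv$d^2 / sum(sv$d^2)
    n_components <- min(n_components, length(sv$d))
    scores <- sv$u[, seq_len(n_components), drop = FALSE] *
        rep(sv$d[seq_len(n_components)], each = nrow(sv$u))
    dimnames(scores) <- list(sampleDesign(dataset)$sample_id,
                             paste0("PC", seq_len(n_components)))
    des <- sampleDesign(dataset)
    variables <- intersect(variables, colnames(des))
    assoc <- do.call(rbind, lapply(seq_len(n_components), function(j) {
        r2 <- vapply(variables, function(v) {
            f <- factor(des[[v]])
            n <- length(f)
            if (nlevels(f) < 2 || nlevels(f) >= n) return(NA_real_)
            fit <- stats::lm.fit(stats::model.matrix(~f), scores[, j])
            raw <- 1 - sum(fit$residuals^2) /
                sum((scores[, j] - mean(scores[, j]))^2)
            1 - (1 - raw) * (n - 1) / (n - nlevels(f))
        }, numeric(1))
        out <- as.data.frame(as.list(r2))
        colnames(out) <- variables
        out
    }))
    # parsimony tie-break: a finer factor nesting a coarser one (study
    # vs platform) always scores at least as high, so among variables
    # within 0.02 of the best adjusted R^2 prefer the fewest levels
    nlev <- vapply(variables, function(v)
        nlevels(factor(des[[v]])), integer(1))
    assoc$best_variable <- apply(
        as.matrix(assoc[, variables, drop = FALSE]), 1L, function(r) {
            r[is.na(r)] <- -Inf
            near <- which(r >= max(r) - 0.02)
            variables[near[which.min(nlev[near])]]
        })
    rownames(assoc) <- paste0("PC", seq_len(n_components))
    list(variance_fraction = vf[seq_len(n_components)],
         scores = scores, association = assoc)
}
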