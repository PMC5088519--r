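#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

REQUIRED_DESIGN_COLS <- c("sample_id", "group", "zt_time",
                          "replicate_group", "study", "platform")

#' Container for a log2 expression matrix with an aligned sample design
#'
#' `SleepExpressionSet` extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with a single `"log2"`
#' assay (features x samples) and a sample design in `colData()` carrying
#' the columns `sample_id`, `group`, `zt_time`, `replicate_group`, `study`
#' and `platform`. It is the object every pipeline stage consumes and
#' produces.
#'
#' Validity requires: unique feature identifiers, all expression values
#' finite (missing values are rejected at load time rather than imputed),
#' one design row per sample column, `zt_time` in [0, 24), and
#' `replicate_group` constant within each (group, study) pair.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @aliases SleepExpressionSet-class
#' @exportClass SleepExpressionSet
setClass("SleepExpressionSet", contains = "SummarizedExperiment")

setValidity("SleepExpressionSet", function(object) {
    msg <- character()
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2' is missing")
    m <- SummarizedExperiment::assay(object, "log2")
    if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
        msg <- c(msg, "feature ids must be present and unique")
    if (any(!is.finite(m)))
        msg <- c(msg, sprintf("%d non-finite expression values (missing values are rejected, not imputed)",
                              sum(!is.finite(m))))
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(REQUIRED_DESIGN_COLS, colnames(cd))
    if (length(missing_cols))
        msg <- c(msg, paste0("design lacks required column(s): ",
                             paste(missing_cols, collapse = ", ")))
    if (!length(missing_cols)) {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_id values must be unique")
        if (any(cd$zt_time < 0 | cd$zt_time >= 24))
            msg <- c(msg, "zt_time must lie in [0, 24)")
        # a replicate group identifies biological replicates of one condition
        tab <- unique(data.frame(group = as.character(cd$group),
                                 study = as.character(cd$study),
                                 rep = as.character(cd$replicate_group)))
        if (anyDuplicated(paste(tab$group, tab$study)) ||
            anyDuplicated(paste(tab$rep, tab$study)))
            msg <- c(msg, "replicate_group must identify exactly one (group, study) pair")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SleepExpressionSet
#'
#' @param exprs numeric matrix of log2 expression, rows = features
#'   (probesets or genes), columns = samples. Row names are the feature
#'   ids; column names the sample ids.
#' @param design `data.frame` with one row per sample and at least the
#'   columns `sample_id`, `group`, `zt_time`, `replicate_group`, `study`,
#'   `platform`. Rows are matched to matrix columns by `sample_id` (order
#'   need not agree).
#' @return a validated [SleepExpressionSet-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' d <- data.frame(sample_id = c("s1", "s2"), group = "CC6", zt_time = 6,
#'                 replicate_group = "CC6.a", study = "demo", platform = "p1")
#' SleepExpressionSet(m, d)
#' @export
SleepExpressionSet <- function(exprs, design) {
    exprs <- as.matrix(exprs)
    storage.mode(exprs) <- "double"
    design <- as.data.frame(design)
    if (is.null(colnames(exprs)))
        stop("expression matrix must carry sample ids as column names")
    if (!"sample_id" %in% colnames(design))
        stop("design lacks required column(s): sample_id")
    missing_samples <- setdiff(colnames(exprs), design$sample_id)
    if (length(missing_samples))
        stop("design is missing sample(s) present in the matrix: ",
             paste(missing_samples, collapse = ", "))
    design <- design[match(colnames(exprs), design$sample_id), , drop = FALSE]
    rownames(design) <- design$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = exprs),
        colData = S4Vectors::DataFrame(design))
    new("SleepExpressionSet", se)
}

#' @describeIn SleepExpressionSet the log2 expression matrix.
#' @param x,object a `SleepExpressionSet`.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "log2")

#' @describeIn SleepExpressionSet the sample design as a plain `data.frame`.
#' @export
sampleDesign <- function(x)
    as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn SleepExpressionSet the ordered feature identifiers.
#' @export
featureIds <- function(x) rownames(x)

setMethod("show", "SleepExpressionSet", function(object) {
    cat("SleepExpressionSet:", nrow(object), "features x",
        ncol(object), "samples\n")
    g <- table(SummarizedExperiment::colData(object)$group)
    cat("groups:", paste(sprintf("%s(%d)", names(g), g), collapse = " "), "\n")
})

#' Negative and positive control gene sets
#'
#' @slot negative character vector of feature ids assumed unaffected by the
#'   treatment (used to learn unwanted variation).
#' @slot positive named list: contrast label -> character vector of feature
#'   ids independently validated as differentially expressed for that
#'   contrast (used to benchmark detection).
#' @aliases ControlGeneSets-class
#' @exportClass ControlGeneSets
setClass("ControlGeneSets",
         representation(negative = "character", positive = "list"))

setValidity("ControlGeneSets", function(object) {
    msg <- character()
    if (anyDuplicated(object@negative))
        msg <- c(msg, "duplicated negative-control ids")
    for (nm in names(object@positive)) {
        ov <- intersect(object@negative, object@positive[[nm]])
        if (length(ov))
            msg <- c(msg, sprintf("id(s) %s are both negative and positive controls (%s)",
                                  paste(utils::head(ov, 3), collapse = ","), nm))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname ControlGeneSets-class
#' @param negative,positive see slots.
#' @export
ControlGeneSets <- function(negative = character(), positive = list()) {
    new("ControlGeneSets", negative = as.character(negative),
        positive = lapply(positive, as.character))
}

#' @rdname ControlGeneSets-class
#' @param x a `ControlGeneSets`.
#' @export
negativeControls <- function(x) x@negative

#' @rdname ControlGeneSets-class
#' @param contrast optional contrast label; if omitted the full list.
#' @export
positiveControls <- function(x, contrast = NULL) {
    if (is.null(contrast)) return(x@positive)
    if (contrast %in% names(x@positive)) return(x@positive[[contrast]])
    if ("all" %in% names(x@positive)) return(x@positive[["all"]])
    character()
}

setMethod("show", "ControlGeneSets", function(object) {
    cat("ControlGeneSets:", length(object@negative), "negative;",
        "positive sets:",
        paste(sprintf("%s(%d)", names(object@positive),
                      lengths(object@positive)), collapse = " "), "\n")
})

#' Gene-set collection (GMT)
#'
#' @slot sets named list: term id -> character vector of gene ids.
#' @slot names named character: term id -> descriptive term name.
#' @slot source character tag recording where the collection came from.
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", names = "character",
                        source = "character"))

setValidity("GeneSetCollection", function(object) {
    if (any(lengths(object@sets) == 0))
        return("every gene set must be non-empty")
    if (anyDuplicated(names(object@sets)))
        return("duplicated term ids")
    TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets,names,source see slots.
#' @export
GeneSetCollection <- function(sets, names = NULL, source = "user") {
    if (is.null(names))
        names <- stats::setNames(base::names(sets), base::names(sets))
    new("GeneSetCollection", sets = lapply(sets, as.character),
        names = names, source = source)
}

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "terms from",
        object@source, "\n")
})

#' Fitted removal-of-unwanted-variation adjustment
#'
#' @slot k number of unwanted factors removed (k = 0 means no adjustment).
#' @slot W samples x k matrix of unwanted factors, columns orthonormal up
#'   to scale.
#' @slot alpha k x features loading matrix.
#' @slot adjusted the adjusted [SleepExpressionSet-class] (input minus W
#'   alpha).
#' @slot variant `"negative_controls"` or `"replicate_samples"`.
#' @slot controlIds feature ids used to estimate the factors.
#' @aliases RUVFit-class
#' @exportClass RUVFit
setClass("RUVFit",
         representation(k = "integer", W = "matrix", alpha = "matrix",
                        adjusted = "SleepExpressionSet", variant = "character",
                        controlIds = "character"))

setValidity("RUVFit", function(object) {
    msg <- character()
    if (object@k < 0) msg <- c(msg, "k must be >= 0")
    if (object@k > 0) {
        if (ncol(object@W) != object@k || nrow(object@alpha) != object@k)
            msg <- c(msg, "W / alpha dimensions disagree with k")
        cp <- crossprod(object@W)
        off <- cp - diag(diag(cp), ncol(cp))
        if (max(abs(off)) > 1e-6 * max(diag(cp)))
            msg <- c(msg, "columns of W must be orthogonal")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname RUVFit-class
#' @param x a `RUVFit`.
#' @export
adjustedData <- function(x) x@adjusted

#' @rdname RUVFit-class
#' @export
unwantedFactors <- function(x) x@W

setMethod("show", "RUVFit", function(object) {
    cat(sprintf("RUVFit: k = %d (%s variant), %d control features\n",
                object@k, object@variant, length(object@controlIds)))
})

#' Moderated differential-expression result for one contrast
#'
#' @slot table `data.frame` with one row per feature: `gene`, `logFC`
#'   (log2), `t` (moderated), `p`, `fdr` (Benjamini-Hochberg).
#' @slot contrast named character of length 3: `name`, `treatment`,
#'   `control`.
#' @slot residDf residual degrees of freedom of the per-gene linear fit.
#' @slot priorDf estimated prior degrees of freedom d0 (may be `Inf`).
#' @slot priorVar estimated prior variance s0^2.
#' @slot posteriorVar per-gene posterior (shrunken) variances.
#' @aliases DEResult-class
#' @exportClass DEResult
setClass("DEResult",
         representation(table = "data.frame", contrast = "character",
                        residDf = "numeric", priorDf = "numeric",
                        priorVar = "numeric", posteriorVar = "numeric"))

setValidity("DEResult", function(object) {
    tb <- object@table
    need <- c("gene", "logFC", "t", "p", "fdr")
    if (!all(need %in% colnames(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (any(tb$fdr < 0 | tb$fdr > 1, na.rm = TRUE))
        return("fdr must lie in [0, 1]")
    TRUE
})

#' @rdname DEResult-class
#' @param x a `DEResult`.
#' @export
deTable <- function(x) x@table

setMethod("show", "DEResult", function(object) {
    n_sig <- sum(object@table$fdr < 0.01, na.rm = TRUE)
    cat(sprintf("DEResult %s: %d genes, %d at FDR < 0.01 (d0 = %.3g, s0^2 = %.3g)\n",
                object@contrast[["name"]], nrow(object@table), n_sig,
                object@priorDf, object@priorVar))
})

#' Per-gene logFC time courses across recovery sleep
#'
#' @slot logFC genes x time-points matrix of log2 fold changes relative to
#'   time-matched controls.
#' @slot significant logical matrix of the same shape (FDR < threshold at
#'   each time point).
#' @slot times hours of recovery sleep at each column (0 = end of sleep
#'   deprivation).
#' @slot circadian logical per-gene time-of-day flag.
#' @aliases TrajectoryMatrix-class
#' @exportClass TrajectoryMatrix
setClass("TrajectoryMatrix",
         representation(logFC = "matrix", significant = "matrix",
                        times = "numeric", circadian = "logical"))

setValidity("TrajectoryMatrix", function(object) {
    msg <- character()
    if (is.unsorted(object@times, strictly = TRUE))
        msg <- c(msg, "time points must be strictly increasing")
    if (!identical(dim(object@logFC), dim(object@significant)))
        msg <- c(msg, "logFC and significance matrices must agree in shape")
    if (ncol(object@logFC) != length(object@times))
        msg <- c(msg, "one column per time point required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TrajectoryMatrix", function(object) {
    cat("TrajectoryMatrix:", nrow(object@logFC), "genes x",
        length(object@times), "time points (t =",
        paste(object@times, collapse = ","), "h)\n")
})

#' Trajectory cluster assignment with responder classes
#'
#' @slot cluster named integer: gene -> cluster id.
#' @slot classes named character: cluster id -> `"fast"`, `"slow"` or
#'   `"late_induced"` (empty until [classifyClusters()] is run).
#' @slot centers clusters x time-points matrix of mean logFC.
#' @slot sds clusters x time-points matrix of logFC standard deviations.
#' @aliases ClusterAssignment-class
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
         representation(cluster = "integer", classes = "character",
                        centers = "matrix", sds = "matrix"))

setValidity("ClusterAssignment", function(object) {
    if (length(object@classes) &&
        !all(object@classes %in% c("fast", "slow", "late_induced")))
        return("responder classes must be fast, slow or late_induced")
    TRUE
})

setMethod("show", "ClusterAssignment", function(object) {
    k <- nrow(object@centers)
    cat("ClusterAssignment:", length(object@cluster), "genes in", k,
        "clusters")
    if (length(object@classes))
        cat(" [", paste(object@classes, collapse = ", "), "]")
    cat("\n")
})

#' Exponential-decay fit of a cluster's mean logFC trajectory
#'
#' Parameterises logFC(t) = LA + (logFC0 - LA) * exp(-t / tauD) on the
#' orientation where the trajectory decreases (downregulated clusters are
#' negated before fitting; `sign` records the orientation).
#'
#' @slot logFC0 mean logFC at the end of sleep deprivation (t = 0), on the
#'   fitted orientation.
#' @slot LA lower asymptote, fixed to the minimum mean logFC of the
#'   oriented trajectory.
#' @slot tauD time constant in hours (NA when degenerate).
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical.
#' @slot sign +1 if fitted as-is, -1 if the trajectory was negated.
#' @aliases DecayFit-class
#' @exportClass DecayFit
setClass("DecayFit",
         representation(logFC0 = "numeric", LA = "numeric", tauD = "numeric",
                        rss = "numeric", converged = "logical",
                        sign = "numeric"))

setValidity("DecayFit", function(object) {
    if (isTRUE(object@converged) && !is.na(object@tauD) && object@tauD <= 0)
        return("tauD must be positive for a converged fit")
    TRUE
})

#' @rdname DecayFit-class
#' @param x a `DecayFit`.
#' @export
timeConstant <- function(x) x@tauD

setMethod("show", "DecayFit", function(object) {
    if (isTRUE(object@converged))
        cat(sprintf("DecayFit: tauD = %.3f h (logFC0 = %.3f, LA = %.3f, rss = %.3g)\n",
                    object@tauD, object@logFC0, object@LA, object@rss))
    else
        cat("DecayFit: degenerate / not converged\n")
})
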