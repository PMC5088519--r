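#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the row means of the column-sorted matrix, preserving each
#' column's rank order; tied values receive the mean of the tied
#' reference quantiles. Delegates to
#' \code{\link[limma]{normalizeQuantiles}}, whose tie handling matches
#' this definition.
#'
#' @param x a [SleepExpressionSet-class] or numeric matrix with >= 2
#'   columns.
#' @return object of the same type as `x`.
#' @export
quantileNormalize <- function(x) {
    m <- if (is(x, "SleepExpressionSet")) exprsMatrix(x) else as.matrix(x)
    if (ncol(m) < 2) stop("quantile normalization requires >= 2 samples")
    q <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(q) <- dimnames(m)
    if (is(x, "SleepExpressionSet")) SleepExpressionSet(q, sampleDesign(x))
    else q
}

# gene-centered copy of a matrix (rows = genes)
.rowCenter <- function(m) m - rowMeans(m)

#' Estimate and remove k factors of unwanted variation
#'
#' Factor-analysis batch correction: latent nuisance factors W are
#' estimated from features that carry no biology of interest and removed
#' by subtraction.
#'
#' \describe{
#' \item{`negative_controls`}{the control-gene submatrix is centered
#'   across samples and decomposed by SVD; W is the first `k` left
#'   singular vectors scaled by their singular values, the full loading
#'   matrix alpha is obtained by design-protected least squares (the
#'   group design is fit jointly with W and only the W coefficients are
#'   kept, so treatment signal cannot leak into the subtraction), and
#'   the adjusted data are `Y - W alpha`.}
#' \item{`replicate_samples`}{within each replicate group the group mean
#'   is subtracted from each sample, cancelling biology; alpha is
#'   estimated from the top `k` right singular vectors of this difference
#'   matrix restricted to the control genes (all genes are permitted as
#'   controls here, the default), each sample's W row follows by least
#'   squares of its control-gene values on alpha, and W is then
#'   re-orthonormalized (the adjustment depends only on span(W)).}
#' }
#'
#' In both variants the removed component never touches the gene means,
#' so the log2 location of each gene is preserved.
#'
#' @param dataset a [SleepExpressionSet-class].
#' @param controls negative-control feature ids
#'   (`variant = "negative_controls"`), or for
#'   `variant = "replicate_samples"` the feature ids allowed into the
#'   alpha estimation (`NULL` = all features).
#' @param k number of factors to remove; `k = 0` returns the input
#'   unchanged.
#' @param variant `"replicate_samples"` (default, uses the
#'   `replicate_group` design column) or `"negative_controls"`.
#' @return a [RUVFit-class].
#' @export
ruvFit <- function(dataset, controls = NULL, k,
                   variant = c("replicate_samples", "negative_controls")) {
    variant <- match.arg(variant)
    k <- as.integer(k)
    if (k < 0) stop("k must be >= 0")
    Y <- exprsMatrix(dataset)
    ctrl <- if (is.null(controls)) rownames(Y) else intersect(controls, rownames(Y))
    if (!length(ctrl)) stop("no control features present in the dataset")
    if (k == 0L)
        return(new("RUVFit", k = 0L, W = matrix(0, ncol(Y), 0),
                   alpha = matrix(0, 0, nrow(Y)), adjusted = dataset,
                   variant = variant, controlIds = character()))

    Yc <- .rowCenter(Y)                       # genes x samples, gene-centered
    if (variant == "negative_controls") {
        if (length(ctrl) < k)
            stop("negative_controls variant needs at least k = ", k,
                 " control genes; got ", length(ctrl))
        Z <- t(Yc[ctrl, , drop = FALSE])      # samples x controls, centered
        sv <- svd(Z)
        attainable <- sum(sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1])
        if (k > attainable)
            stop("k = ", k, " exceeds the rank of the control submatrix; ",
                 "attainable maximum is ", attainable)
        W <- sv$u[, seq_len(k), drop = FALSE] %*%
            diag(sv$d[seq_len(k)], k, k)
    } else {
        rg <- as.character(sampleDesign(dataset)$replicate_group)
        if (!any(table(rg) >= 2))
            stop("replicate_samples variant needs >= 2 samples in at least one replicate group")
        D <- t(Yc)                             # samples x genes
        for (g in unique(rg)) {
            i <- which(rg == g)
            D[i, ] <- D[i, , drop = FALSE] -
                matrix(colMeans(D[i, , drop = FALSE]), length(i),
                       ncol(D), byrow = TRUE)
        }
        Dc <- D[, ctrl, drop = FALSE]
        sv <- svd(Dc)
        attainable <- sum(sv$d > max(dim(Dc)) * .Machine$double.eps * sv$d[1])
        if (k > attainable)
            stop("k = ", k, " exceeds the rank of the replicate-difference ",
                 "control submatrix; attainable maximum is ", attainable)
        a_ctrl <- t(sv$v[, seq_len(k), drop = FALSE])   # k x controls
        # per-sample W row: least squares of control-gene values on alpha
        Zc <- t(Yc[ctrl, , drop = FALSE])                # samples x controls
        W <- Zc %*% t(a_ctrl) %*% solve(tcrossprod(a_ctrl))
        sw <- svd(W)                                     # orthonormal basis
        W <- sw$u[, seq_len(k), drop = FALSE] %*%
            diag(sw$d[seq_len(k)], k, k)
    }
    # design-protected least squares for the loadings: fit the group
    # design jointly with W and keep only the W coefficients, so the
    # treatment profile cannot leak into the subtracted component
    Xg <- stats::model.matrix(~ 0 + factor(sampleDesign(dataset)$group))
    XW <- cbind(Xg, W)
    coefs <- qr.coef(qr(XW), t(Yc))
    alpha <- coefs[ncol(Xg) + seq_len(k), , drop = FALSE]   # k x genes
    adj <- Y - t(W %*% alpha)
    rownames(W) <- colnames(Y)
    rownames(alpha) <- paste0("W", seq_len(k))
    new("RUVFit", k = k, W = W, alpha = alpha,
        adjusted = SleepExpressionSet(adj, sampleDesign(dataset)),
        variant = variant, controlIds = ctrl)
}

#' Scan candidate numbers of unwanted factors
#'
#' Runs [ruvFit()] followed by moderated differential expression for each
#' k in `0..k_max` and reports, per k: positive-control recall at
#' FDR < `fdr`, the Kolmogorov-Smirnov statistic of the negative-control
#' p-values against U(0,1), and the first-two-PC group-separation R^2.
#' The recommended k is the smallest k whose recall is within one control
#' gene of the maximum over the scan and whose negative-control p-values
#' pass the KS uniformity check (statistic below the 5 % critical value
#' `1.36 / sqrt(n)`); if no k passes the uniformity check the plateau
#' rule alone decides.
#'
#' @param dataset a [SleepExpressionSet-class].
#' @param controls a [ControlGeneSets-class] with negative controls and
#'   positive controls for `contrast`.
#' @param contrast contrast to evaluate, as a row of
#'   [defaultContrasts()]-style data (named list/character with
#'   `name`, `treatment`, `control`). Default: SD vs CC6.
#' @param k_max largest k to try.
#' @param variant passed to [ruvFit()].
#' @param fdr significance cutoff for recall.
#' @return list with `report` (`data.frame`: k, recall, ks_negative,
#'   pc_separation) and `recommended_k`.
#' @export
scanK <- function(dataset, controls,
                  contrast = defaultContrasts()[1, ],
                  k_max = 6, variant = "replicate_samples", fdr = 0.01) {
    pos <- positiveControls(controls, contrast[["name"]])
    neg <- negativeControls(controls)
    if (!length(pos) || !length(neg))
        stop("scanK requires both positive and negative controls")
    ctrl_ids <- if (variant == "negative_controls") neg else NULL
    rows <- lapply(0:k_max, function(k) {
        fit <- ruvFit(dataset, controls = ctrl_ids, k = k, variant = variant)
        de <- fitModerated(adjustedData(fit), contrast = contrast)
        tb <- deTable(de)
        pos_in <- intersect(pos, tb$gene)
        recall <- mean(tb$fdr[match(pos_in, tb$gene)] < fdr)
        negp <- tb$p[match(intersect(neg, tb$gene), tb$gene)]
        ks <- .ksUniform(negp)
        pcsep <- .pcGroupSeparation(adjustedData(fit))
        data.frame(k = k, recall = recall, ks_negative = ks,
                   pc_separation = pcsep)
    })
    report <- do.call(rbind, rows)
    n_pos <- length(intersect(pos, featureIds(dataset)))
    plateau <- report$recall >= max(report$recall) - 1 / n_pos
    ks_crit <- 1.36 / sqrt(length(intersect(neg, featureIds(dataset))))
    ok <- plateau & report$ks_negative < ks_crit
    recommended <- if (any(ok)) report$k[which(ok)[1]]
                   else report$k[which(plateau)[1]]
    list(report = report, recommended_k = recommended)
}

# KS statistic of p-values against U(0,1)
.ksUniform <- function(p) {
    p <- p[is.finite(p)]
    n <- length(p)
    if (!n) return(NA_real_)
    p <- sort(p)
    max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

# R^2 of group labels on the first two PCs of the sample covariance
.pcGroupSeparation <- function(dataset) {
    m <- .rowCenter(exprsMatrix(dataset))
    sv <- svd(t(m), nu = 2, nv = 0)
    scores <- sv$u[, 1:2, drop = FALSE] * rep(sv$d[1:2], each = nrow(sv$u))
    g <- factor(sampleDesign(dataset)$group)
    r2 <- vapply(1:2, function(j) {
        fit <- stats::lm.fit(stats::model.matrix(~g), scores[, j])
        1 - sum(fit$residuals^2) / sum((scores[, j] - mean(scores[, j]))^2)
    }, numeric(1))
    mean(r2)
}
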