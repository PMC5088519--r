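#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (`p * m / i` with the monotone
#' correction, capped at 1), via `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as `p`.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

# Newton inversion of trigamma, as used for moment matching of the prior
# degrees of freedom (monotone decreasing on (0, Inf))
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

# Closed-form empirical-Bayes hyperparameters (d0, s0^2) by moment
# matching of log sample variances: log(s^2) - digamma(d/2) + log(d/2)
# has mean log(s0^2) + digamma(d0/2) - log(d0/2) and excess variance
# trigamma(d0/2) beyond trigamma(d/2).
.estimateHyper <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 0
    if (sum(ok) < 2)
        stop("too few genes with positive residual variance to estimate the prior")
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e)
    target <- evar - trigamma(df / 2)
    if (is.finite(target) && target > 0) {
        d0 <- 2 * .trigammaInverse(target)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
        # variances consistent with a single value: infinite prior df,
        # pooled (arithmetic-mean) prior variance
        d0 <- Inf
        s02 <- mean(s2[ok])
    }
    list(d0 = d0, s02 = s02)
}

.asContrast <- function(contrast) {
    if (is.data.frame(contrast)) contrast <- as.list(contrast[1, ])
    contrast <- lapply(contrast, as.character)
    if (is.null(contrast$name))
        contrast$name <- paste0(contrast$treatment, "_vs_", contrast$control)
    c(name = contrast$name, treatment = contrast$treatment,
      control = contrast$control)
}

#' Moderated-t differential expression for one two-group contrast
#'
#' Per-gene ordinary least squares on a cell-means design over all sample
#' groups (optionally augmented with unwanted-factor covariates), followed
#' by empirical-Bayes moderation of the residual variances: the prior
#' degrees of freedom d0 and prior variance s0^2 are obtained in closed
#' form by moment matching of the log sample variances (digamma/trigamma
#' inversion), the posterior variance is
#' `(d0 s0^2 + d s_g^2) / (d0 + d)`, and the moderated t statistic
#' `logFC / (s_post sqrt(v))` is referred to a t distribution on `d0 + d`
#' degrees of freedom. Genes with zero residual variance are excluded
#' from the hyperparameter estimation but still tested.
#'
#' @param dataset a [SleepExpressionSet-class] (typically RUV-adjusted).
#' @param contrast a row of [defaultContrasts()] or a list/named vector
#'   with `treatment` and `control` group labels (and optionally `name`).
#' @param covariates optional samples x q numeric matrix (e.g.
#'   `unwantedFactors(fit)`) entered as nuisance covariates instead of
#'   adjusting by subtraction.
#' @param priorDf override for d0: `0` gives the ordinary (unmoderated)
#'   t with pooled per-gene variances, `Inf` shrinks every variance to
#'   s0^2.
#' @return a [DEResult-class]; the table preserves the dataset's feature
#'   order.
#' @export
fitModerated <- function(dataset, contrast, covariates = NULL,
                         priorDf = NULL) {
    contrast <- .asContrast(contrast)
    Y <- exprsMatrix(dataset)
    des <- sampleDesign(dataset)
    g <- factor(des$group)
    for (side in c("treatment", "control")) {
        grp <- contrast[[side]]
        if (!grp %in% levels(g))
            stop("group '", grp, "' not present in the design")
        if (sum(g == grp) < 2)
            stop("group '", grp, "' has fewer than 2 samples")
    }
    X <- stats::model.matrix(~ 0 + g)
    colnames(X) <- levels(g)
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        colnames(covariates) <- paste0("W", seq_len(ncol(covariates)))
        X <- cbind(X, covariates)
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("design matrix is rank deficient")
    df <- nrow(X) - qrX$rank
    if (df <= 0) stop("zero residual degrees of freedom")
    coefs <- qr.coef(qrX, t(Y))                      # p x genes
    res <- qr.resid(qrX, t(Y))
    s2 <- colSums(res^2) / df
    cvec <- numeric(ncol(X))
    names(cvec) <- colnames(X)
    cvec[contrast[["treatment"]]] <- 1
    cvec[contrast[["control"]]] <- -1
    logFC <- drop(crossprod(coefs, cvec))
    v <- drop(t(cvec) %*% solve(crossprod(X)) %*% cvec)

    hyper <- .estimateHyper(s2, df)
    d0 <- if (is.null(priorDf)) hyper$d0 else priorDf
    s02 <- hyper$s02
    s2post <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + df * s2) / (d0 + df)
    tstat <- logFC / sqrt(s2post * v)
    zero_var <- s2post * v == 0          # only possible when priorDf = 0
    if (any(zero_var)) {
        tstat[zero_var] <- sign(logFC[zero_var]) * Inf
        tstat[zero_var & logFC == 0] <- 0
    }
    df_total <- d0 + df
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    tb <- data.frame(gene = rownames(Y), logFC = logFC, t = tstat,
                     p = p, fdr = bhAdjust(p), row.names = NULL,
                     stringsAsFactors = FALSE)
    new("DEResult", table = tb, contrast = contrast, residDf = df,
        priorDf = d0, priorVar = s02, posteriorVar = unname(s2post))
}

#' Diagnostic summary of a differential-expression result
#'
#' @param de a [DEResult-class].
#' @param controls a [ControlGeneSets-class]; positives are looked up
#'   under the contrast name (or `"all"`).
#' @param fdr significance cutoff (default 0.01).
#' @param bins number of p-value histogram bins.
#' @return list: `recall` (fraction of positive controls with
#'   FDR < `fdr`; `NA` with a warning when no positives are present),
#'   `n_up`, `n_down`, `ks` (KS statistic of all raw p-values vs
#'   uniform), `p_hist` (bin counts), `volcano` (`data.frame` gene,
#'   logFC, neg_log10_p, significant, control).
#' @export
evaluateDE <- function(de, controls, fdr = 0.01, bins = 20) {
    tb <- deTable(de)
    pos <- positiveControls(controls, de@contrast[["name"]])
    pos_in <- intersect(pos, tb$gene)
    recall <- if (!length(pos_in)) {
        warning("no positive controls present for contrast ",
                de@contrast[["name"]], "; recall undefined")
        NA_real_
    } else mean(tb$fdr[match(pos_in, tb$gene)] < fdr)
    sig <- tb$fdr < fdr
    volcano <- data.frame(gene = tb$gene, logFC = tb$logFC,
                          neg_log10_p = -log10(tb$p), significant = sig,
                          control = tb$gene %in%
                              c(pos, negativeControls(controls)),
                          stringsAsFactors = FALSE)
    list(recall = recall,
         n_up = sum(sig & tb$logFC > 0),
         n_down = sum(sig & tb$logFC < 0),
         ks = .ksUniform(tb$p),
         p_hist = graphics::hist(tb$p, breaks = seq(0, 1, length.out = bins + 1),
                                 plot = FALSE)$counts,
         volcano = volcano)
}

#' Flag genes with time-of-day (circadian) expression differences
#'
#' Runs pairwise moderated contrasts among the undisturbed control groups
#' CC0, CC6 and CC11; a gene is flagged when any pair reaches
#' FDR < `fdr`. The flags annotate trajectories so that circadian
#' oscillation is not mistaken for a response to sleep.
#'
#' @param dataset a [SleepExpressionSet-class].
#' @param fdr significance cutoff.
#' @param covariates optional covariates passed to [fitModerated()].
#' @return named logical vector over features (empty, with a warning,
#'   when fewer than two of the control groups are present).
#' @export
circadianContrasts <- function(dataset, fdr = 0.01, covariates = NULL) {
    cc <- intersect(c("CC0", "CC6", "CC11"),
                    unique(sampleDesign(dataset)$group))
    if (length(cc) < 2) {
        warning("fewer than two of CC0/CC6/CC11 present; no circadian flags")
        return(stats::setNames(logical(0), character(0)))
    }
    if (length(cc) < 3)
        warning("only ", length(cc),
                " control groups present; circadian flags use pair(s) among ",
                paste(cc, collapse = ", "))
    flag <- stats::setNames(rep(FALSE, nrow(dataset)), featureIds(dataset))
    pairs <- utils::combn(cc, 2)
    for (j in seq_len(ncol(pairs))) {
        de <- fitModerated(dataset,
                           contrast = list(treatment = pairs[2, j],
                                           control = pairs[1, j]),
                           covariates = covariates)
        flag <- flag | (deTable(de)$fdr < fdr)
    }
    flag
}
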