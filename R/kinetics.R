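#' Assemble logFC time courses across recovery sleep
#'
#' Takes one [DEResult-class] per contrast of the recovery time course
#' (end of deprivation plus 1, 2, 3, 6 h of recovery, each against its
#' time-matched control), restricts to the union of genes significant
#' (FDR < `fdr`) in at least one contrast, and assembles their logFC in
#' time order together with per-time-point significance flags and the
#' time-of-day flag.
#'
#' @param de_results named list of [DEResult-class], one per contrast.
#' @param times hours of recovery sleep for each element of `de_results`
#'   (default 0, 1, 2, 3, 6).
#' @param circadian_flags named logical vector from
#'   [circadianContrasts()] (optional).
#' @param fdr significance cutoff.
#' @return a [TrajectoryMatrix-class] (empty, with a warning, when no
#'   gene is significant anywhere).
#' @export
buildTrajectories <- function(de_results, times = c(0, 1, 2, 3, 6),
                              circadian_flags = NULL, fdr = 0.01) {
    if (length(de_results) != length(times))
        stop("need one differential-expression result per time point; got ",
             length(de_results), " for ", length(times), " time points")
    ord <- order(times)
    de_results <- de_results[ord]
    times <- times[ord]
    tabs <- lapply(de_results, deTable)
    genes <- tabs[[1]]$gene
    for (tb in tabs) if (!identical(tb$gene, genes))
        stop("differential-expression results cover different gene sets")
    sig <- vapply(tabs, function(tb) tb$fdr < fdr,
                  logical(length(genes)))
    keep <- rowSums(sig) > 0
    if (!any(keep))
        warning("no gene is significant in any contrast; trajectory matrix is empty")
    lfc <- vapply(tabs, function(tb) tb$logFC, numeric(length(genes)))
    lfc <- lfc[keep, , drop = FALSE]
    sig <- sig[keep, , drop = FALSE]
    dimnames(lfc) <- dimnames(sig) <- list(genes[keep],
                                           names(de_results))
    circ <- stats::setNames(rep(FALSE, sum(keep)), genes[keep])
    if (!is.null(circadian_flags)) {
        hit <- intersect(names(circadian_flags), names(circ))
        circ[hit] <- circadian_flags[hit]
    }
    new("TrajectoryMatrix", logFC = lfc, significant = sig,
        times = as.numeric(times), circadian = circ)
}

#' Cluster logFC trajectories
#'
#' Agglomerative hierarchical clustering (Euclidean distance) of the
#' per-gene logFC time courses, cut to `n_clusters`. Genes are processed
#' in feature-id order so ties break deterministically.
#'
#' Clustering targets the response *pattern*: by default each gene's
#' trajectory is scaled to unit maximum absolute logFC before computing
#' distances (the sign is preserved, so induced and repressed genes
#' never co-cluster), while the reported cluster means and SDs stay on
#' the raw logFC scale. Distances on raw magnitudes group genes by
#' effect size rather than by recovery kinetics, mixing fast and slow
#' responders of similar amplitude. Ward linkage (`"ward.D2"`) is the
#' default because single outlier trajectories under complete or average
#' linkage claim whole clusters at small `n_clusters`, forcing distinct
#' kinetic classes to merge; both alternatives remain available.
#'
#' @param tm a [TrajectoryMatrix-class].
#' @param n_clusters number of clusters (default 7, the time-course
#'   pattern count of the recovery-sleep analysis).
#' @param scale `"pattern"` (default; unit-max-|logFC| shapes) or
#'   `"raw"` (Euclidean distance on the raw trajectories).
#' @param method linkage passed to `stats::hclust`.
#' @return a [ClusterAssignment-class] (responder classes empty until
#'   [classifyClusters()]).
#' @export
clusterTrajectories <- function(tm, n_clusters = 7,
                                scale = c("pattern", "raw"),
                                method = "ward.D2") {
    scale <- match.arg(scale)
    if (n_clusters < 2) stop("n_clusters must be >= 2")
    lfc <- tm@logFC[order(rownames(tm@logFC)), , drop = FALSE]
    if (nrow(lfc) < n_clusters)
        stop("fewer genes (", nrow(lfc), ") than clusters (", n_clusters, ")")
    dmat <- lfc
    if (scale == "pattern") {
        mx <- apply(abs(lfc), 1, max)
        mx[mx == 0] <- 1
        dmat <- lfc / mx
    }
    cl <- if (nrow(lfc) == n_clusters)
        stats::setNames(seq_len(n_clusters), rownames(lfc))
    else
        stats::cutree(stats::hclust(stats::dist(dmat), method = method),
                      k = n_clusters)
    centers <- do.call(rbind, lapply(seq_len(n_clusters), function(k)
        colMeans(lfc[cl == k, , drop = FALSE])))
    sds <- do.call(rbind, lapply(seq_len(n_clusters), function(k)
        apply(lfc[cl == k, , drop = FALSE], 2, stats::sd)))
    dimnames(centers) <- dimnames(sds) <-
        list(as.character(seq_len(n_clusters)), colnames(lfc))
    new("ClusterAssignment", cluster = cl, classes = character(),
        centers = centers, sds = sds)
}

#' Classify clusters into fast / slow / late-induced responders
#'
#' Operationalizes the visual classification of recovery patterns:
#' a cluster is `late_induced` when its response is absent at the end of
#' sleep deprivation (majority of member genes non-significant at t = 0)
#' but present at 6 h of recovery (majority significant); otherwise it is
#' `fast` when its mean |logFC| by t = 3 has fallen below
#' `recover_fraction` of the t = 0 value and the majority of member
#' genes are non-significant by t = 3; otherwise `slow`.
#'
#' @param ca a [ClusterAssignment-class].
#' @param tm the [TrajectoryMatrix-class] that was clustered.
#' @param recover_fraction fraction of the initial response below which a
#'   cluster counts as recovered (default 0.25).
#' @return `ca` with the `classes` slot filled.
#' @export
classifyClusters <- function(ca, tm, recover_fraction = 0.25) {
    times <- tm@times
    i0 <- which(times == 0)
    i3 <- which(times == 3)
    i6 <- which(times == 6)
    if (!length(i0) || !length(i3) || !length(i6))
        stop("classification requires time points 0, 3 and 6 h")
    sig <- tm@significant[order(rownames(tm@significant)), , drop = FALSE]
    classes <- vapply(seq_len(nrow(ca@centers)), function(k) {
        members <- names(ca@cluster)[ca@cluster == k]
        msig <- sig[members, , drop = FALSE]
        mean0 <- abs(ca@centers[k, i0])
        maj_sig0 <- mean(msig[, i0]) > 0.5
        maj_sig6 <- mean(msig[, i6]) > 0.5
        if (!maj_sig0 && maj_sig6) return("late_induced")
        recovered3 <- abs(ca@centers[k, i3]) < recover_fraction * mean0
        maj_nonsig3 <- mean(msig[, i3]) <= 0.5
        if (recovered3 && maj_nonsig3) "fast" else "slow"
    }, character(1))
    ca@classes <- stats::setNames(classes, rownames(ca@centers))
    validObject(ca)
    ca
}

#' Fit the exponential-decay time constant of a trajectory
#'
#' Models the return of a cluster's mean logFC toward baseline during
#' recovery sleep as
#' `logFC(t) = LA + (logFC0 - LA) * exp(-t / tauD)`:
#' a decreasing exponential approaching the lower asymptote LA. The
#' orientation is set by the sign of the t = 0 value (downregulated,
#' upward-recovering trajectories are negated so the decreasing form
#' applies); LA is fixed to the minimum of the oriented mean trajectory
#' and logFC0 to its t = 0 value, leaving tauD as the single free
#' parameter. tauD is estimated by least squares: a coarse grid over
#' `tau_range` is refined by golden-section/parabolic optimization, so no
#' starting value needs to be supplied by eye.
#'
#' @param trajectory numeric vector of mean logFC at `times`.
#' @param times hours of recovery (must include 0; >= 3 points).
#' @param LA known lower asymptote on the oriented (decreasing) scale;
#'   `NULL` (default) uses the minimum of the oriented trajectory. Note
#'   the approximation biases tauD low whenever the trajectory has not
#'   levelled off by the last time point; supplying the true asymptote
#'   makes noise-free inversion exact.
#' @param tau_range search range for tauD in hours.
#' @param grid_n number of coarse grid points.
#' @return a [DecayFit-class]; flat trajectories (logFC0 equal to LA)
#'   are flagged degenerate (`converged = FALSE`, `tauD = NA`).
#' @export
fitDecay <- function(trajectory, times = c(0, 1, 2, 3, 6), LA = NULL,
                     tau_range = c(0.1, 12), grid_n = 120) {
    if (length(trajectory) != length(times))
        stop("trajectory and times differ in length")
    if (length(times) < 3) stop("at least 3 time points are required")
    if (!any(times == 0)) stop("times must include 0 (end of deprivation)")
    sgn <- if (trajectory[times == 0] < 0) -1 else 1
    y <- sgn * trajectory
    if (is.null(LA)) LA <- min(y)
    y0 <- y[times == 0]
    if (y0 - LA <= 0)
        return(new("DecayFit", logFC0 = y0, LA = LA, tauD = NA_real_,
                   rss = NA_real_, converged = FALSE, sign = sgn))
    rss <- function(tau) sum((y - (LA + (y0 - LA) * exp(-times / tau)))^2)
    grid <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                    length.out = grid_n))
    gr <- vapply(grid, rss, numeric(1))
    i <- which.min(gr)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(grid_n, i + 1)]
    opt <- stats::optimize(rss, lower = lo, upper = hi, tol = 1e-9)
    # a minimum pinned to the search boundary is reported but flagged
    converged <- is.finite(opt$objective) &&
        opt$minimum > tau_range[1] * 1.001 &&
        opt$minimum < tau_range[2] * 0.999
    new("DecayFit", logFC0 = unname(y0), LA = unname(LA),
        tauD = unname(opt$minimum), rss = unname(opt$objective),
        converged = converged, sign = sgn)
}

#' Fit decay constants for every cluster
#'
#' @param ca a classified [ClusterAssignment-class].
#' @param times hours of recovery for the trajectory columns.
#' @return `data.frame`: cluster, class, logFC0, LA, tau_d, rss,
#'   converged.
#' @export
fitClusterDecays <- function(ca, times = c(0, 1, 2, 3, 6)) {
    fits <- lapply(seq_len(nrow(ca@centers)), function(k)
        fitDecay(ca@centers[k, ], times))
    data.frame(
        cluster = rownames(ca@centers),
        class = if (length(ca@classes)) unname(ca@classes)
                else NA_character_,
        logFC0 = vapply(fits, function(f) f@logFC0 * f@sign, numeric(1)),
        LA = vapply(fits, function(f) f@LA * f@sign, numeric(1)),
        tau_d = vapply(fits, function(f) f@tauD, numeric(1)),
        rss = vapply(fits, function(f) f@rss, numeric(1)),
        converged = vapply(fits, function(f) f@converged, logical(1)),
        stringsAsFactors = FALSE)
}

#' Average decay constant per responder class
#'
#' Unweighted mean of the converged cluster time constants within each
#' responder class; degenerate or unconverged fits are excluded.
#'
#' @param fits the `data.frame` from [fitClusterDecays()].
#' @return named numeric vector of class-average tauD (hours); `NA` with
#'   a warning for a class without converged fits.
#' @export
summarizeKinetics <- function(fits) {
    classes <- unique(fits$class[!is.na(fits$class)])
    out <- vapply(classes, function(cl) {
        ok <- fits$class == cl & fits$converged & !is.na(fits$tau_d)
        if (!any(ok)) {
            warning("no converged fits in class ", cl)
            return(NA_real_)
        }
        mean(fits$tau_d[ok])
    }, numeric(1))
    stats::setNames(out, classes)
}
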