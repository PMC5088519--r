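# build a TrajectoryMatrix directly from numbers
mkTM <- function(lfc, sig = NULL, times = c(0, 1, 2, 3, 6)) {
    lfc <- as.matrix(lfc)
    if (is.null(rownames(lfc)))
        rownames(lfc) <- sprintf("g%03d", seq_len(nrow(lfc)))
    colnames(lfc) <- paste0("t", times)
    if (is.null(sig)) sig <- matrix(TRUE, nrow(lfc), ncol(lfc))
    dimnames(sig) <- dimnames(lfc)
    new("TrajectoryMatrix", logFC = lfc, significant = sig,
        times = times, circadian = stats::setNames(
            rep(FALSE, nrow(lfc)), rownames(lfc)))
}

test_that("trajectory assembly takes the union of significant genes in time order", {
    genes <- c("gA", "gB", "gC")
    mkDE <- function(lfc, fdr, name) {
        new("DEResult",
            table = data.frame(gene = genes, logFC = lfc, t = 1,
                               p = fdr, fdr = fdr),
            contrast = c(name = name, treatment = "x", control = "y"),
            residDf = 10, priorDf = 5, priorVar = 0.1,
            posteriorVar = rep(0.1, 3))
    }
    # gA significant only at t=0; gB never; gC at t=6
    des <- list(SD = mkDE(c(2, 0.1, 0.2), c(0.001, 0.5, 0.9), "SD"),
                RS1 = mkDE(c(1, 0.1, 0.2), c(0.2, 0.5, 0.9), "RS1"),
                RS2 = mkDE(c(0.5, 0.1, 0.2), c(0.2, 0.5, 0.9), "RS2"),
                RS3 = mkDE(c(0.2, 0.1, 0.2), c(0.2, 0.5, 0.9), "RS3"),
                RS6 = mkDE(c(0, 0.1, 0.9), c(0.9, 0.5, 0.004), "RS6"))
    tm <- buildTrajectories(des)
    expect_setequal(rownames(tm@logFC), c("gA", "gC"))
    expect_equal(unname(tm@logFC["gA", ]), c(2, 1, 0.5, 0.2, 0))
    expect_equal(ncol(tm@logFC), 5L)
    expect_error(buildTrajectories(des[1:4]), "one differential-expression")
    # nothing significant anywhere: empty matrix plus warning
    des0 <- lapply(des, function(d) { d@table$fdr <- 0.5; d })
    expect_warning(tm0 <- buildTrajectories(des0), "no gene")
    expect_equal(nrow(tm0@logFC), 0L)
})

test_that("well-separated trajectory archetypes are recovered exactly", {
    set.seed(70)
    t5 <- c(0, 1, 2, 3, 6)
    arch1 <- 2 * exp(-t5 / 1.0)
    arch2 <- -1.5 + numeric(5)            # flat repressed archetype
    lfc <- rbind(matrix(rep(arch1, each = 20), 20) + rnorm(100, sd = 0.01),
                 matrix(rep(arch2, each = 20), 20) + rnorm(100, sd = 0.01))
    tm <- mkTM(lfc)
    ca <- clusterTrajectories(tm, n_clusters = 2)
    expect_equal(adjustedRand(ca@cluster[sprintf("g%03d", 1:40)],
                              rep(1:2, each = 20)), 1.0)
})

test_that("duplicate trajectories co-cluster and extremes give singletons", {
    lfc <- rbind(a = c(2, 1, 0.5, 0.2, 0), b = c(2, 1, 0.5, 0.2, 0),
                 c = c(-1, -1, -1, -1, -1), d = c(0, 0, 0, 0.5, 2))
    tm <- mkTM(lfc)
    ca <- clusterTrajectories(tm, n_clusters = 3)
    expect_equal(ca@cluster[["a"]], ca@cluster[["b"]])
    ca4 <- clusterTrajectories(tm, n_clusters = 4)
    expect_length(unique(ca4@cluster), 4L)
    expect_error(clusterTrajectories(tm, n_clusters = 1), "n_clusters")
    expect_error(clusterTrajectories(tm, n_clusters = 5), "fewer genes")
})

test_that("responder classification applies the recovery rules", {
    lfc <- rbind(fast = c(1.0, 0.4, 0.2, 0.05, 0.0),
                 slow = c(1.0, 0.95, 0.9, 0.8, 0.1),
                 late = c(0.0, 0.05, 0.0, 0.1, 0.9))
    # significance: fast loses it at t=2; slow keeps it through t=3;
    # late only has it at t=6
    sig <- rbind(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                 c(TRUE, TRUE, TRUE, TRUE, FALSE),
                 c(FALSE, FALSE, FALSE, FALSE, TRUE))
    tm <- mkTM(lfc, sig)
    ca <- new("ClusterAssignment",
              cluster = stats::setNames(1:3, rownames(tm@logFC)),
              classes = character(), centers = tm@logFC, sds = tm@logFC * 0)
    rownames(ca@centers) <- as.character(1:3)
    ca <- classifyClusters(ca, tm)
    expect_identical(unname(ca@classes),
                     c("fast", "slow", "late_induced"))
})

test_that("classification is invariant to gene order and global sign flip", {
    lfc <- rbind(a = c(1.0, 0.4, 0.2, 0.05, 0.0),
                 b = c(0.9, 0.38, 0.18, 0.04, 0.0))
    sig <- rbind(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                 c(TRUE, TRUE, FALSE, FALSE, FALSE))
    build <- function(m, s) {
        tm <- mkTM(m, s)
        ca <- clusterTrajectories(tm, n_clusters = 2)
        classifyClusters(ca, tm)@classes
    }
    expect_identical(unname(build(lfc, sig)), unname(build(-lfc, sig)))
    expect_identical(sort(unname(build(lfc[2:1, ], sig[2:1, ]))),
                     sort(unname(build(lfc, sig))))
})

test_that("decay fitting inverts noise-free data exactly", {
    t5 <- c(0, 1, 2, 3, 6)
    y <- 0 + (1 - 0) * exp(-t5 / 2.0)
    # with the generating asymptote supplied, the inversion is exact
    fit <- fitDecay(y, t5, LA = 0)
    expect_true(fit@converged)
    expect_equal(timeConstant(fit), 2.0, tolerance = 1e-6)
    # downregulated trajectories are negated before fitting
    fit_dn <- fitDecay(-y, t5, LA = 0)
    expect_equal(timeConstant(fit_dn), 2.0, tolerance = 1e-6)
    expect_equal(fit_dn@sign, -1)
    # the default minimum-of-trajectory asymptote is an approximation:
    # it underestimates tauD when the series has not levelled off
    fit_min <- fitDecay(y, t5)
    expect_equal(fit_min@LA, min(y))
    expect_lt(timeConstant(fit_min), 2.0)
    expect_gt(timeConstant(fit_min), 1.5)
})

test_that("decay fitting matches an exhaustive grid-search oracle", {
    set.seed(71)
    t5 <- c(0, 1, 2, 3, 6)
    y <- 1.4 * exp(-t5 / 1.8) + rnorm(5, sd = 0.05)
    fit <- fitDecay(y, t5)
    LA <- min(y); y0 <- y[1]
    taus <- seq(0.1, 12, by = 1e-3)
    rss <- vapply(taus, function(tau)
        sum((y - (LA + (y0 - LA) * exp(-t5 / tau)))^2), numeric(1))
    expect_equal(timeConstant(fit), taus[which.min(rss)], tolerance = 1e-3)
})

test_that("decay fitting is scale-equivariant and flags degenerate inputs", {
    t5 <- c(0, 1, 2, 3, 6)
    set.seed(72)
    y <- 1.2 * exp(-t5 / 1.5) + rnorm(5, sd = 0.03)
    f1 <- fitDecay(y, t5)
    f3 <- fitDecay(3 * y, t5)
    expect_equal(timeConstant(f3), timeConstant(f1), tolerance = 1e-6)
    expect_equal(f3@LA, 3 * f1@LA)
    expect_equal(f3@logFC0, 3 * f1@logFC0)
    flat <- fitDecay(rep(0.5, 5), t5)
    expect_false(flat@converged)
    expect_true(is.na(timeConstant(flat)))
    expect_error(fitDecay(c(1, 0.5), c(0, 1)), "3 time points")
})

test_that("class-average time constants pool converged fits only", {
    fits <- data.frame(cluster = c("1", "2", "3"),
                       class = c("fast", "fast", "fast"),
                       logFC0 = 1, LA = 0,
                       tau_d = c(1.0, 1.6, NA),
                       rss = c(0.01, 0.01, NA),
                       converged = c(TRUE, TRUE, FALSE))
    expect_equal(unname(summarizeKinetics(fits)["fast"]), 1.3)
    fits$converged <- FALSE
    expect_warning(out <- summarizeKinetics(fits), "no converged")
    expect_true(is.na(out[["fast"]]))
})

test_that("full-scale run recovers trajectories and fast kinetics from truth", {
    run <- pipelineFixture()
    tm <- run$artifacts$trajectories
    tg <- run$artifacts$truth$genes
    affected <- tg$gene[tg$class %in% c("fast", "slow")]
    # nearly all genuinely affected genes enter the trajectory matrix
    expect_gte(mean(affected %in% rownames(tm@logFC)), 0.95)
    # fast clusters recover the generating constant within 10 % (median);
    # slow clusters carry the known truncation bias of the fixed lower
    # asymptote and are not held to it
    fits <- run$kinetics$clusters
    fast <- fits[fits$class == "fast" & fits$converged, ]
    expect_gte(nrow(fast), 1)
    relerr <- abs(fast$tau_d - 1.3) / 1.3
    expect_lt(stats::median(relerr), 0.10)
})
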