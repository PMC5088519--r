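test_that("moderated t at d0 = 0 equals the brute-force pooled t", {
    set.seed(50)
    m <- matrix(rnorm(50 * 10, 8), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
    m[1:5, 6:10] <- m[1:5, 6:10] + 2
    d <- toyDataset(m, rep(c("CC6", "SD"), each = 5))
    de <- fitModerated(d, list(treatment = "SD", control = "CC6"), priorDf = 0)
    brute <- apply(m, 1, function(y) {
        n1 <- 5; n2 <- 5
        sp2 <- (sum((y[6:10] - mean(y[6:10]))^2) +
                    sum((y[1:5] - mean(y[1:5]))^2)) / (n1 + n2 - 2)
        (mean(y[6:10]) - mean(y[1:5])) / sqrt(sp2 * (1 / n1 + 1 / n2))
    })
    expect_lt(max(abs(deTable(de)$t - brute)), 1e-10)
    pbrute <- 2 * stats::pt(-abs(brute), df = 8)
    expect_lt(max(abs(deTable(de)$p - pbrute)), 1e-10)
})

test_that("d0 = Inf shrinks every posterior variance to the prior", {
    set.seed(51)
    d <- toyDataset(matrix(rnorm(200), 20, 10), rep(c("CC6", "SD"), each = 5))
    de <- fitModerated(d, list(treatment = "SD", control = "CC6"),
                       priorDf = Inf)
    expect_true(all(de@posteriorVar == de@priorVar))
})

test_that("moderated fit agrees with the independent reference implementation", {
    set.seed(52)
    # heterogeneous per-gene variances so the prior df is finite and the
    # digamma/trigamma moment matching is actually exercised
    sd_g <- sqrt(6 * 0.3^2 / rchisq(300, 6))
    m <- matrix(rnorm(300 * 12), 300, 12,
                dimnames = list(sprintf("g%03d", 1:300),
                                sprintf("s%02d", 1:12))) * sd_g + 7
    m[1:30, 7:12] <- m[1:30, 7:12] + 1
    d <- toyDataset(m, rep(c("CC6", "SD"), each = 6))
    de <- fitModerated(d, list(treatment = "SD", control = "CC6"))
    X <- stats::model.matrix(~ 0 + rep(c("CC6", "SD"), each = 6))
    colnames(X) <- c("CC6", "SD")
    fit <- limma::eBayes(limma::contrasts.fit(
        limma::lmFit(m, X),
        limma::makeContrasts(SD - CC6, levels = X)))
    expect_equal(de@priorDf, fit$df.prior, tolerance = 1e-8)
    expect_equal(de@priorVar, fit$s2.prior, tolerance = 1e-8)
    expect_equal(deTable(de)$t, unname(fit$t[, 1]), tolerance = 1e-10)
    expect_equal(deTable(de)$p, unname(fit$p.value[, 1]), tolerance = 1e-10)
})

test_that("a gene identical across both groups has logFC 0", {
    m <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    m[2, ] <- 5
    d <- toyDataset(m, rep(c("CC6", "SD"), each = 5))
    de <- fitModerated(d, list(treatment = "SD", control = "CC6"))
    expect_equal(deTable(de)$logFC[2], 0)
})

test_that("Benjamini-Hochberg adjustment matches hand computation and its contracts", {
    # p * m / i with the step-up monotone correction
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    # permutation equivariance
    set.seed(53)
    p <- runif(100)
    perm <- sample(100)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("DE evaluation reports recall, direction counts and uniformity", {
    sim <- simulateSleepStudy(smallConfig(seed = 60, batch_strength = 0,
                                          k_true = 0))
    de <- fitModerated(sim$dataset, defaultContrasts()[1, ])
    ev <- evaluateDE(de, sim$controls)
    expect_equal(ev$recall, 1.0)  # strong positives, no batch: all found
    expect_true(ev$n_up > 0 && ev$n_down > 0)
    expect_equal(sum(ev$p_hist), nrow(deTable(de)))
    # contrast without named positives: recall undefined with warning
    de2 <- fitModerated(sim$dataset, defaultContrasts()[5, ])
    expect_warning(ev2 <- evaluateDE(de2, sim$controls), "recall undefined")
    expect_true(is.na(ev2$recall))
})

test_that("circadian flags are sensitive for oscillating genes and specific for nulls", {
    cfg <- simulationConfig(n_genes = 3000, design = smallDesign(7),
                            frac_up = 0, frac_down = 0, frac_late = 0,
                            frac_circadian = 0.15, batch_strength = 0,
                            k_true = 0, n_negative_controls = 100,
                            n_positive_controls = 0, seed = 61)
    sim <- simulateSleepStudy(cfg)
    flags <- circadianContrasts(sim$dataset)
    tg <- sim$truth$genes
    sens <- mean(flags[tg$gene[tg$is_circadian]])
    fpr <- mean(flags[tg$gene[!tg$is_circadian]])
    expect_gte(sens, 0.9)
    expect_lte(fpr, 0.01)
})

test_that("circadian flagging degrades gracefully without control groups", {
    d <- toyDataset(matrix(rnorm(40), 4, 10), rep(c("RS1", "SD"), each = 5))
    expect_warning(flags <- circadianContrasts(d), "fewer than two")
    expect_length(flags, 0)
})
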