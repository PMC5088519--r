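test_that("quantile normalization matches the hand-computed reference", {
    # 2 genes x 2 samples: columns sort to (1,3) and (2,4); row means of
    # the sorted columns are (1.5, 3.5); both columns get that vector in
    # their original rank order
    m <- matrix(c(1, 3, 2, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    q <- quantileNormalize(m)
    expect_equal(unname(q), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
})

test_that("quantile normalization is a fixed point on identical columns and idempotent", {
    m <- matrix(c(5, 1, 7, 5, 1, 7), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
    expect_equal(quantileNormalize(m), m)
    set.seed(1)
    r <- matrix(rnorm(60), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    q1 <- quantileNormalize(r)
    expect_equal(quantileNormalize(q1), q1, tolerance = 1e-12)
    # every output column is a permutation of one common vector
    ref <- unname(sort(q1[, 1]))
    for (j in 2:6) expect_equal(unname(sort(q1[, j])), ref,
                                tolerance = 1e-12)
    expect_error(quantileNormalize(r[, 1, drop = FALSE]), "2 samples")
})

test_that("ruvFit with k = 0 is the identity and k beyond rank errors", {
    sim <- simulateSleepStudy(smallConfig(seed = 2, n_genes = 300,
                                          n_negative_controls = 40))
    fit0 <- ruvFit(sim$dataset, k = 0)
    expect_identical(exprsMatrix(adjustedData(fit0)),
                     exprsMatrix(sim$dataset))
    neg <- negativeControls(sim$controls)[1:5]
    expect_error(ruvFit(sim$dataset, controls = neg, k = 10,
                        variant = "negative_controls"),
                 "at least k = 10")
    # enough control genes, but their centered submatrix has lower rank
    toy <- toyDataset(matrix(rnorm(24), 6, 4), rep(c("CC6", "SD"), each = 2))
    expect_error(ruvFit(toy, controls = featureIds(toy), k = 5,
                        variant = "negative_controls"),
                 "attainable maximum is 3")
})

test_that("estimated unwanted factors span the true factors", {
    cfg <- smallConfig(seed = 12, k_true = 2, n_genes = 2000,
                       n_negative_controls = 300)
    sim <- simulateSleepStudy(cfg)
    for (variant in c("replicate_samples", "negative_controls")) {
        ctrl <- if (variant == "negative_controls")
            negativeControls(sim$controls) else NULL
        fit <- ruvFit(sim$dataset, controls = ctrl, k = 2, variant = variant)
        cc <- stats::cancor(unwantedFactors(fit), sim$truth$W)$cor
        expect_gt(min(cc), 0.9)
    }
})

test_that("adjustment preserves the treatment signal on noise-free data", {
    # orthogonal-by-construction W (independent of the design) and X
    cfg <- smallConfig(seed = 21, sigma_noise = 0, k_true = 2,
                       batch_strength = 1)
    sim <- simulateSleepStudy(cfg)
    tg <- sim$truth$genes
    aff <- tg$gene[tg$class %in% c("fast", "slow")]
    des <- sampleDesign(sim$dataset)
    gmd <- function(m) rowMeans(m[aff, des$group == "SD", drop = FALSE]) -
        rowMeans(m[aff, des$group == "CC6", drop = FALSE])
    before_true <- tg$beta[match(aff, tg$gene)]
    # negative-control factors carry no treatment: preservation is exact
    fit_nc <- ruvFit(sim$dataset,
                     controls = negativeControls(sim$controls), k = 2,
                     variant = "negative_controls")
    after_nc <- gmd(exprsMatrix(adjustedData(fit_nc)))
    expect_lt(max(abs(after_nc - before_true) / abs(before_true)), 0.01)
    # replicate-sample factors are regressed from all genes, which admits
    # a small self-subtraction; signal still preserved to a few percent
    fit_rs <- ruvFit(sim$dataset, k = 2)
    after_rs <- gmd(exprsMatrix(adjustedData(fit_rs)))
    expect_lt(max(abs(after_rs - before_true) / abs(before_true)), 0.05)
})

test_that("control-gene residual variance is non-increasing in k", {
    sim <- simulateSleepStudy(smallConfig(seed = 30, n_genes = 800,
                                          n_negative_controls = 100))
    neg <- negativeControls(sim$controls)
    resvar <- vapply(0:4, function(k) {
        fit <- ruvFit(sim$dataset, controls = neg, k = k,
                      variant = "negative_controls")
        m <- exprsMatrix(adjustedData(fit))[neg, ]
        mean(apply(m, 1, stats::var))
    }, numeric(1))
    expect_true(all(diff(resvar) <= 1e-10))
})

test_that("factor-count scan recovers the true k and degenerates to 0", {
    cfg <- simulationConfig(n_genes = 4000, design = smallDesign(6),
                            k_true = 3, batch_strength = 1.5,
                            n_negative_controls = 300,
                            n_positive_controls = 30, seed = 41)
    sim <- simulateSleepStudy(cfg)
    scan <- scanK(sim$dataset, sim$controls, k_max = 5)
    expect_equal(scan$recommended_k, 3)
    expect_equal(nrow(scan$report), 6L)
    # the k = 0 row reproduces the unadjusted analysis
    de0 <- fitModerated(sim$dataset, defaultContrasts()[1, ])
    pos <- positiveControls(sim$controls, "SD_vs_CC6")
    recall0 <- mean(deTable(de0)$fdr[match(pos, deTable(de0)$gene)] < 0.01)
    expect_equal(scan$report$recall[1], recall0)
    # data with no unwanted variation recommend k = 0
    sim0 <- simulateSleepStudy(simulationConfig(
        n_genes = 3000, design = smallDesign(6), k_true = 0,
        batch_strength = 0, n_negative_controls = 300,
        n_positive_controls = 30, seed = 42))
    scan0 <- scanK(sim0$dataset, sim0$controls, k_max = 3)
    expect_equal(scan0$recommended_k, 0)
})
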