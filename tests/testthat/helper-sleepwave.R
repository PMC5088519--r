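# shared builders and one memoized full-scale pipeline run

# tiny deterministic dataset: `values` is genes x samples
toyDataset <- function(values, groups, zt = NULL, study = "toy",
                       platform = "p1") {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    if (is.null(zt)) zt <- rep(6, length(groups))
    SleepExpressionSet(values, data.frame(
        sample_id = colnames(values), group = groups, zt_time = zt,
        replicate_group = paste(groups, study, sep = "."),
        study = study, platform = platform, stringsAsFactors = FALSE))
}

# scaled-down study design: same 10 groups, fewer replicates
smallDesign <- function(n = 5) {
    d <- defaultStudyDesign()
    d$n_replicates <- n
    d
}

smallConfig <- function(seed = 1, ...) {
    args <- list(n_genes = 1500, design = smallDesign(6), seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    # control-set sizes that stay feasible as n_genes shrinks
    if (is.null(args$n_negative_controls))
        args$n_negative_controls <- round(args$n_genes / 10)
    if (is.null(args$n_positive_controls))
        args$n_positive_controls <- max(5, round(args$n_genes / 150))
    do.call(simulationConfig, args)
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sum_ij <- sum(comb2(tab))
    sum_a <- sum(comb2(rowSums(tab)))
    sum_b <- sum(comb2(colSums(tab)))
    n <- comb2(sum(tab))
    exp_idx <- sum_a * sum_b / n
    (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# one full-scale default pipeline run, computed once per test session
.fixture_env <- new.env(parent = emptyenv())
pipelineFixture <- function() {
    if (is.null(.fixture_env$run)) {
        .fixture_env$sim_cfg <- simulationConfig(seed = 2024)
        .fixture_env$run <- runPipeline(
            pipelineConfig(synthetic = .fixture_env$sim_cfg, seed = 2024))
    }
    .fixture_env$run
}
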