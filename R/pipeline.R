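#' Pipeline configuration
#'
#' Collects stage parameters for [runPipeline()]. Defaults reproduce the
#' recovery-sleep analysis settings: FDR 0.01, expression filter
#' (log2 > 4 in more than half the samples) disabled for synthetic input,
#' seven trajectory clusters, EASE 0.05 / kappa 0.2 / score 1.5
#' enrichment thresholds.
#'
#' @param synthetic a [simulationConfig()], or `NULL` to read files.
#' @param expression_path,design_path,neg_controls_path,pos_controls_path
#'   input files used when `synthetic` is `NULL`.
#' @param gmt_path optional GMT file enabling the enrichment stage.
#' @param quantile_normalize run quantile normalization first.
#' @param filter_threshold,filter_fraction expression filter
#'   ([filterExpressed()]); `NULL` threshold disables the filter.
#' @param ruv_variant RUV flavour ([ruvFit()]).
#' @param k number of unwanted factors; `NULL` selects k by [scanK()].
#' @param k_max scan range when `k` is `NULL`.
#' @param de_on_adjusted run differential expression on the adjusted
#'   matrix (default); `FALSE` keeps the unadjusted matrix and enters W
#'   as covariates instead.
#' @param fdr significance cutoff throughout.
#' @param n_clusters trajectory cluster count.
#' @param recover_fraction responder-classification threshold
#'   ([classifyClusters()]).
#' @param ease_cutoff,similarity_threshold,group_membership,score_cutoff
#'   enrichment thresholds.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(synthetic = simulationConfig(),
                           expression_path = NULL, design_path = NULL,
                           neg_controls_path = NULL,
                           pos_controls_path = NULL, gmt_path = NULL,
                           quantile_normalize = TRUE,
                           filter_threshold = NULL, filter_fraction = 0.5,
                           ruv_variant = "replicate_samples",
                           k = NULL, k_max = 6,
                           de_on_adjusted = TRUE,
                           fdr = 0.01, n_clusters = 7,
                           recover_fraction = 0.25,
                           ease_cutoff = 0.05, similarity_threshold = 0.2,
                           group_membership = 2, score_cutoff = 1.5,
                           seed = 1L) {
    cfg <- as.list(environment())
    if (is.null(synthetic)) {
        for (p in c("expression_path", "design_path")) {
            if (is.null(cfg[[p]])) stop(p, " is required without synthetic input")
            if (!file.exists(cfg[[p]])) stop("file not found: ", cfg[[p]])
        }
    }
    if (fdr < 0 || fdr > 1) stop("fdr must lie in [0, 1]")
    if (n_clusters < 2) stop("n_clusters must be >= 2")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the arguments of [pipelineConfig()]; a
#' `synthetic:` mapping holds [simulationConfig()] fields.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
loadPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$synthetic)) {
        y$synthetic <- do.call(simulationConfig, y$synthetic)
    }
    do.call(pipelineConfig, y)
}

# deterministic per-stage seed fan-out (kept below 2^31)
.stageSeed <- function(seed, stage)
    (as.integer(seed) * 1009L + stage * 9973L) %% 2147483562L

#' Run the full analysis pipeline
#'
#' Stage order: load or simulate -> quantile normalization ->
#' (optional expression filter) -> RUV with fixed or scanned k ->
#' moderated differential expression against time-matched controls ->
#' circadian flags -> trajectory assembly, clustering, responder
#' classification -> exponential-decay time constants -> (optional)
#' functional enrichment of the fast and slow responder gene lists.
#' Deterministic given the config seed.
#'
#' @param config a [pipelineConfig()].
#' @return a `RunReport` list with one section per executed stage
#'   (gene counts, DE counts per contrast, recall, chosen k, cluster
#'   classes and time constants, class-average tauD, enrichment
#'   clusters), plus `config_echo`, `seed` and `version`. Serializable
#'   with [writeRunReport()].
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    report <- list(version = as.character(utils::packageVersion("sleepwave")),
                   seed = config$seed,
                   config_echo = config[!vapply(config, is.function, TRUE)])
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    truth <- NULL
    if (!is.null(config$synthetic)) {
        sim <- stage("simulate", {
            cfg <- config$synthetic
            cfg$seed <- .stageSeed(config$seed, 1L)
            simulateSleepStudy(cfg)
        })
        dataset <- sim$dataset; controls <- sim$controls; truth <- sim$truth
    } else {
        dataset <- stage("load", loadExpression(config$expression_path,
                                                config$design_path))
        controls <- stage("load", loadControls(config$neg_controls_path,
                                               config$pos_controls_path,
                                               dataset))
    }
    report$input <- list(n_genes = nrow(dataset), n_samples = ncol(dataset),
                         groups = as.list(table(sampleDesign(dataset)$group)))

    if (isTRUE(config$quantile_normalize))
        dataset <- stage("quantile_normalize", quantileNormalize(dataset))
    if (!is.null(config$filter_threshold)) {
        dataset <- stage("filter", filterExpressed(dataset,
                                                   config$filter_threshold,
                                                   config$filter_fraction))
        report$filter <- list(n_genes_kept = nrow(dataset))
    }

    contrasts <- defaultContrasts()
    k <- config$k
    if (is.null(k)) {
        scan <- stage("scan_k", scanK(dataset, controls,
                                      contrast = contrasts[1, ],
                                      k_max = config$k_max,
                                      variant = config$ruv_variant,
                                      fdr = config$fdr))
        k <- scan$recommended_k
        report$scan_k <- list(recommended_k = k, report = scan$report)
    }
    ruv <- stage("ruv", ruvFit(dataset,
                               controls = if (config$ruv_variant ==
                                              "negative_controls")
                                   negativeControls(controls) else NULL,
                               k = k, variant = config$ruv_variant))
    report$ruv <- list(k = k, variant = config$ruv_variant)
    de_data <- if (isTRUE(config$de_on_adjusted)) adjustedData(ruv) else dataset
    covars <- if (isTRUE(config$de_on_adjusted)) NULL
              else if (k > 0) unwantedFactors(ruv) else NULL

    de_results <- stage("differential_expression", {
        res <- lapply(seq_len(nrow(contrasts)), function(i)
            fitModerated(de_data, contrasts[i, ], covariates = covars))
        names(res) <- contrasts$name
        res
    })
    report$differential_expression <- lapply(de_results, function(de) {
        ev <- suppressWarnings(evaluateDE(de, controls, fdr = config$fdr))
        list(n_up = ev$n_up, n_down = ev$n_down, recall = ev$recall,
             ks = ev$ks)
    })

    circ <- stage("circadian", circadianContrasts(de_data, fdr = config$fdr,
                                                  covariates = covars))
    report$circadian <- list(n_flagged = sum(circ))

    tm <- stage("trajectories",
                buildTrajectories(de_results, times = contrasts$recovery_h,
                                  circadian_flags = circ, fdr = config$fdr))
    report$trajectories <- list(n_genes = nrow(tm@logFC))
    if (nrow(tm@logFC) >= config$n_clusters) {
        ca <- stage("clustering", {
            ca <- clusterTrajectories(tm, config$n_clusters)
            classifyClusters(ca, tm, config$recover_fraction)
        })
        fits <- stage("kinetics", fitClusterDecays(ca, times = tm@times))
        class_tau <- suppressWarnings(summarizeKinetics(fits))
        report$kinetics <- list(
            clusters = fits,
            cluster_sizes = as.list(table(ca@cluster)),
            class_tau = as.list(class_tau))
        if (!is.null(config$gmt_path)) {
            gsc <- stage("enrichment", loadGMT(config$gmt_path))
            genes_all <- featureIds(de_data)
            enr <- lapply(c(fast = "fast", slow = "slow"), function(cl) {
                members <- names(ca@cluster)[ca@cluster %in%
                    names(ca@classes)[ca@classes == cl]]
                if (length(members) < 2) return(NULL)
                stage("enrichment",
                      enrichGeneList(members, gsc, background = genes_all,
                                     ease_cutoff = config$ease_cutoff,
                                     similarity_threshold =
                                         config$similarity_threshold,
                                     group_membership = config$group_membership,
                                     score_cutoff = config$score_cutoff))
            })
            report$enrichment <- lapply(enr, function(e)
                if (is.null(e)) NULL else e$headline)
        }
        report$artifacts <- list(trajectories = tm, clusters = ca,
                                 de_results = de_results, ruv = ruv,
                                 truth = truth)
    } else {
        warning("too few significant genes (", nrow(tm@logFC),
                ") for trajectory clustering; kinetics skipped")
        report$artifacts <- list(trajectories = tm, de_results = de_results,
                                 ruv = ruv, truth = truth)
    }
    class(report) <- "RunReport"
    report
}

#' Serialize a run report to JSON
#'
#' Drops the in-memory `artifacts` section (S4 objects) and writes the
#' summary sections; [loadRunReport()] restores them.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param path output JSON path.
#' @export
writeRunReport <- function(report, path) {
    out <- unclass(report)
    out$artifacts <- NULL
    out$config_echo <- lapply(out$config_echo, function(x)
        if (is.data.frame(x) || is.list(x)) NULL else x)
    out$config_echo <- out$config_echo[!vapply(out$config_echo, is.null, TRUE)]
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, na = "null")
    invisible(path)
}

#' @rdname writeRunReport
#' @return `loadRunReport`: the report as a list.
#' @export
loadRunReport <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
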