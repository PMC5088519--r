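#' Default study design: 96 arrays across 10 groups
#'
#' Undisturbed circadian controls at ZT 0/6/7/8/11, sleep deprivation
#' ending at ZT6, and recovery-sleep groups sacrificed after 1, 2, 3 or 6 h
#' of recovery. Replicate counts (9-10 per group) total 96 arrays.
#'
#' @return `data.frame` with columns `group`, `zt_time`, `recovery_h`
#'   (hours of recovery sleep; `NA` for undisturbed controls, 0 for SD)
#'   and `n_replicates`.
#' @export
defaultStudyDesign <- function() {
    data.frame(
        group       = c("CC0", "CC6", "CC7", "CC8", "CC11",
                        "SD", "RS1", "RS2", "RS3", "RS6"),
        zt_time     = c(0, 6, 7, 8, 11, 6, 7, 8, 9, 12),
        recovery_h  = c(NA, NA, NA, NA, NA, 0, 1, 2, 3, 6),
        n_replicates = c(10, 10, 10, 10, 9, 10, 10, 9, 9, 9),
        stringsAsFactors = FALSE)
}

#' The study-design contrast set
#'
#' Each sleep-deprivation / recovery-sleep group is compared to its
#' time-matched undisturbed control: SD vs CC6, RS1 vs CC7, RS2 vs CC8,
#' RS3 vs CC8, RS6 vs CC11 (hours of recovery 0, 1, 2, 3, 6).
#'
#' @return `data.frame` with columns `name`, `treatment`, `control`,
#'   `recovery_h`.
#' @export
defaultContrasts <- function() {
    data.frame(
        name = c("SD_vs_CC6", "RS1_vs_CC7", "RS2_vs_CC8",
                 "RS3_vs_CC8", "RS6_vs_CC11"),
        treatment = c("SD", "RS1", "RS2", "RS3", "RS6"),
        control = c("CC6", "CC7", "CC8", "CC8", "CC11"),
        recovery_h = c(0, 1, 2, 3, 6),
        stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Gene-level generative model (log2 scale):
#' baseline + circadian cosine + treatment effect + W alpha + noise, where
#' the treatment effect of an affected gene equals `logFC0` at the end of
#' sleep deprivation and decays during recovery sleep as
#' `logFC_t = logFC0 * exp(-t / tau)` (lower asymptote 0), with `tau` the
#' gene's class time constant. Late-induced genes are unaffected by sleep
#' deprivation and appear only at 6 h of recovery. W rows are i.i.d.
#' standard normal per sample; loadings are a sparse-dense mix so a subset
#' of genes is heavily batch-affected. Per-gene noise SD is drawn from a
#' scaled inverse-chi-square (`sigma^2 = noise_df * sigma_noise^2 / X`,
#' `X ~ chisq(noise_df)`), the conjugate form the moderated-t model
#' assumes.
#'
#' @param n_genes number of genes.
#' @param design study design `data.frame` as [defaultStudyDesign()].
#' @param k_true number of latent unwanted factors.
#' @param sigma_noise scale of the per-gene residual SD (log2 units);
#'   0 gives noise-free data.
#' @param noise_df degrees of freedom of the inverse-chi-square noise law.
#' @param frac_up,frac_down fractions of genes up-/down-regulated at the
#'   end of sleep deprivation.
#' @param effect_range range of |logFC0| for affected genes.
#' @param tau_fast,tau_slow true decay constants (hours); fast mirrors the
#'   delta-power discharge constant of C57BL/6, slow completes recovery
#'   between 3 and 6 h.
#' @param frac_fast fraction of affected genes given `tau_fast`.
#' @param frac_late fraction of genes induced only by the 6th hour of
#'   recovery sleep.
#' @param frac_circadian fraction of genes with a sinusoidal time-of-day
#'   effect `A * cos(2*pi*(zt - phase)/24)`.
#' @param circadian_amplitude amplitude range for circadian genes.
#' @param n_negative_controls,n_positive_controls control-set sizes.
#' @param batch_strength scale of the W alpha contributions; 0 disables
#'   unwanted variation.
#' @param seed random seed.
#' @return a `SimulationConfig` (validated list).
#' @export
simulationConfig <- function(n_genes = 10000,
                             design = defaultStudyDesign(),
                             k_true = 3,
                             sigma_noise = 0.25,
                             noise_df = 6,
                             frac_up = 0.05,
                             frac_down = 0.03,
                             effect_range = c(0.75, 2.0),
                             tau_fast = 1.3,
                             tau_slow = 4.5,
                             frac_fast = 0.48,
                             frac_late = 0.005,
                             frac_circadian = 0.10,
                             circadian_amplitude = c(0.5, 2.0),
                             n_negative_controls = 500,
                             n_positive_controls = 50,
                             batch_strength = 1.0,
                             seed = 1L) {
    cfg <- list(n_genes = n_genes, design = design, k_true = k_true,
                sigma_noise = sigma_noise, noise_df = noise_df,
                frac_up = frac_up, frac_down = frac_down,
                effect_range = effect_range, tau_fast = tau_fast,
                tau_slow = tau_slow, frac_fast = frac_fast,
                frac_late = frac_late, frac_circadian = frac_circadian,
                circadian_amplitude = circadian_amplitude,
                n_negative_controls = n_negative_controls,
                n_positive_controls = n_positive_controls,
                batch_strength = batch_strength, seed = as.integer(seed))
    fr <- c(frac_up, frac_down, frac_fast, frac_late, frac_circadian)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (frac_up + frac_down + frac_late > 1)
        stop("frac_up + frac_down + frac_late exceeds 1")
    if (tau_fast >= tau_slow) stop("tau_fast must be smaller than tau_slow")
    if (n_genes < 1 || k_true < 0 || any(design$n_replicates < 1))
        stop("counts must be positive")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Generate a synthetic sleep-deprivation / recovery-sleep dataset
#'
#' @param config a [simulationConfig()].
#' @return list with elements
#'   \describe{
#'     \item{dataset}{[SleepExpressionSet-class] of `n_genes` x total
#'       samples.}
#'     \item{truth}{list: `genes` (per-gene class, logFC0 `beta`, `tau`,
#'       circadian amplitude/phase, noise SD), `beta_group` (genes x
#'       groups matrix of true treatment effects), `W`, `alpha`.}
#'     \item{controls}{[ControlGeneSets-class]; negatives drawn from null
#'       non-circadian genes, per-contrast positives from affected genes
#'       whose true effect magnitude at that time point exceeds the 60th
#'       percentile of `effect_range`.}
#'   }
#' @export
simulateSleepStudy <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    des <- config$design
    n_genes <- config$n_genes
    groups <- rep(des$group, des$n_replicates)
    zt <- rep(des$zt_time, des$n_replicates)
    n_samples <- length(groups)
    sample_id <- sprintf("S%02d_%s", seq_len(n_samples), groups)
    design <- data.frame(sample_id = sample_id, group = groups,
                         zt_time = zt %% 24,
                         replicate_group = groups, study = "sim",
                         platform = "simarray",
                         stringsAsFactors = FALSE)

    genes <- sprintf("G%05d", seq_len(n_genes))
    n_up <- round(config$frac_up * n_genes)
    n_down <- round(config$frac_down * n_genes)
    n_late <- round(config$frac_late * n_genes)
    idx <- sample.int(n_genes)          # random, disjoint class assignment
    i_up <- idx[seq_len(n_up)]
    i_down <- idx[n_up + seq_len(n_down)]
    i_late <- idx[n_up + n_down + seq_len(n_late)]
    i_affected <- c(i_up, i_down)

    class <- rep("null", n_genes)
    beta <- numeric(n_genes)
    tau <- rep(NA_real_, n_genes)
    eff <- function(n) stats::runif(n, config$effect_range[1],
                                    config$effect_range[2])
    beta[i_up] <- eff(n_up)
    beta[i_down] <- -eff(n_down)
    n_fast <- round(config$frac_fast * length(i_affected))
    i_fast <- i_affected[sample.int(length(i_affected), n_fast)]
    tau[i_affected] <- config$tau_slow
    tau[i_fast] <- config$tau_fast
    class[i_affected] <- ifelse(is.na(match(i_affected, i_fast)),
                                "slow", "fast")
    class[i_late] <- "late"
    beta[i_late] <- eff(n_late)

    is_circ <- rep(FALSE, n_genes)
    n_circ <- round(config$frac_circadian * n_genes)
    i_circ <- sample.int(n_genes, n_circ)
    is_circ[i_circ] <- TRUE
    class[is_circ & class == "null"] <- "circadian"
    amp <- numeric(n_genes)
    phase <- numeric(n_genes)
    amp[i_circ] <- stats::runif(n_circ, config$circadian_amplitude[1],
                                config$circadian_amplitude[2])
    phase[i_circ] <- stats::runif(n_circ, 0, 24)

    # per-group treatment effect (log2): decay during recovery, LA = 0
    beta_group <- matrix(0, n_genes, nrow(des),
                         dimnames = list(genes, des$group))
    for (j in seq_len(nrow(des))) {
        t_rec <- des$recovery_h[j]
        if (is.na(t_rec)) next
        if (length(i_affected))
            beta_group[i_affected, j] <-
                beta[i_affected] * exp(-t_rec / tau[i_affected])
        if (length(i_late) && t_rec >= 6)
            beta_group[i_late, j] <- beta[i_late]
    }

    baseline <- stats::runif(n_genes, 5, 12)
    sigma <- if (config$sigma_noise > 0)
        sqrt(config$noise_df * config$sigma_noise^2 /
                 stats::rchisq(n_genes, config$noise_df))
    else rep(0, n_genes)

    k <- config$k_true
    W <- matrix(stats::rnorm(n_samples * k), n_samples, k)
    heavy <- stats::rbinom(n_genes, 1, 0.3)
    alpha <- matrix(stats::rnorm(k * n_genes, sd = 0.5), k, n_genes) +
        matrix(stats::rnorm(k * n_genes), k, n_genes) *
            rep(heavy, each = k)
    alpha <- alpha * config$batch_strength
    if (k == 0) { W <- matrix(0, n_samples, 0); alpha <- matrix(0, 0, n_genes) }

    grp_idx <- match(groups, des$group)
    m <- matrix(baseline, n_genes, n_samples) +
        beta_group[, grp_idx, drop = FALSE]
    circ <- outer(amp, rep(1, n_samples)) *
        cos(2 * pi * (matrix(zt, n_genes, n_samples, byrow = TRUE) -
                          matrix(phase, n_genes, n_samples)) / 24)
    circ[!is_circ, ] <- 0
    m <- m + circ
    if (k > 0) m <- m + t(W %*% alpha)
    if (config$sigma_noise > 0)
        m <- m + matrix(stats::rnorm(n_genes * n_samples), n_genes) * sigma
    dimnames(m) <- list(genes, sample_id)

    # controls -------------------------------------------------------------
    eligible_neg <- which(class == "null")
    if (length(eligible_neg) < config$n_negative_controls)
        stop("config requests ", config$n_negative_controls,
             " negative controls but only ", length(eligible_neg),
             " null non-circadian genes are available")
    neg <- sort(eligible_neg[sample.int(length(eligible_neg),
                                        config$n_negative_controls)])
    # positives: affected genes with |logFC0| above the 60th percentile of
    # the effect range, benchmarked on the end-of-deprivation contrast
    thr <- config$effect_range[1] + 0.6 * diff(range(config$effect_range))
    elig <- which(abs(beta) > thr & class %in% c("fast", "slow"))
    if (length(elig) < config$n_positive_controls)
        stop("config requests ", config$n_positive_controls,
             " positive controls but only ", length(elig), " genes qualify")
    positive <- list(SD_vs_CC6 = genes[sort(
        elig[sample.int(length(elig), config$n_positive_controls)])])
    controls <- ControlGeneSets(genes[neg], positive)

    truth <- list(
        genes = data.frame(gene = genes, class = class, beta = beta,
                           tau = tau, is_circadian = is_circ, amp = amp,
                           phase = phase, sigma = sigma,
                           stringsAsFactors = FALSE),
        beta_group = beta_group, W = W, alpha = alpha, config = config)
    list(dataset = SleepExpressionSet(m, design), truth = truth,
         controls = controls)
}

#' Generate a multi-study dataset with platform and laboratory offsets
#'
#' Emulates the cross-study integration setting: several studies assay
#' overlapping subsets of a shared gene universe under study-specific
#' probeset identifiers, with additive per-gene platform and laboratory
#' offset vectors that are large relative to the treatment effects, plus a
#' study-specific unwanted-factor term. The true sleep-deprivation effects
#' are shared across studies. Each study contains time-matched control
#' (CC6) and sleep-deprived (SD) groups.
#'
#' A handful of deliberately multi-mapping probes (one probeset hitting
#' two genes; two probesets hitting one gene within a platform) is
#' injected so that identifier harmonization can be exercised.
#'
#' @param studies `data.frame` with columns `study`, `platform`, `lab`,
#'   `n_per_group`.
#' @param n_genes size of the shared gene universe.
#' @param frac_measured fraction of the universe measured by each study.
#' @param platform_offset_sd,lab_offset_sd SDs of the per-gene offset
#'   vectors (log2 units); platform offsets dominate by default, as in
#'   cross-platform microarray compendia.
#' @param k_true,batch_strength,sigma_noise,frac_up,frac_down,effect_range
#'   passed to the per-study generative model.
#' @param seed random seed.
#' @return list: `datasets` (per-study [SleepExpressionSet-class] under
#'   probeset ids), `mapping` (`data.frame` probeset_id/gene_id),
#'   `truth` (shared per-gene effects and measured-gene index per study).
#' @export
simulateMetaStudies <- function(studies = data.frame(
                                    study = c("stA", "stB", "stC", "stD"),
                                    platform = c("geneST", "mo430", "mo430", "u74"),
                                    lab = c("L1", "L2", "L3", "L4"),
                                    n_per_group = c(8, 6, 6, 6),
                                    stringsAsFactors = FALSE),
                                n_genes = 2000,
                                frac_measured = 0.9,
                                platform_offset_sd = 2.0,
                                lab_offset_sd = 1.0,
                                k_true = 2,
                                batch_strength = 0.5,
                                sigma_noise = 0.25,
                                frac_up = 0.05, frac_down = 0.03,
                                effect_range = c(0.75, 2.0),
                                seed = 1L) {
    if (nrow(studies) < 2) stop("at least two studies are required")
    set.seed(as.integer(seed))
    genes <- sprintf("ENSG%05d", seq_len(n_genes))
    n_aff <- round((frac_up + frac_down) * n_genes)
    i_aff <- sample.int(n_genes, n_aff)
    beta <- numeric(n_genes)
    sgn <- rep(c(1, -1), times = c(round(frac_up * n_genes),
                                   n_aff - round(frac_up * n_genes)))
    beta[i_aff] <- sgn * stats::runif(n_aff, effect_range[1], effect_range[2])

    baseline <- stats::runif(n_genes, 5, 12)   # shared biology across studies
    plats <- unique(studies$platform)
    labs <- unique(studies$lab)
    plat_off <- matrix(stats::rnorm(n_genes * length(plats),
                                    sd = platform_offset_sd),
                       n_genes, dimnames = list(genes, plats))
    lab_off <- matrix(stats::rnorm(n_genes * length(labs),
                                   sd = lab_offset_sd),
                      n_genes, dimnames = list(genes, labs))

    datasets <- list()
    mapping <- NULL
    measured <- list()
    for (si in seq_len(nrow(studies))) {
        st <- studies$study[si]
        idx <- sort(sample.int(n_genes, round(frac_measured * n_genes)))
        measured[[st]] <- genes[idx]
        n_m <- length(idx)
        probes <- sprintf("%s_ps%05d", st, seq_len(n_m))
        map <- data.frame(probeset_id = probes, gene_id = genes[idx],
                          stringsAsFactors = FALSE)
        n_rep <- studies$n_per_group[si]
        grp <- rep(c("CC6", "SD"), each = n_rep)
        sample_id <- sprintf("%s_%s_%d", st, grp, seq_len(n_rep))
        des <- data.frame(sample_id = sample_id, group = grp, zt_time = 6,
                          replicate_group = paste(grp, st, sep = "."),
                          study = st, platform = studies$platform[si],
                          stringsAsFactors = FALSE)
        n_s <- length(grp)
        treat <- outer(beta[idx], as.numeric(grp == "SD"))
        W <- matrix(stats::rnorm(n_s * k_true), n_s, k_true)
        alpha <- matrix(stats::rnorm(k_true * n_m, sd = batch_strength),
                        k_true, n_m)
        sig <- sqrt(6 * sigma_noise^2 / stats::rchisq(n_m, 6))
        m <- matrix(baseline[idx], n_m, n_s) + treat +
            plat_off[idx, studies$platform[si]] +
            lab_off[idx, studies$lab[si]] +
            t(W %*% alpha) +
            matrix(stats::rnorm(n_m * n_s), n_m) * sig
        # inject multi-mapping probes: one probe -> two genes, and a
        # duplicate probe for an existing gene on this platform
        extra_probe <- sprintf("%s_psMULTI", st)
        map <- rbind(map,
                     data.frame(probeset_id = extra_probe,
                                gene_id = genes[idx[1:2]]),
                     data.frame(probeset_id = sprintf("%s_psDUP", st),
                                gene_id = genes[idx[3]]))
        m <- rbind(m, m[1, , drop = FALSE], m[3, , drop = FALSE])
        rownames(m) <- c(probes, extra_probe, sprintf("%s_psDUP", st))
        colnames(m) <- sample_id
        datasets[[st]] <- SleepExpressionSet(m, des)
        mapping <- rbind(mapping, map)
    }
    shared <- Reduce(intersect, measured)
    if (!length(shared)) stop("zero gene overlap across studies")
    list(datasets = datasets, mapping = mapping,
         truth = list(genes = genes, beta = beta, measured = measured,
                      shared = shared))
}
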