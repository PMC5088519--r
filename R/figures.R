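#' Write diagnostic figures for a pipeline run
#'
#' Produces, as PDF files in `dir`: first-two-PC sample scatter, p-value
#' histogram per contrast, volcano plot per contrast, trajectory cluster
#' means with a +/- 1 SD band, a bar chart of up/down-regulated counts
#' per time point, and (when enrichment ran) an enrichment-score bar
#' chart. Figures whose inputs are missing from the report are skipped
#' with a warning.
#'
#' @param report a `RunReport` from [runPipeline()] (with `artifacts`).
#' @param controls optional [ControlGeneSets-class] to circle controls in
#'   the volcano plots.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
makeFigures <- function(report, controls = NULL, dir = ".") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    written <- character()
    art <- report$artifacts
    emit <- function(name, fun) {
        path <- file.path(dir, name)
        grDevices::pdf(path, width = 7, height = 5)
        on.exit(grDevices::dev.off(), add = TRUE)
        fun()
        written <<- c(written, path)
    }
    if (!is.null(art$ruv)) {
        emit("pca.pdf", function() {
            ds <- adjustedData(art$ruv)
            pr <- pcaReport(ds, n_components = 2)
            g <- factor(sampleDesign(ds)$group)
            plot(pr$scores[, 1], pr$scores[, 2], col = as.integer(g),
                 pch = 19,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * pr$variance_fraction[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * pr$variance_fraction[2]),
                 main = "Samples, first two principal components")
            graphics::legend("topright", legend = levels(g), pch = 19,
                             col = seq_len(nlevels(g)), cex = 0.7)
        })
    } else warning("no RUV artifact; PCA figure skipped")
    if (!is.null(art$de_results)) {
        emit("pvalue_histograms.pdf", function() {
            graphics::par(mfrow = c(2, 3))
            for (nm in names(art$de_results))
                graphics::hist(deTable(art$de_results[[nm]])$p, breaks = 20,
                               main = nm, xlab = "p-value", col = "grey")
        })
        emit("volcano.pdf", function() {
            graphics::par(mfrow = c(2, 3))
            for (nm in names(art$de_results)) {
                tb <- deTable(art$de_results[[nm]])
                if (!nrow(tb)) { warning("empty DE result for ", nm); next }
                sig <- tb$fdr < 0.01
                plot(tb$logFC, -log10(tb$p), pch = 20, cex = 0.4,
                     col = ifelse(sig, "blue", "grey40"),
                     xlab = "log2 fold change", ylab = "-log10 p", main = nm)
                if (!is.null(controls)) {
                    pos <- positiveControls(controls, nm)
                    i <- match(intersect(pos, tb$gene), tb$gene)
                    if (length(i))
                        graphics::points(tb$logFC[i], -log10(tb$p[i]),
                                         col = "red", cex = 1.2)
                }
            }
        })
    } else warning("no DE artifacts; histogram and volcano figures skipped")
    if (!is.null(art$clusters)) {
        emit("trajectory_clusters.pdf", function() {
            ca <- art$clusters
            times <- art$trajectories@times
            cols <- grDevices::rainbow(nrow(ca@centers))
            plot(range(times), range(ca@centers - ca@sds,
                                     ca@centers + ca@sds, na.rm = TRUE),
                 type = "n", xlab = "hours of recovery sleep",
                 ylab = "mean logFC", main = "Cluster mean trajectories")
            for (k in seq_len(nrow(ca@centers))) {
                s <- ifelse(is.na(ca@sds[k, ]), 0, ca@sds[k, ])
                graphics::polygon(c(times, rev(times)),
                                  c(ca@centers[k, ] + s,
                                    rev(ca@centers[k, ] - s)),
                                  col = grDevices::adjustcolor(cols[k], 0.15),
                                  border = NA)
                graphics::lines(times, ca@centers[k, ], col = cols[k], lwd = 2)
            }
            graphics::legend("topright", cex = 0.7, lwd = 2, col = cols,
                             legend = sprintf("cluster %s (%s)",
                                              rownames(ca@centers),
                                              ca@classes))
        })
    } else warning("no clustering artifact; trajectory figure skipped")
    if (!is.null(report$differential_expression)) {
        emit("de_counts.pdf", function() {
            up <- vapply(report$differential_expression, `[[`, 0, "n_up")
            dn <- vapply(report$differential_expression, `[[`, 0, "n_down")
            graphics::barplot(rbind(up, dn), beside = TRUE,
                              col = c("firebrick", "steelblue"),
                              names.arg = names(report$differential_expression),
                              las = 2, cex.names = 0.7,
                              main = "Significant genes per time point",
                              ylab = "genes at FDR < 0.01")
            graphics::legend("topright", fill = c("firebrick", "steelblue"),
                             legend = c("up", "down"))
        })
    }
    if (!is.null(report$enrichment)) {
        emit("enrichment.pdf", function() {
            graphics::par(mfrow = c(1, 2))
            for (nm in names(report$enrichment)) {
                hl <- report$enrichment[[nm]]
                if (is.null(hl) || !nrow(hl)) {
                    plot.new(); graphics::title(paste(nm, "(none)")); next
                }
                graphics::barplot(hl$score, names.arg = hl$cluster,
                                  main = paste(nm, "responders"),
                                  ylab = "enrichment score")
                graphics::abline(h = 1.5, lty = 2)
            }
        })
    }
    invisible(written)
}
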