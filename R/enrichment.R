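#' Jackknifed exact enrichment test (EASE score)
#'
#' One-sided hypergeometric upper-tail probability for the overlap
#' between a gene list and an annotation term, computed on the 2x2 table
#' with the overlap count reduced by one (the jackknife that makes the
#' score conservative for single-gene overlaps): with `a` list genes in
#' the term, the score is `P(X >= a - 1)` for
#' `X ~ Hypergeom(term, background - term, list)`. An overlap of 0 or 1
#' scores p = 1.
#'
#' @param gene_list character vector of genes of interest (subset of
#'   `background`; genes outside it are dropped).
#' @param term_set character vector of genes annotated to the term; the
#'   effective term is its intersection with `background`.
#' @param background character vector: all genes assayed (the array
#'   background).
#' @return the EASE p-value.
#' @export
easeTest <- function(gene_list, term_set, background) {
    background <- unique(background)
    if (!length(background)) stop("background gene set is empty")
    gene_list <- intersect(unique(gene_list), background)
    term_set <- intersect(unique(term_set), background)
    a <- length(intersect(gene_list, term_set))
    if (a <= 1) return(1)
    N <- length(background)
    K <- length(term_set)
    n <- length(gene_list)
    # P(X >= a - 1)
    stats::phyper(a - 2, K, N - K, n, lower.tail = FALSE)
}

#' Pairwise kappa agreement between annotation terms
#'
#' Cohen's kappa between the binary gene-membership vectors of each pair
#' of terms over a gene universe. Terms with no genes in the universe are
#' excluded with a warning.
#'
#' @param terms named list: term id -> character vector of genes.
#' @param universe character vector over which membership is evaluated
#'   (typically the genes of the analysed list).
#' @return symmetric matrix of kappa values (diagonal 1).
#' @export
kappaMatrix <- function(terms, universe) {
    universe <- unique(universe)
    memb <- vapply(terms, function(s) universe %in% s,
                   logical(length(universe)))
    if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                               dimnames = list(NULL, names(terms)))
    empty <- colSums(memb) == 0
    if (any(empty)) {
        warning("term(s) with no genes in the universe excluded: ",
                paste(names(terms)[empty], collapse = ", "))
        memb <- memb[, !empty, drop = FALSE]
    }
    if (ncol(memb) < 2) stop("need at least two terms with genes in the universe")
    n <- length(universe)
    K <- matrix(1, ncol(memb), ncol(memb),
                dimnames = list(colnames(memb), colnames(memb)))
    for (i in seq_len(ncol(memb) - 1)) for (j in (i + 1):ncol(memb)) {
        x <- memb[, i]; y <- memb[, j]
        po <- mean(x == y)
        pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
        K[i, j] <- K[j, i] <- if (pe == 1) 1 else (po - pe) / (1 - pe)
    }
    K
}

#' Group enriched terms by kappa similarity and score the clusters
#'
#' Single-linkage grouping of EASE-significant terms whose pairwise
#' kappa reaches `similarity_threshold` (equivalently, connected
#' components of the kappa graph at that cutoff). Groups smaller than
#' `group_membership` are reported separately as singletons. Each
#' cluster's enrichment score is `-log10` of the geometric mean of its
#' member p-values; clusters at or below `score_cutoff` are dropped from
#' the headline report.
#'
#' @param p_values named numeric vector of EASE p-values for the
#'   enriched terms (p < 0.05), names = term ids.
#' @param kappa symmetric kappa matrix over (at least) those terms.
#' @param similarity_threshold kappa cutoff (default 0.2).
#' @param group_membership minimum cluster size (default 2).
#' @param score_cutoff headline enrichment-score cutoff (default 1.5,
#'   i.e. geometric-mean p < 0.05 is not sufficient; the mean must beat
#'   10^-1.5).
#' @return list: `clusters` (`data.frame` cluster, n_terms, score,
#'   terms), `headline` (clusters with score > `score_cutoff`),
#'   `singletons` (`data.frame` term, p).
#' @export
clusterTerms <- function(p_values, kappa, similarity_threshold = 0.2,
                         group_membership = 2, score_cutoff = 1.5) {
    terms <- names(p_values)
    terms_in <- intersect(terms, rownames(kappa))
    # connected components of the thresholded kappa graph (single linkage)
    comp <- stats::setNames(seq_along(terms_in), terms_in)
    if (length(terms_in) > 1) {
        for (i in seq_len(length(terms_in) - 1))
            for (j in (i + 1):length(terms_in)) {
                if (kappa[terms_in[i], terms_in[j]] >= similarity_threshold) {
                    old <- comp[terms_in[j]]
                    comp[comp == old] <- comp[terms_in[i]]
                }
            }
    }
    groups <- split(terms_in, comp)
    big <- groups[lengths(groups) >= group_membership]
    small <- unlist(groups[lengths(groups) < group_membership],
                    use.names = FALSE)
    score <- function(members) -log10(exp(mean(log(p_values[members]))))
    clusters <- data.frame(
        cluster = seq_along(big),
        n_terms = lengths(big),
        score = vapply(big, score, numeric(1)),
        terms = vapply(big, paste, character(1), collapse = ";"),
        row.names = NULL, stringsAsFactors = FALSE)
    clusters <- clusters[order(-clusters$score), , drop = FALSE]
    clusters$cluster <- seq_len(nrow(clusters))
    list(clusters = clusters,
         headline = clusters[clusters$score > score_cutoff, , drop = FALSE],
         singletons = data.frame(term = small,
                                 p = unname(p_values[small]),
                                 stringsAsFactors = FALSE))
}

#' Local functional-enrichment analysis of a gene list
#'
#' End-to-end enrichment: EASE test of every gene set against the
#' background, retention of terms with p < `ease_cutoff`, kappa-matrix
#' computation over the gene list, and kappa clustering with enrichment
#' scores. This replaces a web annotation service with a user-supplied
#' collection ([loadGMT()]).
#'
#' @param gene_list character vector of genes of interest.
#' @param gsc a [GeneSetCollection-class].
#' @param background all assayed genes (default: union of the
#'   collection's genes; pass the array's gene universe when available).
#' @param ease_cutoff per-term EASE cutoff (default 0.05).
#' @param similarity_threshold,group_membership,score_cutoff passed to
#'   [clusterTerms()].
#' @return list: `terms` (`data.frame` term, name, n_overlap, n_term, p
#'   for every tested term), `enriched` (terms below the cutoff),
#'   `clusters`, `headline`, `singletons` as in [clusterTerms()].
#' @export
enrichGeneList <- function(gene_list, gsc, background = NULL,
                           ease_cutoff = 0.05, similarity_threshold = 0.2,
                           group_membership = 2, score_cutoff = 1.5) {
    sets <- geneSets(gsc)
    if (is.null(background))
        background <- unique(unlist(sets, use.names = FALSE))
    gene_list <- intersect(unique(gene_list), background)
    terms <- data.frame(
        term = names(sets),
        name = unname(gsc@names[names(sets)]),
        n_overlap = vapply(sets, function(s)
            length(intersect(gene_list, intersect(s, background))),
            integer(1)),
        n_term = vapply(sets, function(s)
            length(intersect(s, background)), integer(1)),
        p = vapply(sets, function(s) easeTest(gene_list, s, background),
                   numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    enriched <- terms[terms$p < ease_cutoff, , drop = FALSE]
    if (nrow(enriched) < 2) {
        return(list(terms = terms, enriched = enriched,
                    clusters = data.frame(), headline = data.frame(),
                    singletons = data.frame(term = enriched$term,
                                            p = enriched$p)))
    }
    kap <- kappaMatrix(sets[enriched$term], universe = gene_list)
    cl <- clusterTerms(stats::setNames(enriched$p, enriched$term), kap,
                       similarity_threshold, group_membership, score_cutoff)
    c(list(terms = terms, enriched = enriched), cl)
}
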