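#' Upper-tail hypergeometric p-value of a contingency quartet
#'
#' Given quartet counts `(i, j, k, l)`, returns `P(X >= i)` where `X` is
#' hypergeometric with population `i+j+k+l`, success count `i+k` and
#' sample size `i+j` -- the probability of observing at least `i`
#' annotated elements among the cluster-derived draw.  Computed through
#' the survival form of [stats::phyper()] (log-space internally), never
#' through naive factorials.
#'
#' @param q A `contingency_quartet`, or the count `i` when `j`, `k`, `l`
#'   are supplied.
#' @param j,k,l Remaining counts (vectorized) when `q` is numeric.
#' @return p-value(s) in `(0, 1]`; `i = 0` gives exactly 1.
#' @export
hypergeom_upper_tail <- function(q, j = NULL, k = NULL, l = NULL) {
  if (inherits(q, "contingency_quartet")) {
    i <- q$i; j <- q$j; k <- q$k; l <- q$l
  } else {
    i <- q
  }
  stopifnot(all(i >= 0), all(j >= 0), all(k >= 0), all(l >= 0),
            all(i + j + k + l > 0))
  stats::phyper(i - 1, m = i + k, n = j + l, k = i + j, lower.tail = FALSE)
}

#' Fisher's combined probability of 2 or 3 p-values
#'
#' Combines independent p-values through `S = -2 * sum(log(p))`, referred
#' to a chi-squared distribution with `2 * length(p)` degrees of freedom
#' (the standard Fisher method).  A `"literal"` variant referring
#' `S = sum(-log(p))` to chi-squared with `length(p)` degrees of freedom
#' is kept for comparison with descriptions that treat each `-ln(p)` as a
#' one-degree chi-squared variable; the standard form is the default and
#' is what the usual `fisherSum`-style implementations compute.
#'
#' @param p Numeric vector of 2 or 3 p-values in `(0, 1]`.  Zeros are
#'   clamped to the smallest positive double with a warning.
#' @param method `"standard"` (default) or `"literal"`.
#' @return The combined p-value.
#' @export
fisher_combine <- function(p, method = c("standard", "literal")) {
  method <- match.arg(method)
  if (!length(p) %in% c(2L, 3L)) {
    stop("fisher_combine expects 2 or 3 p-values, got ", length(p))
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  if (method == "standard") {
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  } else {
    stats::pchisq(sum(-log(p)), df = length(p), lower.tail = FALSE)
  }
}

# vectorized standard Fisher combination over columns of a matrix of
# p-values (rows = terms); used by the enrichment driver.
.fisher_combine_rows <- function(pm, method = "standard") {
  pm[pm == 0] <- .Machine$double.xmin
  s <- rowSums(log(pm))
  if (method == "standard") {
    stats::pchisq(-2 * s, df = 2 * ncol(pm), lower.tail = FALSE)
  } else {
    stats::pchisq(-s, df = ncol(pm), lower.tail = FALSE)
  }
}

#' Rank-normalize p-values (competition ranking)
#'
#' Ascending ranks: rank 1 is the smallest p-value and ties share the
#' minimum rank of their block, so the rank vector is a permutation of
#' `1..N` up to the tie policy.
#'
#' @param p Numeric vector of p-values.
#' @return Integer ranks.
#' @export
rank_normalize <- function(p) {
  as.integer(rank(p, ties.method = "min"))
}

#' Fit tri-partite functional enrichment for one miRNA cluster
#'
#' The central fitting function.  For every non-obsolete GO term of the
#' requested category that has at least one annotated gene inside the
#' network's gene universe, it derives the gene-centric (rho),
#' link-centric (tau) and miRNA-centric (mu) contingency quartets,
#' converts each to an upper-tail hypergeometric p-value, Fisher-combines
#' the p-values of every measure pair and of the triple, and
#' rank-normalizes each p-value column within the category.
#'
#' @param network A [target_network()]; its link endpoints define the
#'   gene, link and miRNA universes.
#' @param cluster A [mirna_cluster()].  A cluster without a single target
#'   gene cannot be tested: the function warns and returns `NULL` so
#'   callers can skip it.
#' @param onto A `go_ontology` from [read_obo()].
#' @param anno A `go_annotations` table from [read_gaf()] or a synthetic
#'   scenario.
#' @param category GO category to test: `"BP"`, `"MF"` or `"CC"`.
#' @param measures Subset of `c("rho", "tau", "mu")`; at least one.
#' @param combine Compute Fisher-combined p-values for every pair/triple
#'   of the requested measures (default `TRUE` when 2+ measures).
#' @param propagate Apply the true-path rule before counting (default
#'   `TRUE`): a gene annotated to a term then counts for every ancestor
#'   of that term.  Pass `FALSE` to count direct annotations only.
#' @param fisher_method Passed to the combiner; see [fisher_combine()].
#' @param bh_adjust Add Benjamini-Hochberg adjusted columns per measure
#'   (diagnostic only; ranking and term sets always use raw p-values).
#' @return An object of class `mirna_enrichment`, or `NULL` for a
#'   target-less cluster.  The `records` data.frame has one row per
#'   tested term with the quartets (`<measure>_i` .. `<measure>_l`),
#'   p-values (`p_rho`, `p_tau`, `p_mu`, `p_rho_tau`, ...), and ranks
#'   (`rank_rho`, ..., `rank_rho_tau_mu`).
#' @seealso [top_n_set()], [compare_measures()], [summary.mirna_enrichment()]
#' @export
enrich_mirna_cluster <- function(network, cluster, onto, anno,
                                 category = c("BP", "MF", "CC"),
                                 measures = c("rho", "tau", "mu"),
                                 combine = TRUE,
                                 propagate = TRUE,
                                 fisher_method = c("standard", "literal"),
                                 bh_adjust = FALSE) {
  category <- match.arg(category)
  fisher_method <- match.arg(fisher_method)
  measures <- match.arg(measures, c("rho", "tau", "mu"), several.ok = TRUE)
  if (propagate && !is_propagated(anno)) {
    anno <- propagate_annotations(anno, onto)
  }

  members <- .cluster_in_universe(network, cluster)
  tgc <- target_gene_cluster(network, cluster)
  if (!length(tgc)) {
    warning("cluster '", cluster$cluster_id,
            "' has no target gene; skipping")
    return(NULL)
  }

  live <- onto$terms[!onto$terms$is_obsolete &
                       onto$terms$category %in% category, ]
  adf <- as.data.frame(anno)
  adf <- adf[adf$term %in% live$term_id & adf$gene %in% network$genes,
             c("gene", "term")]
  adf <- adf[!duplicated(adf), , drop = FALSE]
  if (!nrow(adf)) {
    return(.enrichment_fit(data.frame(), cluster, category, measures,
                           network, members, fisher_method))
  }
  terms <- sort(unique(adf$term))
  tf <- factor(adf$term, levels = terms)

  n_genes <- length(network$genes)
  n_links <- network$n_links
  n_mirnas <- length(network$mirnas)

  rec <- data.frame(term_id = terms, stringsAsFactors = FALSE)
  rec$name <- live$name[match(terms, live$term_id)]
  rec$category <- category

  if ("rho" %in% measures) {
    n_annot <- as.integer(table(tf))
    i <- as.integer(tapply(adf$gene %in% tgc, tf, sum, default = 0L))
    rec$rho_i <- i
    rec$rho_j <- length(tgc) - i
    rec$rho_k <- n_annot - i
    rec$rho_l <- n_genes - length(tgc) - rec$rho_k
    rec$p_rho <- hypergeom_upper_tail(rec$rho_i, rec$rho_j,
                                      rec$rho_k, rec$rho_l)
  }
  if ("tau" %in% measures) {
    # one row per (link, term): join links to annotations on gene
    lt <- merge(network$links, adf, by = "gene")
    ltf <- factor(lt$term, levels = terms)
    in_cl <- lt$mirna %in% members
    i <- as.integer(tapply(in_cl, ltf, sum, default = 0L))
    k <- as.integer(tapply(!in_cl, ltf, sum, default = 0L))
    links_from_cluster <- sum(network$links$mirna %in% members)
    rec$tau_i <- i
    rec$tau_j <- links_from_cluster - i
    rec$tau_k <- k
    rec$tau_l <- n_links - links_from_cluster - k
    rec$p_tau <- hypergeom_upper_tail(rec$tau_i, rec$tau_j,
                                      rec$tau_k, rec$tau_l)
  }
  if ("mu" %in% measures) {
    lt <- merge(network$links, adf, by = "gene")
    mt <- unique(lt[c("mirna", "term")])
    mtf <- factor(mt$term, levels = terms)
    in_cl <- mt$mirna %in% members
    i <- as.integer(tapply(in_cl, mtf, sum, default = 0L))
    k <- as.integer(tapply(!in_cl, mtf, sum, default = 0L))
    rec$mu_i <- i
    rec$mu_j <- length(members) - i
    rec$mu_k <- k
    rec$mu_l <- n_mirnas - length(members) - k
    rec$p_mu <- hypergeom_upper_tail(rec$mu_i, rec$mu_j,
                                     rec$mu_k, rec$mu_l)
  }

  if (combine && length(measures) >= 2) {
    combos <- .measure_combos(measures)
    for (cmb in combos) {
      col <- paste0("p_", paste(cmb, collapse = "_"))
      rec[[col]] <- .fisher_combine_rows(
        as.matrix(rec[paste0("p_", cmb)]), fisher_method)
    }
  }

  for (col in grep("^p_", names(rec), value = TRUE)) {
    rec[[paste0("rank_", sub("^p_", "", col))]] <- rank_normalize(rec[[col]])
  }
  if (bh_adjust) {
    for (m in measures) {
      rec[[paste0("bh_", m)]] <-
        stats::p.adjust(rec[[paste0("p_", m)]], method = "BH")
    }
  }
  rownames(rec) <- NULL
  .enrichment_fit(rec, cluster, category, measures, network, members,
                  fisher_method)
}

.measure_combos <- function(measures) {
  out <- list()
  if (length(measures) >= 2) {
    cm <- utils::combn(measures, 2, simplify = FALSE)
    out <- c(out, cm)
  }
  if (length(measures) == 3) out <- c(out, list(measures))
  out
}

.enrichment_fit <- function(records, cluster, category, measures,
                            network, members, fisher_method) {
  structure(
    list(records = records,
         cluster_id = cluster$cluster_id,
         members = members,
         category = category,
         measures = measures,
         fisher_method = fisher_method,
         universes = c(genes = length(network$genes),
                       links = network$n_links,
                       mirnas = length(network$mirnas))),
    class = "mirna_enrichment")
}

#' @export
print.mirna_enrichment <- function(x, ...) {
  cat("Tri-partite miRNA cluster enrichment\n")
  cat("  cluster:", x$cluster_id, "(", length(x$members),
      "members in universe )\n")
  cat("  category:", x$category, " measures:",
      paste(x$measures, collapse = ", "), "\n")
  cat("  universes: genes =", x$universes["genes"],
      ", links =", x$universes["links"],
      ", miRNAs =", x$universes["mirnas"], "\n")
  cat("  terms tested:", nrow(x$records), "\n")
  invisible(x)
}

#' Summarize an enrichment fit
#'
#' @param object A `mirna_enrichment`.
#' @param n Number of top terms to display per measure.
#' @param ... Unused.
#' @return Invisibly, a named list of the top-`n` records per measure.
#' @export
summary.mirna_enrichment <- function(object, n = 5, ...) {
  print(object)
  out <- list()
  for (m in object$measures) {
    pcol <- paste0("p_", m)
    if (!pcol %in% names(object$records)) next
    ord <- order(object$records[[pcol]])
    top <- utils::head(object$records[ord, c("term_id", "name", pcol)], n)
    rownames(top) <- NULL
    out[[m]] <- top
    cat("\nTop", nrow(top), "terms by", m, ":\n")
    print(top)
  }
  invisible(out)
}

#' @export
as.data.frame.mirna_enrichment <- function(x, ...) x$records

#' Histogram of enrichment p-values per measure
#'
#' @param x A `mirna_enrichment`.
#' @param bins Number of equal-width bins on `[0, 1]`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mirna_enrichment <- function(x, bins = 20, ...) {
  pcols <- intersect(paste0("p_", x$measures), names(x$records))
  if (!length(pcols)) stop("no p-value columns to plot")
  old <- graphics::par(mfrow = c(1, length(pcols)))
  on.exit(graphics::par(old))
  for (pc in pcols) {
    graphics::hist(x$records[[pc]], breaks = seq(0, 1, length.out = bins + 1),
                   main = pc, xlab = "p-value", col = "grey80", ...)
  }
  invisible(x)
}

#' Rank-threshold term set S_theta(n)
#'
#' For a single measure, the set of terms whose rank is at most `n`
#' (competition ranking, so ties at the boundary are included).  For
#' several measures the per-measure sets are combined by intersection
#' (default, a consensus set) or union.
#'
#' @param fit A `mirna_enrichment`, or its `records` data.frame with rank
#'   columns.
#' @param measures Character vector naming measures or measure
#'   combinations whose rank columns exist, e.g. `"mu"` or `"rho_tau"`.
#' @param n Rank threshold (>= 1).
#' @param combine_op `"intersection"` (default) or `"union"` across the
#'   requested measures.
#' @return Object of class `term_set`: list with `terms`, `measures`, `n`,
#'   `combine_op`, `category`.
#' @export
top_n_set <- function(fit, measures, n, combine_op = c("intersection",
                                                       "union")) {
  combine_op <- match.arg(combine_op)
  if (n < 1) stop("n must be >= 1")
  rec <- if (inherits(fit, "mirna_enrichment")) fit$records else fit
  category <- if (inherits(fit, "mirna_enrichment")) fit$category
              else unique(rec$category)[1]
  sets <- lapply(measures, function(m) {
    col <- paste0("rank_", m)
    if (!col %in% names(rec)) stop("no rank column for measure '", m, "'")
    rec$term_id[rec[[col]] <= n]
  })
  terms <- Reduce(if (combine_op == "intersection") intersect else union,
                  sets)
  structure(list(terms = sort(terms), measures = measures, n = n,
                 combine_op = combine_op, category = category),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("term set S_{", paste(x$measures, collapse = ","), "}(", x$n, "): ",
      length(x$terms), " term(s)",
      if (length(x$measures) > 1) paste0(" [", x$combine_op, "]"), "\n",
      sep = "")
  invisible(x)
}
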