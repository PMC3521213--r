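#' Contingency quartets for the three enrichment measures
#'
#' For a miRNA cluster and the set of genes annotated to one GO term,
#' each measure partitions its own universe into a 2x2 table
#' `(i, j, k, l)`: inside/outside the cluster-derived set crossed with
#' annotated/not annotated to the term.
#'
#' \describe{
#'   \item{rho (gene-centric)}{universe = genes with at least one link.
#'     `i` counts target-cluster genes annotated to the term, `j` the
#'     remaining target-cluster genes, `k` annotated genes outside the
#'     target cluster, `l` the rest.}
#'   \item{tau (link-centric)}{universe = all links.  `i` counts links from
#'     cluster members to annotated genes, `j` links from members to
#'     unannotated genes, `k`/`l` the analogous counts for non-members.}
#'   \item{mu (miRNA-centric)}{universe = all miRNAs.  `i` counts cluster
#'     members targeting at least one annotated gene, `j` the remaining
#'     members, `k`/`l` the analogous counts for non-members.}
#' }
#'
#' Cluster members absent from the miRNA universe are dropped (with a
#' warning) before counting; `annotated_genes` is intersected with the
#' gene universe so that all three measures see the same annotation set.
#'
#' @param network A [target_network()].
#' @param cluster A [mirna_cluster()].
#' @param annotated_genes Character vector: genes annotated to the term
#'   under scrutiny.
#' @param term_id Optional term accession recorded on the quartet.
#' @return An object of class `contingency_quartet`: list with fields
#'   `measure`, `i`, `j`, `k`, `l`, `cluster_id`, `term_id`.  The four
#'   counts always sum to the measure's universe size.
#' @name contingency
NULL

.quartet <- function(measure, i, j, k, l, cluster_id, term_id) {
  structure(list(measure = measure, i = as.integer(i), j = as.integer(j),
                 k = as.integer(k), l = as.integer(l),
                 cluster_id = cluster_id, term_id = term_id),
            class = "contingency_quartet")
}

#' @rdname contingency
#' @export
rho_quartet <- function(network, cluster, annotated_genes, term_id = NA) {
  tgc <- target_gene_cluster(network, cluster)
  if (!length(tgc)) stop("cluster '", cluster$cluster_id,
                         "' has an empty target gene cluster")
  a <- intersect(annotated_genes, network$genes)
  i <- length(intersect(tgc, a))
  .quartet("rho", i, length(tgc) - i, length(a) - i,
           length(network$genes) - length(tgc) - (length(a) - i),
           cluster$cluster_id, term_id)
}

#' @rdname contingency
#' @export
tau_quartet <- function(network, cluster, annotated_genes, term_id = NA) {
  members <- .cluster_in_universe(network, cluster)
  if (!length(target_gene_cluster(network, cluster))) {
    stop("cluster '", cluster$cluster_id,
         "' has an empty target gene cluster")
  }
  a <- intersect(annotated_genes, network$genes)
  from_cluster <- network$links$mirna %in% members
  to_annotated <- network$links$gene %in% a
  .quartet("tau",
           sum(from_cluster & to_annotated),
           sum(from_cluster & !to_annotated),
           sum(!from_cluster & to_annotated),
           sum(!from_cluster & !to_annotated),
           cluster$cluster_id, term_id)
}

#' @rdname contingency
#' @export
mu_quartet <- function(network, cluster, annotated_genes, term_id = NA) {
  members <- .cluster_in_universe(network, cluster)
  if (!length(target_gene_cluster(network, cluster))) {
    stop("cluster '", cluster$cluster_id,
         "' has an empty target gene cluster")
  }
  a <- intersect(annotated_genes, network$genes)
  hits <- unique(network$links$mirna[network$links$gene %in% a])
  i <- length(intersect(members, hits))
  k <- length(setdiff(hits, members))
  .quartet("mu", i, length(members) - i, k,
           length(network$mirnas) - length(members) - k,
           cluster$cluster_id, term_id)
}

#' @export
print.contingency_quartet <- function(x, ...) {
  cat(sprintf("%s quartet (cluster %s, term %s): i=%d j=%d k=%d l=%d  [universe %d]\n",
              x$measure, x$cluster_id, x$term_id,
              x$i, x$j, x$k, x$l, x$i + x$j + x$k + x$l))
  invisible(x)
}
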