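#' Construct a miRNA-target network
#'
#' The network is an unweighted set of miRNA-to-gene links; the miRNA and
#' gene universes are exactly the endpoints of those links.  Identifiers
#' are trimmed and miRNA ids compared case-insensitively (lower-cased on
#' input); duplicate pairs collapse to one link.
#'
#' @param pairs data.frame with columns `mirna` and `gene`.
#' @return An object of class `target_network`: list with `links`
#'   (data.frame `mirna`, `gene`), `mirnas`, `genes`, `n_links`.
#' @export
target_network <- function(pairs) {
  stopifnot(all(c("mirna", "gene") %in% names(pairs)))
  links <- data.frame(mirna = tolower(trimws(as.character(pairs$mirna))),
                      gene = trimws(as.character(pairs$gene)),
                      stringsAsFactors = FALSE)
  links <- links[!duplicated(links), , drop = FALSE]
  rownames(links) <- NULL
  structure(
    list(links = links,
         mirnas = sort(unique(links$mirna)),
         genes = sort(unique(links$gene)),
         n_links = nrow(links)),
    class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat("miRNA-target network:", x$n_links, "links,",
      length(x$mirnas), "miRNAs,", length(x$genes), "genes\n")
  invisible(x)
}

#' Read a miRNA-target pair table
#'
#' The TSV must have a header with columns `mirna` and `gene`.  Any further
#' columns are interpreted as per-algorithm 0/1 prediction votes (one
#' column per target-prediction algorithm), in which case a vote table is
#' returned; without vote columns the bare pairs become a
#' [target_network()].
#'
#' @param path Path to a tab-separated file.
#' @return A `target_network`, or a `prediction_votes` object: a data.frame
#'   with columns `mirna`, `gene` and one 0/1 column per algorithm, plus
#'   attribute `algorithms`.
#' @export
read_target_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("mirna", "gene") %in% names(df))) {
    stop("pairs file must have columns 'mirna' and 'gene'; found: ",
         paste(names(df), collapse = ", "))
  }
  algos <- setdiff(names(df), c("mirna", "gene"))
  dup <- duplicated(df[c("mirna", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (mirna, gene) row(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  if (!length(algos)) return(target_network(df))
  for (a in algos) {
    v <- df[[a]]
    if (!all(v %in% c(0L, 1L))) {
      stop("algorithm column '", a, "' must contain only 0/1 votes")
    }
    df[[a]] <- as.integer(v)
  }
  df$mirna <- tolower(trimws(df$mirna))
  df$gene <- trimws(df$gene)
  rownames(df) <- NULL
  structure(df, algorithms = algos,
            class = c("prediction_votes", "data.frame"))
}

#' Filter a vote table into a target-pair variation
#'
#' Reproduces the vote-count filters used to build target-pair variations:
#' keep a (miRNA, gene) pair when its number of positive algorithm votes
#' falls in `[votes_min, votes_max]`, optionally additionally requiring a
#' named algorithm to be among the positive voters.  An exact-count rule is
#' `votes_min == votes_max`.
#'
#' @param votes A `prediction_votes` table from [read_target_pairs()].
#' @param votes_min,votes_max Inclusive bounds on the positive-vote count;
#'   `votes_max` defaults to the number of algorithms.
#' @param including Optional algorithm name that must itself have voted
#'   positive for the pair.
#' @return A [target_network()] of the retained pairs.
#' @export
build_variation <- function(votes, votes_min, votes_max = NULL,
                            including = NULL) {
  algos <- attr(votes, "algorithms")
  if (is.null(votes_max)) votes_max <- length(algos)
  if (votes_min < 0 || votes_max > length(algos) || votes_min > votes_max) {
    stop("vote bounds must satisfy 0 <= votes_min <= votes_max <= ",
         length(algos))
  }
  n_pos <- rowSums(as.data.frame(votes)[, algos, drop = FALSE])
  keep <- n_pos >= votes_min & n_pos <= votes_max
  if (!is.null(including)) {
    if (!including %in% algos) {
      stop("unknown algorithm: ", including)
    }
    keep <- keep & votes[[including]] == 1L
  }
  target_network(as.data.frame(votes)[keep, c("mirna", "gene"),
                                      drop = FALSE])
}

#' A miRNA cluster
#'
#' @param cluster_id Label for the cluster.
#' @param members Character vector of miRNA ids (must be non-empty).
#' @return Object of class `mirna_cluster`.
#' @export
mirna_cluster <- function(cluster_id, members) {
  members <- unique(tolower(trimws(as.character(members))))
  if (!length(members)) stop("cluster '", cluster_id, "' has no members")
  structure(list(cluster_id = as.character(cluster_id), members = members),
            class = "mirna_cluster")
}

#' @export
print.mirna_cluster <- function(x, ...) {
  cat("miRNA cluster '", x$cluster_id, "': ", length(x$members),
      " member(s)\n", sep = "")
  invisible(x)
}

#' Read miRNA cluster memberships
#'
#' Long-format TSV with header columns `cluster_id` and `mirna`, one row
#' per membership.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of [mirna_cluster()] objects.
#' @export
read_mirna_clusters <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "mirna") %in% names(df))) {
    stop("clusters file must have columns 'cluster_id' and 'mirna'")
  }
  by_cl <- split(df$mirna, df$cluster_id)
  stats::setNames(
    lapply(names(by_cl), function(id) mirna_cluster(id, by_cl[[id]])),
    names(by_cl))
}

# cluster members present in the network's miRNA universe; warns when any
# are dropped so downstream margins stay consistent.
.cluster_in_universe <- function(network, cluster) {
  inside <- intersect(cluster$members, network$mirnas)
  missing <- setdiff(cluster$members, inside)
  if (length(missing)) {
    warning("cluster '", cluster$cluster_id, "': ", length(missing),
            " member(s) absent from the miRNA universe dropped")
  }
  inside
}

#' Target gene cluster of a miRNA cluster
#'
#' All genes targeted by at least one member of the cluster.  Members
#' absent from the network's miRNA universe are ignored (with a warning);
#' a cluster whose members target nothing yields an empty vector, which
#' callers treat as a skip signal.
#'
#' @param network A `target_network`.
#' @param cluster A `mirna_cluster`.
#' @return Character vector of gene ids (possibly empty).
#' @export
target_gene_cluster <- function(network, cluster) {
  members <- suppressWarnings(.cluster_in_universe(network, cluster))
  sort(unique(network$links$gene[network$links$mirna %in% members]))
}
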