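# Seeded synthetic tri-partite scenarios: ontology + annotations + target
# network + cluster, with a heavy-tailed miRNA out-degree distribution and
# an optional planted enriched term.

#' Configuration for a synthetic scenario
#'
#' Defaults describe a scaled-down but structurally realistic study: 200
#' miRNAs with heavy-tailed target multiplicity (one miRNA may target from
#' a handful to hundreds of genes), a 2000-gene universe annotated to a
#' 150-term DAG, and one 6-member cluster whose links are biased toward
#' the genes of a planted term.  The defaults roughly preserve the
#' gene:miRNA ratio of genome-scale prediction compendia while keeping a
#' single scenario cheap to generate and analyse.
#'
#' @param n_mirnas,n_genes,n_terms Universe sizes.
#' @param dag_branching Mean number of children drawn per term while
#'   building the DAG top-down.
#' @param annotation_density Mean number of direct term annotations per
#'   gene (at least 1).
#' @param degree_skew Exponent of the truncated discrete power law for
#'   miRNA out-degrees: `P(d) ~ d^-degree_skew` on
#'   `[min_out_degree, max_out_degree]`.  Larger values concentrate mass
#'   on low degrees.
#' @param planted_term_fraction Probability that each link of a cluster
#'   member points into the planted term's gene pool (0 = null scenario,
#'   links uniform).
#' @param cluster_size Number of miRNAs in the cluster under study.
#' @param seed Integer seed; one generator instance drives all draws and
#'   the global RNG state is left untouched.
#' @param min_out_degree,max_out_degree Out-degree support;
#'   `max_out_degree` defaults to `n_genes`.
#' @param planted_pool_fraction Share of the gene universe directly
#'   annotated to the planted term (its direct annotations are topped up
#'   to this size), keeping the planted signal neither undetectable nor
#'   trivially saturated.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_mirnas = 200, n_genes = 2000, n_terms = 150,
                            dag_branching = 5, annotation_density = 2,
                            degree_skew = 2, planted_term_fraction = 0.9,
                            cluster_size = 6, seed = 1,
                            min_out_degree = 3, max_out_degree = NULL,
                            planted_pool_fraction = 0.04) {
  if (is.null(max_out_degree)) max_out_degree <- n_genes
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes, n_terms = n_terms,
              dag_branching = dag_branching,
              annotation_density = annotation_density,
              degree_skew = degree_skew,
              planted_term_fraction = planted_term_fraction,
              cluster_size = cluster_size, seed = as.integer(seed),
              min_out_degree = min_out_degree,
              max_out_degree = max_out_degree,
              planted_pool_fraction = planted_pool_fraction)
  stopifnot(n_mirnas >= 1, n_genes >= 2, n_terms >= 2,
            dag_branching > 0, annotation_density >= 1,
            cluster_size >= 1, cluster_size <= n_mirnas,
            planted_term_fraction >= 0, planted_term_fraction <= 1,
            min_out_degree >= 1, min_out_degree <= max_out_degree,
            max_out_degree <= n_genes,
            planted_pool_fraction > 0, planted_pool_fraction <= 1)
  class(cfg) <- "scenario_config"
  cfg
}

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# truncated discrete power law on lo..hi with P(d) proportional to d^-skew
.rpowerlaw <- function(n, skew, lo, hi) {
  support <- lo:hi
  w <- support^(-skew)
  sample(support, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic tri-partite scenario
#'
#' Builds, from one seed: (1) a single-category GO-like DAG grown
#' top-down with Poisson branching plus sparse extra `is_a` edges (so it
#' is a DAG, not a tree); (2) direct gene annotations drawn uniformly
#' over non-root terms at the configured density; (3) a target network
#' whose miRNA out-degrees follow a truncated power law, with the cluster
#' members' links biased into the gene pool of a planted leaf term;
#' (4) the miRNA cluster itself (the first `cluster_size` miRNAs).
#'
#' The planted term is the leaf term with the most directly annotated
#' genes; generation aborts if no leaf has at least two annotated genes
#' (infeasible configuration).  With `planted_term_fraction = 0` the
#' cluster's links are drawn exactly like everyone else's, giving an
#' exact null for all three measures.
#'
#' @param config A [scenario_config()].
#' @return A list of class `synthetic_scenario` with elements `ontology`,
#'   `annotations` (raw, unpropagated), `network`, `cluster`,
#'   `planted_term`, `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  .with_seed(config$seed, {
    onto <- .gen_dag(config$n_terms, config$dag_branching)
    anno <- .gen_annotations(config, onto)

    # planted term: the best-annotated leaf
    leaves <- onto$terms$term_id[lengths(onto$children[onto$terms$term_id])
                                 == 0L]
    leaves <- setdiff(leaves, onto$roots)
    counts <- table(factor(anno$term, levels = leaves))
    if (!length(leaves) || max(counts) < 2) {
      stop("infeasible configuration: no leaf term with >= 2 annotated ",
           "genes to plant")
    }
    planted <- leaves[which.max(counts)]

    genes <- sprintf("g%05d", seq_len(config$n_genes))
    # size the planted term's gene pool to a fixed share of the universe,
    # so its enrichment signal is neither undetectable nor trivial
    pool <- unique(anno$gene[anno$term == planted])
    pool_target <- ceiling(config$planted_pool_fraction * config$n_genes)
    if (length(pool) < pool_target) {
      extra_genes <- sample(setdiff(genes, pool),
                            pool_target - length(pool))
      anno <- .annotations(rbind(
        as.data.frame(anno),
        data.frame(gene = extra_genes, term = planted, evidence = "IEA",
                   stringsAsFactors = FALSE)))
      pool <- c(pool, extra_genes)
    }
    mirnas <- sprintf("mir-%04d", seq_len(config$n_mirnas))
    members <- mirnas[seq_len(config$cluster_size)]
    deg <- .rpowerlaw(config$n_mirnas, config$degree_skew,
                      config$min_out_degree, config$max_out_degree)
    nonpool <- setdiff(genes, pool)
    frac <- config$planted_term_fraction

    link_list <- vector("list", config$n_mirnas)
    for (m in seq_len(config$n_mirnas)) {
      d <- deg[m]
      if (mirnas[m] %in% members && frac > 0) {
        n_pool <- min(stats::rbinom(1, d, frac), length(pool))
        link_list[[m]] <- c(sample(pool, n_pool),
                            sample(nonpool, min(d - n_pool,
                                                length(nonpool))))
      } else {
        link_list[[m]] <- sample(genes, d)
      }
    }
    network <- target_network(data.frame(
      mirna = rep(mirnas, lengths(link_list)),
      gene = unlist(link_list, use.names = FALSE),
      stringsAsFactors = FALSE))
    cluster <- mirna_cluster("C1", members)

    structure(list(ontology = onto, annotations = anno, network = network,
                   cluster = cluster, planted_term = planted,
                   config = config),
              class = "synthetic_scenario")
  })
}

# DAG grown level by level; extra parents (20% of non-root terms) point to
# a strictly shallower term, preserving acyclicity.
.gen_dag <- function(n_terms, branching) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parent_of <- stats::setNames(rep(list(character(0)), n_terms), ids)
  depth <- stats::setNames(integer(n_terms), ids)
  made <- 1L
  frontier <- 1L
  while (made < n_terms) {
    nxt <- integer(0)
    for (t in frontier) {
      if (made >= n_terms) break
      kids <- stats::rpois(1, branching)
      if (kids > 0) {
        take <- min(kids, n_terms - made)
        idx <- made + seq_len(take)
        for (i in idx) {
          parent_of[[ids[i]]] <- ids[t]
          depth[ids[i]] <- depth[ids[t]] + 1L
        }
        made <- made + take
        nxt <- c(nxt, idx)
      }
    }
    if (made < n_terms && !length(nxt)) {
      # a barren level: force one child on the last term
      made <- made + 1L
      parent_of[[ids[made]]] <- ids[made - 1L]
      depth[ids[made]] <- depth[ids[made - 1L]] + 1L
      nxt <- made
    }
    frontier <- nxt
  }
  # sparse multiple inheritance
  for (i in 2:n_terms) {
    if (stats::runif(1) < 0.2) {
      shallower <- ids[depth < depth[ids[i]]]
      shallower <- setdiff(shallower, c(ids[i], parent_of[[ids[i]]]))
      if (length(shallower)) {
        parent_of[[ids[i]]] <- c(parent_of[[ids[i]]],
                                 sample(shallower, 1))
      }
    }
  }
  terms <- data.frame(term_id = ids,
                      name = paste("synthetic term", seq_len(n_terms)),
                      category = "BP", is_obsolete = FALSE,
                      stringsAsFactors = FALSE)
  onto <- structure(list(terms = terms, parents = parent_of,
                         children = .invert_edges(parent_of, ids),
                         roots = NULL),
                    class = "go_ontology")
  .check_acyclic(onto)
  onto$roots <- .find_roots(onto)
  onto
}

.gen_annotations <- function(config, onto) {
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  non_root <- setdiff(onto$terms$term_id, onto$roots)
  n_t <- pmin(1L + stats::rpois(config$n_genes,
                                config$annotation_density - 1),
              length(non_root))
  terms <- unlist(lapply(n_t, function(k) sample(non_root, k)),
                  use.names = FALSE)
  df <- data.frame(gene = rep(genes, n_t), term = terms,
                   evidence = "IEA", stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("gene", "term")]), , drop = FALSE]
  rownames(df) <- NULL
  .annotations(df)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("synthetic tri-partite scenario (seed", x$config$seed, ")\n")
  print(x$ontology); print(x$annotations); print(x$network)
  cat("  planted term:", x$planted_term,
      "( bias", x$config$planted_term_fraction, ")\n")
  invisible(x)
}

#' Write a scenario to the four standard input files
#'
#' Emits `ontology.obo`, `annotations.gaf`, `pairs.tsv`, `clusters.tsv`
#' and a `manifest.json` recording the seed and parameters, so that
#' end-to-end runs consume the same readers as real data.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing scenario files (default `FALSE`:
#'   refuse if any target file already exists).
#' @return Invisibly, the named vector of file paths.
#' @export
write_scenario <- function(scenario, dir, force = FALSE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  files <- c(obo = file.path(dir, "ontology.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             pairs = file.path(dir, "pairs.tsv"),
             clusters = file.path(dir, "clusters.tsv"),
             manifest = file.path(dir, "manifest.json"))
  if (!force && any(file.exists(files))) {
    stop("output files already exist in '", dir,
         "'; use force = TRUE to overwrite")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(.format_obo(scenario$ontology), files["obo"])
  writeLines(.format_gaf(scenario$annotations, scenario$ontology),
             files["gaf"])
  utils::write.table(scenario$network$links, files["pairs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cluster_id = scenario$cluster$cluster_id,
               mirna = scenario$cluster$members),
    files["clusters"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(generator = "mirtrigo::write_scenario",
         seed = scenario$config$seed,
         parameters = unclass(scenario$config),
         planted_term = scenario$planted_term,
         files = as.list(basename(files[1:4]))),
    files["manifest"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}

.format_obo <- function(onto) {
  ns_map <- c(BP = "biological_process", MF = "molecular_function",
              CC = "cellular_component")
  out <- c("format-version: 1.2", "")
  for (r in seq_len(nrow(onto$terms))) {
    id <- onto$terms$term_id[r]
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", onto$terms$name[r]),
                paste0("namespace: ", ns_map[onto$terms$category[r]]))
    if (onto$terms$is_obsolete[r]) {
      stanza <- c(stanza, "is_obsolete: true")
    } else {
      stanza <- c(stanza, paste0("is_a: ", onto$parents[[id]]))
    }
    out <- c(out, stanza, "")
  }
  out
}

.format_gaf <- function(anno, onto) {
  aspect <- c(BP = "P", MF = "F", CC = "C")
  cat_of <- onto$terms$category[match(anno$term, onto$terms$term_id)]
  rows <- paste("SYNTH", anno$gene, anno$gene, "", anno$term,
                "SYNTH:0000001", anno$evidence, "", aspect[cat_of],
                "", "", "protein", "taxon:0000", "20120101", "synth",
                "", "", sep = "\t")
  c("!gaf-version: 2.1", rows)
}

#' Fixture pairs illustrating measure discriminability
#'
#' Two hand-built pairs of targeting topologies embedded in a fixed
#' 30-miRNA, 60-gene background network, all sharing the same target gene
#' cluster and the same 11-gene annotated set, so their gene-centric
#' (rho) contingency quartets are identical by construction:
#' \describe{
#'   \item{A vs B}{the same 5 cluster miRNAs reach the same 6 annotated
#'     genes through 8 (sparse) vs 22 (dense) links -- only the
#'     link-centric tau measure separates them.}
#'   \item{C vs D}{6 links to annotated genes carried by 6 vs 3 distinct
#'     cluster miRNAs -- only the miRNA-centric mu measure separates
#'     them.}
#' }
#'
#' @return Named list `A`, `B`, `C`, `D`; each element is a list with
#'   `network`, `cluster`, `annotated_genes`, `term_id`.
#' @export
make_discriminability_fixtures <- function() {
  genes <- sprintf("g%02d", 1:60)
  mirnas <- sprintf("mir-%02d", 1:30)
  annotated <- genes[1:11]
  term_id <- "GO:0000101"
  cluster <- mirna_cluster("FIG", mirnas[1:6])

  # fixed background: mir-07..mir-30, 3 genes each, covering all 60 genes
  bg <- do.call(rbind, lapply(7:30, function(b) {
    idx <- ((b - 7) * 3 + 0:2) %% 60 + 1
    data.frame(mirna = mirnas[b], gene = genes[idx],
               stringsAsFactors = FALSE)
  }))

  lk <- function(m, g) data.frame(mirna = mirnas[m], gene = genes[g],
                                  stringsAsFactors = FALSE)
  unann_ab <- lk(6, 20:25)                       # mir-06 -> unannotated
  sparse <- rbind(lk(1, c(1, 2)), lk(2, c(2, 3)), lk(3, 3), lk(4, 4),
                  lk(5, c(5, 6)))                # 8 links, 5 miRNAs
  dense_all <- merge(data.frame(m = 1:5), data.frame(g = 1:6))
  drop <- paste(c(1, 2, 3, 3, 4, 4, 5, 5), c(6, 6, 5, 6, 5, 6, 1, 2))
  dense_all <- dense_all[!paste(dense_all$m, dense_all$g) %in% drop, ]
  dense <- lk(dense_all$m, dense_all$g)          # 22 links, 5 miRNAs

  unann_cd <- lk(1:6, 20:25)                     # one unannotated each
  six_mirnas <- lk(1:6, 1:6)                     # 6 links, 6 miRNAs
  three_mirnas <- rbind(lk(1, c(1, 2)), lk(2, c(3, 4)),
                        lk(3, c(5, 6)))          # 6 links, 3 miRNAs

  fixture <- function(cluster_links) {
    list(network = target_network(rbind(cluster_links, bg)),
         cluster = cluster, annotated_genes = annotated,
         term_id = term_id)
  }
  list(A = fixture(rbind(sparse, unann_ab)),
       B = fixture(rbind(dense, unann_ab)),
       C = fixture(rbind(six_mirnas, unann_cd)),
       D = fixture(rbind(three_mirnas, unann_cd)))
}
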