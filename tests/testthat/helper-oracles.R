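# Independent oracles and tiny fixture builders used across the suite.

# exact upper-tail hypergeometric probability by direct enumeration of the
# pmf with binomial coefficients (no distribution functions involved)
oracle_upper_tail <- function(i, j, k, l) {
  N <- i + j + k + l
  m <- i + k      # annotated elements in the universe
  s <- i + j      # elements drawn from the cluster side
  xs <- max(0, s - (N - m)):min(m, s)
  xs <- xs[xs >= i]
  if (!length(xs)) return(0)
  sum(choose(m, xs) * choose(N - m, s - xs)) / choose(N, s)
}

# brute-force transitive ancestor closure by repeated parent walking
oracle_ancestors <- function(parents, term) {
  out <- character(0)
  stack <- parents[[term]]
  while (length(stack)) {
    x <- stack[[1]]
    stack <- stack[-1]
    if (!x %in% out) {
      out <- c(out, x)
      stack <- c(stack, parents[[x]])
    }
  }
  sort(unique(out))
}

# brute-force descendant enumeration from a parent list
oracle_descendants <- function(parents, term) {
  ids <- names(parents)
  sort(Filter(function(t) term %in% oracle_ancestors(parents, t), ids))
}

# random parent list on n terms (term 1 is the root); some terms get two
# parents so the result is a DAG, not a tree
random_parent_list <- function(n, two_parent_prob = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)[-1]) {
    np <- if (i > 2 && stats::runif(1) < two_parent_prob) 2L else 1L
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], min(np, i - 1))
  }
  parents
}

# render a parent list as OBO text (category BP throughout)
obo_text <- function(parents, obsolete = character(0)) {
  ids <- names(parents)
  out <- c("format-version: 1.2", "")
  for (id in ids) {
    stanza <- c("[Term]", paste0("id: ", id),
                paste0("name: name of ", id),
                "namespace: biological_process")
    if (id %in% obsolete) {
      stanza <- c(stanza, "is_obsolete: true")
    } else {
      stanza <- c(stanza, paste0("is_a: ", parents[[id]]))
    }
    out <- c(out, stanza, "")
  }
  out
}

ontology_from_parents <- function(parents, obsolete = character(0)) {
  read_obo(obo_text(parents, obsolete))
}

# one GAF 2.1 line with the given gene symbol, term and evidence code
gaf_line <- function(gene, term, evidence = "IEA", qualifier = "") {
  paste("DB", paste0("ID:", gene), gene, qualifier, term, "REF:1",
        evidence, "", "P", "", "", "protein", "taxon:9606", "20120101",
        "GOA", "", "", sep = "\t")
}

gaf_text <- function(genes, terms, evidence = "IEA", qualifier = "") {
  c("!gaf-version: 2.1",
    mapply(gaf_line, genes, terms, evidence, qualifier))
}

# annotations table built directly (bypasses GAF round-trip)
annotations_from <- function(genes, terms) {
  read_gaf(gaf_text(genes, terms))
}

# small deterministic network fixture
toy_network <- function() {
  target_network(data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m3", "m4"),
    gene  = c("g1", "g2", "g2", "g3", "g4", "g5", "g6")))
}
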