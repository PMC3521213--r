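test_that("read_obo builds the DAG, handles multiple parents and obsoletes", {
  # minimal chain: root <- a <- b
  parents <- list("GO:0000001" = character(0), "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000002")
  onto <- ontology_from_parents(parents)
  expect_equal(nrow(onto$terms), 3)
  expect_equal(sum(lengths(onto$parents)), 2)
  expect_equal(unname(onto$roots["BP"]), "GO:0000001")
  expect_setequal(term_ancestors(onto, "GO:0000003"),
                  c("GO:0000001", "GO:0000002"))

  # diamond: d has two parents -> DAG, not a tree
  parents <- list("GO:0000001" = character(0), "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000001",
                  "GO:0000004" = c("GO:0000002", "GO:0000003"))
  onto <- ontology_from_parents(parents)
  expect_length(onto$parents[["GO:0000004"]], 2)
  expect_setequal(term_ancestors(onto, "GO:0000004"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))

  # obsolete term: retained, flagged, no edges
  onto <- ontology_from_parents(parents, obsolete = "GO:0000004")
  expect_true(onto$terms$is_obsolete[onto$terms$term_id == "GO:0000004"])
  expect_length(onto$parents[["GO:0000004"]], 0)
})

test_that("read_obo rejects malformed stanzas and cyclic is_a", {
  bad <- c("format-version: 1.2", "", "[Term]",
           "name: no id here", "namespace: biological_process")
  expect_error(read_obo(bad), "missing id")

  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: a",
           "namespace: biological_process", "is_a: GO:0000002", "",
           "[Term]", "id: GO:0000002", "name: b",
           "namespace: biological_process", "is_a: GO:0000001")
  expect_error(read_obo(cyc), "cyclic")
})

test_that("read_gaf filters evidence, NOT qualifiers and duplicates", {
  txt <- c("!gaf-version: 2.1",
           "! comment",
           gaf_line("geneA", "GO:0000002", "IEA"),
           gaf_line("geneB", "GO:0000002", "ND"),
           gaf_line("geneC", "GO:0000003", "NR"),
           gaf_line("geneD", "GO:0000002", "IDA", qualifier = "NOT"),
           gaf_line("geneA", "GO:0000002", "TAS"))
  anno <- read_gaf(txt)
  # ND and NR rows excluded, NOT row dropped, duplicate pair collapsed
  expect_equal(nrow(anno), 1)
  expect_equal(anno$gene, "geneA")
  expect_false(is_propagated(anno))

  expect_warning(read_gaf(gaf_text("geneA", "GO:0000002", "XYZ")),
                 "unknown evidence")
  expect_error(read_gaf(c("!gaf-version: 2.1", "geneA\tGO:0000002")),
               "columns")

  # db-object-id column selectable
  anno2 <- read_gaf(txt, id_column = "db_object_id")
  expect_equal(anno2$gene, "ID:geneA")
})

test_that("true-path propagation matches brute-force transitive closure", {
  parents <- list("GO:0000001" = character(0), "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000002")
  onto <- ontology_from_parents(parents)
  anno <- annotations_from("geneA", "GO:0000003")
  prop <- propagate_annotations(anno, onto)
  expect_true(is_propagated(prop))
  expect_setequal(prop$term[prop$gene == "geneA"],
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_error(propagate_annotations(prop, onto), "already propagated")

  # random toy DAGs vs exhaustive ancestor-walk oracle
  set.seed(41)
  for (rep in 1:5) {
    parents <- random_parent_list(sample(8:20, 1))
    onto <- ontology_from_parents(parents)
    genes <- sprintf("gene%02d", 1:5)
    terms <- sample(names(parents), 5, replace = TRUE)
    prop <- propagate_annotations(annotations_from(genes, terms), onto)
    for (g in seq_along(genes)) {
      expected <- sort(unique(c(terms[g], oracle_ancestors(parents,
                                                           terms[g]))))
      expect_equal(sort(prop$term[prop$gene == genes[g]]), expected)
    }
  }
})

test_that("propagation warns on and drops terms missing from the ontology", {
  onto <- ontology_from_parents(list("GO:0000001" = character(0),
                                     "GO:0000002" = "GO:0000001"))
  anno <- annotations_from(c("geneA", "geneB"),
                           c("GO:0000002", "GO:0009999"))
  expect_warning(prop <- propagate_annotations(anno, onto),
                 "absent from the ontology")
  expect_false("GO:0009999" %in% prop$term)
})

test_that("term_frequency honours the two counting conventions", {
  # leaf with 4 genes: identical in both modes
  onto <- ontology_from_parents(list("GO:0000001" = character(0),
                                     "GO:0000002" = "GO:0000001"))
  anno <- annotations_from(sprintf("gene%d", 1:4), rep("GO:0000002", 4))
  expect_equal(unname(term_frequency("GO:0000002", onto, anno,
                                     "paper_sum")), 4)
  expect_equal(unname(term_frequency("GO:0000002", onto, anno,
                                     "unique_genes")), 4)

  # the same single gene under two children: the literal sum counts it
  # twice, the unique-gene mode once
  onto <- ontology_from_parents(list("GO:0000001" = character(0),
                                     "GO:0000002" = "GO:0000001",
                                     "GO:0000003" = "GO:0000001"))
  anno <- annotations_from(c("geneX", "geneX"),
                           c("GO:0000002", "GO:0000003"))
  expect_equal(unname(term_frequency("GO:0000001", onto, anno,
                                     "paper_sum")), 2)
  expect_equal(unname(term_frequency("GO:0000001", onto, anno,
                                     "unique_genes")), 1)

  expect_error(term_frequency("GO:0000009", onto, anno), "unknown term")
  expect_error(term_frequency("GO:0000001", onto,
                              propagate_annotations(anno, onto),
                              "paper_sum"),
               "unpropagated")
})

test_that("term_frequency equals exhaustive descendant enumeration", {
  set.seed(42)
  for (rep in 1:4) {
    parents <- random_parent_list(sample(10:20, 1))
    onto <- ontology_from_parents(parents)
    genes <- sprintf("gene%02d", 1:30)
    terms <- sample(names(parents), 30, replace = TRUE)
    anno <- annotations_from(genes, terms)
    for (t in sample(names(parents), 5)) {
      fam <- c(t, oracle_descendants(parents, t))
      expect_equal(unname(term_frequency(t, onto, anno, "paper_sum")),
                   sum(terms %in% fam))
      expect_equal(unname(term_frequency(t, onto, anno, "unique_genes")),
                   length(unique(genes[terms %in% fam])))
    }
  }
})

test_that("information content is zero at the root and monotone on edges", {
  parents <- list("GO:0000001" = character(0), "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000002")
  onto <- ontology_from_parents(parents)
  # 10 annotations total, 1 on the leaf
  anno <- annotations_from(sprintf("gene%02d", 1:10),
                           c(rep("GO:0000002", 9), "GO:0000003"))
  ic <- information_content(c("GO:0000001", "GO:0000003"), onto, anno)
  expect_equal(unname(ic["GO:0000001"]), 0)
  expect_equal(unname(ic["GO:0000003"]), 2.302585, tolerance = 1e-6)
  # base change rescales
  ic2 <- information_content("GO:0000003", onto, anno, log_base = 10)
  expect_equal(unname(ic2), 1, tolerance = 1e-9)

  # IC non-decreasing from parent to child on random corpora
  set.seed(43)
  parents <- random_parent_list(15)
  onto <- ontology_from_parents(parents)
  anno <- annotations_from(sprintf("gene%02d", 1:40),
                           sample(names(parents), 40, replace = TRUE))
  ics <- suppressWarnings(
    information_content(names(parents), onto, anno))
  for (child in names(parents)) {
    for (p in parents[[child]]) {
      if (!is.na(ics[child]) && !is.na(ics[p])) {
        expect_gte(ics[child], ics[p])
      }
    }
  }
})

test_that("Resnik similarity is the max-IC common ancestor", {
  # two common ancestors with different IC: the larger one wins
  parents <- list("GO:0000001" = character(0),
                  "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000002",
                  "GO:0000004" = c("GO:0000002", "GO:0000003"),
                  "GO:0000005" = c("GO:0000002", "GO:0000003"))
  onto <- ontology_from_parents(parents)
  anno <- annotations_from(sprintf("gene%02d", 1:8),
                           c("GO:0000002", "GO:0000002", "GO:0000003",
                             "GO:0000004", "GO:0000004", "GO:0000005",
                             "GO:0000005", "GO:0000001"))
  ics <- information_content(names(parents), onto, anno)
  s <- resnik_similarity("GO:0000004", "GO:0000005", onto, anno)
  common <- c("GO:0000001", "GO:0000002", "GO:0000003")
  expect_equal(s, max(ics[common]))
  expect_gt(ics["GO:0000003"], ics["GO:0000002"])  # fixture is informative

  # self-similarity is the term's own IC
  expect_equal(resnik_similarity("GO:0000004", "GO:0000004", onto, anno),
               unname(ics["GO:0000004"]))

  # disjoint branches meeting only at the root: similarity 0
  parents <- list("GO:0000001" = character(0),
                  "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000001")
  onto <- ontology_from_parents(parents)
  anno <- annotations_from(c("geneA", "geneB"),
                           c("GO:0000002", "GO:0000003"))
  expect_equal(resnik_similarity("GO:0000002", "GO:0000003", onto, anno), 0)
})

test_that("Resnik similarity is symmetric and bounded by endpoint ICs", {
  set.seed(44)
  parents <- random_parent_list(20)
  onto <- ontology_from_parents(parents)
  anno <- annotations_from(sprintf("gene%02d", 1:60),
                           sample(names(parents), 60, replace = TRUE))
  ics <- suppressWarnings(information_content(names(parents), onto, anno))
  ids <- names(parents)
  for (rep in 1:50) {
    ab <- sample(ids, 2)
    s1 <- resnik_similarity(ab[1], ab[2], onto, anno)
    s2 <- resnik_similarity(ab[2], ab[1], onto, anno)
    expect_equal(s1, s2)
    expect_lte(s1, min(ics[ab], na.rm = TRUE) + 1e-12)
    expect_gte(s1, 0)
  }
  # root-only common ancestry gives zero
  expect_equal(resnik_similarity(ids[1], ids[2], onto, anno,
                                 counting_mode = "unique_genes") >= 0, TRUE)
})
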