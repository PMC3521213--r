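#' Parse an OBO ontology file into a DAG
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file and builds a directed
#' acyclic graph of `is_a` relations.  Obsolete terms are retained (so GAF
#' rows pointing at them can be diagnosed) but carry no edges and are
#' excluded from all enrichment universes downstream.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @param include_part_of Logical; also treat `relationship: part_of` lines
#'   as parent edges.  Default `FALSE`: only `is_a` defines ancestry.
#' @return An object of class `go_ontology`: a list with
#'   \describe{
#'     \item{terms}{data.frame with columns `term_id`, `name`, `category`
#'       (one of `BP`, `MF`, `CC`), `is_obsolete`.}
#'     \item{parents}{named list mapping each term id to its parent ids.}
#'     \item{children}{the reverse mapping.}
#'     \item{roots}{named character vector of the root term per category.}
#'   }
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    stop("no [Term] stanza found in OBO input")
  }
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")

  ids <- character(0); names_ <- character(0); cats <- character(0)
  obs <- logical(0)
  parent_of <- list()

  for (s in seq_along(term_starts)) {
    beg <- term_starts[s] + 1L
    nxt <- stanza_starts[stanza_starts > term_starts[s]]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[beg:end]
    block <- block[nzchar(block)]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub(paste0("^", key, ":\\s*"), "", hit[1])
    }
    id <- get1("id")
    if (is.na(id)) {
      stop("malformed [Term] stanza starting at line ", term_starts[s],
           ": missing id")
    }
    ns <- get1("namespace")
    cat <- if (is.na(ns)) NA_character_ else unname(ns_map[ns])
    obsolete <- identical(get1("is_obsolete"), "true")
    isa_lines <- grep("^is_a:", block, value = TRUE)
    pars <- sub("^is_a:\\s*([^!\\s]+).*$", "\\1", isa_lines)
    if (include_part_of) {
      rel <- grep("^relationship:\\s*part_of\\s", block, value = TRUE)
      pars <- c(pars, sub("^relationship:\\s*part_of\\s+([^!\\s]+).*$",
                          "\\1", rel))
    }
    if (obsolete) pars <- character(0)
    ids <- c(ids, id); names_ <- c(names_, get1("name"))
    cats <- c(cats, cat); obs <- c(obs, obsolete)
    parent_of[[id]] <- unique(pars)
  }

  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  terms <- data.frame(term_id = ids, name = names_, category = cats,
                      is_obsolete = obs, stringsAsFactors = FALSE)
  # drop parent edges pointing outside the file (partial extracts)
  parent_of <- lapply(parent_of, function(p) p[p %in% ids])
  children_of <- .invert_edges(parent_of, ids)

  onto <- structure(
    list(terms = terms, parents = parent_of, children = children_of,
         roots = NULL),
    class = "go_ontology")
  .check_acyclic(onto)
  onto$roots <- .find_roots(onto)
  onto
}

.invert_edges <- function(parent_of, ids) {
  children_of <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parent_of[[id]]) {
      children_of[[p]] <- c(children_of[[p]], id)
    }
  }
  children_of
}

# Kahn's algorithm; stops on a cycle.
.check_acyclic <- function(onto) {
  ids <- onto$terms$term_id
  indeg <- vapply(onto$parents[ids], length, integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg <- stats::setNames(indeg, ids)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in onto$children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) stop("cyclic is_a relations detected in ontology")
  invisible(TRUE)
}

.find_roots <- function(onto) {
  live <- onto$terms[!onto$terms$is_obsolete, ]
  roots <- character(0)
  for (cat in unique(live$category)) {
    if (is.na(cat)) next
    in_cat <- live$term_id[live$category %in% cat]
    r <- in_cat[vapply(onto$parents[in_cat], length, integer(1)) == 0L]
    if (length(r)) roots[cat] <- r[1]
  }
  roots
}

#' Ancestors and descendants of a term
#'
#' Transitive closure over `is_a` edges; the term itself is excluded.
#'
#' @param onto A `go_ontology`.
#' @param term_id A single term accession.
#' @return Character vector of term ids (possibly empty).
#' @export
term_ancestors <- function(onto, term_id) {
  .closure(onto$parents, term_id)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(onto, term_id) {
  .closure(onto$children, term_id)
}

.closure <- function(edges, start) {
  if (!start %in% names(edges)) stop("unknown term: ", start)
  out <- character(0)
  frontier <- edges[[start]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(edges[frontier], use.names = FALSE))
  }
  unique(out)
}

# closure for every term at once, in topological order (children before
# parents for ancestor sets computed bottom-up would be wrong; we do a
# simple memoized recursion instead -- ontologies here are small).
.all_closures <- function(edges, ids) {
  memo <- new.env(parent = emptyenv())
  walk <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    direct <- edges[[id]]
    res <- direct
    for (d in direct) res <- c(res, walk(d))
    res <- unique(res)
    memo[[id]] <- res
    res
  }
  stats::setNames(lapply(ids, walk), ids)
}

#' Parse a GAF gene-association file
#'
#' Reads GAF 2.x rows into a gene/term/evidence table.  Comment lines
#' (starting with `!`) are skipped, rows whose qualifier contains `NOT`
#' are dropped, rows with an excluded evidence code (by default `ND`,
#' No biological Data, and `NR`, Not Recorded) are removed, and duplicate
#' (gene, term) pairs are collapsed to one record.
#'
#' @param path Path to a GAF file, or a character vector of GAF lines.
#' @param excluded_evidence Evidence codes to drop; default `c("ND","NR")`.
#' @param id_column Which GAF column identifies the gene: `"symbol"`
#'   (column 3, default -- target-pair tables use symbols) or
#'   `"db_object_id"` (column 2).
#' @return An object of class `go_annotations`: a data.frame with columns
#'   `gene`, `term`, `evidence` and attribute `propagated = FALSE`.
#' @export
read_gaf <- function(path, excluded_evidence = c("ND", "NR"),
                     id_column = c("symbol", "db_object_id")) {
  id_column <- match.arg(id_column)
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) {
    return(.annotations(data.frame(gene = character(0), term = character(0),
                                   evidence = character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 15L)) {
    stop("GAF row ", which(ncols < 15L)[1],
         " has ", ncols[which(ncols < 15L)[1]],
         " columns; expected >= 15")
  }
  gene_col <- if (id_column == "symbol") 3L else 2L
  gene <- vapply(fields, `[`, "", gene_col)
  qualifier <- vapply(fields, `[`, "", 4L)
  term <- vapply(fields, `[`, "", 5L)
  evidence <- vapply(fields, `[`, "", 7L)

  known <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "HTP", "HDA", "HMP",
             "HGI", "HEP", "IBA", "IBD", "IKR", "IRD", "ISS", "ISO", "ISA",
             "ISM", "IGC", "RCA", "TAS", "NAS", "IC", "ND", "NR", "IEA")
  odd <- setdiff(unique(evidence), known)
  if (length(odd)) {
    warning("unknown evidence code(s) kept: ", paste(odd, collapse = ", "))
  }
  keep <- !(evidence %in% excluded_evidence) &
    !grepl("(^|\\|)NOT($|\\|)", qualifier)
  df <- data.frame(gene = gene[keep], term = term[keep],
                   evidence = evidence[keep], stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("gene", "term")]), , drop = FALSE]
  rownames(df) <- NULL
  .annotations(df)
}

.annotations <- function(df, propagated = FALSE) {
  structure(df, propagated = propagated,
            class = c("go_annotations", "data.frame"))
}

#' Is an annotation table true-path propagated?
#' @param anno A `go_annotations` table.
#' @return Logical flag.
#' @export
is_propagated <- function(anno) isTRUE(attr(anno, "propagated"))

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term, within the same GO category.  Annotations to terms absent
#' from the ontology are dropped with a warning.
#'
#' @param anno Unpropagated `go_annotations`.
#' @param onto A `go_ontology`.
#' @return A propagated `go_annotations` table; propagated records carry
#'   evidence code `"TPR"` unless the (gene, ancestor) pair was already
#'   directly annotated.
#' @export
propagate_annotations <- function(anno, onto) {
  if (is_propagated(anno)) {
    stop("annotations are already propagated")
  }
  unknown <- setdiff(unique(anno$term), onto$terms$term_id)
  if (length(unknown)) {
    warning("dropping annotations to ", length(unknown),
            " term(s) absent from the ontology: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    anno <- anno[!anno$term %in% unknown, , drop = FALSE]
  }
  anc <- .all_closures(onto$parents, unique(anno$term))
  n_up <- lengths(anc[anno$term])
  extra <- data.frame(
    gene = rep(anno$gene, n_up),
    term = unlist(anc[anno$term], use.names = FALSE),
    evidence = "TPR", stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(anno)[c("gene", "term", "evidence")], extra)
  out <- out[!duplicated(out[c("gene", "term")]), , drop = FALSE]
  rownames(out) <- NULL
  .annotations(out, propagated = TRUE)
}

#' Annotation frequency of a term
#'
#' Counts genes attached to a term and to all of its descendants
#' (transitively).  Two counting conventions are offered:
#' \describe{
#'   \item{`paper_sum`}{direct-annotation count of the term plus the sum of
#'     direct-annotation counts of every descendant term.  A gene annotated
#'     to two descendants contributes twice (the count carries
#'     multiplicity).}
#'   \item{`unique_genes`}{size of the union of genes annotated to the term
#'     or to any descendant.}
#' }
#' With `paper_sum` the annotation table must be unpropagated, otherwise
#' every descendant's genes would be re-counted at each ancestor level.
#'
#' @param term_id Term accession(s); vectorized.
#' @param onto A `go_ontology`.
#' @param anno A `go_annotations` table.
#' @param counting_mode `"paper_sum"` (default) or `"unique_genes"`.
#' @return Nonnegative count(s), named by term id.
#' @export
term_frequency <- function(term_id, onto, anno,
                           counting_mode = c("paper_sum", "unique_genes")) {
  counting_mode <- match.arg(counting_mode)
  if (counting_mode == "paper_sum" && is_propagated(anno)) {
    stop("paper_sum counting requires unpropagated annotations")
  }
  missing_t <- setdiff(term_id, onto$terms$term_id)
  if (length(missing_t)) stop("unknown term: ", missing_t[1])
  genes_by_term <- split(anno$gene, anno$term)
  desc <- .all_closures(onto$children, unique(term_id))
  out <- vapply(term_id, function(t) {
    fam <- c(t, desc[[t]])
    if (counting_mode == "paper_sum") {
      sum(lengths(genes_by_term[fam]), na.rm = TRUE)
    } else {
      length(unique(unlist(genes_by_term[fam], use.names = FALSE)))
    }
  }, numeric(1))
  stats::setNames(out, term_id)
}

#' Information Content of a term
#'
#' `IC(t) = -log(freq(t) / freq(root))` where `root` is the category root
#' of `t` and `freq` is [term_frequency()] under the chosen counting mode.
#' The root has IC 0; rarer (more specific) terms score higher.  Terms with
#' zero frequency have undefined IC and return `NA` with a warning rather
#' than `Inf`.
#'
#' @inheritParams term_frequency
#' @param log_base Base of the logarithm; natural log by default.  All
#'   comparisons between terms are base-invariant.
#' @return Nonnegative IC value(s), named by term id; `NA` where undefined.
#' @export
information_content <- function(term_id, onto, anno,
                                counting_mode = c("paper_sum",
                                                  "unique_genes"),
                                log_base = exp(1)) {
  counting_mode <- match.arg(counting_mode)
  cats <- onto$terms$category[match(term_id, onto$terms$term_id)]
  if (anyNA(cats)) stop("unknown term: ", term_id[which(is.na(cats))[1]])
  roots <- onto$roots[cats]
  root_freq <- term_frequency(unique(roots), onto, anno, counting_mode)
  f <- term_frequency(term_id, onto, anno, counting_mode)
  if (any(root_freq == 0)) stop("root term has zero annotation frequency")
  ic <- -log(f / root_freq[roots]) / log(log_base)
  ic[f == 0] <- NA_real_
  if (anyNA(ic)) warning("IC undefined for zero-frequency term(s)")
  stats::setNames(as.numeric(ic), term_id)
}

#' Resnik semantic similarity between two terms
#'
#' The IC of the most informative common ancestor (MICA) of the two terms:
#' in a DAG the "lowest" common ancestor is taken to be the most specific
#' one, i.e. the common ancestor with the highest Information Content.
#' Both terms must belong to the same GO category.
#'
#' @param term_a,term_b Term accessions.
#' @inheritParams information_content
#' @return A nonnegative similarity; `sim(t, t) = IC(t)` and the value is
#'   bounded above by `min(IC(a), IC(b))`.
#' @export
resnik_similarity <- function(term_a, term_b, onto, anno,
                              counting_mode = c("paper_sum", "unique_genes"),
                              log_base = exp(1)) {
  counting_mode <- match.arg(counting_mode)
  cat_a <- onto$terms$category[match(term_a, onto$terms$term_id)]
  cat_b <- onto$terms$category[match(term_b, onto$terms$term_id)]
  if (is.na(cat_a)) stop("unknown term: ", term_a)
  if (is.na(cat_b)) stop("unknown term: ", term_b)
  if (!identical(cat_a, cat_b)) {
    stop("terms belong to different GO categories (", cat_a, " vs ",
         cat_b, ")")
  }
  common <- intersect(c(term_a, term_ancestors(onto, term_a)),
                      c(term_b, term_ancestors(onto, term_b)))
  if (!length(common)) stop("terms share no common ancestor")
  ics <- suppressWarnings(
    information_content(common, onto, anno, counting_mode, log_base))
  max(ics, na.rm = TRUE)
}

#' @export
print.go_ontology <- function(x, ...) {
  live <- x$terms[!x$terms$is_obsolete, ]
  cat("GO ontology:", nrow(x$terms), "terms (",
      sum(x$terms$is_obsolete), "obsolete ),",
      sum(lengths(x$parents)), "is_a edges\n")
  tab <- table(live$category)
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  roots:", paste(sprintf("%s:%s", names(x$roots), x$roots),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("GO annotations:", nrow(x), "gene-term pairs,",
      length(unique(x$gene)), "genes,",
      length(unique(x$term)), "terms",
      if (is_propagated(x)) "(true-path propagated)\n" else "(raw)\n")
  invisible(x)
}
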