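#' Average Information Content of a term set
#'
#' The arithmetic mean IC of the terms in a set, used as a specificity
#' score: rarer terms carry higher IC, so a higher average means the set
#' is made of more specific annotations.  Terms whose IC is undefined
#' (zero annotation frequency) are excluded with a warning.
#'
#' @param s A [top_n_set()] `term_set` or a character vector of term ids
#'   (non-empty).
#' @param onto A `go_ontology`.
#' @param anno A `go_annotations` table (unpropagated when
#'   `counting_mode = "paper_sum"`).
#' @inheritParams information_content
#' @return Nonnegative mean IC.
#' @export
average_ic <- function(s, onto, anno,
                       counting_mode = c("paper_sum", "unique_genes"),
                       log_base = exp(1)) {
  terms <- if (inherits(s, "term_set")) s$terms else s
  if (!length(terms)) stop("cannot average IC of an empty term set")
  ic <- suppressWarnings(
    information_content(terms, onto, anno, counting_mode, log_base))
  if (anyNA(ic)) {
    warning(sum(is.na(ic)), " term(s) with undefined IC excluded")
    ic <- ic[!is.na(ic)]
  }
  if (!length(ic)) stop("no term with defined IC in the set")
  mean(ic)
}

#' Semantic similarity density of a term set
#'
#' The mean of Resnik similarities over all unordered distinct pairs of
#' terms in the set (self-pairs excluded), a functional-homogeneity
#' score: sets of terms sharing informative ancestors score high.
#' Undefined (returns `NA`) for sets of fewer than two terms.
#'
#' @inheritParams average_ic
#' @return Nonnegative mean pairwise similarity, or `NA` when `|s| < 2`.
#' @export
semsim_density <- function(s, onto, anno,
                           counting_mode = c("paper_sum", "unique_genes"),
                           log_base = exp(1)) {
  counting_mode <- match.arg(counting_mode)
  terms <- if (inherits(s, "term_set")) s$terms else s
  terms <- unique(terms)
  if (length(terms) < 2) return(NA_real_)
  # precompute IC of every ancestor once
  anc <- lapply(terms, function(t) c(t, term_ancestors(onto, t)))
  all_anc <- unique(unlist(anc, use.names = FALSE))
  ics <- suppressWarnings(
    information_content(all_anc, onto, anno, counting_mode, log_base))
  pairs <- utils::combn(length(terms), 2)
  sims <- apply(pairs, 2, function(idx) {
    common <- intersect(anc[[idx[1]]], anc[[idx[2]]])
    if (!length(common)) stop("terms share no common ancestor: ",
                              terms[idx[1]], " / ", terms[idx[2]])
    max(ics[common], na.rm = TRUE)
  })
  mean(sims)
}

#' Compare enrichment measures across rank thresholds
#'
#' For each measure combination (the three single measures and their
#' Fisher-combined pairs/triple) and each threshold `n`, builds the
#' rank-threshold set from that combination's own rank column and scores
#' it by average IC and semantic similarity density.
#'
#' @param fit A `mirna_enrichment` with all seven rank columns (fit with
#'   `measures = c("rho","tau","mu")` and `combine = TRUE`).
#' @param n_grid Integer vector of rank thresholds.
#' @param onto,anno Ontology and (unpropagated, for `paper_sum`)
#'   annotations used for IC.
#' @inheritParams average_ic
#' @return A long-format data.frame with columns `combination`, `n`,
#'   `set_size`, `average_ic`, `semsim_density`, `capped` (`TRUE` when
#'   `n` exceeded the number of tested terms and the full set was used).
#' @export
compare_measures <- function(fit, n_grid, onto, anno,
                             counting_mode = c("paper_sum", "unique_genes"),
                             log_base = exp(1)) {
  counting_mode <- match.arg(counting_mode)
  rec <- fit$records
  combos <- c("rho", "tau", "mu", "rho_tau", "rho_mu", "tau_mu",
              "rho_tau_mu")
  missing_cols <- setdiff(paste0("rank_", combos), names(rec))
  if (length(missing_cols)) {
    stop("fit lacks rank column(s): ", paste(missing_cols, collapse = ", "),
         "; refit with all three measures and combine = TRUE")
  }
  rows <- list()
  for (cmb in combos) {
    for (n in n_grid) {
      s <- top_n_set(fit, cmb, n)
      rows[[length(rows) + 1L]] <- data.frame(
        combination = cmb, n = n, set_size = length(s$terms),
        average_ic = if (length(s$terms))
          average_ic(s, onto, anno, counting_mode, log_base) else NA_real_,
        semsim_density = semsim_density(s, onto, anno, counting_mode,
                                        log_base),
        capped = n > nrow(rec),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Equal-width p-value histogram counts
#'
#' Diagnostic binning of a p-value vector on `[0, 1]`; no statistical
#' claim is attached.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param bins Number of equal-width bins (default 20).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
pvalue_histogram <- function(p, bins = 20) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p <- p[!is.na(p)]
  edges <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(ceiling(p * bins), 1L), bins)
  data.frame(bin_lo = edges[-(bins + 1)], bin_hi = edges[-1],
             count = as.integer(tabulate(idx, nbins = bins)))
}
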