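#' Correlate gene set of a candidate gene
#'
#' Ranks every other probe by `|r|` against the candidate's own (first
#' SNP-free) probe, keeps the top `n_top`, filters them to the detection
#' threshold, and maps the survivors to unique gene ids with the seed gene
#' (and its duplicate probes) excluded. This is the gene set submitted to GO
#' over-representation to characterize the candidate's network.
#'
#' @param expr an [expression_dataset()].
#' @param gene_id the candidate gene.
#' @param n_top rank cutoff.
#' @param detect detection threshold (log2).
#' @return character vector of gene ids (possibly empty; an undetected seed
#'   gene yields an empty set with a warning).
#' @export
gene_correlate_set <- function(expr, gene_id, n_top = 1000, detect = 6.8) {
  own <- expr$probes$probe_id[expr$probes$gene_id %in% gene_id]
  if (length(own) == 0) data_error("gene %s has no probe", gene_id)
  clean <- own[!(expr$probes$snp_overlap[match(own, expr$probes$probe_id)] %in% TRUE)]
  seedp <- if (length(clean) > 0) clean[1] else own[1]
  det <- detection_filter(expr, detect)
  if (!det[seedp]) {
    warning(sprintf("seed gene %s below detection; empty correlate set", gene_id))
    return(character())
  }
  seed_tt <- trait_table(colnames(expr$values), expr$values[seedp, ])
  tc <- trait_correlates(seed_tt, expr, n_top = n_top + length(own))
  tc <- tc[!(tc$probe_id %in% own), ]          # seed gene's probes excluded
  tc <- tc[seq_len(min(n_top, nrow(tc))), ]
  keep <- det[tc$probe_id]
  ids <- tc$gene_id[keep]
  unique(ids[!is.na(ids) & ids != gene_id])
}

#' Hypergeometric GO over-representation
#'
#' For every GO term with at least one background gene, tests whether the
#' query set over-represents the term: upper-tail hypergeometric probability
#' `P(X >= observed)` drawing `|set|` genes from a population of
#' `|background|` containing `|term|` successes. The expected count is
#' `|set| * |term| / |background|` and the enrichment ratio
#' `observed/expected`. FDR is Benjamini-Hochberg across all tested terms.
#'
#' @param set query gene ids (must be a subset of `background`).
#' @param annotations an [annotation_tables()] carrying the GO table.
#' @param background background gene ids (typically all detection-passing
#'   genes on the platform).
#' @return data.frame of class `enrichment_result`: `term_id`, `name`,
#'   `observed`, `expected`, `ratio`, `p`, `fdr`, ordered by p.
#' @export
go_ora <- function(set, annotations, background) {
  if (length(set) == 0)
    return(structure(data.frame(term_id = character(), name = character(),
                                observed = integer(), expected = numeric(),
                                ratio = numeric(), p = numeric(),
                                fdr = numeric()),
                     class = c("enrichment_result", "data.frame")))
  extra <- setdiff(set, background)
  if (length(extra) > 0)
    data_error("query gene not in background: %s", extra[1])
  sets <- go_term_genes(annotations$go_terms)
  sets <- lapply(sets, intersect, background)
  keep <- lengths(sets) > 0
  terms <- annotations$go_terms[keep, ]
  sets <- sets[keep]
  N <- length(background); k <- length(set)
  obs <- vapply(sets, function(tg) length(intersect(tg, set)), integer(1))
  m <- lengths(sets)
  p <- phyper(obs - 1, m, N - m, k, lower.tail = FALSE)
  expected <- k * m / N
  out <- data.frame(term_id = terms$term_id, name = terms$name,
                    observed = obs, expected = expected,
                    ratio = ifelse(expected > 0, obs / expected, NA_real_),
                    p = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# all descendants of each term in the GO DAG (children map from go_children)
go_descendants <- function(go_terms) {
  kids <- go_children(go_terms)
  memo <- new.env(parent = emptyenv())
  desc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    direct <- kids[[id]] %||% character()
    all <- direct
    for (d in direct) all <- union(all, desc(d))
    memo[[id]] <- all
    all
  }
  setNames(lapply(go_terms$term_id, desc), go_terms$term_id)
}

#' Terminal significant GO terms
#'
#' Keeps the terms with FDR below `alpha_fdr` that have no significant
#' descendant in the ontology graph — the "terminal branches" of the
#' significant subtree, which are the most specific categories worth
#' reporting. (A term can be an interior node of the full DAG and still be
#' terminal here, as long as none of its descendants is itself significant.)
#'
#' @param results an [go_ora()] result.
#' @param annotations an [annotation_tables()] (for the DAG).
#' @param alpha_fdr significance level on the BH FDR.
#' @return the significant-and-terminal rows of `results`.
#' @export
terminal_significant <- function(results, annotations, alpha_fdr = 0.05) {
  sig <- results$term_id[results$fdr < alpha_fdr]
  if (length(sig) == 0) return(results[0, , drop = FALSE])
  desc <- go_descendants(annotations$go_terms)
  keep <- vapply(sig, function(id)
    length(intersect(desc[[id]] %||% character(), sig)) == 0, logical(1))
  results[results$term_id %in% sig[keep], , drop = FALSE]
}

#' Network criterion flags for triage
#'
#' For each candidate gene, builds its correlate set
#' ([gene_correlate_set()]), runs GO over-representation against the
#' detection-passing background and checks whether any significant terminal
#' term name matches the configured keyword pattern. Satisfied in any one
#' tissue.
#'
#' @param gene_ids candidate genes.
#' @param tissues named list of [expression_dataset()]s.
#' @param annotations an [annotation_tables()].
#' @param keywords case-insensitive regular expression on term names.
#' @param n_top,detect,alpha_fdr passed through.
#' @return named logical vector over `gene_ids`.
#' @export
network_flags <- function(gene_ids, tissues, annotations,
                          keywords = "mitochondri|axon|cytoskelet",
                          n_top = 1000, detect = 6.8, alpha_fdr = 0.05) {
  flags <- setNames(rep(FALSE, length(gene_ids)), gene_ids)
  for (expr in tissues) {
    det <- detection_filter(expr, detect)
    bg <- unique(expr$probes$gene_id[match(names(det)[det],
                                           expr$probes$probe_id)])
    bg <- bg[!is.na(bg)]
    for (gid in gene_ids) {
      if (flags[[gid]]) next
      cs <- tryCatch(suppressWarnings(
        gene_correlate_set(expr, gid, n_top = n_top, detect = detect)),
        riqtl_data_error = function(e) character())
      cs <- intersect(cs, bg)
      if (length(cs) == 0) next
      enr <- go_ora(cs, annotations, bg)
      term <- terminal_significant(enr, annotations, alpha_fdr)
      if (any(grepl(keywords, term$name, ignore.case = TRUE)))
        flags[[gid]] <- TRUE
    }
  }
  flags
}
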