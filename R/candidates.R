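#' Positional candidates within a QTL interval
#'
#' Genes whose annotated start lies within the closed interval
#' `[Mb_lo, Mb_hi]` on the named chromosome.
#'
#' @param annotations an [annotation_tables()].
#' @param interval list or vector with `chr`, `Mb_lo`, `Mb_hi`.
#' @return the matching rows of the gene table.
#' @export
genes_in_interval <- function(annotations, interval) {
  genes <- annotations$genes
  if (nrow(genes) == 0) data_error("empty gene annotation")
  keep <- genes$chr == as.character(interval$chr) &
    genes$Mb >= interval$Mb_lo & genes$Mb <= interval$Mb_hi
  genes[keep, , drop = FALSE]
}

#' Rank probes by correlation with a trait
#'
#' Pearson correlation of every probe with the trait's strain means over the
#' shared strains, ranked by `|r|` descending (both signs are informative),
#' ties broken by probe id. Zero-variance probes are excluded (their count
#' is recorded in the `n_excluded` attribute).
#'
#' @param trait a [trait_table()].
#' @param expr an [expression_dataset()].
#' @param n_top membership cutoff for the `in_top` flag.
#' @return data.frame `probe_id`, `gene_id`, `r`, `rank`, `in_top`, sorted by
#'   rank; attributes `n_shared`, `n_excluded`.
#' @export
trait_correlates <- function(trait, expr, n_top = 1000) {
  shared <- intersect(trait$strain, colnames(expr$values))
  if (length(shared) < 4) data_error("fewer than 4 shared strains")
  y <- trait$mean[match(shared, trait$strain)]
  E <- expr$values[, shared, drop = FALSE]
  sds <- apply(E, 1, sd)
  ok <- sds > 0 & sd(y) > 0
  r <- rep(NA_real_, nrow(E))
  r[ok] <- as.vector(cor(t(E[ok, , drop = FALSE]), y))
  out <- data.frame(probe_id = rownames(E),
                    gene_id = expr$probes$gene_id[match(rownames(E),
                                                        expr$probes$probe_id)],
                    r = r, stringsAsFactors = FALSE)
  out <- out[!is.na(out$r), ]
  out <- out[order(-abs(out$r), out$probe_id), ]
  out$rank <- seq_len(nrow(out))
  out$in_top <- out$rank <= n_top
  attr(out, "n_shared") <- length(shared)
  attr(out, "n_excluded") <- sum(!ok)
  rownames(out) <- NULL
  out
}

#' Variant-harboring flag for one gene
#'
#' @param gene_id gene to look up.
#' @param variants the variant annotation table (`gene_id`, `class`).
#' @param accepted variant classes that satisfy the criterion.
#' @return list `flag` (TRUE if the gene carries at least one accepted-class
#'   variant) and `classes` (the accepted classes found).
#' @export
gene_variants <- function(gene_id, variants,
                          accepted = c("nonsynonymous_snp", "indel",
                                       "transcript_variant")) {
  cls <- variants$class[variants$gene_id == gene_id]
  hit <- intersect(cls, accepted)
  list(flag = length(hit) > 0, classes = hit)
}

#' Triage configuration
#'
#' @param interval list `chr`, `Mb_lo`, `Mb_hi` (the QTL support interval).
#' @param top_n_correlates rank cutoff for the trait-correlation criterion.
#' @param detection_threshold log2 detection level.
#' @param cis_window_Mb cis half-width in Mb.
#' @param variant_classes_accepted classes satisfying the variant criterion.
#' @param network_keywords regular expression matched (case-insensitively)
#'   against significant terminal GO term names for the network criterion.
#' @param comparison_top_n rank cutoff for cross-trait correlate comparison.
#' @return list of class `triage_config`.
#' @export
triage_config <- function(interval, top_n_correlates = 1000,
                          detection_threshold = 6.8, cis_window_Mb = 5,
                          variant_classes_accepted = c("nonsynonymous_snp",
                                                       "indel",
                                                       "transcript_variant"),
                          network_keywords = "mitochondri|axon|cytoskelet",
                          comparison_top_n = 2000) {
  if (interval$Mb_lo >= interval$Mb_hi) config_error("Mb_lo must be < Mb_hi")
  if (top_n_correlates <= 0 || comparison_top_n <= 0)
    config_error("rank cutoffs must be positive")
  structure(as.list(environment()), class = "triage_config")
}

#' Seven-criterion candidate-gene triage cascade
#'
#' Assembles the per-gene boolean record over the positional candidates:
#' \enumerate{
#'   \item positional: gene start within the QTL interval;
#'   \item cis-modulated in at least one tissue;
#'   \item among the top-N trait correlates in at least one tissue (any
#'     SNP-free probe of the gene counts);
#'   \item detected (expression at or above threshold) in at least one
#'     tissue, on a SNP-free probe;
#'   \item has at least one SNP-free probe set;
#'   \item harbors an accepted-class sequence variant;
#'   \item network criterion: the gene's correlate network is enriched for a
#'     configured GO keyword (supplied as a per-gene flag, see
#'     [network_flags()]).
#' }
#' Tier 1 requires all seven; tier 2 exactly one failure (the pattern of a
#' gene failing only the correlation criterion); everything else is
#' excluded. `relaxed_pass` re-evaluates with the cis criterion waived.
#' A gene missing from an input table fails the corresponding criterion
#' explicitly (recorded in the `provenance` column), never silently.
#'
#' @param cfg a [triage_config()].
#' @param interval_genes gene table from [genes_in_interval()].
#' @param eqtl_by_tissue named list of [eqtl_table()] results.
#' @param correlates_by_tissue named list of [trait_correlates()] results.
#' @param variants variant annotation table.
#' @param network_flags named logical vector per gene (`TRUE` = criterion 7
#'   satisfied); genes absent default to `FALSE`.
#' @return data.frame of class `candidate_table`: gene id/symbol, `c1`..`c7`,
#'   `tier` (`"1"`, `"2"`, `"excluded"`), `relaxed_pass`, `provenance`.
#' @export
triage <- function(cfg, interval_genes, eqtl_by_tissue, correlates_by_tissue,
                   variants, network_flags = logical()) {
  gid <- interval_genes$gene_id
  nt <- length(eqtl_by_tissue)
  per_tissue <- function(f) {
    hit <- matrix(FALSE, length(gid), nt)
    for (t in seq_len(nt)) hit[, t] <- f(t)
    apply(hit, 1, any)
  }
  c2 <- per_tissue(function(t) {
    tab <- eqtl_by_tissue[[t]]
    vapply(gid, function(g)
      any(tab$is_cis[tab$gene_id == g & tab$eligible], na.rm = TRUE), logical(1))
  })
  c3 <- per_tissue(function(t) {
    tab <- correlates_by_tissue[[t]]
    el <- eqtl_by_tissue[[t]]
    clean <- el$probe_id[el$eligible %in% TRUE]
    vapply(gid, function(g)
      any(tab$in_top[tab$gene_id == g & tab$probe_id %in% clean &
                       tab$rank <= cfg$top_n_correlates]), logical(1))
  })
  c4 <- per_tissue(function(t) {
    tab <- eqtl_by_tissue[[t]]
    vapply(gid, function(g)
      any(tab$detected[tab$gene_id == g & tab$eligible %in% TRUE]), logical(1))
  })
  c5 <- per_tissue(function(t) {
    tab <- eqtl_by_tissue[[t]]
    vapply(gid, function(g)
      any(tab$eligible[tab$gene_id == g], na.rm = TRUE), logical(1))
  })
  c6 <- vapply(gid, function(g)
    gene_variants(g, variants, cfg$variant_classes_accepted)$flag, logical(1))
  c7 <- vapply(gid, function(g) isTRUE(unname(network_flags[g])), logical(1))
  crit <- cbind(c1 = TRUE, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, c7 = c7)
  n_fail <- rowSums(!crit)
  tier <- ifelse(n_fail == 0, "1", ifelse(n_fail == 1, "2", "excluded"))
  relaxed <- rowSums(!crit[, colnames(crit) != "c2", drop = FALSE]) == 0
  prov <- apply(crit, 1, function(x)
    if (all(x)) "" else paste0("fails:", paste(names(x)[!x], collapse = ",")))
  out <- data.frame(gene_id = gid, symbol = interval_genes$symbol,
                    crit, tier = tier, relaxed_pass = relaxed,
                    provenance = prov, stringsAsFactors = FALSE)
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Correlation between two strain-level traits
#'
#' Pearson correlation over the strains present in both tables, with the
#' two-sided p-value from the t transform.
#'
#' @param traitA,traitB [trait_table()]s.
#' @return list `r`, `p`, `n`.
#' @export
trait_correlation <- function(traitA, traitB) {
  shared <- intersect(traitA$strain, traitB$strain)
  if (length(shared) < 4) data_error("fewer than 4 shared strains")
  a <- traitA$mean[match(shared, traitA$strain)]
  b <- traitB$mean[match(shared, traitB$strain)]
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Shared correlates of two traits
#'
#' For each trait, takes the top-N probes by `|r|` in its expression
#' dataset, keeps those at or above the detection threshold, maps them to
#' unique gene symbols (case-insensitive) and intersects the two gene lists.
#'
#' @param traitA,traitB [trait_table()]s.
#' @param exprA,exprB the [expression_dataset()] used for each trait.
#' @param n_top rank cutoff per trait (2000 by default).
#' @param detect detection threshold.
#' @return list `countA_detected`, `countB_detected`, `shared_genes`,
#'   `shared_count`.
#' @export
shared_correlates <- function(traitA, traitB, exprA, exprB,
                              n_top = 2000, detect = 6.8) {
  top_genes <- function(trait, expr) {
    tc <- trait_correlates(trait, expr, n_top = n_top)
    top <- tc$probe_id[tc$in_top]
    det <- detection_filter(expr, detect)
    top <- top[det[top]]
    sym <- expr$probes$gene_id[match(top, expr$probes$probe_id)]
    unique(tolower(sym[!is.na(sym)]))
  }
  ga <- top_genes(traitA, exprA)
  gb <- top_genes(traitB, exprB)
  shared <- intersect(ga, gb)
  list(countA_detected = length(ga), countB_detected = length(gb),
       shared_genes = shared, shared_count = length(shared))
}
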