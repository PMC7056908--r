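#' Expression detection filter
#'
#' A probe is called detected when its summary expression across strains
#' reaches the platform detection threshold (log2 scale, 6.8 by default,
#' inclusive). The default summary is the strain mean; `summary = "max"`
#' calls a probe detected if any strain reaches the threshold.
#'
#' @param expr an [expression_dataset()].
#' @param threshold log2 detection level.
#' @param summary `"mean"` (default) or `"max"`.
#' @return named logical vector, one flag per probe.
#' @export
detection_filter <- function(expr, threshold = 6.8, summary = c("mean", "max")) {
  summary <- match.arg(summary)
  s <- switch(summary, mean = rowMeans(expr$values),
              max = apply(expr$values, 1, max))
  setNames(s >= threshold, rownames(expr$values))
}

#' Probe SNP-overlap filter
#'
#' Probes whose target region overlaps a SNP between the parental genomes
#' produce hybridization artifacts and are excluded from triage. Probes with
#' a missing flag are excluded with a warning.
#'
#' @param expr an [expression_dataset()].
#' @return named logical vector: `TRUE` for eligible (SNP-free) probes.
#' @export
probe_snp_filter <- function(expr) {
  flag <- expr$probes$snp_overlap
  if (anyNA(flag)) {
    warning(sprintf("%d probe(s) lack a SNP-overlap flag; excluded", sum(is.na(flag))))
    flag[is.na(flag)] <- TRUE
  }
  setNames(!flag, expr$probes$probe_id)
}

#' Genome scan of one expression microtrait
#'
#' Treats a probe's strain values as a quantitative trait and scans the
#' genome ([hk_scan()] or [lmm_scan()]), reporting the peak position and
#' statistic.
#'
#' @param expr an [expression_dataset()].
#' @param probe_id probe to scan.
#' @param g a [geno_matrix()].
#' @param method `"HK"` (default, fast) or `"LMM"`.
#' @param step_cM pseudomarker spacing (`NULL` = typed markers only).
#' @return one-row data.frame of class `eqtl_result`: `probe_id`, `gene_id`,
#'   `peak_chr`, `peak_Mb`, `peak_cM`, `peak_lrs`.
#' @export
eqtl_peak <- function(expr, probe_id, g, method = c("HK", "LMM"),
                      step_cM = NULL) {
  method <- match.arg(method)
  i <- match(probe_id, rownames(expr$values))
  if (is.na(i)) data_error("probe %s not in dataset", probe_id)
  tt <- trait_table(colnames(expr$values), expr$values[i, ])
  sc <- if (method == "HK") hk_scan(g, tt, step_cM = step_cM) else lmm_scan(g, tt)
  pk <- which.max(sc$lrs)
  out <- data.frame(probe_id = probe_id,
                    gene_id = expr$probes$gene_id[match(probe_id, expr$probes$probe_id)],
                    peak_chr = sc$chr[pk], peak_Mb = sc$Mb[pk],
                    peak_cM = sc$cM[pk], peak_lrs = sc$lrs[pk],
                    stringsAsFactors = FALSE)
  class(out) <- c("eqtl_result", "data.frame")
  out
}

# vectorized HK peaks for every probe at typed markers; used by the pipeline
eqtl_scan_all <- function(expr, g, probe_ids = rownames(expr$values),
                          min_shared = 10) {
  shared <- intersect(g$strains, colnames(expr$values))
  if (length(shared) < min_shared)
    data_error("only %d strains shared between genotypes and expression",
               length(shared))
  gs <- subset_strains(g, shared)
  E <- expr$values[probe_ids, shared, drop = FALSE]
  X <- geno_dosage(gs)
  complete <- colSums(is.na(X)) == 0
  X <- X[, complete, drop = FALSE]
  keep <- apply(X, 2, sd) > 0
  X <- X[, keep, drop = FALSE]
  map <- gs$map[complete, ][keep, ]
  n <- length(shared)
  Zx <- scale(X)
  se <- apply(E, 1, sd)
  Ze <- t(E)
  Ze <- scale(Ze)
  Ze[, se == 0] <- 0
  R <- crossprod(Ze, Zx) / (n - 1)       # probes x markers
  r2max <- apply(R^2, 1, max)
  pk <- apply(R^2, 1, which.max)
  data.frame(probe_id = probe_ids,
             gene_id = expr$probes$gene_id[match(probe_ids, expr$probes$probe_id)],
             peak_chr = map$chr[pk], peak_Mb = map$Mb[pk], peak_cM = map$cM[pk],
             peak_lrs = -n * log(pmax(1 - r2max, .Machine$double.eps)),
             stringsAsFactors = FALSE)
}

#' Classify an eQTL peak as cis or trans
#'
#' A transcript is cis-modulated when its expression peak lies on the gene's
#' own chromosome within `window_Mb` of the gene position (boundary
#' inclusive) and the peak statistic reaches `min_lrs`. The configured
#' half-width defaults to 5 Mb (a 10 Mb window centred on the gene);
#' set `window_Mb = 10` for the wider reading.
#'
#' @param res an `eqtl_result` row (from [eqtl_peak()] or [eqtl_scan_all()]).
#' @param gene_chr,gene_Mb the gene's annotated position. `NA` position
#'   returns `NA` (not classifiable).
#' @param window_Mb half-width of the cis window in Mb.
#' @param min_lrs minimum peak LRS to call a cis-eQTL (typically the
#'   suggestive permutation threshold).
#' @return logical (vectorized over rows of `res`).
#' @export
classify_cis <- function(res, gene_chr, gene_Mb, window_Mb = 5, min_lrs = 0) {
  ifelse(is.na(gene_chr) | is.na(gene_Mb), NA,
         res$peak_chr == gene_chr &
           abs(res$peak_Mb - gene_Mb) <= window_Mb &
           res$peak_lrs >= min_lrs)
}

#' Per-probe eQTL table for a tissue
#'
#' Convenience wrapper combining [eqtl_scan_all()], [detection_filter()],
#' [probe_snp_filter()] and [classify_cis()] into the per-probe record that
#' candidate triage consumes.
#'
#' @param expr an [expression_dataset()].
#' @param g a [geno_matrix()].
#' @param annotations an [annotation_tables()] (gene positions).
#' @param detect_threshold log2 detection level.
#' @param window_Mb cis half-width in Mb.
#' @param min_lrs minimum LRS for a cis call.
#' @return data.frame: probe_id, gene_id, peak chr/Mb/LRS, `detected`,
#'   `eligible` (SNP-free), `is_cis`.
#' @export
eqtl_table <- function(expr, g, annotations, detect_threshold = 6.8,
                       window_Mb = 5, min_lrs = 0) {
  res <- eqtl_scan_all(expr, g)
  m <- match(res$gene_id, annotations$genes$gene_id)
  res$detected <- unname(detection_filter(expr, detect_threshold)[res$probe_id])
  res$eligible <- unname(suppressWarnings(probe_snp_filter(expr))[res$probe_id])
  res$is_cis <- classify_cis(res, annotations$genes$chr[m],
                             annotations$genes$Mb[m],
                             window_Mb = window_Mb, min_lrs = min_lrs)
  res
}
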