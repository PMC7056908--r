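#' Construct a strain-level trait table
#'
#' The per-strain summary used for mapping: mean, standard error of the mean
#' and replicate count, mirroring GeneNetwork trait exports.
#'
#' @param strain strain labels (unique).
#' @param mean per-strain trait means.
#' @param sem per-strain SEM, or `NULL`/`NA` when unavailable (n = 1 strains
#'   must carry `NA`).
#' @param n per-strain replicate counts, or `NULL` when unavailable.
#' @return data.frame of class `trait_table` with columns `strain`, `mean`,
#'   `sem`, `n`.
#' @export
trait_table <- function(strain, mean, sem = NULL, n = NULL) {
  strain <- as.character(strain)
  if (anyDuplicated(strain))
    data_error("duplicate strain in trait table: %s", strain[duplicated(strain)][1])
  if (!is.numeric(mean) || anyNA(suppressWarnings(as.numeric(mean))))
    data_error("non-numeric trait value")
  out <- data.frame(strain = strain, mean = as.numeric(mean),
                    sem = if (is.null(sem)) NA_real_ else as.numeric(sem),
                    n = if (is.null(n)) NA_integer_ else as.integer(n),
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$n) & out$n < 1)) data_error("replicate count < 1")
  out$sem[!is.na(out$n) & out$n == 1] <- NA_real_
  attr(out, "has_sem") <- !is.null(sem)
  attr(out, "has_n") <- !is.null(n)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Read a trait table (GeneNetwork trait export layout)
#'
#' Tab-separated with header `Strain`, `Value` and optional `SE`, `N`
#' columns. Missing SE/N columns are tolerated and flagged as unavailable.
#'
#' @param path file path.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- tolower(names(tab))
  si <- match("strain", cn); vi <- match("value", cn)
  if (is.na(si) || is.na(vi))
    format_error("trait table %s must have Strain and Value columns", path)
  val <- suppressWarnings(as.numeric(tab[[vi]]))
  if (anyNA(val))
    data_error("non-numeric trait value for strain %s", tab[[si]][is.na(val)][1])
  sei <- match("se", cn); ni <- match("n", cn)
  trait_table(tab[[si]], val,
              sem = if (!is.na(sei)) suppressWarnings(as.numeric(tab[[sei]])),
              n = if (!is.na(ni)) suppressWarnings(as.integer(tab[[ni]])))
}

#' Write a trait table
#' @param tt a [trait_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(tt, path) {
  out <- data.frame(Strain = tt$strain, Value = tt$mean)
  if (isTRUE(attr(tt, "has_sem"))) out$SE <- tt$sem
  if (isTRUE(attr(tt, "has_n"))) out$N <- tt$n
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression dataset
#'
#' Probe-level log2 abundances across strains plus probe annotation
#' (owning gene and whether the probe target region overlaps a SNP between
#' the parental genomes, which disqualifies it from triage).
#'
#' @param values numeric matrix, probes x strains, log2 scale. Row names are
#'   probe ids, column names strain labels.
#' @param probes data.frame with columns `probe_id`, `gene_id`,
#'   `snp_overlap` (logical). Probes absent from this table are retained but
#'   flagged unannotated (`gene_id` NA).
#' @param tissue label, e.g. `"retina"` or `"eye"`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, probes = NULL, tissue = "retina") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) data_error("expression values must be finite")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%05d", seq_len(nrow(values)))
  ann <- data.frame(probe_id = rownames(values), gene_id = NA_character_,
                    snp_overlap = NA, stringsAsFactors = FALSE)
  if (!is.null(probes)) {
    m <- match(ann$probe_id, probes$probe_id)
    ann$gene_id <- probes$gene_id[m]
    ann$snp_overlap <- probes$snp_overlap[m]
  }
  structure(list(values = values, probes = ann, tissue = tissue),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset (%s): %d probes x %d strains (%d annotated)\n",
              x$tissue, nrow(x$values), ncol(x$values),
              sum(!is.na(x$probes$gene_id))))
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' First column holds probe ids, remaining columns one strain each, values on
#' the log2 scale. If `strain_order` is given the columns are aligned to it;
#' probes not found in `annotations` are retained but flagged unannotated.
#'
#' @param path file path.
#' @param annotations an [annotation_tables()] object or `NULL`.
#' @param strain_order character vector of strains to align/subset to (e.g.
#'   the genotyped strains); an error is raised if no strains overlap.
#' @param tissue label stored on the dataset.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, annotations = NULL,
                                   strain_order = NULL, tissue = "retina") {
  if (!file.exists(path)) data_error("file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- as.character(tab[[1]])
  if (!is.null(strain_order)) {
    keep <- intersect(strain_order, colnames(vals))
    if (length(keep) == 0)
      data_error("no overlapping strains between %s and the genotype panel", path)
    vals <- vals[, keep, drop = FALSE]
  }
  expression_dataset(vals, probes = if (!is.null(annotations)) annotations$probes,
                     tissue = tissue)
}

#' Write an expression dataset as TSV
#' @param expr an [expression_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- data.frame(ProbeId = rownames(expr$values), expr$values,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct the annotation bundle used by candidate triage
#'
#' @param genes data.frame: `gene_id`, `symbol`, `chr`, `Mb` (gene start).
#' @param probes data.frame: `probe_id`, `gene_id`, `snp_overlap` (logical).
#' @param variants data.frame: `gene_id`, `class` with class one of
#'   `nonsynonymous_snp`, `indel`, `transcript_variant`, `other`.
#' @param go_terms data.frame: `term_id`, `name`, `parents` (comma-separated
#'   term ids, empty for roots), `genes` (comma-separated gene ids).
#' @return object of class `annotation_tables`.
#' @export
annotation_tables <- function(genes, probes, variants, go_terms) {
  genes$gene_id <- as.character(genes$gene_id)
  for (nm in c("probes", "variants")) {
    tab <- get(nm)
    missing <- setdiff(tab$gene_id, genes$gene_id)
    if (length(missing) > 0)
      data_error("%s reference unknown gene_id: %s", nm, missing[1])
  }
  go_genes <- unlist(strsplit(go_terms$genes, ",", fixed = TRUE))
  missing <- setdiff(trimws(go_genes[nzchar(go_genes)]), genes$gene_id)
  if (length(missing) > 0)
    data_error("go_terms reference unknown gene_id: %s", missing[1])
  ann <- structure(list(genes = genes, probes = probes, variants = variants,
                        go_terms = go_terms), class = "annotation_tables")
  go_children(ann$go_terms)  # errors on cyclic parent links
  ann
}

# parse the comma-separated list columns of the GO table
go_term_genes <- function(go_terms) {
  sets <- strsplit(go_terms$genes, ",", fixed = TRUE)
  sets <- lapply(sets, function(x) trimws(x[nzchar(trimws(x))]))
  names(sets) <- go_terms$term_id
  sets
}

# children map from the parents column; errors if the links are cyclic
go_children <- function(go_terms) {
  parents <- strsplit(go_terms$parents, ",", fixed = TRUE)
  parents <- lapply(parents, function(x) trimws(x[nzchar(trimws(x))]))
  edges <- data.frame(
    child = rep(go_terms$term_id, lengths(parents)),
    parent = unlist(parents), stringsAsFactors = FALSE)
  kids <- split(edges$child, edges$parent)
  # cycle check by Kahn's algorithm
  indeg <- setNames(integer(length(go_terms$term_id)), go_terms$term_id)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (k in kids[[v]] %||% character()) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (seen < length(indeg)) data_error("GO parent links contain a cycle")
  kids
}

#' Read annotation tables from a directory of TSV files
#'
#' Expects `genes.tsv` (gene_id, symbol, chr, Mb), `probes.tsv` (probe_id,
#' gene_id, snp_overlap), `variants.tsv` (gene_id, class) and `go_terms.tsv`
#' (term_id, name, parents, genes; list fields comma-separated).
#'
#' @param dir directory path.
#' @return an [annotation_tables()].
#' @export
read_annotation_tables <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) data_error("annotation file not found: %s", p)
    read.delim(p, stringsAsFactors = FALSE, check.names = FALSE,
               colClasses = "character")
  }
  genes <- rd("genes.tsv"); genes$Mb <- as.numeric(genes$Mb)
  probes <- rd("probes.tsv")
  probes$snp_overlap <- as.logical(probes$snp_overlap)
  annotation_tables(genes, probes, rd("variants.tsv"), rd("go_terms.tsv"))
}

#' Write annotation tables to a directory
#' @param ann an [annotation_tables()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_annotation_tables <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wr(ann$genes, "genes.tsv"); wr(ann$probes, "probes.tsv")
  wr(ann$variants, "variants.tsv"); wr(ann$go_terms, "go_terms.tsv")
  invisible(dir)
}

#' Write a genome scan as TSV
#'
#' Columns `chr`, `cM`, `Mb`, `lrs`, `lod`, `additive`, ordered by map
#' position. [read_scan()] restores the object.
#'
#' @param scan a `qtl_scan` data.frame from [hk_scan()] or [lmm_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  write.table(scan[, c("chr", "cM", "Mb", "lrs", "lod", "additive")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome scan written by [write_scan()]
#' @param path file path.
#' @return a `qtl_scan` data.frame.
#' @export
read_scan <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chr = "character"))
  class(tab) <- c("qtl_scan", "data.frame")
  tab
}
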