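#' Construct a genotype matrix for an RI panel
#'
#' Holds biallelic homozygous calls for a set of inbred strains together with
#' the genetic (cM) and physical (Mb) marker map. Calls use the canonical
#' four-letter alphabet: `B` (maternal homozygote), `D` (paternal homozygote),
#' `H` (heterozygous) and `U` (unknown). RI strains are expected homozygous,
#' so `H` and `U` are treated as missing by all dosage-based computations.
#'
#' @param calls character matrix, strains x markers, entries in `B/D/H/U`.
#'   Row names are strain labels, column names marker ids.
#' @param map data.frame with columns `marker`, `chr`, `cM`, `Mb`; one row per
#'   marker, in the same order as the columns of `calls`. Positions must be
#'   strictly increasing within each chromosome on both scales.
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `map` and `strains`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  if (!is.data.frame(map) || !all(c("marker", "chr", "cM", "Mb") %in% names(map)))
    format_error("marker map must have columns marker, chr, cM, Mb")
  map$chr <- as.character(map$chr)
  map$marker <- as.character(map$marker)
  if (ncol(calls) != nrow(map))
    data_error("genotype matrix has %d marker columns but map has %d rows",
               ncol(calls), nrow(map))
  if (anyDuplicated(map$marker))
    data_error("duplicated marker id: %s", map$marker[duplicated(map$marker)][1])
  bad <- !(calls %in% c("B", "D", "H", "U"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    data_error("unknown genotype code '%s' at marker %s (strain %s)",
               calls[bad][1], map$marker[idx[2]],
               rownames(calls)[idx[1]] %||% idx[1])
  }
  for (ch in unique(map$chr)) {
    m <- map[map$chr == ch, ]
    if (nrow(m) > 1 && (any(diff(m$cM) <= 0) || any(diff(m$Mb) <= 0)))
      data_error("marker positions not strictly increasing on chromosome %s", ch)
  }
  colnames(calls) <- map$marker
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  structure(list(calls = calls, map = map, strains = rownames(calls)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d strains x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chr))))
  invisible(x)
}

#' Read a GeneNetwork-style .geno file
#'
#' Parses the GeneNetwork dialect: lines starting `#` are comments, lines
#' starting `@` declare metadata including the genotype code mapping
#' (`@mat`, `@pat`, `@het`, `@unk`), then a header row
#' `Chr Locus cM Mb strain1 strain2 ...` followed by one tab-separated row per
#' marker. Declared codes are recoded to the canonical `B/D/H/U` alphabet.
#'
#' @param path path to the .geno file.
#' @return A [geno_matrix()].
#' @export
read_geno <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  meta_idx <- grepl("^@", lines)
  meta <- lines[meta_idx]
  body <- lines[!meta_idx]
  codes <- c(mat = "B", pat = "D", het = "H", unk = "U")
  declared <- c(B = "B", D = "D", H = "H", U = "U")
  for (m in meta) {
    kv <- sub("^@", "", m)
    parts <- strsplit(kv, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) format_error("malformed header line: %s", m)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (key %in% names(codes)) declared[[val]] <- codes[[key]]
  }
  if (length(body) == 0) format_error("no header row found in %s", path)
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 5 || !identical(tolower(hdr[1:4]), c("chr", "locus", "cm", "mb")))
    format_error("malformed header line: %s", body[1])
  strains <- hdr[-(1:4)]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(hdr)))
    format_error("malformed data line (expected %d fields, got %d): %s",
                 length(hdr), nf[nf != length(hdr)][1],
                 body[-1][nf != length(hdr)][1])
  tab <- do.call(rbind, rows)
  map <- data.frame(marker = tab[, 2], chr = tab[, 1],
                    cM = as.numeric(tab[, 3]), Mb = as.numeric(tab[, 4]),
                    stringsAsFactors = FALSE)
  raw <- tab[, -(1:4), drop = FALSE]
  unknown <- matrix(!(raw %in% names(declared)), nrow = nrow(raw))
  if (any(unknown)) {
    idx <- which(unknown, arr.ind = TRUE)[1, ]
    data_error("unknown genotype code '%s' at marker %s",
               raw[unknown][1], map$marker[idx[1]])
  }
  calls <- matrix(unname(declared[raw]), nrow = nrow(raw))
  calls <- t(calls)  # markers were rows in the file; we store strains x markers
  rownames(calls) <- strains
  # canonical order: chromosomes in order of first appearance, then cM
  ord <- order(match(map$chr, unique(map$chr)), map$cM)
  geno_matrix(calls[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

#' Write a genotype matrix as a GeneNetwork-style .geno file
#'
#' Emits the canonical dialect accepted by [read_geno()]: `@` metadata lines
#' declaring the `B/D/H/U` code mapping, the `Chr Locus cM Mb strain...`
#' header, then one tab-separated row per marker in map order. A
#' write-then-read round trip reproduces the object exactly.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @param name dataset name written to the `@name` field.
#' @return `path`, invisibly.
#' @export
write_geno <- function(g, path, name = "riqtl") {
  stopifnot(inherits(g, "geno_matrix"))
  if (length(g$strains) == 0) format_error("genotype matrix has no strains")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("@name:%s", name), "@type:riset",
               "@mat:B", "@pat:D", "@het:H", "@unk:U"), con)
  writeLines(paste(c("Chr", "Locus", "cM", "Mb", g$strains), collapse = "\t"), con)
  body <- cbind(g$map$chr, g$map$marker,
                format(g$map$cM, trim = TRUE, scientific = FALSE),
                format(g$map$Mb, trim = TRUE, scientific = FALSE),
                t(g$calls))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Per-strain allele dosage at typed markers
#'
#' Codes `B` homozygotes 0 and `D` homozygotes 2, so a regression slope on
#' dosage is the additive effect per allele substitution. `H` and `U` calls
#' are returned as `NA` (RI strains are expected homozygous).
#'
#' @param g a [geno_matrix()].
#' @return numeric matrix, strains x markers.
#' @export
geno_dosage <- function(g) {
  d <- matrix(NA_real_, nrow(g$calls), ncol(g$calls),
              dimnames = dimnames(g$calls))
  d[g$calls == "B"] <- 0
  d[g$calls == "D"] <- 2
  d
}

#' Per-marker minor-allele frequency
#'
#' Computed over non-missing homozygous calls only; `H` and `U` are excluded.
#'
#' @param g a [geno_matrix()].
#' @return numeric vector, one frequency per marker (NaN where no homozygous
#'   calls exist).
#' @export
geno_maf <- function(g) {
  nb <- colSums(g$calls == "B")
  nd <- colSums(g$calls == "D")
  pmin(nb, nd) / (nb + nd)
}
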