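#' Configuration for the synthetic RI-panel generator
#'
#' The defaults emulate an aged biparental sib-mated RI family phenotyped for
#' optic-nerve axon necrosis: 75 strains, a 19-chromosome map at 2 cM marker
#' spacing, one planted QTL with an additive effect of +380 trait units per
#' paternal allele, a strain-mean baseline near 2,000 necrotic axons per
#' nerve, between-strain residual genetic sd 600, within-strain replicate sd
#' 1,000, 1 to 10 replicates per strain, an age trend of +34 counts per month
#' above 13 months, four injected outlier strains (3 high, 1 low), and two
#' expression tissues (retina, eye) carrying planted cis-eQTLs and a
#' trait-correlated module. An IOP-like second trait is generated with
#' correlation -0.296 to the primary trait.
#'
#' @param n_strains number of RI strains.
#' @param chromosomes data.frame `label`, `length_cM`, `spacing_cM`.
#' @param cM_to_Mb linear genetic-to-physical scale (Mb per cM).
#' @param qtl_spec data.frame `chr`, `cM`, `effect` (trait units per allele
#'   substitution); markers are inserted at QTL positions.
#' @param baseline trait grand mean.
#' @param var_strain between-strain residual genetic variance (beyond the
#'   planted QTL).
#' @param var_within within-strain replicate variance.
#' @param replicates vector of possible replicate counts per strain
#'   (sampled uniformly).
#' @param age_range months; ages drawn uniformly.
#' @param age_slope trait units added per month above 13 months.
#' @param p_female probability an animal is female.
#' @param outlier_spec list `n_high`, `n_low`, `inflation`: outlier strains
#'   have their strain effect replaced by `+/- inflation * sd(strain + within)`
#'   (scaled up by a small random amount), truncated at zero for lows.
#' @param expression_spec list: `n_genes`, `n_interval_genes`,
#'   `interval_Mb` (`c(lo, hi)` on the QTL chromosome), `n_cis_interval`,
#'   `n_cis_outside`, `cis_effect` (log2 units per allele), `n_module_genes`,
#'   `module_correlation`, `module_amplitude`, `noise_sd`, `base_range`
#'   (uniform log2 baseline), `detect_floor` (detection threshold the
#'   platform emulates), `p_snp_probe` (fraction of probes overlapping a
#'   SNP), `p_variant` (fraction of genes carrying an accepted-class
#'   variant), `p_other_variant`.
#' @param trait2_correlation generating correlation of the IOP-like trait
#'   with the primary trait's strain means.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 75,
                       chromosomes = data.frame(label = as.character(1:19),
                                                length_cM = 60,
                                                spacing_cM = 2),
                       cM_to_Mb = 2,
                       qtl_spec = data.frame(chr = "12", cM = 55, effect = 380),
                       baseline = 2000,
                       var_strain = 3e5,
                       var_within = 8e5,
                       replicates = 1:10,
                       age_range = c(13, 30),
                       age_slope = 34,
                       p_female = 0.7,
                       outlier_spec = list(n_high = 3, n_low = 1, inflation = 2.2),
                       expression_spec = list(
                         n_genes = 5000, n_interval_genes = 156,
                         interval_Mb = c(109, 112.5),
                         n_cis_interval = 10, n_cis_outside = 10,
                         cis_effect = 0.5, n_module_genes = 50,
                         module_correlation = 0.7, module_amplitude = 0.5,
                         noise_sd = 0.3, base_range = c(5, 12),
                         detect_floor = 6.8, p_snp_probe = 0.1,
                         p_variant = 0.3, p_other_variant = 0.2),
                       trait2_correlation = -0.296,
                       seed) {
  if (missing(seed)) config_error("seed is mandatory")
  if (nrow(chromosomes) == 0) config_error("at least one chromosome required")
  if (var_strain < 0 || var_within < 0) config_error("variances must be >= 0")
  if (!all(is.finite(qtl_spec$effect))) config_error("QTL effects must be finite")
  es <- expression_spec
  if (es$n_module_genes + es$n_interval_genes > es$n_genes)
    config_error("module/interval gene counts exceed n_genes")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate RI genotypes as Markov mosaics
#'
#' Each strain is an independent two-state Markov chain along each
#' chromosome: the first marker is `B` or `D` with probability 1/2
#' (expected MAF 0.5) and adjacent markers recombine with the RI-expanded
#' probability `R = 4r/(1+6r)` (sib mating), `r` Haldane at the marker gap.
#' Marker grids follow the configured spacing, with extra markers inserted
#' at planted QTL positions; physical positions are `cM * cM_to_Mb`.
#'
#' @param cfg a [sim_config()].
#' @return a [geno_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_strains
  maps <- list(); callcols <- list()
  for (i in seq_len(nrow(cfg$chromosomes))) {
    ch <- as.character(cfg$chromosomes$label[i])
    len <- cfg$chromosomes$length_cM[i]
    sp <- cfg$chromosomes$spacing_cM[i]
    cm <- seq(0, len, by = sp)
    qcm <- cfg$qtl_spec$cM[as.character(cfg$qtl_spec$chr) == ch]
    cm <- sort(unique(c(cm, qcm[qcm >= 0 & qcm <= len])))
    m <- length(cm)
    calls <- matrix("B", n, m)
    state <- rbinom(n, 1, 0.5)  # 1 = D
    calls[, 1] <- c("B", "D")[state + 1]
    if (m > 1) for (j in 2:m) {
      Rj <- ri_recomb(cm[j] - cm[j - 1])
      flip <- rbinom(n, 1, Rj) == 1
      state <- ifelse(flip, 1 - state, state)
      calls[, j] <- c("B", "D")[state + 1]
    }
    maps[[i]] <- data.frame(
      marker = sprintf("C%sM%03d", ch, seq_len(m)), chr = ch, cM = cm,
      Mb = cm * cfg$cM_to_Mb, stringsAsFactors = FALSE)
    callcols[[i]] <- calls
  }
  calls <- do.call(cbind, callcols)
  rownames(calls) <- sprintf("RIS%03d", seq_len(n))
  geno_matrix(calls, do.call(rbind, maps))
}

# marker id nearest a (chr, Mb) point
nearest_marker <- function(g, chr, Mb) {
  on <- which(g$map$chr == as.character(chr))
  on[which.min(abs(g$map$Mb[on] - Mb))]
}

qtl_marker_index <- function(g, cfg) {
  vapply(seq_len(nrow(cfg$qtl_spec)), function(i) {
    on <- which(g$map$chr == as.character(cfg$qtl_spec$chr[i]))
    hit <- on[abs(g$map$cM[on] - cfg$qtl_spec$cM[i]) < 1e-9]
    if (length(hit) == 0) config_error("QTL marker not on map (chr %s, %.2f cM)",
                                       cfg$qtl_spec$chr[i], cfg$qtl_spec$cM[i])
    hit[1]
  }, integer(1))
}

#' Simulate replicated animal-level phenotypes
#'
#' Strain values are `baseline + sum(effect * dosage) + strain effect` with
#' the strain effect drawn `N(0, var_strain)`; animals add the configured
#' age trend, and replicate noise `N(0, var_within)`, truncated at zero
#' (counts are non-negative). Outlier strains have their strain effect
#' replaced by an inflated value per `outlier_spec`. Field-level counts
#' (12 fields of 7.49 x 7.49 um) consistent with each animal's per-nerve
#' count are attached so field-based aggregation can be exercised; the
#' recorded `necrotic_count` is the simulated per-nerve value itself.
#'
#' @param g a [geno_matrix()] from [simulate_genotypes()].
#' @param cfg the [sim_config()].
#' @return data.frame of animal records (`strain`, `sex`, `age_months`,
#'   `necrotic_count`, `live_count`, field list-columns) with attributes
#'   `strain_values` and `outliers`.
#' @export
simulate_phenotype <- function(g, cfg) {
  if (cfg$var_strain < 0 || cfg$var_within < 0)
    config_error("variances must be >= 0")
  n <- length(g$strains)
  D <- geno_dosage(g)
  qi <- qtl_marker_index(g, cfg)
  genet <- as.vector(D[, qi, drop = FALSE] %*% cfg$qtl_spec$effect)
  strain_eff <- rnorm(n, 0, sqrt(cfg$var_strain))
  sd_tot <- sqrt(cfg$var_strain + cfg$var_within)
  os <- cfg$outlier_spec
  hi <- lo <- character()
  if ((os$n_high + os$n_low) > 0) {
    picked <- sample.int(n, os$n_high + os$n_low)
    hi_idx <- picked[seq_len(os$n_high)]
    lo_idx <- picked[os$n_high + seq_len(os$n_low)]
    hi <- g$strains[hi_idx]
    lo <- g$strains[lo_idx]
    if (os$n_high > 0)
      strain_eff[hi_idx] <- os$inflation * sd_tot * (1 + 0.25 * abs(rnorm(os$n_high)))
    if (os$n_low > 0)
      strain_eff[lo_idx] <- -os$inflation * sd_tot * (1 + 0.25 * abs(rnorm(os$n_low)))
  }
  strain_val <- cfg$baseline + genet + strain_eff
  reps <- if (length(cfg$replicates) == 1) rep(cfg$replicates, n)
          else sample(cfg$replicates, n, replace = TRUE)
  rows <- vector("list", n)
  field_area <- 7.49^2
  nerve_area <- 1e5
  for (i in seq_len(n)) {
    k <- reps[i]
    age <- runif(k, cfg$age_range[1], cfg$age_range[2])
    sex <- ifelse(runif(k) < cfg$p_female, "F", "M")
    val <- pmax(0, strain_val[i] + cfg$age_slope * (age - 13) +
                  rnorm(k, 0, sqrt(cfg$var_within)))
    val <- round_half_up(val)
    necro_fields <- lapply(val, function(v)
      rpois(12, v / nerve_area * field_area))
    live_fields <- lapply(seq_len(k), function(j)
      rpois(12, 5e4 / nerve_area * field_area))
    rows[[i]] <- data.frame(
      strain = g$strains[i], sex = sex, age_months = age,
      necrotic_count = val,
      live_count = vapply(live_fields, function(f)
        round_half_up(sum(f) / (12 * field_area) * nerve_area), numeric(1)),
      field_area_um2 = field_area, nerve_area_um2 = nerve_area,
      stringsAsFactors = FALSE)
    rows[[i]]$field_counts_necrotic <- I(necro_fields)
    rows[[i]]$field_counts_live <- I(live_fields)
  }
  out <- do.call(rbind, rows)
  attr(out, "strain_values") <- setNames(strain_val, g$strains)
  attr(out, "outliers") <- list(high = hi, low = lo)
  out
}

#' Simulate expression datasets with planted cis-eQTLs and a trait module
#'
#' Builds two tissues (retina and eye) over the same synthetic gene catalog:
#' `n_interval_genes` genes placed inside the configured QTL interval
#' (the first of which, located at the planted QTL itself, is the causal
#' gene), the rest scattered across the genome. Planted cis genes receive
#' `cis_effect * dosage` at the marker nearest their own position; module
#' genes are correlated with the trait's strain means at
#' `module_correlation`; everything gets independent noise per tissue.
#' Annotations include probes (one per gene, a SNP-overlap flag on a random
#' fraction, plus a second, SNP-contaminated probe for the causal gene),
#' variants (nonsynonymous SNP + indel on the causal gene; random classes
#' elsewhere) and a small GO cellular-component vocabulary whose
#' "mitochondrion-like" leaf covers the trait module and the causal gene.
#'
#' @param g a [geno_matrix()].
#' @param cfg the [sim_config()].
#' @param trait the strain-level [trait_table()] the module tracks.
#' @return list: `tissues` (named list of [expression_dataset()]),
#'   `annotations` ([annotation_tables()]), `truth` (causal gene, cis gene
#'   ids, module gene ids).
#' @export
simulate_expression <- function(g, cfg, trait) {
  es <- cfg$expression_spec
  if (es$n_module_genes + es$n_interval_genes > es$n_genes)
    config_error("module size exceeds n_genes")
  n_genes <- es$n_genes
  qchr <- as.character(cfg$qtl_spec$chr[1])
  qMb <- cfg$qtl_spec$cM[1] * cfg$cM_to_Mb
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  symbol <- sprintf("Gene%05d", seq_len(n_genes))
  chr_len_Mb <- setNames(cfg$chromosomes$length_cM * cfg$cM_to_Mb,
                         as.character(cfg$chromosomes$label))
  chr <- sample(names(chr_len_Mb), n_genes, replace = TRUE,
                prob = chr_len_Mb / sum(chr_len_Mb))
  Mb <- runif(n_genes, 0, chr_len_Mb[chr])
  ivl <- seq_len(es$n_interval_genes)
  chr[ivl] <- qchr
  Mb[ivl] <- sort(runif(es$n_interval_genes, es$interval_Mb[1], es$interval_Mb[2]))
  # keep background genes out of the interval so its census equals the
  # planted count
  clash <- which(chr == qchr & seq_len(n_genes) > es$n_interval_genes &
                   Mb >= es$interval_Mb[1] & Mb <= es$interval_Mb[2])
  while (length(clash) > 0) {
    Mb[clash] <- runif(length(clash), 0, chr_len_Mb[qchr])
    clash <- clash[Mb[clash] >= es$interval_Mb[1] & Mb[clash] <= es$interval_Mb[2]]
  }
  causal <- gene_id[1]
  Mb[1] <- qMb  # causal gene sits at the planted QTL
  cis_ids <- c(gene_id[seq_len(es$n_cis_interval)],
               gene_id[es$n_interval_genes + seq_len(es$n_cis_outside)])
  pool <- setdiff(seq_len(n_genes), seq_len(es$n_interval_genes + es$n_cis_outside))
  module_idx <- sample(pool, es$n_module_genes)
  module_ids <- gene_id[module_idx]

  strains <- g$strains
  ns <- length(strains)
  ty <- trait$mean[match(strains, trait$strain)]
  z <- as.vector(scale(ty))
  base <- runif(n_genes, es$base_range[1], es$base_range[2])
  base[1] <- runif(1, 8, 10)                       # causal gene well detected
  base[module_idx] <- runif(es$n_module_genes, 7.5, 11)
  base[match(cis_ids, gene_id)] <- pmax(base[match(cis_ids, gene_id)], 7.2)

  make_tissue <- function(tissue) {
    vals <- matrix(rnorm(n_genes * ns, 0, es$noise_sd), n_genes, ns) + base
    for (cid in cis_ids) {
      i <- match(cid, gene_id)
      mk <- nearest_marker(g, chr[i], Mb[i])
      dos <- geno_dosage(g)[, mk]
      dos[is.na(dos)] <- 1
      vals[i, ] <- vals[i, ] + es$cis_effect * dos
    }
    rho <- es$module_correlation
    for (i in module_idx) {
      eps <- rnorm(ns)
      vals[i, ] <- base[i] + es$module_amplitude *
        (rho * z + sqrt(max(0, 1 - rho^2)) * eps)
    }
    rownames(vals) <- paste0(gene_id, "_at")
    colnames(vals) <- strains
    # second probe for the causal gene, contaminated by a SNP under the probe
    extra <- vals[1, , drop = FALSE] + rnorm(ns, 0, 0.2)
    rownames(extra) <- paste0(causal, "_x_at")
    rbind(vals, extra)
  }
  probes <- data.frame(
    probe_id = c(paste0(gene_id, "_at"), paste0(causal, "_x_at")),
    gene_id = c(gene_id, causal),
    snp_overlap = c(runif(n_genes) < es$p_snp_probe, TRUE),
    stringsAsFactors = FALSE)
  probes$snp_overlap[1] <- FALSE  # the causal gene keeps one clean probe

  u <- runif(n_genes)
  vclass <- rep(NA_character_, n_genes)
  acc <- c("nonsynonymous_snp", "indel", "transcript_variant")
  vclass[u < es$p_variant] <- sample(acc, sum(u < es$p_variant), replace = TRUE)
  vclass[u >= es$p_variant & u < es$p_variant + es$p_other_variant] <- "other"
  variants <- data.frame(gene_id = gene_id[!is.na(vclass)],
                         class = vclass[!is.na(vclass)],
                         stringsAsFactors = FALSE)
  variants <- rbind(data.frame(gene_id = causal,
                               class = c("nonsynonymous_snp", "indel")),
                    variants[variants$gene_id != causal, ])

  detected_pool <- gene_id[base >= es$detect_floor]
  avail <- setdiff(detected_pool, c(module_ids, causal))
  axon_genes <- sample(avail, min(80, length(avail)))
  avail <- setdiff(avail, axon_genes)
  nucleus_genes <- sample(avail, min(100, length(avail)))
  mito_genes <- c(causal, module_ids)
  go_terms <- data.frame(
    term_id = c("CC:0000001", "CC:0000002", "CC:0000003",
                "CC:0000010", "CC:0000011", "CC:0000012"),
    name = c("cellular_component", "organelle", "cell_projection",
             "mitochondrion-like", "nucleus-like", "axon-like"),
    parents = c("", "CC:0000001", "CC:0000001",
                "CC:0000002", "CC:0000002", "CC:0000003"),
    genes = c("",
              paste(unique(c(mito_genes, nucleus_genes)), collapse = ","),
              paste(axon_genes, collapse = ","),
              paste(mito_genes, collapse = ","),
              paste(nucleus_genes, collapse = ","),
              paste(axon_genes, collapse = ",")),
    stringsAsFactors = FALSE)

  genes <- data.frame(gene_id = gene_id, symbol = symbol, chr = chr, Mb = Mb,
                      stringsAsFactors = FALSE)
  ann <- annotation_tables(genes, probes, variants, go_terms)
  tissues <- list(
    retina = expression_dataset(make_tissue("retina"), probes, "retina"),
    eye = expression_dataset(make_tissue("eye"), probes, "eye"))
  list(tissues = tissues, annotations = ann,
       truth = list(causal_gene = causal, cis_genes = cis_ids,
                    module_genes = module_ids,
                    interval_genes = gene_id[ivl]))
}

#' Generate a complete synthetic panel fixture
#'
#' Runs [simulate_genotypes()], [simulate_phenotype()] and
#' [simulate_expression()] under the configured seed and bundles the results
#' with the ground truth (planted QTL, causal gene, cis/module gene sets,
#' injected outlier strains). Deterministic: the same config yields an
#' identical fixture.
#'
#' @param cfg a [sim_config()].
#' @return list of class `panel_fixture`: `genotypes`, `animals`, `trait`
#'   (strain-level [trait_table()]), `trait2` (IOP-like second trait),
#'   `expression` (named tissue list), `annotations`, `truth`, `config`.
#' @export
make_fixture <- function(cfg) {
  set.seed(cfg$seed)
  g <- simulate_genotypes(cfg)
  animals <- simulate_phenotype(g, cfg)
  trait <- strain_summary(animals)
  expr <- simulate_expression(g, cfg, trait)
  z <- as.vector(scale(trait$mean))
  rho <- cfg$trait2_correlation
  iop <- 15 + 2 * (rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(nrow(trait)))
  trait2 <- trait_table(trait$strain, iop,
                        sem = rep(0.5, nrow(trait)), n = rep(5L, nrow(trait)))
  qtl <- cfg$qtl_spec
  qtl$Mb <- qtl$cM * cfg$cM_to_Mb
  truth <- c(expr$truth,
             list(qtl = qtl,
                  outliers = attr(animals, "outliers"),
                  strain_values = attr(animals, "strain_values"),
                  interval = list(chr = as.character(qtl$chr[1]),
                                  Mb_lo = cfg$expression_spec$interval_Mb[1],
                                  Mb_hi = cfg$expression_spec$interval_Mb[2])))
  structure(list(genotypes = g, animals = animals, trait = trait,
                 trait2 = trait2, expression = expr$tissues,
                 annotations = expr$annotations, truth = truth, config = cfg),
            class = "panel_fixture")
}

#' Write a panel fixture to disk
#'
#' Emits `panel.geno`, `animals.tsv` (scalar columns only), `trait.tsv`,
#' `trait2.tsv`, one expression TSV per tissue, the annotation TSVs and
#' `truth.json`.
#'
#' @param fix a [make_fixture()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geno(fix$genotypes, file.path(dir, "panel.geno"))
  scalars <- c("strain", "sex", "age_months", "necrotic_count", "live_count",
               "field_area_um2", "nerve_area_um2")
  write.table(fix$animals[, scalars], file.path(dir, "animals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_trait_table(fix$trait, file.path(dir, "trait.tsv"))
  write_trait_table(fix$trait2, file.path(dir, "trait2.tsv"))
  for (tis in names(fix$expression))
    write_expression_matrix(fix$expression[[tis]],
                            file.path(dir, sprintf("expression_%s.tsv", tis)))
  write_annotation_tables(fix$annotations, file.path(dir, "annotations"))
  truth <- fix$truth
  truth$strain_values <- as.list(truth$strain_values)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
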