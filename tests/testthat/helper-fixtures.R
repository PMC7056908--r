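# Small simulation configs used across the suite. Sizes are chosen so the
# whole suite runs in minutes while keeping the statistical structure of the
# full panel.

# compact 3-chromosome panel, no outliers, no age/sex structure
quiet_cfg <- function(seed, n_strains = 40, effect = 1, var_strain = 1,
                      var_within = 0.5, replicates = 4, n_genes = 300, ...) {
  sim_config(
    n_strains = n_strains,
    chromosomes = data.frame(label = c("1", "2", "3"), length_cM = 50,
                             spacing_cM = 5),
    qtl_spec = data.frame(chr = "2", cM = 25, effect = effect),
    baseline = 20, var_strain = var_strain, var_within = var_within,
    replicates = replicates, age_slope = 0,
    outlier_spec = list(n_high = 0, n_low = 0, inflation = 0),
    expression_spec = list(
      n_genes = n_genes, n_interval_genes = 20, interval_Mb = c(45, 55),
      n_cis_interval = 5, n_cis_outside = 5, cis_effect = 0.6,
      n_module_genes = 15, module_correlation = 0.8, module_amplitude = 0.5,
      noise_sd = 0.2, base_range = c(5, 12), detect_floor = 6.8,
      p_snp_probe = 0.1, p_variant = 0.3, p_other_variant = 0.2),
    seed = seed, ...)
}

# literal toy genotype object built by hand
toy_geno <- function() {
  calls <- rbind(S1 = c("B", "B", "D", "D"),
                 S2 = c("D", "D", "B", "B"),
                 S3 = c("B", "D", "D", "B"),
                 S4 = c("D", "B", "B", "D"))
  map <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                    chr = c("1", "1", "2", "2"),
                    cM = c(0, 10, 0, 10), Mb = c(0, 20, 0, 20),
                    stringsAsFactors = FALSE)
  geno_matrix(calls, map)
}

# annotation bundle with a 3-level GO chain for terminal-branch tests
toy_annotations <- function() {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      symbol = sprintf("Sym%02d", 1:10),
                      chr = "1", Mb = seq(10, 100, by = 10),
                      stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = paste0(genes$gene_id, "_at"),
                       gene_id = genes$gene_id, snp_overlap = FALSE,
                       stringsAsFactors = FALSE)
  variants <- data.frame(gene_id = c("g01", "g02"),
                         class = c("nonsynonymous_snp", "other"),
                         stringsAsFactors = FALSE)
  go <- data.frame(
    term_id = c("T:root", "T:mid", "T:leaf", "T:other"),
    name = c("cellular_component", "organelle", "mitochondrion", "membrane"),
    parents = c("", "T:root", "T:mid", "T:root"),
    genes = c("", "g01,g02,g03,g04,g05", "g01,g02,g03,g04,g05",
              "g06,g07,g08,g09,g10"),
    stringsAsFactors = FALSE)
  annotation_tables(genes, probes, variants, go)
}
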