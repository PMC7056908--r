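#' Run the full mapping-and-triage pipeline
#'
#' Orchestrates every stage on either a synthetic panel (config with a
#' `simulate` block of [sim_config()] arguments) or a directory of exported
#' files (config with an `inputs` block naming `geno`, `trait`, expression
#' and annotation paths): strain aggregation, outlier handling and
#' winsorization, heritability, Haley-Knott scan, permutation thresholds,
#' LOCO mixed-model scan, support interval, per-tissue eQTL tables,
#' the seven-criterion triage cascade with GO network flags, and (when a
#' second trait is available) cross-trait correlation and shared-correlate
#' comparison. All stage tables, a run manifest (config snapshot, seeds,
#' file digests, per-stage row counts and durations) and a human-readable
#' summary are written to `out_dir`.
#'
#' @param config a list or path to a YAML file. Recognized blocks:
#'   `simulate` (passed to [sim_config()]), `inputs` (file paths:
#'   `geno`, `animals`, `trait`, `trait2`, `expression` named per tissue,
#'   `annotations` directory), `mapping` (`step_cM`, `n_perm`, `n_boot`),
#'   `triage` ([triage_config()] arguments; `interval` defaults to the
#'   computed support interval), and a top-level `seed`.
#' @param out_dir output directory (created).
#' @return list of all stage results, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed
  if (is.null(seed)) config_error("config key 'seed' is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = seed,
                   version = as.character(utils::packageVersion("riqtl")),
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      riqtl_stop(class(e)[1], "stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      rows = if (is.data.frame(val)) nrow(val) else NA)
    val
  }

  if (!is.null(config$simulate)) {
    cfg <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      do.call(sim_config, args)
    })
    fix <- stage("fixture", make_fixture(cfg))
    g <- fix$genotypes; animals <- fix$animals
    trait_raw <- fix$trait; trait2 <- fix$trait2
    tissues <- fix$expression; ann <- fix$annotations
    results$truth <- fix$truth
  } else if (!is.null(config$inputs)) {
    ip <- config$inputs
    for (key in c("geno", "trait", "annotations"))
      if (is.null(ip[[key]])) config_error("config key 'inputs.%s' is required", key)
    g <- stage("read_geno", read_geno(ip$geno))
    trait_raw <- stage("read_trait", read_trait_table(ip$trait))
    trait2 <- if (!is.null(ip$trait2)) read_trait_table(ip$trait2)
    ann <- stage("read_annotations", read_annotation_tables(ip$annotations))
    animals <- NULL
    tissues <- list()
    for (tis in names(ip$expression %||% list()))
      tissues[[tis]] <- read_expression_matrix(ip$expression[[tis]], ann,
                                               strain_order = g$strains,
                                               tissue = tis)
  } else config_error("config needs a 'simulate' or 'inputs' block")

  mp <- config$mapping %||% list()
  step_cM <- mp$step_cM %||% 1
  n_perm <- mp$n_perm %||% 1000

  if (!is.null(animals)) {
    results$heritability <- stage("heritability", heritability(animals))
    results$sex <- tryCatch(sex_compare(animals), riqtl_data_error = function(e) NULL)
    results$age <- tryCatch(age_regression(animals), riqtl_data_error = function(e) NULL)
  } else if (isTRUE(attr(trait_raw, "has_sem")) && isTRUE(attr(trait_raw, "has_n"))) {
    results$heritability <- stage("heritability", heritability(trait_raw))
  }

  out_flags <- stage("detect_outliers", {
    fl <- detect_outliers(trait_raw)
    data.frame(strain = c(fl$high, fl$low),
               side = rep(c("high", "low"), c(length(fl$high), length(fl$low))),
               stringsAsFactors = FALSE)
  })
  high <- out_flags$strain[out_flags$side == "high"]
  low <- out_flags$strain[out_flags$side == "low"]
  trait <- stage("winsorize", winsorize(trait_raw, high, low))
  write_trait_table(trait, file.path(out_dir, "trait_winsorized.tsv"))

  scan_hk <- stage("hk_scan", hk_scan(g, trait, step_cM = step_cM))
  write_scan(scan_hk, file.path(out_dir, "scan_hk.tsv"))
  thr <- stage("permutation_thresholds",
               permutation_thresholds(g, trait, n_perm = n_perm,
                                      seed = seed + 1L, step_cM = step_cM))
  scan_lmm <- stage("lmm_scan", lmm_scan(g, trait, loco = TRUE))
  write_scan(scan_lmm, file.path(out_dir, "scan_lmm.tsv"))
  si <- stage("support_interval", {
    as.data.frame(support_interval(scan_hk))
  })
  results$robustness <- stage("robustness",
                              robustness_suite(g, trait_raw, high, low,
                                               step_cM = step_cM))
  results$scan_hk <- scan_hk; results$scan_lmm <- scan_lmm
  results$thresholds <- thr; results$support_interval <- si
  results$outliers <- out_flags; results$trait <- trait

  tri <- config$triage %||% list()
  interval <- tri$interval %||% list(chr = si$chr, Mb_lo = si$Mb_lo,
                                     Mb_hi = si$Mb_hi)
  tcfg <- triage_config(
    interval = interval,
    top_n_correlates = tri$top_n_correlates %||% 1000,
    detection_threshold = tri$detection_threshold %||% 6.8,
    cis_window_Mb = tri$cis_window_Mb %||% 5,
    network_keywords = tri$network_keywords %||% "mitochondri|axon|cytoskelet",
    comparison_top_n = tri$comparison_top_n %||% 2000)

  if (length(tissues) > 0) {
    eqtls <- list(); correlates <- list()
    for (tis in names(tissues)) {
      eqtls[[tis]] <- stage(paste0("eqtl_", tis),
                            eqtl_table(tissues[[tis]], g, ann,
                                       detect_threshold = tcfg$detection_threshold,
                                       window_Mb = tcfg$cis_window_Mb,
                                       min_lrs = thr$suggestive_lrs))
      write.table(eqtls[[tis]],
                  file.path(out_dir, sprintf("eqtl_%s.tsv", tis)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      correlates[[tis]] <- stage(paste0("correlates_", tis),
                                 trait_correlates(trait, tissues[[tis]],
                                                  n_top = tcfg$top_n_correlates))
    }
    ig <- stage("genes_in_interval", genes_in_interval(ann, tcfg$interval))
    nf <- stage("network_flags", {
      fl <- network_flags(ig$gene_id, tissues, ann,
                          keywords = tcfg$network_keywords,
                          n_top = tcfg$top_n_correlates,
                          detect = tcfg$detection_threshold)
      data.frame(gene_id = names(fl), flag = unname(fl))
    })
    flags <- setNames(nf$flag, nf$gene_id)
    cand <- stage("triage", triage(tcfg, ig, eqtls, correlates,
                                   ann$variants, flags))
    write.table(cand, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$eqtl <- eqtls; results$correlates <- correlates
    results$interval_genes <- ig; results$candidates <- cand

    if (!is.null(trait2)) {
      results$trait2_correlation <- stage("trait_correlation",
                                          as.data.frame(trait_correlation(trait, trait2)))
      tis2 <- if (length(tissues) > 1) names(tissues)[2] else names(tissues)[1]
      sc <- stage("shared_correlates",
                  with(shared_correlates(trait, trait2,
                                         tissues[[1]], tissues[[tis2]],
                                         n_top = tcfg$comparison_top_n,
                                         detect = tcfg$detection_threshold),
                       data.frame(countA_detected = countA_detected,
                                  countB_detected = countB_detected,
                                  shared_count = shared_count)))
      results$shared_correlates <- sc
    }
  }

  manifest$digests <- as.list(md5sum(list.files(out_dir, full.names = TRUE,
                                                pattern = "\\.tsv$")))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(report(results), file.path(out_dir, "summary.txt"))
  invisible(results)
}

#' Human-readable pipeline summary
#'
#' Renders the peak table, thresholds, heritability, the tier-1 candidate
#' list and the cross-trait comparison as text lines.
#'
#' @param results the list returned by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
report <- function(results) {
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  if (!is.null(results$heritability)) {
    h <- results$heritability
    add("heritability: h2 conventional = %.1f%%, h2 RI strain-mean = %.1f%% (n_eff %.2f)",
        100 * h$h2_conventional, 100 * h$h2_rix, h$n_eff)
  }
  if (!is.null(results$scan_hk)) {
    for (nm in c("scan_hk", "scan_lmm")) {
      sc <- results[[nm]]
      pk <- which.max(sc$lrs)
      add("%s peak: chr %s at %.2f Mb, LRS %.2f (LOD %.2f), additive %+.4g/allele",
          nm, sc$chr[pk], sc$Mb[pk], sc$lrs[pk], sc$lod[pk], sc$additive[pk])
    }
    add("thresholds: significant LRS %.2f, suggestive %.2f (%d permutations)",
        results$thresholds$significant_lrs, results$thresholds$suggestive_lrs,
        results$thresholds$n_perm)
    si <- results$support_interval
    add("support interval: chr %s [%.2f, %.2f] Mb", si$chr, si$Mb_lo, si$Mb_hi)
  }
  if (!is.null(results$candidates)) {
    t1 <- results$candidates$symbol[results$candidates$tier == "1"]
    add("positional candidates: %d in interval, %d tier-1, %d tier-2",
        nrow(results$candidates), sum(results$candidates$tier == "1"),
        sum(results$candidates$tier == "2"))
    if (length(t1) > 0) add("tier-1: %s", paste(t1, collapse = ", "))
    else add("no tier-1 candidates")
  }
  if (!is.null(results$trait2_correlation))
    add("cross-trait correlation: r = %.3f (p = %.3g, n = %d)",
        results$trait2_correlation$r, results$trait2_correlation$p,
        results$trait2_correlation$n)
  if (!is.null(results$shared_correlates))
    add("shared correlates: %d vs %d detected, %d shared",
        results$shared_correlates$countA_detected,
        results$shared_correlates$countB_detected,
        results$shared_correlates$shared_count)
  lines
}
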