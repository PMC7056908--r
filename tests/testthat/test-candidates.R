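test_that("interval gene lookup uses closed boundaries", {
  ann <- toy_annotations()
  iv <- list(chr = "1", Mb_lo = 10, Mb_hi = 40)
  got <- genes_in_interval(ann, iv)
  expect_setequal(got$gene_id, c("g01", "g02", "g03", "g04"))  # 10 and 40 in
  iv2 <- list(chr = "1", Mb_lo = 40.1, Mb_hi = 49.9)
  expect_equal(nrow(genes_in_interval(ann, iv2)), 0)
  expect_error(genes_in_interval(list(genes = ann$genes[0, ]), iv),
               class = "riqtl_data_error")
})

test_that("trait correlates rank by |r| with deterministic ties", {
  strains <- sprintf("S%d", 1:5)
  y <- c(1, 2, 3, 4, 5)
  v <- rbind(self_at = y, anti_at = -y, noise_at = c(2, 1, 5, 3, 2),
             flat_at = rep(1, 5))
  colnames(v) <- strains
  probes <- data.frame(probe_id = rownames(v),
                       gene_id = sub("_at", "", rownames(v)),
                       snp_overlap = FALSE)
  e <- expression_dataset(v, probes)
  tt <- trait_table(strains, y)
  tc <- trait_correlates(tt, e, n_top = 2)
  expect_equal(tc$probe_id[1:2], c("anti_at", "self_at"))  # |r| = 1, tie by id
  expect_equal(abs(tc$r[1:2]), c(1, 1))
  expect_equal(attr(tc, "n_excluded"), 1)                  # flat probe dropped
  expect_false("flat_at" %in% tc$probe_id)
  # closed-form Pearson oracle for the noisy probe
  x <- c(2, 1, 5, 3, 2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tc$r[tc$probe_id == "noise_at"], r_hand, tolerance = 1e-12)
})

test_that("variant criterion accepts the three damaging classes only", {
  variants <- data.frame(gene_id = c("a", "b", "b", "c", "d"),
                         class = c("nonsynonymous_snp", "other", "synonymous",
                                   "indel", "transcript_variant"))
  expect_true(gene_variants("a", variants)$flag)
  expect_false(gene_variants("b", variants)$flag)
  expect_true(gene_variants("c", variants)$flag)
  expect_true(gene_variants("d", variants)$flag)
  expect_false(gene_variants("absent", variants)$flag)
})

# build a fully controlled triage input for one gene per criterion pattern
triage_toy <- function(fail = NULL) {
  genes <- data.frame(gene_id = "g1", symbol = "Sym1", chr = "12", Mb = 110)
  eq <- data.frame(probe_id = "g1_at", gene_id = "g1", peak_chr = "12",
                   peak_Mb = 110.5, peak_cM = 55, peak_lrs = 25,
                   detected = TRUE, eligible = TRUE, is_cis = TRUE)
  tc <- data.frame(probe_id = "g1_at", gene_id = "g1", r = 0.8, rank = 5,
                   in_top = TRUE)
  variants <- data.frame(gene_id = "g1", class = "indel")
  flags <- c(g1 = TRUE)
  if ("c2" %in% fail) eq$is_cis <- FALSE
  if ("c3" %in% fail) { tc$rank <- 5000; tc$in_top <- FALSE }
  if ("c4" %in% fail) eq$detected <- FALSE
  if ("c5" %in% fail) eq$eligible <- FALSE
  if ("c6" %in% fail) variants$class <- "other"
  if ("c7" %in% fail) flags["g1"] <- FALSE
  cfg <- triage_config(interval = list(chr = "12", Mb_lo = 109, Mb_hi = 112.5))
  triage(cfg, genes, list(retina = eq), list(retina = tc), variants, flags)
}

test_that("triage tiers follow the all/all-but-one rule", {
  expect_equal(triage_toy()$tier, "1")
  # the second-tier pattern: all criteria except trait correlation
  t2 <- triage_toy(fail = "c3")
  expect_equal(t2$tier, "2")
  expect_false(t2$c3)
  expect_match(t2$provenance, "c3")
  expect_equal(triage_toy(fail = c("c3", "c6"))$tier, "excluded")
})

test_that("relaxed mode waives only the cis criterion", {
  t <- triage_toy(fail = "c2")
  expect_equal(t$tier, "2")
  expect_true(t$relaxed_pass)
  t2 <- triage_toy(fail = c("c2", "c6"))
  expect_false(t2$relaxed_pass)
})

test_that("triage is monotone: satisfying a criterion never demotes", {
  tiers <- c("1" = 3, "2" = 2, "excluded" = 1)
  for (f in c("c2", "c3", "c4", "c5", "c6", "c7")) {
    for (extra in c("c4", "c6")) {
      worse <- triage_toy(fail = union(f, extra))
      better <- triage_toy(fail = setdiff(union(f, extra), f))
      expect_gte(tiers[[better$tier]], tiers[[worse$tier]])
    }
  }
})

test_that("genes absent from an input fail that criterion with provenance", {
  genes <- data.frame(gene_id = c("g1", "g2"), symbol = c("S1", "S2"),
                      chr = "12", Mb = c(110, 111))
  eq <- data.frame(probe_id = "g1_at", gene_id = "g1", peak_chr = "12",
                   peak_Mb = 110.5, peak_cM = 55, peak_lrs = 25,
                   detected = TRUE, eligible = TRUE, is_cis = TRUE)
  tc <- data.frame(probe_id = "g1_at", gene_id = "g1", r = 0.8, rank = 1,
                   in_top = TRUE)
  cfg <- triage_config(interval = list(chr = "12", Mb_lo = 109, Mb_hi = 112.5))
  out <- triage(cfg, genes, list(retina = eq), list(retina = tc),
                data.frame(gene_id = "g1", class = "indel"), c(g1 = TRUE))
  g2 <- out[out$gene_id == "g2", ]
  expect_equal(g2$tier, "excluded")
  expect_match(g2$provenance, "c2")
  expect_match(g2$provenance, "c5")
})

test_that("a gene passes probe criteria through any clean probe", {
  genes <- data.frame(gene_id = "g1", symbol = "S1", chr = "12", Mb = 110)
  # dirty probe is cis+detected, clean probe is not cis but detected
  eq <- data.frame(probe_id = c("g1_a", "g1_b"), gene_id = "g1",
                   peak_chr = c("12", "3"), peak_Mb = c(110.5, 50),
                   peak_cM = c(55, 25), peak_lrs = c(30, 12),
                   detected = c(TRUE, TRUE), eligible = c(FALSE, TRUE),
                   is_cis = c(TRUE, FALSE))
  tc <- data.frame(probe_id = c("g1_a", "g1_b"), gene_id = "g1",
                   r = c(0.9, 0.5), rank = c(1, 900), in_top = c(TRUE, TRUE))
  cfg <- triage_config(interval = list(chr = "12", Mb_lo = 109, Mb_hi = 112.5))
  out <- triage(cfg, genes, list(retina = eq), list(retina = tc),
                data.frame(gene_id = "g1", class = "indel"), c(g1 = TRUE))
  expect_false(out$c2)   # only the SNP-contaminated probe is cis
  expect_true(out$c3)    # the clean probe ranks inside the cutoff
  expect_true(out$c5)
})

test_that("tissue-specific criteria are satisfied by either tissue", {
  genes <- data.frame(gene_id = "g1", symbol = "S1", chr = "12", Mb = 110)
  eq_ret <- data.frame(probe_id = "g1_at", gene_id = "g1", peak_chr = "3",
                       peak_Mb = 20, peak_cM = 10, peak_lrs = 12,
                       detected = FALSE, eligible = TRUE, is_cis = FALSE)
  eq_eye <- data.frame(probe_id = "g1_at", gene_id = "g1", peak_chr = "12",
                       peak_Mb = 110.2, peak_cM = 55, peak_lrs = 28,
                       detected = TRUE, eligible = TRUE, is_cis = TRUE)
  tc_ret <- data.frame(probe_id = "g1_at", gene_id = "g1", r = 0.1,
                       rank = 4000, in_top = FALSE)
  tc_eye <- data.frame(probe_id = "g1_at", gene_id = "g1", r = 0.9, rank = 2,
                       in_top = TRUE)
  cfg <- triage_config(interval = list(chr = "12", Mb_lo = 109, Mb_hi = 112.5))
  out <- triage(cfg, genes, list(retina = eq_ret, eye = eq_eye),
                list(retina = tc_ret, eye = tc_eye),
                data.frame(gene_id = "g1", class = "indel"), c(g1 = TRUE))
  expect_true(all(unlist(out[, c("c2", "c3", "c4", "c5")])))
  expect_equal(out$tier, "1")
})

test_that("triage output is invariant to input row order", {
  fix <- make_fixture(quiet_cfg(seed = 211, n_genes = 150))
  ig <- genes_in_interval(fix$annotations, fix$truth$interval)
  et <- suppressWarnings(eqtl_table(fix$expression$retina, fix$genotypes,
                                    fix$annotations, min_lrs = 10))
  tc <- trait_correlates(fix$trait, fix$expression$retina, n_top = 50)
  cfg <- triage_config(interval = fix$truth$interval, top_n_correlates = 50)
  flags <- setNames(rep(TRUE, nrow(ig)), ig$gene_id)
  o1 <- triage(cfg, ig, list(retina = et), list(retina = tc),
               fix$annotations$variants, flags)
  set.seed(1)
  o2 <- triage(cfg, ig, list(retina = et[sample(nrow(et)), ]),
               list(retina = tc[sample(nrow(tc)), ]),
               fix$annotations$variants[sample(nrow(fix$annotations$variants)), ],
               flags)
  expect_equal(o1[order(o1$gene_id), ], o2[order(o2$gene_id), ],
               ignore_attr = TRUE)
})

test_that("cross-trait correlation matches the t-transform oracle", {
  tt <- trait_table(sprintf("s%d", 1:8), c(3, 1, 4, 1, 5, 9, 2, 6))
  self <- trait_correlation(tt, tt)
  expect_equal(self$r, 1)
  neg <- trait_table(tt$strain, -tt$mean)
  expect_equal(trait_correlation(tt, neg)$r, -1)

  other <- trait_table(sprintf("s%d", 1:8), c(2, 7, 1, 8, 2, 8, 1, 8))
  got <- trait_correlation(tt, other)
  r <- cor(tt$mean, other$mean)
  tstat <- r * sqrt(6) / sqrt(1 - r^2)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tstat), 6), tolerance = 1e-12)
  expect_equal(got$n, 8)
  expect_error(trait_correlation(tt, trait_table("s1", 1)),
               class = "riqtl_data_error")
})

test_that("a trait shares all detected correlates with itself", {
  fix <- make_fixture(quiet_cfg(seed = 221, n_genes = 100))
  e <- fix$expression$retina
  sc <- shared_correlates(fix$trait, fix$trait, e, e, n_top = 50)
  expect_equal(sc$countA_detected, sc$countB_detected)
  expect_equal(sc$shared_count, sc$countA_detected)
})

test_that("independent traits overlap near the hypergeometric null", {
  fix <- make_fixture(quiet_cfg(seed = 231, n_genes = 400))
  set.seed(99)
  rnd <- trait_table(fix$trait$strain, rnorm(nrow(fix$trait)))
  e <- fix$expression$retina
  sc <- shared_correlates(fix$trait, rnd, e, e, n_top = 100)
  # null overlap of two detection-filtered lists from the same platform
  n_detected <- sum(detection_filter(e))
  m <- sc$countA_detected; k <- sc$countB_detected
  lohi <- qhyper(c(0.005, 0.995), m, n_detected - m, k)
  expect_gte(sc$shared_count, lohi[1])
  # allow extra overlap from the correlated module but not wholesale identity
  expect_lt(sc$shared_count, min(m, k))
})
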