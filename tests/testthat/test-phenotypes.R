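test_that("nerve counts extrapolate sampled density to the nerve area", {
  rec <- list(field_counts_live = rep(40, 12),
              field_counts_necrotic = rep(5, 12),
              field_area_um2 = 56.1, nerve_area_um2 = 12 * 56.1)
  nc <- nerve_counts(rec)
  expect_equal(nc$necrotic_per_nerve, 60)      # nerve area equals sampled area
  expect_equal(nc$live_per_nerve, 480)

  rec$field_counts_necrotic <- rep(0, 12)
  nc0 <- nerve_counts(rec)
  expect_equal(nc0$necrotic_per_nerve, 0)
  expect_equal(nc0$necrotic_density_per_um2, 0)

  # direct arithmetic oracle: 78 counts over 12 x 56.1 um2, 10,000 um2 nerve
  rec$field_counts_necrotic <- 1:12
  rec$nerve_area_um2 <- 10000
  expect_equal(nerve_counts(rec)$necrotic_per_nerve,
               floor(sum(1:12) / (12 * 56.1) * 10000 + 0.5))
  expect_equal(nerve_counts(rec)$necrotic_per_nerve, 1159)

  rec$field_counts_necrotic <- numeric(0)
  expect_error(nerve_counts(rec), class = "riqtl_data_error")
})

test_that("strain summaries carry mean, SEM and replicate count", {
  an <- data.frame(strain = c("A", "B", "B", "C", "C"),
                   necrotic_count = c(5, 4, 6, 7, 7))
  tt <- strain_summary(an)
  expect_equal(tt$mean, c(5, 5, 7))
  expect_true(is.na(tt$sem[1]))              # single animal: SEM absent
  expect_equal(tt$sem[2], sd(c(4, 6)) / sqrt(2))
  expect_equal(tt$sem[3], 0)                 # two equal values
  expect_equal(tt$n, c(1L, 2L, 2L))
  expect_error(strain_summary(an[0, ]), class = "riqtl_data_error")
})

test_that("winsorization reproduces the published worked examples", {
  # four aged-panel strains winsorized against retained extremes 3,733 / 617
  tt <- trait_table(c("BXD102", "BXD56", "BXD29", "BXD71", "K1", "K2", "K3"),
                    c(5825, 5552, 4121, 376, 3733, 617, 2000))
  w <- winsorize(tt, high_outliers = c("BXD102", "BXD56", "BXD29"),
                 low_outliers = "BXD71")
  expect_equal(w$mean[w$strain == "BXD29"], 3734)
  expect_equal(w$mean[w$strain == "BXD56"], 3735)
  expect_equal(w$mean[w$strain == "BXD102"], 3736)
  expect_equal(w$mean[w$strain == "BXD71"], 616)
  # untouched strains bit-identical
  expect_identical(w$mean[5:7], tt$mean[5:7])
})

test_that("winsorization applies unit rank steps and preserves order", {
  tt <- trait_table(c("a", "b", "c", "d"), c(1, 2, 3, 100))
  w <- winsorize(tt, high_outliers = "d")
  expect_equal(w$mean, c(1, 2, 3, 4))
  expect_error(winsorize(tt, high_outliers = "d", low_outliers = "d"),
               class = "riqtl_config_error")
  expect_error(winsorize(tt, high_outliers = "zz"), class = "riqtl_data_error")

  # property: flagging the distribution's extremes preserves every rank and
  # leaves non-flagged values bit-identical
  set.seed(17)
  for (i in 1:20) {
    vals <- rnorm(15)
    tt <- trait_table(sprintf("s%02d", 1:15), vals)
    hi <- tt$strain[order(vals, decreasing = TRUE)[1:2]]
    lo <- tt$strain[order(vals)[1:2]]
    w <- winsorize(tt, hi, lo)
    expect_identical(order(w$mean), order(tt$mean))
    keep <- !(tt$strain %in% c(hi, lo))
    expect_identical(w$mean[keep], tt$mean[keep])
  }
})

test_that("Tukey fences flag extreme strains", {
  tt <- trait_table(sprintf("s%02d", 1:12), c(seq(-1, 1, length.out = 11), 0))
  fl <- detect_outliers(tt)
  expect_length(fl$high, 0)
  expect_length(fl$low, 0)
  tt2 <- trait_table(sprintf("s%02d", 1:12),
                     c(seq(-1, 1, length.out = 11), 25))
  expect_equal(detect_outliers(tt2)$high, "s12")
  expect_error(detect_outliers(trait_table(c("a", "b"), c(1, 2))),
               class = "riqtl_data_error")
})

test_that("injected outlier strains are recovered by the automatic fences", {
  # scenario design: outliers inflated to ~6 panel SDs and fences at 2.5 IQR,
  # so planted outliers sit far beyond the fence while the Gaussian strain
  # effects stay inside it; the flagged set should equal the injected set
  hits <- 0L
  for (s in 1:20) {
    cfg <- quiet_cfg(seed = 600 + s, n_strains = 50, effect = 0.5,
                     replicates = 4)
    cfg$outlier_spec <- list(n_high = 2, n_low = 1, inflation = 6)
    fix <- make_fixture(cfg)
    fl <- detect_outliers(fix$trait, k_iqr = 2.5)
    ok <- setequal(fl$high, fix$truth$outliers$high) &&
      setequal(fl$low, fix$truth$outliers$low)
    hits <- hits + ok
  }
  expect_gte(hits, 19)
})

test_that("heritability matches an explicit sums-of-squares oracle", {
  # balanced toy: 3 strains x 2 replicates with +/-0.1 within noise
  an <- data.frame(strain = rep(c("a", "b", "c"), each = 2),
                   necrotic_count = c(0.9, 1.1, 1.9, 2.1, 2.9, 3.1))
  h <- heritability(an)
  # hand ANOVA: MSB = 2 * var(strain means), MSW = pooled within
  msb <- 2 * var(c(1, 2, 3))
  msw <- sum((an$necrotic_count - rep(c(1, 2, 3), each = 2))^2) / 3
  va <- (msb - msw) / 2
  expect_equal(h$Ve, msw, tolerance = 1e-9)
  expect_equal(h$Va, va, tolerance = 1e-9)
  expect_equal(h$h2_conventional, va / (va + msw), tolerance = 1e-9)
  expect_equal(h$h2_rix, va / (va + msw / 2), tolerance = 1e-9)
  expect_gte(h$h2_rix, h$h2_conventional)
})

test_that("heritability handles degenerate variance structures", {
  an <- data.frame(strain = rep(c("a", "b"), each = 3),
                   necrotic_count = rep(c(1, 5), each = 3))
  h <- heritability(an)
  expect_equal(h$Ve, 0)
  expect_equal(h$h2_conventional, 1)
  expect_equal(h$h2_rix, 1)

  set.seed(2)
  an2 <- data.frame(strain = rep(sprintf("s%02d", 1:10), each = 40),
                    necrotic_count = rnorm(400))
  h2 <- heritability(an2)
  expect_lt(h2$h2_conventional, 0.2)  # Va clamps near 0 under the null

  an3 <- data.frame(strain = c("a", "b"), necrotic_count = c(1, 2))
  expect_error(heritability(an3), class = "riqtl_data_error")
})

test_that("summary-path heritability reconstructs the replicate-path answer", {
  set.seed(33)
  an <- data.frame(strain = rep(sprintf("s%02d", 1:12), times = rep(2:5, 3)),
                   necrotic_count = rnorm(sum(rep(2:5, 3)), 10, 2))
  tt <- strain_summary(an)
  h1 <- heritability(an)
  h2 <- heritability(tt)
  expect_equal(h2$Va, h1$Va, tolerance = 1e-9)
  expect_equal(h2$Ve, h1$Ve, tolerance = 1e-9)
  expect_equal(h2$h2_rix, h1$h2_rix, tolerance = 1e-9)
})

test_that("heritability recovers the generator plug-in truth on fixtures", {
  est <- replicate(25, NA_real_)
  for (s in seq_along(est)) {
    cfg <- quiet_cfg(seed = 700 + s, n_strains = 50, effect = 0.5,
                     var_strain = 0.75, var_within = 1, replicates = 4)
    fix <- make_fixture(cfg)
    est[s] <- heritability(fix$animals)$h2_conventional
  }
  truth <- (0.5^2 + 0.75) / (0.5^2 + 0.75 + 1)
  expect_lt(abs(mean(est) - truth), 0.1)
})

test_that("age regression recovers planted trends", {
  an <- data.frame(strain = "s", age_months = 13:22,
                   necrotic_count = 34 * (13:22 - 13))
  ar <- age_regression(an)
  expect_equal(ar$slope_per_month, 34, tolerance = 1e-9)
  expect_equal(ar$r2, 1, tolerance = 1e-9)

  an$necrotic_count <- rep(7, 10)
  ar0 <- age_regression(an)
  expect_equal(ar0$slope_per_month, 0)
  expect_equal(ar0$r2, 0)

  an$age_months <- rep(15, 10)
  expect_error(age_regression(an), class = "riqtl_data_error")

  # permuted ages carry no signal
  set.seed(5)
  an2 <- data.frame(strain = "s", age_months = runif(60, 13, 30))
  an2$necrotic_count <- 100 + 30 * (an2$age_months - 13) + rnorm(60, 0, 5)
  r2s <- replicate(30, {
    an2$age_months <- sample(an2$age_months)
    age_regression(an2)$r2
  })
  expect_lt(median(r2s), 0.1)
})

test_that("sex comparison follows the Welch construction", {
  an <- data.frame(strain = "s", sex = rep(c("M", "F"), each = 3),
                   necrotic_count = rep(c(1, 2, 3), 2))
  sc <- sex_compare(an)
  expect_equal(sc$p, 1)
  expect_equal(sc$mean_M, sc$mean_F)

  an$necrotic_count <- c(1, 2, 3, 101, 102, 103)
  expect_lt(sex_compare(an)$p, 0.01)

  # closed-form Welch oracle
  x <- c(1.1, 2.3, 3.7, 2.2); y <- c(4.5, 6.1, 5.2)
  an2 <- data.frame(strain = "s", sex = rep(c("M", "F"), c(4, 3)),
                    necrotic_count = c(x, y))
  sc2 <- sex_compare(an2)
  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 3)
  df <- (var(x) / 4 + var(y) / 3)^2 /
    ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  expect_equal(sc2$p, 2 * pt(-abs(tstat), df), tolerance = 1e-9)

  an3 <- an2[an2$sex == "M", ]
  expect_error(sex_compare(an3), class = "riqtl_data_error")
})

test_that("paired-by-strain mode compares within-strain sex means", {
  set.seed(8)
  an <- data.frame(strain = rep(sprintf("s%d", 1:6), each = 4),
                   sex = rep(c("M", "M", "F", "F"), 6))
  an$necrotic_count <- rnorm(24, 10 + 2 * as.integer(factor(an$strain)))
  sc <- sex_compare(an, paired_by_strain = TRUE)
  expect_equal(sc$n_strains, 6)
  sm <- tapply(an$necrotic_count, list(an$strain, an$sex), mean)
  expect_equal(sc$p, t.test(sm[, "M"], sm[, "F"])$p.value, tolerance = 1e-12)
})
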