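#' Per-nerve axon counts from sampled field counts
#'
#' Optic-nerve cross sections are sampled with at least 12 evenly spaced
#' counting fields; the per-nerve count extrapolates the sampled density to
#' the whole nerve area. Live and necrotic axons are treated identically.
#'
#' @param rec a single animal record: a list or one-row data.frame with
#'   elements `field_counts_live`, `field_counts_necrotic` (numeric vectors),
#'   `field_area_um2` and `nerve_area_um2`.
#' @return list with `necrotic_per_nerve`, `necrotic_density_per_um2`,
#'   `live_per_nerve`, `live_density_per_um2`. Per-nerve counts are rounded
#'   half-up to integers; densities are per square micron.
#' @export
nerve_counts <- function(rec) {
  live <- unlist(rec$field_counts_live)
  necro <- unlist(rec$field_counts_necrotic)
  fa <- rec$field_area_um2[[1]]; na_ <- rec$nerve_area_um2[[1]]
  k <- length(necro)
  if (k == 0 || fa <= 0 || k * fa <= 0) data_error("zero sampled area")
  dens_n <- sum(necro) / (k * fa)
  dens_l <- sum(live) / (length(live) * fa)
  list(necrotic_per_nerve = round_half_up(dens_n * na_),
       necrotic_density_per_um2 = dens_n,
       live_per_nerve = round_half_up(dens_l * na_),
       live_density_per_um2 = dens_l)
}

#' Summarize animal-level values into a strain trait table
#'
#' @param records data.frame of animal records with columns `strain` and the
#'   value column named by `value` (default `necrotic_count`).
#' @param value name of the column to summarize.
#' @return a [trait_table()] with per-strain mean, SEM (`sd/sqrt(n)`, `NA`
#'   when n = 1) and replicate count.
#' @export
strain_summary <- function(records, value = "necrotic_count") {
  if (nrow(records) == 0) data_error("no animal records")
  v <- records[[value]]
  if (is.null(v)) data_error("no column '%s' in records", value)
  s <- factor(records$strain, levels = unique(records$strain))
  m <- tapply(v, s, mean)
  n <- tapply(v, s, length)
  sdv <- tapply(v, s, sd)  # NA when n = 1
  trait_table(levels(s), as.numeric(m), sem = as.numeric(sdv / sqrt(n)),
              n = as.integer(n))
}

#' Winsorize flagged outlier strains by unit rank steps
#'
#' Rank-preserving nearest-value replacement: the k flagged high strains, in
#' ascending order of their raw values, are set to `max(retained) + 1, + 2,
#' ..., + k`; flagged low strains, in descending raw order, to
#' `min(retained) - 1, - 2, ...`. All other values are untouched, so the rank
#' order of every strain is preserved while the outliers are pulled to the
#' edge of the retained distribution.
#'
#' @param strain_means a [trait_table()].
#' @param high_outliers,low_outliers strain labels to winsorize (either may
#'   be empty).
#' @return the trait table with outlier means replaced.
#' @export
winsorize <- function(strain_means, high_outliers = character(),
                      low_outliers = character()) {
  if (length(intersect(high_outliers, low_outliers)) > 0)
    config_error("outlier sets overlap: %s",
                 intersect(high_outliers, low_outliers)[1])
  missing <- setdiff(c(high_outliers, low_outliers), strain_means$strain)
  if (length(missing) > 0) data_error("unknown outlier strain: %s", missing[1])
  flagged <- strain_means$strain %in% c(high_outliers, low_outliers)
  if (all(flagged)) data_error("no retained strains after flagging outliers")
  out <- strain_means
  ret <- strain_means$mean[!flagged]
  if (length(high_outliers) > 0) {
    i <- match(high_outliers, strain_means$strain)
    i <- i[order(strain_means$mean[i])]           # ascending raw order
    out$mean[i] <- max(ret) + seq_along(i)
  }
  if (length(low_outliers) > 0) {
    i <- match(low_outliers, strain_means$strain)
    i <- i[order(strain_means$mean[i], decreasing = TRUE)]  # descending
    out$mean[i] <- min(ret) - seq_along(i)
  }
  out
}

#' Flag outlier strains by Tukey fences
#'
#' @param strain_means a [trait_table()].
#' @param k_iqr fence multiplier (1.5 = conventional Tukey fences).
#' @return list with `high` and `low` character vectors of strain labels
#'   outside `[Q1 - k IQR, Q3 + k IQR]`.
#' @export
detect_outliers <- function(strain_means, k_iqr = 1.5) {
  if (nrow(strain_means) < 4) data_error("need at least 4 strains")
  q <- quantile(strain_means$mean, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  list(high = strain_means$strain[strain_means$mean > q[2] + k_iqr * iqr],
       low = strain_means$strain[strain_means$mean < q[1] - k_iqr * iqr])
}

#' Heritability of a strain-replicated trait
#'
#' One-way random-effects ANOVA across strains. The within-strain
#' environmental variance is the within mean square; the between-strain
#' genetic variance is `(MS_between - MS_within) / n0` with
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)` (the unbalanced-design replicate
#' coefficient), clamped at zero. Two heritabilities are reported:
#' conventional `h2 = Va / (Va + Ve)` at the level of individual animals, and
#' the RI strain-mean heritability `h2_rix = Va / (Va + Ve / n_bar)` with
#' `n_bar` the harmonic mean replicate count, which credits the variance
#' reduction from averaging replicates within a strain.
#'
#' @param x either a data.frame of animal records (columns `strain` and
#'   `necrotic_count`, or pass `value`) or a [trait_table()] carrying `sem`
#'   and `n`, from which within-strain variances are reconstructed as
#'   `n_i * sem_i^2`.
#' @param value value column when `x` is animal-level.
#' @return list of class `heritability_result`: `Va`, `Ve`, `n_eff`
#'   (harmonic-mean replicates), `h2_conventional`, `h2_rix`.
#' @export
heritability <- function(x, value = "necrotic_count") {
  if (inherits(x, "trait_table")) {
    if (!isTRUE(attr(x, "has_sem")) || !isTRUE(attr(x, "has_n")))
      data_error("summary-path heritability needs SEM and N columns")
    keep <- !is.na(x$n)
    ni <- x$n[keep]; mi <- x$mean[keep]
    s2 <- ifelse(ni > 1, ni * x$sem[keep]^2, NA_real_)
    ss_within <- sum((ni - 1) * s2, na.rm = TRUE)
    df_within <- sum(ni - 1)
  } else {
    v <- x[[value]]
    s <- factor(x$strain)
    ni <- as.integer(table(s))
    mi <- as.numeric(tapply(v, s, mean))
    ss_within <- sum((v - mi[as.integer(s)])^2)
    df_within <- length(v) - nlevels(s)
  }
  k <- length(ni)
  if (k < 2) data_error("need at least 2 strains")
  if (df_within < 1) data_error("heritability undefined: no within-strain replication")
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  ms_between <- sum(ni * (mi - grand)^2) / (k - 1)
  ms_within <- ss_within / df_within
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  Va <- max(0, (ms_between - ms_within) / n0)
  Ve <- ms_within
  nbar <- harmonic_mean(ni)
  structure(list(Va = Va, Ve = Ve, n_eff = nbar,
                 h2_conventional = Va / (Va + Ve),
                 h2_rix = Va / (Va + Ve / nbar)),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("Va = %.4g, Ve = %.4g, n_eff = %.2f\nh2 (conventional) = %.1f%%, h2 (RI strain-mean) = %.1f%%\n",
              x$Va, x$Ve, x$n_eff, 100 * x$h2_conventional, 100 * x$h2_rix))
  invisible(x)
}

#' Regression of a trait on age
#'
#' Ordinary least squares of the animal value on age centred at 13 months
#' (the youngest age in an aged cohort), or on log(age) when
#' `log_age = TRUE`.
#'
#' @param records animal records with columns `age_months` and `value`.
#' @param value value column name.
#' @param log_age regress on `log(age_months)` instead of `age_months - 13`.
#' @param center_months centring constant for the linear fit.
#' @return list with `slope_per_month` (or per log-month), `intercept`, `r2`.
#' @export
age_regression <- function(records, value = "necrotic_count",
                           log_age = FALSE, center_months = 13) {
  if (nrow(records) < 3) data_error("need at least 3 records")
  if (length(unique(records$age_months)) < 2) data_error("age is constant")
  xv <- if (log_age) log(records$age_months) else records$age_months - center_months
  yv <- records[[value]]
  fit <- lm(yv ~ xv)
  list(slope_per_month = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r2 = if (var(yv) == 0) 0 else suppressWarnings(summary(fit)$r.squared))
}

#' Compare trait values between sexes
#'
#' Welch two-sample t-test of male vs female animal values, either over all
#' animals (`paired_by_strain = FALSE`) or over within-strain sex means
#' restricted to strains with at least two animals of each sex
#' (`paired_by_strain = TRUE`), which removes between-strain genetic variance
#' from the comparison.
#'
#' @param records animal records with columns `sex` (`"M"`/`"F"`), `strain`
#'   and the value column.
#' @param paired_by_strain compare within-strain sex means (paired test).
#' @param value value column name.
#' @param min_per_sex minimum animals of each sex for a strain to enter the
#'   paired comparison.
#' @return list with `mean_M`, `mean_F`, `p`, `n_M`, `n_F` (and `n_strains`
#'   in paired mode).
#' @export
sex_compare <- function(records, paired_by_strain = FALSE,
                        value = "necrotic_count", min_per_sex = 2) {
  v <- records[[value]]
  if (!all(c("M", "F") %in% records$sex)) data_error("both sexes must be present")
  if (!paired_by_strain) {
    m <- v[records$sex == "M"]; f <- v[records$sex == "F"]
    tt <- t.test(m, f)
    return(list(mean_M = mean(m), mean_F = mean(f), p = tt$p.value,
                n_M = length(m), n_F = length(f)))
  }
  cnt <- table(records$strain, records$sex)
  ok <- rownames(cnt)[cnt[, "M"] >= min_per_sex & cnt[, "F"] >= min_per_sex]
  if (length(ok) < 2) data_error("fewer than 2 strains with both sexes replicated")
  sub <- records[records$strain %in% ok, ]
  sm <- tapply(sub[[value]], list(sub$strain, sub$sex), mean)
  tt <- t.test(sm[, "M"], sm[, "F"])
  list(mean_M = mean(sm[, "M"]), mean_F = mean(sm[, "F"]), p = tt$p.value,
       n_M = sum(cnt[ok, "M"]), n_F = sum(cnt[ok, "F"]),
       n_strains = length(ok))
}
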