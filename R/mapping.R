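# Recombination model for sib-mated RI strains: a single-meiosis Haldane
# fraction r(d) is expanded to the RI-panel fraction R = 4r/(1+6r).
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

ri_expand <- function(r) 4 * r / (1 + 6 * r)

ri_recomb <- function(d_cM) ri_expand(haldane_r(d_cM))

#' Expected allele dosage at an arbitrary map position
#'
#' At a typed marker the dosage is 0 (`B`), 2 (`D`) or `NA` (`H`/`U`).
#' Between markers the expected dosage is the conditional probability of the
#' `D` state given the flanking genotypes under a two-state Markov chain
#' whose step probability is the RI-expanded recombination fraction
#' `R(d) = 4r/(1+6r)` with Haldane `r` at map distance `d`. Positions beyond
#' the terminal markers, or strains typed on one flank only, condition on the
#' nearest single flank; strains missing both flanks get `NA`.
#'
#' @param g a [geno_matrix()].
#' @param chr chromosome label.
#' @param cM genetic position.
#' @return numeric vector of expected dosages in `[0, 2]`, one per strain.
#' @export
dosage_at <- function(g, chr, cM) {
  map <- g$map
  on <- which(map$chr == as.character(chr))
  if (length(on) == 0) range_error("no markers on chromosome %s", chr)
  pos <- map$cM[on]
  if (cM < min(pos) - 1e-9 || cM > max(pos) + 1e-9)
    range_error("position %.3f cM off the chromosome %s map [%g, %g]",
                cM, chr, min(pos), max(pos))
  d <- geno_dosage(g)[, on, drop = FALSE] / 2  # P(D) in {0,1}, NA missing
  hit <- which(abs(pos - cM) < 1e-9)
  if (length(hit) == 1) return(2 * d[, hit])
  li <- max(which(pos < cM)); ri <- min(which(pos > cM))
  rl <- ri_recomb(cM - pos[li]); rr <- ri_recomb(pos[ri] - cM)
  L <- d[, li]; R <- d[, ri]
  # transition prob to state D from an observed flank state
  pD_from <- function(x, r) ifelse(x == 1, 1 - r, r)
  wD <- pD_from(L, rl) * pD_from(R, rr)
  wB <- (1 - pD_from(L, rl)) * (1 - pD_from(R, rr))
  p <- wD / (wD + wB)
  p[is.na(L) & !is.na(R)] <- pD_from(R, rr)[is.na(L) & !is.na(R)]
  p[!is.na(L) & is.na(R)] <- pD_from(L, rl)[!is.na(L) & is.na(R)]
  2 * p
}

# scan positions: typed markers plus a pseudomarker grid every step_cM
# (step_cM = NULL scans typed markers only). Mb for pseudomarkers is linearly
# interpolated between flanking markers.
scan_positions <- function(map, step_cM = 1) {
  out <- lapply(unique(map$chr), function(ch) {
    m <- map[map$chr == ch, ]
    cm <- m$cM
    if (!is.null(step_cM))
      cm <- sort(unique(c(cm, seq(min(m$cM), max(m$cM), by = step_cM))))
    data.frame(chr = ch, cM = cm,
               Mb = approx(m$cM, m$Mb, xout = cm, rule = 2, ties = "ordered")$y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# dosage matrix (strains x positions) for a set of scan positions
dosage_matrix <- function(g, positions) {
  X <- matrix(NA_real_, length(g$strains), nrow(positions))
  for (j in seq_len(nrow(positions)))
    X[, j] <- dosage_at(g, positions$chr[j], positions$cM[j])
  rownames(X) <- g$strains
  X
}

# align a trait table to the genotyped strains
align_strains <- function(g, trait, min_shared = 10) {
  shared <- intersect(g$strains, trait$strain)
  if (length(shared) < min_shared)
    data_error("only %d strains shared between genotypes and trait (need >= %d)",
               length(shared), min_shared)
  list(strains = shared,
       y = trait$mean[match(shared, trait$strain)])
}

# single-marker regression LRS profile, vectorized over positions.
# LRS = n ln(RSS0/RSS1); for simple regression RSS1 = RSS0 (1 - r^2) over the
# strains typed at that position, so complete columns take the fast
# correlation path and columns with missing dosages fall back to
# position-wise least squares.
hk_profile <- function(y, X) {
  n <- length(y)
  lrs <- numeric(ncol(X)); beta <- numeric(ncol(X))
  complete <- !colSums(is.na(X))
  sy <- sd(y)
  if (any(complete) && sy > 0) {
    Xc <- X[, complete, drop = FALSE]
    sx <- apply(Xc, 2, sd)
    r <- suppressWarnings(as.vector(cor(y, Xc)))
    r[sx == 0] <- 0
    lrs[complete] <- -n * log(pmax(1 - r^2, .Machine$double.eps))
    beta[complete] <- ifelse(sx > 0, r * sy / sx, 0)
  }
  for (j in which(!complete)) {
    ok <- !is.na(X[, j])
    nj <- sum(ok)
    if (nj < 3 || sd(X[ok, j]) == 0 || sd(y[ok]) == 0) next
    r <- cor(y[ok], X[ok, j])
    lrs[j] <- -nj * log(max(1 - r^2, .Machine$double.eps))
    beta[j] <- r * sd(y[ok]) / sd(X[ok, j])
  }
  list(lrs = lrs, additive = beta)
}

new_qtl_scan <- function(positions, lrs, additive, method, n) {
  out <- data.frame(chr = positions$chr, cM = positions$cM, Mb = positions$Mb,
                    lrs = lrs, lod = lrs / LOD_SCALE, additive = additive,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "n") <- n
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Haley-Knott interval mapping
#'
#' At every typed marker and pseudomarker, regresses strain means on the
#' expected allele dosage ([dosage_at()]) and reports the likelihood-ratio
#' statistic `LRS = n ln(RSS0/RSS1)` against the intercept-only model
#' (`LOD = LRS / (2 ln 10)`), together with the additive effect per allele
#' substitution (the slope on the 0/2 dosage coding). Strains missing a
#' dosage at a position are dropped position-wise.
#'
#' @param g a [geno_matrix()].
#' @param trait a [trait_table()]; strain means are used unweighted.
#' @param step_cM pseudomarker spacing in cM (`NULL` scans typed markers only).
#' @param min_shared minimum strains shared between genotypes and trait.
#' @return a `qtl_scan` data.frame (`chr`, `cM`, `Mb`, `lrs`, `lod`,
#'   `additive`), sorted by map position, with attributes `method = "HK"` and
#'   `n` (strains used).
#' @export
hk_scan <- function(g, trait, step_cM = 1, min_shared = 10) {
  al <- align_strains(g, trait, min_shared)
  gs <- subset_strains(g, al$strains)
  positions <- scan_positions(gs$map, step_cM)
  X <- dosage_matrix(gs, positions)
  if (all(apply(X, 2, function(x) length(unique(x[!is.na(x)]))) <= 1))
    warning("monomorphic genome: all LRS are zero")
  prof <- hk_profile(al$y, X)
  new_qtl_scan(positions, prof$lrs, prof$additive, "HK", length(al$y))
}

subset_strains <- function(g, strains) {
  structure(list(calls = g$calls[strains, , drop = FALSE], map = g$map,
                 strains = strains), class = "geno_matrix")
}

#' Genome-wide permutation thresholds
#'
#' Strain means are permuted across strains `n_perm` times; each permutation
#' is scanned and its genome-wide maximum LRS recorded. The significant
#' threshold is the empirical 95th percentile of that null distribution
#' (genome-wide p = 0.05) and the suggestive threshold the 37th percentile
#' (genome-wide p = 0.63, one false positive expected per genome scan).
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (mandatory, recorded in the result).
#' @return list of class `qtl_thresholds`: `significant_lrs`,
#'   `suggestive_lrs`, `max_lrs` (the null maxima), `n_perm`, `seed`.
#' @export
permutation_thresholds <- function(g, trait, n_perm = 2000, seed,
                                   step_cM = 1, min_shared = 10) {
  if (n_perm < 100) config_error("n_perm must be >= 100 (got %d)", n_perm)
  al <- align_strains(g, trait, min_shared)
  gs <- subset_strains(g, al$strains)
  positions <- scan_positions(gs$map, step_cM)
  X <- dosage_matrix(gs, positions)
  n <- length(al$y)
  set.seed(seed)
  perm <- replicate(n_perm, sample(al$y))
  complete <- !colSums(is.na(X))
  maxima <- numeric(n_perm)
  if (any(complete)) {
    Xc <- X[, complete, drop = FALSE]
    keep <- apply(Xc, 2, sd) > 0
    Xc <- Xc[, keep, drop = FALSE]
    if (ncol(Xc) > 0 && sd(al$y) > 0) {
      Zx <- scale(Xc); Zy <- scale(perm)
      r2max <- apply((crossprod(Zx, Zy) / (n - 1))^2, 2, max)
      maxima <- -n * log(pmax(1 - r2max, .Machine$double.eps))
    }
  }
  if (any(!complete)) {  # rare path: markers with missing calls
    for (p in seq_len(n_perm)) {
      prof <- hk_profile(perm[, p], X[, !complete, drop = FALSE])
      maxima[p] <- max(maxima[p], prof$lrs)
    }
  }
  structure(list(significant_lrs = unname(quantile(maxima, 0.95)),
                 suggestive_lrs = unname(quantile(maxima, 1 - 0.63)),
                 max_lrs = maxima, n_perm = n_perm, seed = seed),
            class = "qtl_thresholds")
}

#' @export
print.qtl_thresholds <- function(x, ...) {
  cat(sprintf("genome-wide LRS thresholds (%d permutations): significant (p=0.05) %.2f, suggestive (p=0.63) %.2f\n",
              x$n_perm, x$significant_lrs, x$suggestive_lrs))
  invisible(x)
}

#' Bootstrap localization of the peak
#'
#' Strains are resampled with replacement `n_boot` times; each bootstrap
#' panel is rescanned and the position of its maximum LRS tallied (ties go
#' to the lowest genomic coordinate). The frequency profile estimates the
#' sampling distribution of the peak location.
#'
#' @inheritParams hk_scan
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @return data.frame `chr`, `cM`, `Mb`, `freq` (frequencies sum to 1).
#' @export
bootstrap_peak <- function(g, trait, n_boot = 2000, seed,
                           step_cM = 1, min_shared = 10) {
  if (n_boot < 100) config_error("n_boot must be >= 100 (got %d)", n_boot)
  al <- align_strains(g, trait, min_shared)
  gs <- subset_strains(g, al$strains)
  positions <- scan_positions(gs$map, step_cM)
  X <- dosage_matrix(gs, positions)
  n <- length(al$y)
  set.seed(seed)
  counts <- integer(nrow(positions))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    prof <- hk_profile(al$y[idx], X[idx, , drop = FALSE])
    counts[which.max(prof$lrs)] <- counts[which.max(prof$lrs)] + 1L
  }
  data.frame(chr = positions$chr, cM = positions$cM, Mb = positions$Mb,
             freq = counts / n_boot, stringsAsFactors = FALSE)
}

#' LOD-drop support interval around the scan peak
#'
#' Finds the widest contiguous run of positions around the genome-wide peak
#' whose LOD stays within `drop_lod` of the peak LOD, then extends one
#' position outward on each side (the interval endpoints are the first
#' positions that fall below the drop). Ties in the peak go to the lowest
#' genomic coordinate.
#'
#' @param scan a `qtl_scan`.
#' @param drop_lod LOD units to drop (1.5 by default).
#' @return list `chr`, `Mb_lo`, `Mb_hi`, `cM_lo`, `cM_hi`, `peak_Mb`,
#'   `peak_lrs`.
#' @export
support_interval <- function(scan, drop_lod = 1.5) {
  if (max(scan$lrs) <= 0) data_error("flat scan: no positive peak")
  pk <- which.max(scan$lrs)
  ch <- scan$chr[pk]
  on <- which(scan$chr == ch)
  lod <- scan$lod[on]
  pk_local <- match(pk, on)
  keep <- lod >= lod[pk_local] - drop_lod
  lo <- pk_local
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- pk_local
  while (hi < length(on) && keep[hi + 1]) hi <- hi + 1
  lo <- max(1, lo - 1); hi <- min(length(on), hi + 1)
  list(chr = ch, Mb_lo = scan$Mb[on[lo]], Mb_hi = scan$Mb[on[hi]],
       cM_lo = scan$cM[on[lo]], cM_hi = scan$cM[on[hi]],
       peak_Mb = scan$Mb[pk], peak_lrs = scan$lrs[pk])
}

#' Scan robustness under outlier treatments
#'
#' Repeats the Haley-Knott scan under three treatments of flagged outlier
#' strains: raw (as given), winsorized ([winsorize()]) and censored (outlier
#' strains dropped), and summarizes the peak per scenario. A locus that is
#' real should map to the same chromosome under all three.
#'
#' @inheritParams hk_scan
#' @param trait_raw the unwinsorized [trait_table()].
#' @param high_outliers,low_outliers strain labels flagged as outliers.
#' @return data.frame with one row per scenario: `scenario`, `n_strains`,
#'   `peak_chr`, `peak_Mb`, `peak_lrs`.
#' @export
robustness_suite <- function(g, trait_raw, high_outliers = character(),
                             low_outliers = character(), step_cM = 1) {
  flagged <- c(high_outliers, low_outliers)
  traits <- list(
    raw = trait_raw,
    winsorized = winsorize(trait_raw, high_outliers, low_outliers),
    censored = {
      keep <- !(trait_raw$strain %in% flagged)
      tt <- trait_raw[keep, ]
      class(tt) <- class(trait_raw)
      tt
    })
  rows <- lapply(names(traits), function(nm) {
    sc <- hk_scan(g, traits[[nm]], step_cM = step_cM)
    pk <- which.max(sc$lrs)
    data.frame(scenario = nm,
               n_strains = length(intersect(g$strains, traits[[nm]]$strain)),
               peak_chr = sc$chr[pk], peak_Mb = sc$Mb[pk], peak_lrs = sc$lrs[pk],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
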