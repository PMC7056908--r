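#' Genomic kinship matrix
#'
#' `K = Z Z' / p` over the `p` retained markers, where `Z` is the
#' column-centred 0/2 dosage matrix. Markers with minor-allele frequency at
#' or below `maf_min` are excluded, as is the whole chromosome named by
#' `loco_chromosome` (leave-one-chromosome-out, which prevents the scanned
#' chromosome's markers from absorbing their own signal through the kinship
#' correction). Missing dosages are mean-imputed before centring.
#'
#' @param g a [geno_matrix()].
#' @param loco_chromosome chromosome label to exclude, or `NULL`.
#' @param maf_min MAF exclusion threshold (markers kept need MAF > maf_min).
#' @return list of class `kinship_matrix`: `K` (strains x strains),
#'   `excluded_chromosome`, `n_markers`.
#' @export
kinship <- function(g, loco_chromosome = NULL, maf_min = 0.05) {
  keep <- geno_maf(g) > maf_min
  if (!is.null(loco_chromosome)) keep <- keep & g$map$chr != as.character(loco_chromosome)
  keep[is.na(keep)] <- FALSE
  if (sum(keep) < 2)
    data_error("fewer than 2 markers survive MAF/LOCO filtering")
  Z <- geno_dosage(g)[, keep, drop = FALSE]
  for (j in seq_len(ncol(Z))) {
    na <- is.na(Z[, j])
    if (any(na)) Z[na, j] <- mean(Z[, j], na.rm = TRUE)
  }
  Z <- scale(Z, center = TRUE, scale = FALSE)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(g$strains, g$strains)
  structure(list(K = K, excluded_chromosome = loco_chromosome,
                 n_markers = ncol(Z)), class = "kinship_matrix")
}

# ML log-likelihood of y = X b + u + e, Var = sigma_e^2 (lambda K + I),
# profiled over b and sigma_e^2, in the eigenbasis of K.
# d: eigenvalues of K; Uty, UtX: rotated response and design.
lmm_profile_loglik <- function(log10_lambda, d, Uty, UtX) {
  lam <- 10^log10_lambda
  v <- lam * d + 1
  w <- 1 / v
  XtWX <- crossprod(UtX, UtX * w)
  XtWy <- crossprod(UtX, Uty * w)
  beta <- solve(XtWX, XtWy)
  r <- Uty - UtX %*% beta
  n <- length(Uty)
  sigma2 <- sum(r^2 * w) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + sum(log(v)) + n)
  list(loglik = ll, beta = as.vector(beta), lambda = lam, sigma2_e = sigma2)
}

#' Fit the single-marker linear mixed model
#'
#' Maximum-likelihood fit of `y = X beta + u + e` with `u ~ N(0, sg^2 K)`
#' and `e ~ N(0, se^2 I)`. The variance ratio `lambda = sg^2/se^2` is
#' profiled by bounded scalar search on `log10(lambda)` in `[-5, 5]` after a
#' single eigendecomposition of `K`.
#'
#' @param K kinship matrix (plain matrix or [kinship()] result).
#' @param y response vector.
#' @param X design matrix (an intercept column is *not* added automatically).
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return list of class `lmm_fit`: `lambda`, `beta`, `sigma2_e`, `loglik`.
#' @export
lmm_fit <- function(K, y, X, eig = NULL) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  if (is.null(eig)) {
    if (max(abs(K - t(K))) > 1e-8) data_error("kinship matrix not symmetric")
    eig <- eigen(K, symmetric = TRUE)
    if (min(eig$values) < -1e-8 * max(abs(eig$values), 1))
      riqtl_stop("riqtl_numerical_error",
                 "kinship matrix not positive semi-definite (min eigenvalue %.3g)",
                 min(eig$values))
  }
  d <- pmax(eig$values, 0)
  Uty <- crossprod(eig$vectors, y)
  UtX <- crossprod(eig$vectors, X)
  opt <- optimize(function(l) lmm_profile_loglik(l, d, Uty, UtX)$loglik,
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-8)
  fit <- lmm_profile_loglik(opt$maximum, d, Uty, UtX)
  structure(fit[c("lambda", "beta", "sigma2_e", "loglik")], class = "lmm_fit")
}

#' Kinship-corrected mixed-model genome scan
#'
#' GEMMA-style association scan at every typed marker: the model
#' `y = mu + x beta + u + e` with `u ~ N(0, sg^2 K)` is fit by maximum
#' likelihood, with the kinship matrix recomputed per chromosome under LOCO.
#' The variance ratio is re-optimized under both the null (`beta = 0`) and
#' the alternative, and the reported LRS is `2 (l1 - l0)` (`mode = "lrt"`);
#' `mode = "wald"` instead keeps the null variance ratio and converts the
#' Wald chi-square to the same LRS scale. Markers with MAF at or below
#' `maf_min` are skipped (LRS 0).
#'
#' @inheritParams hk_scan
#' @param loco recompute kinship leaving out the scanned chromosome.
#' @param maf_min marker MAF filter.
#' @param mode `"lrt"` (default) or `"wald"`.
#' @return a `qtl_scan` at the typed markers, `method = "LMM"`.
#' @export
lmm_scan <- function(g, trait, loco = TRUE, maf_min = 0.05, mode = c("lrt", "wald"),
                     min_shared = 10) {
  mode <- match.arg(mode)
  al <- align_strains(g, trait, min_shared)
  gs <- subset_strains(g, al$strains)
  y <- al$y
  n <- length(y)
  maf <- geno_maf(gs)
  D <- geno_dosage(gs)
  ones <- matrix(1, n, 1)
  chrs <- unique(gs$map$chr)
  lrs <- numeric(nrow(gs$map)); beta <- numeric(nrow(gs$map))
  for (ch in chrs) {
    Kc <- kinship(gs, loco_chromosome = if (loco) ch else NULL, maf_min = maf_min)
    eig <- eigen(Kc$K, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    Uty <- crossprod(eig$vectors, y)
    Ut1 <- crossprod(eig$vectors, ones)
    null_opt <- optimize(function(l) lmm_profile_loglik(l, d, Uty, Ut1)$loglik,
                         interval = c(-5, 5), maximum = TRUE, tol = 1e-8)
    null_fit <- lmm_profile_loglik(null_opt$maximum, d, Uty, Ut1)
    on <- which(gs$map$chr == ch)
    for (j in on) {
      if (is.na(maf[j]) || maf[j] <= maf_min) next
      x <- D[, j]
      ok <- !is.na(x)
      if (sum(!ok) > 0) x[!ok] <- mean(x, na.rm = TRUE)
      UtX <- cbind(Ut1, crossprod(eig$vectors, x))
      if (mode == "lrt") {
        opt <- optimize(function(l) lmm_profile_loglik(l, d, Uty, UtX)$loglik,
                        interval = c(-5, 5), maximum = TRUE, tol = 1e-8)
        fit <- lmm_profile_loglik(opt$maximum, d, Uty, UtX)
        lrs[j] <- max(0, 2 * (fit$loglik - null_fit$loglik))
        beta[j] <- fit$beta[2]
      } else {
        # Wald at the null lambda: GLS slope and its chi-square
        lam <- null_fit$lambda
        w <- 1 / (lam * d + 1)
        XtWX <- crossprod(UtX, UtX * w)
        XtWy <- crossprod(UtX, Uty * w)
        b <- solve(XtWX, XtWy)
        r <- Uty - UtX %*% b
        sigma2 <- sum(r^2 * w) / (n - ncol(UtX))
        se2 <- sigma2 * solve(XtWX)[2, 2]
        lrs[j] <- as.vector(b[2]^2 / se2)
        beta[j] <- b[2]
      }
    }
  }
  positions <- data.frame(chr = gs$map$chr, cM = gs$map$cM, Mb = gs$map$Mb,
                          stringsAsFactors = FALSE)
  new_qtl_scan(positions, lrs, beta, "LMM", n)
}
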