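# The core association method: per-SNP regional autozygosity status
# regressed on a quantitative trait under a linear mixed model with a
# GRM-structured random effect. REML variance components are estimated once
# on the null model (covariates only) via a one-time eigendecomposition of
# the GRM and a 1-D optimization of the variance ratio; each SNP is then
# tested by generalized least squares with those components held fixed
# (the standard efficient two-stage scheme). Additive/recessive genotype
# encodings with OLS provide the validation route.

#' Filter the inclusion matrix for association
#'
#' Removes samples without any ROH first, then SNP columns whose regional
#' autozygosity frequency (computed on the remaining samples) is below
#' \code{freq_min}.
#'
#' @param r inclusion matrix (samples x SNPs, rownames = sample ids).
#' @param freq_min minimum regional frequency (default 0.01).
#' @return filtered matrix with attribute \code{report} (samples and SNPs
#'   removed). Errors if no SNP survives.
#' @export
filter_for_association <- function(r, freq_min = 0.01) {
  keep_s <- rowSums(r) > 0
  if (!any(keep_s)) stop("no SNP passes the regional-frequency filter: ",
                         "every sample lacks ROH")
  r2 <- r[keep_s, , drop = FALSE]
  freq <- colMeans(r2)
  keep_v <- freq >= freq_min
  if (!any(keep_v)) stop("no SNP passes the regional-frequency filter")
  out <- r2[, keep_v, drop = FALSE]
  attr(out, "report") <- list(samples_removed = sum(!keep_s),
                              snps_removed = sum(!keep_v),
                              n_samples = nrow(out), n_snps = ncol(out))
  out
}

#' Fit the null linear mixed model
#'
#' REML fit of \code{y = X b + g + e} with \code{g ~ N(0, var_g K)} and
#' \code{e ~ N(0, var_e I)}: the GRM \code{K} is eigendecomposed once, the
#' data rotated, and the restricted likelihood profiled over the variance
#' ratio \code{gamma = var_g / var_e} (optimized on the log scale after a
#' coarse grid bracket). Fixed effects come from generalized least squares
#' at the optimum.
#'
#' @param y numeric trait vector, no missing values.
#' @param covariates numeric matrix of covariates (an intercept is added).
#' @param kinship symmetric PSD GRM aligned to \code{y}.
#' @param gamma_range log-variance-ratio search interval.
#' @param kinship_eigen optional precomputed \code{eigen()} of the GRM;
#'   avoids redecomposing when many traits are fit on one cohort.
#' @return object of class \code{null_lmm}: fixed-effect table, \code{var_g},
#'   \code{var_e}, restricted log-likelihood, and the spectral pieces reused
#'   by \code{\link{test_regional}}.
#' @export
fit_null_lmm <- function(y, covariates, kinship,
                         gamma_range = c(-12, 12), kinship_eigen = NULL) {
  if (anyNA(y) || anyNA(covariates)) stop("complete cases required")
  n <- length(y)
  x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  k <- ncol(x)
  stopifnot(nrow(x) == n)
  eg <- kinship_eigen
  if (is.null(eg)) {
    stopifnot(nrow(kinship) == n, ncol(kinship) == n)
    eg <- eigen((kinship + t(kinship)) / 2, symmetric = TRUE)
  }
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("kinship matrix is not positive semidefinite")
  lam <- pmax(eg$values, 0)
  u <- eg$vectors
  ys <- crossprod(u, y)
  xs <- crossprod(u, x)

  reml <- function(lg) {
    gam <- exp(lg)
    w <- 1 / (gam * lam + 1)
    xtwx <- crossprod(xs, xs * w)
    beta <- solve(xtwx, crossprod(xs, ys * w))
    r <- ys - xs %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - k)
    -0.5 * ((n - k) * (log(2 * pi * s2) + 1) + sum(log(gam * lam + 1)) +
              as.numeric(determinant(xtwx)$modulus) -
              as.numeric(determinant(crossprod(xs))$modulus))
  }
  grid <- seq(gamma_range[1], gamma_range[2], length.out = 25)
  vals <- vapply(grid, reml, numeric(1))
  if (any(!is.finite(vals))) stop("REML optimization failed (non-finite)")
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lg <- opt$maximum
  gam <- exp(lg)
  # var_g -> 0 when the optimum sits on the lower search bound
  if (abs(lg - gamma_range[1]) < 1e-6 && i0 == 1) gam <- 0

  w <- 1 / (gam * lam + 1)
  xtwx <- crossprod(xs, xs * w)
  beta <- solve(xtwx, crossprod(xs, ys * w))
  r <- ys - xs %*% beta
  var_e <- sum(w * r^2) / (n - k)
  var_g <- gam * var_e
  wabs <- 1 / (var_g * lam + var_e)     # absolute precision weights
  cov_beta <- solve(crossprod(xs, xs * wabs))
  fixed <- data.frame(term = colnames(x), estimate = as.numeric(beta),
                      se = sqrt(diag(cov_beta)), stringsAsFactors = FALSE)
  fixed$p <- 2 * stats::pt(-abs(fixed$estimate / fixed$se), df = n - k)
  structure(list(fixed = fixed, var_g = var_g, var_e = var_e,
                 loglik = opt$objective, gamma = gam,
                 eigenvalues = lam, rotation = u,
                 y_rot = as.numeric(ys), x_rot = xs, weights = wabs,
                 n = n, k = k),
            class = "null_lmm")
}

#' @export
print.null_lmm <- function(x, ...) {
  cat("null LMM fit: n =", x$n, " var_g =", signif(x$var_g, 4),
      " var_e =", signif(x$var_e, 4), "\n")
  print(x$fixed, ...)
  invisible(x)
}

#' Per-SNP regional autozygosity association
#'
#' Wald t-test of the ROH-inclusion status coefficient by generalized least
#' squares with the null-fit variance ratio held fixed (the overall residual
#' scale is re-estimated per SNP, so the identity-GRM limit is exactly the
#' OLS t-test). Vectorized over the columns of \code{status}. Columns
#' constant after sample filtering are flagged (NA results), not tested.
#'
#' @param status binary matrix (samples x SNPs) from
#'   \code{\link{filter_for_association}}, sample order matching the fit.
#' @param fit a \code{\link{fit_null_lmm}} object.
#' @param variants optional variant map (chrom, pos, id) aligned to the
#'   columns, copied into the output.
#' @return data.frame with id, model, freq, beta, se, p (two-sided) and a
#'   note column.
#' @export
test_regional <- function(status, fit, variants = NULL) {
  stopifnot(inherits(fit, "null_lmm"))
  status <- as.matrix(status)
  if (nrow(status) != fit$n) stop("status rows do not match the null fit")
  m <- ncol(status)
  freq <- colMeans(status)
  constant <- freq == 0 | freq == 1
  w <- fit$weights
  xs <- fit$x_rot
  ys <- fit$y_rot
  ss <- crossprod(fit$rotation, status)          # rotated status columns
  a <- crossprod(xs, xs * w)
  ainv <- solve(a)
  xw_y <- crossprod(xs, ys * w)
  b <- crossprod(xs, ss * w)                     # k x m
  s_w_s <- colSums(ss^2 * w)
  s_w_y <- as.numeric(crossprod(ss, ys * w))
  q <- ainv %*% b
  s_m_s <- s_w_s - colSums(b * q)
  s_m_y <- s_w_y - as.numeric(crossprod(b, ainv %*% xw_y))
  beta <- s_m_y / s_m_s
  # residual scale re-estimated per SNP (variance ratio fixed from the null
  # fit): the GLS t-test, exact OLS in the identity-GRM limit
  y_m_y <- sum(w * ys^2) - as.numeric(crossprod(xw_y, ainv %*% xw_y))
  df <- fit$n - fit$k - 1
  sigma2 <- pmax(y_m_y - s_m_y^2 / s_m_s, 0) / df
  se <- sqrt(sigma2 / s_m_s)
  p <- 2 * stats::pt(-abs(beta / se), df = df)
  beta[constant] <- NA; se[constant] <- NA; p[constant] <- NA
  out <- data.frame(id = colnames(status) %||% paste0("snp", seq_len(m)),
                    model = "regional_lmm", freq = freq,
                    beta = beta, se = se, p = p,
                    note = ifelse(constant, "constant status", NA_character_),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(variants)) {
    ix <- match(out$id, variants$id)
    out <- cbind(chrom = variants$chrom[ix], pos = variants$pos[ix], out)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return \code{alpha / n_tests}.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1, alpha > 0, alpha <= 1)
  alpha / n_tests
}

#' Greedy LD clumping of association results
#'
#' Sorted by ascending p (variant-id tie-break), the most significant
#' unassigned SNP with p <= \code{p1} becomes an index; every unassigned SNP
#' on the same chromosome within \code{kb} kilobases with p <= \code{p2} and
#' squared dosage correlation above \code{r2} against the index joins its
#' clump. SNPs never indexed or assigned stay unclumped (NA).
#'
#' @param results association data.frame with columns id, chrom, pos, p.
#' @param g \code{genotype_matrix} providing the dosages for r-squared.
#' @param p1,p2,r2,kb clumping parameters (index p ceiling, member p
#'   ceiling, r-squared floor, distance in kb).
#' @return \code{results} with a \code{clump} column (index variant id, NA
#'   if unclumped), rows in p-sorted order.
#' @export
clump_assoc <- function(results, g, p1 = 1e-4, p2 = 0.01, r2 = 0.5,
                        kb = 250) {
  res <- results[order(results$p, results$id), , drop = FALSE]
  res$clump <- NA_character_
  gi <- match(res$id, g$variants$id)
  assigned <- rep(FALSE, nrow(res))
  testable <- !is.na(res$p)
  repeat {
    cand <- which(!assigned & testable & res$p <= p1)
    if (!length(cand)) break
    ix <- cand[1]
    assigned[ix] <- TRUE
    res$clump[ix] <- res$id[ix]
    near <- which(!assigned & testable &
                    res$chrom == res$chrom[ix] &
                    abs(res$pos - res$pos[ix]) <= kb * 1000 &
                    res$p <= p2)
    if (length(near) && !is.na(gi[ix])) {
      d_ix <- g$calls[, gi[ix]]
      rr <- vapply(near, function(jj) {
        if (is.na(gi[jj])) return(0)
        suppressWarnings(stats::cor(d_ix, g$calls[, gi[jj]],
                                    use = "pairwise.complete.obs"))^2
      }, numeric(1))
      rr[is.na(rr)] <- 0
      hit <- near[rr > r2]
      assigned[hit] <- TRUE
      res$clump[hit] <- res$id[ix]
    }
  }
  rownames(res) <- NULL
  res
}

#' Encode genotype dosages for a model
#'
#' Additive: the 0/1/2 dosage of allele1 unchanged. Recessive: 1 iff the
#' dosage is 2, else 0. Missing stays missing.
#'
#' @param calls integer dosage vector.
#' @param model \code{"additive"} or \code{"recessive"}.
#' @return numeric regressor vector.
#' @export
encode_genotype <- function(calls, model = c("additive", "recessive")) {
  model <- match.arg(model)
  if (model == "additive") return(as.numeric(calls))
  out <- as.numeric(calls == 2L)
  out[is.na(calls)] <- NA_real_
  out
}

#' OLS genotype-model association test
#'
#' Ordinary least-squares Wald test of the encoded genotype coefficient,
#' adjusting for the supplied covariates. Complete-case analysis; fewer
#' than 10 complete cases is an error, a constant regressor is flagged.
#'
#' @param regressor encoded genotype vector (see
#'   \code{\link{encode_genotype}}).
#' @param y trait vector.
#' @param covariates numeric covariate matrix (intercept added).
#' @param model label copied into the output.
#' @return one-row data.frame: model, beta, se, p, n_used, note.
#' @export
test_genotype <- function(regressor, y, covariates,
                          model = "additive") {
  x <- cbind(1, as.matrix(covariates), g = regressor)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 10) stop("fewer than 10 complete cases")
  x <- x[ok, , drop = FALSE]
  yy <- y[ok]
  if (length(unique(x[, ncol(x)])) == 1)
    return(data.frame(model = model, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n_used = sum(ok),
                      note = "constant regressor", stringsAsFactors = FALSE))
  fit <- stats::lm(yy ~ 0 + x)
  tab <- summary(fit)$coefficients
  row <- tab[nrow(tab), ]
  data.frame(model = model, beta = unname(row[1]), se = unname(row[2]),
             p = unname(row[4]),
             n_used = sum(ok), note = NA_character_,
             stringsAsFactors = FALSE)
}
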