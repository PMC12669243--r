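# Genome-wide autozygosity-trait association: Spearman correlation of
# F_ROH with each quantitative trait, Benjamini-Hochberg adjusted across
# the trait family.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (ties averaged); the
#' two-sided p-value uses the t-approximation with n - 2 degrees of freedom.
#' Pairs with a missing member are dropped. A constant vector yields
#' \code{rho = NA} with a note rather than an error.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{rho}, \code{p}, \code{n_used}, \code{note}.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))$rho   # 0.8
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n_used = n,
                note = "constant input"))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p = p, n_used = n, note = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, monotone-enforced and capped at 1, returned in
#' input order. Inputs outside (0, 1] are an error.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' F_ROH-trait correlation scan
#'
#' Spearman correlation of per-sample F_ROH with each listed trait,
#' BH-adjusted across the whole trait family; missing trait values are
#' dropped pairwise.
#'
#' @param pheno data.frame holding a \code{froh} column and the traits.
#' @param traits character vector of trait column names.
#' @return data.frame with one row per trait: trait, rho, p, p_adjusted,
#'   n_used.
#' @export
froh_trait_scan <- function(pheno, traits) {
  if (!"froh" %in% names(pheno)) stop("pheno lacks a froh column")
  missing_tr <- setdiff(traits, names(pheno))
  if (length(missing_tr))
    stop("trait(s) absent from phenotype frame: ",
         paste(missing_tr, collapse = ", "))
  rows <- lapply(traits, function(tr) {
    s <- spearman_test(pheno$froh, pheno[[tr]])
    data.frame(trait = tr, rho = s$rho, p = s$p, n_used = s$n_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adjusted[ok] <- bh_adjust(out$p[ok])
  out[, c("trait", "rho", "p", "p_adjusted", "n_used")]
}
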