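#' Pairwise Pearson correlation matrix with significance codes
#'
#' Pairwise-complete Pearson correlations between trait columns, with
#' two-sided t-test p-values and the usual significance codes. Zero-variance
#' columns yield `NA` correlations for their pairs.
#'
#' @param traits A `trait_table` or numeric matrix/data frame (genotypes x
#'   traits).
#' @return List with matrices `r`, `p` and `sig` (character codes), all
#'   traits x traits.
#' @export
correlation_matrix <- function(traits) {
  m <- if (inherits(traits, "trait_table")) trait_matrix(traits) else as.matrix(traits)
  p_ <- ncol(m)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(m))
  pmat <- matrix(NA_real_, p_, p_, dimnames = dimnames(r))
  ok <- !is.na(r) & n_pair > 2 & abs(r) < 1
  tstat <- r[ok] * sqrt((n_pair[ok] - 2) / (1 - r[ok]^2))
  pmat[ok] <- 2 * stats::pt(abs(tstat), n_pair[ok] - 2, lower.tail = FALSE)
  pmat[!is.na(r) & abs(r) >= 1 & n_pair > 2] <- 0
  diag(pmat) <- NA
  sig <- matrix(sig_code(pmat), p_, p_, dimnames = dimnames(r))
  list(r = r, p = pmat, sig = sig)
}

#' Principal component summary of a trait table
#'
#' Eigen decomposition of the correlation matrix of the (centered, scaled)
#' traits. Constant columns are dropped with a warning. Component signs are
#' fixed so that the loading with the largest absolute value in each
#' component is positive.
#'
#' @param traits A `trait_table` or numeric matrix (genotypes x traits).
#' @return List with `loadings` (traits x components), `scores` (genotypes x
#'   components of the standardized data), `pct_variance` (percent per
#'   component, summing to 100) and `eigenvalues`.
#' @export
pca_summary <- function(traits) {
  m <- if (inherits(traits, "trait_table")) trait_matrix(traits) else as.matrix(traits)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least two non-constant traits")
  R <- stats::cor(m, use = "pairwise.complete.obs")
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors
  # sign convention: largest-|loading| entry positive in each component
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(R), paste0("PC", seq_len(ncol(L))))
  Z <- scale(m)
  scores <- Z %*% L
  list(loadings = L, scores = scores,
       pct_variance = 100 * ev / sum(ev), eigenvalues = ev)
}
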