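#' Rescale a trait to the 0-100 desirability scale
#'
#' Linear rescaling so that 100 is always the ideal value: for
#' direction `"increase"`, `100 * (x - min) / (max - min)`; for
#' `"decrease"`, `100 * (max - x) / (max - min)`. After rescaling, the
#' all-100 row is the ideotype regardless of each trait's original
#' orientation.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param direction `"increase"` or `"decrease"`.
#' @return Vector on \[0, 100\].
#' @examples
#' rescale_trait(1:3, "increase")  # 0 50 100
#' rescale_trait(1:3, "decrease")  # 100 50 0
#' @export
rescale_trait <- function(values, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("cannot rescale a constant trait")
  if (direction == "increase") 100 * (values - rng[1]) / diff(rng)
  else 100 * (rng[2] - values) / diff(rng)
}

#' Varimax rotation by normalized pairwise sweeps
#'
#' Classic planar-rotation varimax with Kaiser normalization: loadings rows
#' are scaled to unit communality, factor pairs are rotated in turn by the
#' closed-form angle that maximizes the varimax criterion, and sweeps repeat
#' until every angle falls below `tol`. Rows are rescaled afterwards.
#'
#' @param loadings Traits x factors matrix of initial (unrotated) loadings.
#' @param tol Convergence tolerance on the rotation angle (default 1e-8).
#' @param max_sweeps Maximum number of full pair sweeps (default 1000).
#' @return Rotated loadings with attribute `rotmat` (the accumulated
#'   orthogonal rotation).
#' @export
varimax_rotate <- function(loadings, tol = 1e-8, max_sweeps = 1000) {
  f <- ncol(loadings)
  rot <- diag(f)
  if (f < 2) {
    attr(loadings, "rotmat") <- rot
    return(loadings)
  }
  h <- sqrt(rowSums(loadings^2))
  Ln <- loadings / h
  p <- nrow(Ln)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in seq_len(f - 1)) for (j in (i + 1):f) {
      u <- Ln[, i]^2 - Ln[, j]^2
      v <- 2 * Ln[, i] * Ln[, j]
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- 2 * sum(u * v)
      num <- D - 2 * A * B / p
      den <- C - (A^2 - B^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) > tol) {
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
        Ln[, c(i, j)] <- Ln[, c(i, j)] %*% G
        rot[, c(i, j)] <- rot[, c(i, j)] %*% G
        delta <- max(delta, abs(phi))
      }
    }
    if (delta <= tol) break
  }
  out <- Ln * h
  dimnames(out) <- dimnames(loadings)
  attr(out, "rotmat") <- rot
  out
}

ridge_solve <- function(R, ridge = 1e-8) {
  tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; using ridge-stabilized inverse")
    solve(R + diag(ridge, nrow(R)))
  })
}

#' Exploratory factor analysis of a rescaled trait matrix
#'
#' Principal-axis factor extraction from the correlation matrix of the
#' rescaled (0-100) traits: factors with eigenvalue >= 1 are retained
#' (Kaiser rule), initial loadings are `eigenvector * sqrt(eigenvalue)`,
#' rotated by normalized varimax. Genotype scores use the regression method,
#' `scores = Z R^-1 L`, where `Z` is the column-standardized rescaled matrix
#' and `L` the rotated loadings. The ideotype scores are the same projection
#' of the all-100 ideotype standardized with the rescaled-trait means and
#' SDs.
#'
#' @param rescaled Numeric matrix (genotypes x traits) on the 0-100 scale;
#'   no constant columns.
#' @return List of class `"factor_model"`: `correlation`, `eigenvalues`,
#'   `n_factors`, `loadings` (rotated, traits x factors FA1..FAf), `scores`
#'   (genotypes x factors), `ideotype_scores`, `trait_means`, `trait_sds`.
#' @export
factor_analysis <- function(rescaled) {
  rescaled <- as.matrix(rescaled)
  mu <- colMeans(rescaled)
  sds <- apply(rescaled, 2, stats::sd)
  if (any(sds == 0)) stop("constant column(s) in rescaled matrix")
  R <- stats::cor(rescaled)
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  f <- max(1L, sum(ev >= 1))
  if (nrow(rescaled) <= f)
    stop("need more genotypes than retained factors")
  L0 <- e$vectors[, seq_len(f), drop = FALSE] %*% diag(sqrt(ev[seq_len(f)]), f)
  L <- varimax_rotate(L0)
  attr(L, "rotmat") <- NULL
  dimnames(L) <- list(colnames(rescaled), paste0("FA", seq_len(f)))
  Rinv <- ridge_solve(R)
  B <- Rinv %*% L                       # regression-method score weights
  Z <- scale(rescaled, center = mu, scale = sds)
  scores <- Z %*% B
  z_ideo <- (rep(100, ncol(rescaled)) - mu) / sds
  ideo <- drop(z_ideo %*% B)
  rownames(scores) <- rownames(rescaled)
  structure(list(correlation = R, eigenvalues = ev, n_factors = f,
                 loadings = L, scores = scores, ideotype_scores = ideo,
                 trait_means = mu, trait_sds = sds),
            class = "factor_model")
}

#' Genotype-ideotype distance index from a factor model
#'
#' `MGIDI_i = sqrt(sum_j (score_ij - ideotype_j)^2)`: the Euclidean distance
#' between each genotype and the ideotype in rotated factor-score space.
#' Lower values are closer to the ideotype. The per-factor share
#' `omega_ij = |score_ij - ideotype_j| / sum_j |...|` decomposes each
#' genotype's index into factor contributions (large share = weakness).
#'
#' @param fm A `"factor_model"` from [factor_analysis()].
#' @return List of class `"mgidi_result"`: `mgidi` (named vector), `rank`
#'   (ascending), `omega` (genotypes x factors, rows summing to 1).
#' @export
mgidi_index <- function(fm) {
  stopifnot(inherits(fm, "factor_model"))
  D <- sweep(fm$scores, 2, fm$ideotype_scores)
  mgidi <- sqrt(rowSums(D^2))
  absd <- abs(D)
  tot <- rowSums(absd)
  at_ideo <- tot < sqrt(.Machine$double.eps)
  omega <- absd / tot
  if (any(at_ideo)) {
    warning("genotype(s) exactly at the ideotype; omega set to uniform")
    omega[at_ideo, ] <- 1 / ncol(D)
  }
  structure(list(mgidi = mgidi, rank = rank(mgidi, ties.method = "first"),
                 omega = omega),
            class = "mgidi_result")
}

#' Select genotypes under a selection pressure
#'
#' The `ceiling(pressure * n)` genotypes with the lowest index values are
#' selected; the cutpoint is the index of the last genotype retained. Ties at
#' the cutpoint are broken by stable input order with a warning.
#'
#' @param mgidi Named numeric vector of index values (or an
#'   `"mgidi_result"`).
#' @param pressure Fraction selected, in (0, 1).
#' @return List with `selected` (names), `cutpoint`, `n_selected`.
#' @export
select_genotypes <- function(mgidi, pressure = 0.15) {
  if (inherits(mgidi, "mgidi_result")) mgidi <- mgidi$mgidi
  stopifnot(pressure > 0, pressure < 1)
  n_sel <- ceiling(pressure * length(mgidi))
  ord <- order(mgidi)             # stable for ties
  cut_val <- mgidi[ord[n_sel]]
  if (n_sel < length(mgidi) && mgidi[ord[n_sel + 1]] == cut_val)
    warning("tie at the selection cutpoint; broken by input order")
  list(selected = names(mgidi)[ord[seq_len(n_sel)]],
       cutpoint = unname(cut_val), n_selected = n_sel)
}

#' Selection gain per trait
#'
#' `SG% = 100 * (mean(selected) - mean(all)) / mean(all)` for each trait,
#' with a desirability flag: a gain is desirable when positive for
#' increase-direction traits and negative for decrease-direction traits.
#'
#' @param traits A `trait_table` or numeric matrix (genotypes x traits,
#'   rownames = genotypes).
#' @param selected Character vector of selected genotype ids.
#' @param directions Optional named direction vector; defaults to the
#'   table's `"directions"` attribute or [trait_directions()].
#' @return Data frame with `trait`, `sg_pct`, `direction`, `desirable`.
#' @export
selection_gain <- function(traits, selected, directions = NULL) {
  m <- if (inherits(traits, "trait_table")) trait_matrix(traits) else as.matrix(traits)
  if (length(selected) == 0) stop("selected set is empty")
  if (is.null(directions))
    directions <- attr(traits, "directions") %||% trait_directions(colnames(m))
  mean_all <- colMeans(m, na.rm = TRUE)
  mean_sel <- colMeans(m[rownames(m) %in% selected, , drop = FALSE], na.rm = TRUE)
  sg <- ifelse(mean_all == 0, NA_real_, 100 * (mean_sel - mean_all) / mean_all)
  dirv <- directions[colnames(m)]
  data.frame(trait = colnames(m), sg_pct = unname(sg),
             direction = unname(dirv),
             desirable = unname(ifelse(is.na(sg), NA,
                                       (sg >= 0) == (dirv == "increase"))),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-trait genotype-ideotype distance selection (one call)
#'
#' Runs the full chain on a trait table: direction-aware 0-100 rescaling
#' (constant traits dropped with a warning), factor analysis with varimax
#' rotation and Kaiser retention, the distance index, selection under a
#' pressure cutoff, and per-trait selection gains.
#'
#' @param traits A `trait_table` (or matrix with genotype rownames).
#' @param directions Named direction vector (defaults as in
#'   [selection_gain()]).
#' @param pressure Selection pressure, default 0.15.
#' @return List of class `"mgidi"`: `factor_model`, `mgidi`, `rank`,
#'   `omega`, `selected`, `cutpoint`, `gains`, `dropped_traits`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(65 * 6), 65, 6,
#'             dimnames = list(paste0("G", 1:65), paste0("T", 1:6)))
#' res <- mgidi(m, directions = trait_directions(colnames(m)))
#' head(sort(res$mgidi))
#' @export
mgidi <- function(traits, directions = NULL, pressure = 0.15) {
  m <- if (inherits(traits, "trait_table")) trait_matrix(traits) else as.matrix(traits)
  if (is.null(directions))
    directions <- attr(traits, "directions") %||% trait_directions(colnames(m))
  keep <- colnames(m)[!is.na(colSums(m))]
  sds <- apply(m[, keep, drop = FALSE], 2, stats::sd)
  dropped <- c(setdiff(colnames(m), keep), keep[sds == 0])
  keep <- keep[sds > 0]
  if (length(dropped))
    warning("dropping trait(s) not usable for selection: ",
            paste(dropped, collapse = ", "))
  if (length(keep) < 2) stop("need at least two usable traits")
  resc <- sapply(keep, function(tr) rescale_trait(m[, tr], directions[[tr]]))
  rownames(resc) <- rownames(m)
  fm <- factor_analysis(resc)
  res <- mgidi_index(fm)
  sel <- select_genotypes(res$mgidi, pressure)
  gains <- selection_gain(m[, keep, drop = FALSE], sel$selected,
                          directions[keep])
  structure(list(factor_model = fm, mgidi = res$mgidi, rank = res$rank,
                 omega = res$omega, selected = sel$selected,
                 cutpoint = sel$cutpoint, gains = gains,
                 dropped_traits = dropped),
            class = "mgidi")
}

#' @export
print.mgidi <- function(x, ...) {
  cat("MGIDI selection:", length(x$mgidi), "genotypes,",
      x$factor_model$n_factors, "factors retained\n")
  cat("Selected (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("Cutpoint:", format(x$cutpoint, digits = 4), "\n")
  invisible(x)
}
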