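# Independent brute-force oracles. These deliberately avoid the closed-form
# code paths in R/: indices are computed by per-seed enumeration, ANOVA by
# aov(), regression by lm(), and the factor chain by a hand-coded
# eigen + pairwise-rotation varimax.

# expand a daily-count vector into one germination day per seed
seed_days <- function(counts) rep(seq_along(counts), counts)

oracle_germ <- function(counts) {
  days <- seed_days(counts)
  n <- length(days)
  mgt <- mean(days)
  cvt <- if (n >= 2) 100 * stats::sd(days) / mgt else NA_real_
  f <- as.vector(table(days)) / n
  u <- -sum(f * log2(f))
  # count same-day pairs by brute force over all C(n, 2) pairs
  z <- if (n >= 2) {
    pairs <- utils::combn(n, 2)
    mean(days[pairs[1, ]] == days[pairs[2, ]])
  } else NA_real_
  list(mgt = mgt, cvt = cvt, u = u, z = z)
}

oracle_anova2 <- function(values) {
  g <- factor(rep(seq_len(nrow(values)), ncol(values)))
  r <- factor(rep(seq_len(ncol(values)), each = nrow(values)))
  fit <- stats::aov(as.vector(values) ~ g + r)
  summary(fit)[[1]]
}

oracle_anova3 <- function(arr) {
  d <- dim(arr)
  idx <- expand.grid(g = seq_len(d[1]), t = seq_len(d[2]), r = seq_len(d[3]))
  y <- arr[as.matrix(idx)]
  fit <- stats::aov(y ~ factor(idx$g) + factor(idx$r) + factor(idx$t) +
                      factor(idx$g):factor(idx$t))
  summary(fit)[[1]]
}

# explicit pairwise-rotation varimax with Kaiser normalization
oracle_varimax <- function(L, max_sweeps = 1000, tol = 1e-12) {
  h <- sqrt(rowSums(L^2))
  Ln <- L / h
  p <- nrow(Ln); f <- ncol(Ln)
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
        delta <- max(delta, abs(phi))
      }
    }
    if (delta < tol) break
  }
  Ln * h
}

# full independent factor/score/distance chain
oracle_mgidi <- function(rescaled) {
  R <- stats::cor(rescaled)
  e <- eigen(R, symmetric = TRUE)
  f <- max(1, sum(e$values >= 1))
  L0 <- e$vectors[, 1:f, drop = FALSE] %*% diag(sqrt(e$values[1:f]), f)
  L <- if (f > 1) oracle_varimax(L0) else L0
  mu <- colMeans(rescaled); sds <- apply(rescaled, 2, stats::sd)
  Z <- scale(rescaled, center = mu, scale = sds)
  B <- solve(R) %*% L
  S <- Z %*% B
  ideo <- drop(((100 - mu) / sds) %*% B)
  D <- sweep(S, 2, ideo)
  list(loadings = L, scores = S, ideotype = ideo,
       mgidi = sqrt(rowSums(D^2)))
}

# align oracle factor columns to implementation columns (order + sign);
# `other` applies the same permutation/sign to a companion matrix (scores)
align_factors <- function(L_ref, L_other, other = NULL) {
  f <- ncol(L_ref)
  perm <- integer(f); sign_ <- numeric(f)
  avail <- seq_len(f)
  for (j in seq_len(f)) {
    cors <- vapply(avail, function(k) sum(L_ref[, j] * L_other[, k]), numeric(1))
    k <- avail[which.max(abs(cors))]
    perm[j] <- k; sign_[j] <- sign(cors[which.max(abs(cors))])
    avail <- setdiff(avail, k)
  }
  target <- if (is.null(other)) L_other else other
  sweep(target[, perm, drop = FALSE], 2, sign_, `*`)
}

# small trait table generator used across tests
sim_trait_table <- function(seed = 1, n = 30) {
  cfg <- sim_config(seed = seed, n_lines = n,
                    map_spec = data.frame(chrom = c("1A", "2A", "2B", "3B"),
                                          n_markers = rep(40L, 4),
                                          length_cM = c(177.29, 281.13, 200.77, 174.65)))
  st <- simulate_study(cfg)
  suppressWarnings(assemble_trait_table(st$germination, st$seedlings))
}

small_map_spec <- function(n_chrom = 5, n_markers = 100, len = 150) {
  data.frame(chrom = paste0(seq_len(n_chrom), "A"),
             n_markers = as.integer(n_markers), length_cM = len)
}
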