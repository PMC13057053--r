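#' Significance codes for p-values
#'
#' Conventional codes for trait-wise ANOVA tables: `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `+` p < 0.1, `ns` otherwise.
#'
#' @param p Vector of p-values (NA allowed).
#' @return Character vector of codes.
#' @export
sig_code <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*",
             ifelse(p[ok] < 0.1, "+", "ns"))))
  out
}

#' Balanced two-way random-effects ANOVA for one trait
#'
#' Fits `Y_ij = mu + g_i + r_j + gr_ij(error)` to a balanced genotype x
#' replicate matrix (one dish per cell, as in a randomized complete block
#' design), with genotypes and replicates random. The genotype x replicate
#' interaction is the error stratum. From the expected mean squares,
#' `sigma2_GR = MS_error` and `sigma2_G = (MS_G - MS_error)/r` (clamped at
#' zero), and broad-sense heritability is computed in both supported modes
#' (see [heritability()]).
#'
#' @param values Numeric matrix, genotypes in rows, replicates in columns; no
#'   missing cells.
#' @return An object of class `"seedqtl_anova"`: a list with `table` (source,
#'   df, ss, ms, f, p, sig), `var_g`, `var_gr`, `n_reps`, `f_g`,
#'   `h2_entry_mean`, `h2_plot`, and `f_infinite` (TRUE when the error SS is
#'   zero so F is unbounded).
#' @examples
#' m <- matrix(c(1, 2, 4, 3, 5, 6), nrow = 3, byrow = TRUE)
#' a <- anova_two_way(m)   # SS_G = 16, SS_R = 1/6, SS_E = 4/3, F_G = 12
#' a$h2_entry_mean
#' @export
anova_two_way <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("invalid design: missing cells (balanced data required)")
  g <- nrow(values); r <- ncol(values)
  if (g < 2 || r < 2) stop("invalid design: need >= 2 genotypes and >= 2 replicates")
  grand <- mean(values)
  gm <- rowMeans(values); rm_ <- colMeans(values)
  ss_g <- r * sum((gm - grand)^2)
  ss_r <- g * sum((rm_ - grand)^2)
  ss_t <- sum((values - grand)^2)
  ss_e <- max(ss_t - ss_g - ss_r, 0)
  df_g <- g - 1L; df_r <- r - 1L; df_e <- (g - 1L) * (r - 1L)
  ms_g <- ss_g / df_g; ms_r <- ss_r / df_r; ms_e <- ss_e / df_e
  f_infinite <- ms_e <= 0 && (ms_g > 0 || ms_r > 0)
  f_g <- if (ms_e > 0) ms_g / ms_e else NA_real_
  f_r <- if (ms_e > 0) ms_r / ms_e else NA_real_
  p_g <- if (!is.na(f_g)) stats::pf(f_g, df_g, df_e, lower.tail = FALSE) else NA_real_
  p_r <- if (!is.na(f_r)) stats::pf(f_r, df_r, df_e, lower.tail = FALSE) else NA_real_
  var_gr <- ms_e
  var_g <- max((ms_g - ms_e) / r, 0)
  h2_entry <- if (var_g + var_gr / r > 0) var_g / (var_g + var_gr / r) else NA_real_
  h2_plot <- if (var_g + var_gr > 0) var_g / (var_g + var_gr) else NA_real_
  tab <- data.frame(
    source = c("genotype", "replicate", "error"),
    df = c(df_g, df_r, df_e),
    ss = c(ss_g, ss_r, ss_e),
    ms = c(ms_g, ms_r, ms_e),
    f = c(f_g, f_r, NA),
    p = c(p_g, p_r, NA),
    sig = c(sig_code(p_g), sig_code(p_r), NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, var_g = var_g, var_gr = var_gr, n_reps = r,
                 f_g = f_g, f_infinite = f_infinite,
                 h2_entry_mean = h2_entry, h2_plot = h2_plot),
            class = "seedqtl_anova")
}

#' Balanced three-way ANOVA with a fixed treatment factor
#'
#' Fits `Y_ijk = mu + g_i + r_j + t_k + tg_ki + tgr_ijk(error)` to a balanced
#' genotype x treatment x replicate array. Treatments are fixed; genotypes
#' and replicates random, so the treatment main effect is tested against the
#' genotype x treatment interaction, while genotype, replicate and the
#' interaction are tested against the residual.
#'
#' @param values 3-d numeric array with `dim = c(genotypes, treatments,
#'   replicates)`, dimnames optional; no missing cells.
#' @return List of class `"seedqtl_anova3"` with the source `table`
#'   (genotype, replicate, treatment, genotype:treatment, error).
#' @export
anova_with_treatment <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a genotype x treatment x replicate array")
  if (anyNA(values)) stop("invalid design: missing cells (balanced data required)")
  d <- dim(values); g <- d[1]; t_ <- d[2]; r <- d[3]
  if (any(d < 2)) stop("invalid design: need >= 2 levels per factor")
  grand <- mean(values)
  gm <- apply(values, 1, mean); tm <- apply(values, 2, mean)
  rm_ <- apply(values, 3, mean)
  gtm <- apply(values, c(1, 2), mean)
  ss_g <- t_ * r * sum((gm - grand)^2)
  ss_t <- g * r * sum((tm - grand)^2)
  ss_r <- g * t_ * sum((rm_ - grand)^2)
  ss_gt <- r * sum((sweep(sweep(gtm, 1, gm), 2, tm) + grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_e <- max(ss_tot - ss_g - ss_t - ss_r - ss_gt, 0)
  df <- c(g - 1, r - 1, t_ - 1, (g - 1) * (t_ - 1))
  df_e <- (g * t_ * r - 1) - sum(df)
  ms <- c(ss_g, ss_r, ss_t, ss_gt) / df
  ms_e <- ss_e / df_e
  # F_T against MS_GT (fixed treatment over random interaction); others vs error
  f <- c(ms[1] / ms_e, ms[2] / ms_e, ms[3] / ms[4], ms[4] / ms_e)
  fdf2 <- c(df_e, df_e, df[4], df_e)
  p <- stats::pf(f, df, fdf2, lower.tail = FALSE)
  tab <- data.frame(
    source = c("genotype", "replicate", "treatment", "genotype:treatment", "error"),
    df = c(df, df_e),
    ss = c(ss_g, ss_r, ss_t, ss_gt, ss_e),
    ms = c(ms, ms_e),
    f = c(f, NA),
    p = c(p, NA),
    sig = c(sig_code(p), NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab), class = "seedqtl_anova3")
}

#' Broad-sense heritability from variance components
#'
#' Two conventions are supported. `"entry_mean"` (the default) puts the
#' phenotypic variance on a replicate-mean basis,
#' `H2 = sigma2_G / (sigma2_G + sigma2_GR / r)`; for the balanced two-way
#' design this equals `1 - 1/F_G`, which is the quantity trait-wise ANOVA
#' reports typically tabulate. `"plot"` uses the single-dish phenotypic
#' variance, `H2 = sigma2_G / (sigma2_G + sigma2_GR)`.
#'
#' @param var_g Genotypic variance component (sigma2_G, >= 0).
#' @param var_gr Genotype x replicate (error) variance component (>= 0).
#' @param n_reps Number of replicates r (>= 1).
#' @param mode `"entry_mean"` or `"plot"`.
#' @return Heritability as a fraction in \[0, 1\].
#' @examples
#' heritability(9, 3, 3)                  # 0.9
#' heritability(9, 3, 3, mode = "plot")   # 0.75
#' @export
heritability <- function(var_g, var_gr, n_reps = 3,
                         mode = c("entry_mean", "plot")) {
  mode <- match.arg(mode)
  stopifnot(var_g >= 0, var_gr >= 0, n_reps >= 1)
  denom <- var_g + if (mode == "entry_mean") var_gr / n_reps else var_gr
  if (denom == 0) stop("undefined statistic: both variance components are zero")
  var_g / denom
}

#' Entry-mean heritability from a genotype F ratio
#'
#' For the balanced two-way design with r replicates,
#' `H2(entry mean) = 1 - 1/F_G` whenever `F_G >= 1`, because
#' `sigma2_G = (MS_G - MS_E)/r` and the entry-mean phenotypic variance is
#' `MS_G / r`. Convenient when only the published F ratios are available.
#'
#' @param f_g Genotype F ratio (MS_G / MS_error).
#' @param n_reps Number of replicates (kept for interface symmetry; the
#'   result does not depend on it).
#' @return Heritability fraction (0 when `f_g <= 1`).
#' @examples
#' 100 * h2_from_f(24.31)  # 95.89
#' @export
h2_from_f <- function(f_g, n_reps = 3) {
  stopifnot(f_g >= 0)
  # route through the variance components so both conventions stay linked
  var_gr <- 1
  var_g <- max((f_g - 1) / n_reps, 0)
  if (var_g == 0) return(0)
  heritability(var_g, var_gr, n_reps, mode = "entry_mean")
}
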