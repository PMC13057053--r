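#' Additive effect needed for a target PVE
#'
#' For a DH population with +/-1 marker coding the variance contributed by a
#' QTL of additive effect `a` is `a^2` (allele frequency 1/2), so the effect
#' giving a target share `p` of the phenotypic variance against background
#' variance `var_other` is `a = sqrt(p/(1-p) * var_other)`.
#'
#' @param pve_pct Target percent variance explained.
#' @param var_other Background (non-QTL) phenotypic variance on the analysis
#'   basis (entry-mean basis: `sigma2_g + sigma2_e / r`).
#' @return Additive effect in trait units.
#' @export
additive_for_pve <- function(pve_pct, var_other) {
  p <- pve_pct / 100
  stopifnot(p > 0, p < 1, var_other > 0)
  sqrt(p / (1 - p) * var_other)
}

#' Simulation configuration for a DH germination study
#'
#' Bundles every parameter of the synthetic study: population and design
#' sizes, the linkage-map template, the planted QTLs, variance components
#' and the germination-time model. The defaults emulate a wheat DH drought /
#' nano-priming germination experiment: 63 lines, 3 replicate dishes of 20
#' seeds scored daily for 12 days under four treatments (C, D, CN, DN), a
#' 3,567-SNP map over 3,150.71 cM ([wheat_map_template()]), planted additive
#' QTLs with PVE in the 3-22 percent range, high entry-mean heritability
#' (about 0.95), and drought shifting germination later and making it less
#' likely, with nano-priming intermediate.
#'
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it.
#' @param n_lines Number of DH lines (default 63).
#' @param n_reps Replicate dishes per genotype x treatment (default 3).
#' @param treatments Subset of `c("C", "D", "CN", "DN")`.
#' @param map_spec Data frame `chrom`, `n_markers`, `length_cM`.
#' @param trait_spec Data frame per seedling trait: `trait`, `mu`, `sg2`
#'   (polygenic variance), `se2` (dish-error variance), and treatment shifts
#'   `t_C`, `t_D`, `t_CN`, `t_DN`.
#' @param qtl_spec Data frame of planted QTLs: `trait`, `chrom`, `pos`, and
#'   per-treatment additive effects `a_C`, `a_D`, `a_CN`, `a_DN` (trait
#'   units; the trait `"GERMDAY"` shifts the germination-day mean instead).
#' @param germ_spec List: `seeds_per_dish`, `n_days`, `mean_day` (named per
#'   treatment, days), `genotype_sd` (between-line SD of the mean day),
#'   `seed_sd` (within-dish per-seed SD), `fail_prob` (named per-treatment
#'   non-germination probability).
#' @param sigma2_rep Replicate (block) variance for the seedling traits.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_lines = 63L,
                       n_reps = 3L,
                       treatments = c("C", "D", "CN", "DN"),
                       map_spec = wheat_map_template(),
                       trait_spec = default_trait_spec(),
                       qtl_spec = default_qtl_spec(),
                       germ_spec = default_germ_spec(),
                       sigma2_rep = 0.01) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  treatments <- match.arg(treatments, several.ok = TRUE)
  if (!all(qtl_spec$chrom %in% map_spec$chrom))
    stop("qtl_spec chromosome(s) not in map_spec")
  len <- map_spec$length_cM[match(qtl_spec$chrom, map_spec$chrom)]
  if (any(qtl_spec$pos < 0 | qtl_spec$pos > len))
    stop("qtl_spec position(s) outside chromosome length")
  if (any(trait_spec$sg2 < 0 | trait_spec$se2 < 0) || sigma2_rep < 0)
    stop("variances must be >= 0")
  if (any(germ_spec$fail_prob < 0 | germ_spec$fail_prob > 1))
    stop("fail_prob must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_lines = as.integer(n_lines),
                 n_reps = as.integer(n_reps), treatments = treatments,
                 map_spec = map_spec, trait_spec = trait_spec,
                 qtl_spec = qtl_spec, germ_spec = germ_spec,
                 sigma2_rep = sigma2_rep),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_trait_spec <- function() {
  data.frame(
    trait = c("FW", "SL", "RL", "RNo"),
    mu = c(0.35, 10, 9, 5),
    sg2 = c(0.004, 4, 4, 0.8),
    se2 = c(0.0006, 0.6, 0.6, 0.12),
    t_C = c(0, 0, 0, 0),
    t_D = c(-0.12, -3.5, 0.5, -1),   # root length gains under drought
    t_CN = c(0.01, 0.3, 0.2, 0.1),
    t_DN = c(-0.08, -2.3, 0.8, -0.6),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_qtl_spec <- function() {
  # entry-mean background variance per trait (sg2 + se2/3) from
  # default_trait_spec(): SL 4.2, FW 0.0042, RNo 0.84
  data.frame(
    trait = c("SL", "FW", "RNo", "GERMDAY"),
    chrom = c("2A", "3B", "1A", "2B"),
    pos = c(85, 102, 111, 168),
    a_C = c(0, 0, 0, 0),
    a_D = c(additive_for_pve(20, 4.2), -additive_for_pve(15, 0.0042), 0, 0.25),
    a_CN = c(0, -additive_for_pve(10, 0.0042), 0, 0),
    a_DN = c(additive_for_pve(10, 4.2), -additive_for_pve(15, 0.0042),
             -additive_for_pve(5, 0.84), 0.15),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_germ_spec <- function() {
  list(seeds_per_dish = 20L, n_days = 12L,
       mean_day = c(C = 3.0, CN = 2.8, D = 5.0, DN = 4.3),
       genotype_sd = 0.6, seed_sd = 1.0,
       fail_prob = c(C = 0.05, CN = 0.04, D = 0.35, DN = 0.25))
}

#' Simulate a linkage map
#'
#' Per chromosome, `n_markers` positions: the first at 0, the last at the
#' chromosome length, the rest uniform and sorted. Deterministic for a fixed
#' seed.
#'
#' @param map_spec Data frame `chrom`, `n_markers`, `length_cM` (or a
#'   `"sim_config"`).
#' @param seed Integer seed.
#' @return A `"genetic_map"` with markers named `<chrom>_m<k>`.
#' @export
simulate_map <- function(map_spec, seed) {
  if (inherits(map_spec, "sim_config")) {
    if (missing(seed)) seed <- map_spec$seed
    map_spec <- map_spec$map_spec
  }
  if (any(map_spec$n_markers < 2 & map_spec$length_cM > 0))
    stop("chromosomes with positive length need >= 2 markers")
  old <- .Random.seed_exists(); set.seed(seed); on.exit(old(), add = TRUE)
  pieces <- lapply(seq_len(nrow(map_spec)), function(i) {
    n <- map_spec$n_markers[i]; len <- map_spec$length_cM[i]
    pos <- if (n == 1) 0 else c(0, sort(stats::runif(n - 2, 0, len)), len)
    data.frame(chrom = map_spec$chrom[i],
               marker = sprintf("%s_m%03d", map_spec$chrom[i], seq_len(n)),
               pos = pos, stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, pieces)
  genetic_map(m$chrom, m$marker, m$pos)
}

#' Simulate DH genotypes along a map
#'
#' One recombinant gamete per line: the first marker of each chromosome is
#' +/-1 with probability 1/2; each subsequent marker flips relative to its
#' neighbour with the Kosambi recombination fraction of the interval.
#' Intervals are independent (no interference beyond the Kosambi marginal
#' r). Doubled haploids carry no heterozygotes.
#'
#' @param map A `"genetic_map"`.
#' @param n_lines Number of lines.
#' @param seed Integer seed.
#' @return Lines x markers matrix of +1/-1, rownames `L001`, ...
#' @export
simulate_dh_genotypes <- function(map, n_lines, seed) {
  old <- .Random.seed_exists(); set.seed(seed); on.exit(old(), add = TRUE)
  n_mark <- nrow(map)
  out <- matrix(0L, n_lines, n_mark,
                dimnames = list(sprintf("L%03d", seq_len(n_lines)), map$marker))
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    pos <- map$pos[idx]
    r <- kosambi(diff(pos), "d_to_r")
    first <- sample(c(-1L, 1L), n_lines, replace = TRUE)
    block <- matrix(0L, n_lines, length(idx))
    block[, 1] <- first
    if (length(idx) > 1) {
      flips <- matrix(stats::runif(n_lines * (length(idx) - 1)), n_lines) <
        matrix(r, n_lines, length(r), byrow = TRUE)
      for (j in 2:length(idx))
        block[, j] <- ifelse(flips[, j - 1], -block[, j - 1], block[, j - 1])
    }
    out[, idx] <- block
  }
  out
}

nearest_marker <- function(map, chrom, pos) {
  mm <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(mm) == 0) stop("no markers on chromosome ", chrom)
  mm$marker[which.min(abs(mm$pos - pos))]
}

#' Simulate replicated seedling phenotypes with planted QTLs
#'
#' Generates `y = mu + t_k + sum_q a_q(t) x_q + polygene_i + rep_j + e_ijk`
#' for every trait in the configuration's `trait_spec`, with
#' `polygene ~ N(0, sg2)`, `rep ~ N(0, sigma2_rep)` and
#' `e ~ N(0, se2)`. QTL effects act through the marker nearest the planted
#' position. Realized per-treatment entry-mean heritability and per-QTL PVE
#' (the R^2 of the line means on the QTL genotype) are returned alongside
#' the data.
#'
#' @param geno Lines x markers +/-1 matrix.
#' @param map The `"genetic_map"` the genotypes follow.
#' @param config A `"sim_config"`.
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return Long data frame `genotype`, `treatment`, `replicate`, `trait`,
#'   `value` with attribute `truth`: list with `qtl` (planted marker,
#'   realized PVE per treatment) and `h2` (realized entry-mean H2 per trait
#'   x treatment).
#' @export
simulate_phenotypes <- function(geno, map, config, seed = config$seed + 1L) {
  old <- .Random.seed_exists(); set.seed(seed); on.exit(old(), add = TRUE)
  n <- nrow(geno); lines <- rownames(geno)
  trts <- config$treatments; reps <- seq_len(config$n_reps)
  ts <- config$trait_spec
  qs <- config$qtl_spec[config$qtl_spec$trait %in% ts$trait, , drop = FALSE]
  qs$marker <- vapply(seq_len(nrow(qs)), function(i)
    nearest_marker(map, qs$chrom[i], qs$pos[i]), character(1))

  rows <- list(); truth_q <- list(); truth_h2 <- list()
  for (ti in seq_len(nrow(ts))) {
    tr <- ts$trait[ti]
    polygene <- stats::rnorm(n, 0, sqrt(ts$sg2[ti]))
    qrows <- qs[qs$trait == tr, , drop = FALSE]
    for (trt in trts) {
      shift <- ts[[paste0("t_", trt)]][ti]
      qeff <- rep(0, n)
      for (qi in seq_len(nrow(qrows))) {
        a <- qrows[[paste0("a_", trt)]][qi]
        if (a != 0) qeff <- qeff + a * geno[, qrows$marker[qi]]
      }
      rep_eff <- stats::rnorm(config$n_reps, 0, sqrt(config$sigma2_rep))
      vals <- matrix(NA_real_, n, config$n_reps)
      for (j in reps)
        vals[, j] <- ts$mu[ti] + shift + qeff + polygene + rep_eff[j] +
          stats::rnorm(n, 0, sqrt(ts$se2[ti]))
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = rep(lines, config$n_reps),
        treatment = trt, replicate = rep(reps, each = n),
        trait = tr, value = as.vector(vals), stringsAsFactors = FALSE)
      # realized quantities on the analysis basis
      lm_means <- rowMeans(vals)
      h2 <- anova_two_way(vals)$h2_entry_mean
      truth_h2[[paste(tr, trt, sep = "_")]] <- h2
      for (qi in seq_len(nrow(qrows))) {
        a <- qrows[[paste0("a_", trt)]][qi]
        if (a != 0) {
          x <- geno[, qrows$marker[qi]]
          pve <- 100 * stats::cor(lm_means, x)^2
          truth_q[[length(truth_q) + 1L]] <- data.frame(
            trait = tr, treatment = trt, chrom = qrows$chrom[qi],
            pos = qrows$pos[qi], marker = qrows$marker[qi], a = a,
            realized_pve = pve, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(
    qtl = if (length(truth_q)) do.call(rbind, truth_q) else NULL,
    h2 = unlist(truth_h2))
  out
}

#' Simulate per-dish germination time-courses
#'
#' Per seed, the germination day is a rounded draw from
#' `N(mean_day[treatment] + line_shift, seed_sd)` truncated to
#' `[1, n_days]`; each seed independently fails to germinate with the
#' treatment's `fail_prob`. Counts are aggregated per dish. With the default
#' configuration drought germinates later and less often than control, with
#' nano-primed treatments intermediate, so that downstream DTI < 100 and
#' reductions > 0 on average.
#'
#' @param config A `"sim_config"`.
#' @param line_shifts Per-line shift (days) of the mean germination day
#'   (positive = slower); default drawn `N(0, genotype_sd)`.
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return Data frame `genotype`, `treatment`, `replicate`, `total_seeds`,
#'   `d1` ... `d<n_days>`.
#' @export
simulate_germination <- function(config, line_shifts = NULL,
                                 seed = config$seed + 2L) {
  old <- .Random.seed_exists(); set.seed(seed); on.exit(old(), add = TRUE)
  gs <- config$germ_spec
  n <- config$n_lines
  lines <- sprintf("L%03d", seq_len(n))
  if (is.null(line_shifts))
    line_shifts <- stats::rnorm(n, 0, gs$genotype_sd)
  if (length(line_shifts) != n) stop("line_shifts must have one entry per line")
  day_cols <- paste0("d", seq_len(gs$n_days))
  out <- list()
  for (trt in config$treatments) {
    for (rep_j in seq_len(config$n_reps)) {
      counts <- matrix(0L, n, gs$n_days)
      for (i in seq_len(n)) {
        germinates <- stats::runif(gs$seeds_per_dish) >= gs$fail_prob[[trt]]
        n_g <- sum(germinates)
        if (n_g > 0) {
          day <- round(stats::rnorm(n_g, gs$mean_day[[trt]] + line_shifts[i],
                                    gs$seed_sd))
          day <- pmin(pmax(day, 1L), gs$n_days)
          tab <- tabulate(day, nbins = gs$n_days)
          counts[i, ] <- tab
        }
      }
      df <- data.frame(genotype = lines, treatment = trt, replicate = rep_j,
                       total_seeds = gs$seeds_per_dish,
                       stringsAsFactors = FALSE)
      df[day_cols] <- as.data.frame(counts)
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}

#' Simulate a complete DH germination study
#'
#' Chains [simulate_map()], [simulate_dh_genotypes()],
#' [simulate_phenotypes()] and [simulate_germination()] into the full set of
#' pipeline inputs, including a germination-day QTL if the configuration
#' plants one (trait `"GERMDAY"`). Fully deterministic for a fixed
#' configuration.
#'
#' @param config A `"sim_config"`.
#' @return List with `map`, `geno`, `germination`, `seedlings` (wide
#'   per-dish table: `fw_g`, `sl_cm`, `rl_cm`, `rno`), `phenotypes` (long)
#'   and `truth` (planted markers, realized PVE and H2, line germination
#'   shifts).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- simulate_map(config$map_spec, config$seed)
  geno <- simulate_dh_genotypes(map, config$n_lines, config$seed + 10L)
  pheno <- simulate_phenotypes(geno, map, config, config$seed + 20L)

  gq <- config$qtl_spec[config$qtl_spec$trait == "GERMDAY", , drop = FALSE]
  old <- .Random.seed_exists(); set.seed(config$seed + 30L)
  shifts <- stats::rnorm(config$n_lines, 0, config$germ_spec$genotype_sd)
  old()
  germ_truth <- NULL
  if (nrow(gq)) {
    mk <- vapply(seq_len(nrow(gq)), function(i)
      nearest_marker(map, gq$chrom[i], gq$pos[i]), character(1))
    for (i in seq_len(nrow(gq)))
      shifts <- shifts + mean(unlist(gq[i, paste0("a_", config$treatments)])) *
        geno[, mk[i]]
    germ_truth <- data.frame(gq, marker = mk, stringsAsFactors = FALSE)
  }
  germ <- simulate_germination(config, shifts, config$seed + 40L)

  wide <- pheno_to_seedlings(pheno)
  list(map = map, geno = geno, germination = germ, seedlings = wide,
       phenotypes = pheno,
       truth = list(qtl = attr(pheno, "truth")$qtl,
                    h2 = attr(pheno, "truth")$h2,
                    germ_qtl = germ_truth, line_shifts = shifts))
}

pheno_to_seedlings <- function(pheno) {
  key_cols <- c("genotype", "treatment", "replicate")
  base <- unique(pheno[key_cols])
  col_map <- c(FW = "fw_g", SL = "sl_cm", RL = "rl_cm", RNo = "rno")
  for (tr in intersect(names(col_map), unique(pheno$trait))) {
    sub <- pheno[pheno$trait == tr, , drop = FALSE]
    m <- match(do.call(paste, base[key_cols]), do.call(paste, sub[key_cols]))
    base[[col_map[[tr]]]] <- sub$value[m]
  }
  if ("rno" %in% names(base)) base$rno <- pmax(round(base$rno), 0)
  rownames(base) <- NULL
  base
}
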