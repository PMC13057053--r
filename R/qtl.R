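#' Kosambi map function
#'
#' Converts between recombination fraction r and map distance d under the
#' Kosambi model of partial crossover interference:
#' `d = 0.25 * ln((1 + 2r) / (1 - 2r))` Morgans, with inverse
#' `r = 0.5 * tanh(2d)`. Distances are expressed in centiMorgans at this
#' interface.
#'
#' @param value Recombination fraction in \[0, 0.5) (`mode = "r_to_d"`) or
#'   map distance in cM >= 0 (`mode = "d_to_r"`). Vectorized.
#' @param mode `"r_to_d"` or `"d_to_r"`.
#' @return Map distance in cM, or recombination fraction.
#' @examples
#' kosambi(0.25, "r_to_d")          # 25 * log(3) ~ 27.465 cM
#' kosambi(kosambi(0.1, "r_to_d"), "d_to_r")  # 0.1
#' @export
kosambi <- function(value, mode = c("r_to_d", "d_to_r")) {
  mode <- match.arg(mode)
  if (mode == "r_to_d") {
    if (any(value < 0 | value >= 0.5))
      stop("recombination fraction must be in [0, 0.5)")
    100 * 0.25 * log((1 + 2 * value) / (1 - 2 * value))
  } else {
    if (any(value < 0)) stop("map distance must be non-negative")
    0.5 * tanh(2 * value / 100)
  }
}

#' Construct a genetic map
#'
#' @param chrom Chromosome names (character), one per marker.
#' @param marker Globally unique marker names.
#' @param pos Positions in cM, non-negative; sorted within chromosome.
#' @return Data frame of class `"genetic_map"` with columns `chrom`,
#'   `marker`, `pos`, ordered by chromosome (input order) then position.
#' @export
genetic_map <- function(chrom, marker, pos) {
  if (anyDuplicated(marker)) stop("duplicate marker name(s)")
  if (any(!is.finite(pos) | pos < 0)) stop("positions must be finite and non-negative")
  chrom <- as.character(chrom)
  ord <- order(chrom, pos, method = "radix")
  out <- data.frame(chrom = chrom[ord], marker = as.character(marker)[ord],
                    pos = as.numeric(pos)[ord], stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Single-marker QTL scan
#'
#' Per-marker least-squares regression of a phenotype on the +/-1 DH
#' genotype code: `y = mu + a x`. For each marker, lines with a missing
#' genotype or phenotype are dropped (pairwise deletion),
#' `LOD = (n/2) log10(SS_total / SS_residual)`,
#' `PVE = 100 (1 - SS_res / SS_tot)` (the regression R^2), and `add` is the
#' fitted slope: half the difference between the two homozygote class means,
#' positive when the +1 (first-parent) allele increases the trait.
#'
#' @param geno Lines x markers matrix coded +1/-1 with `NA` for missing;
#'   column names are marker names, rownames line ids.
#' @param map A `"genetic_map"`; markers absent from `geno` are ignored.
#' @param phenotype Named (or geno-row-ordered) numeric vector of per-line
#'   trait values.
#' @param min_lines Minimum informative lines per marker (default 10).
#' @param lod_ceiling LOD value reported when the residual SS is zero
#'   (default 50).
#' @return Data frame of class `"qtl_scan"` with columns `marker`, `chrom`,
#'   `pos`, `n`, `lod`, `pve`, `add` and attribute `skipped` (markers that
#'   were monomorphic or under-covered).
#' @export
single_marker_scan <- function(geno, map, phenotype, min_lines = 10,
                               lod_ceiling = 50) {
  geno <- as.matrix(geno)
  if (!is.null(names(phenotype)) && !is.null(rownames(geno)))
    phenotype <- phenotype[rownames(geno)]
  if (length(phenotype) != nrow(geno))
    stop("phenotype length does not match number of lines")
  keep <- map$marker %in% colnames(geno)
  map_use <- map[keep, , drop = FALSE]
  X <- geno[, map_use$marker, drop = FALSE]
  ok_y <- !is.na(phenotype)
  X <- X[ok_y, , drop = FALSE]
  y <- phenotype[ok_y]

  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  n_k <- colSums(M)
  sx <- colSums(X0)
  sxx <- colSums(X0^2)
  sy <- crossprod(M, y)[, 1]
  syy <- crossprod(M, y^2)[, 1]
  sxy <- crossprod(X0, y)[, 1]
  sxx_c <- sxx - sx^2 / n_k
  sxy_c <- sxy - sx * sy / n_k
  syy_c <- syy - sy^2 / n_k

  poly_ok <- sxx_c > 1e-12            # both genotype classes present
  usable <- poly_ok & n_k >= min_lines
  add <- lod <- pve <- rep(NA_real_, ncol(X))
  add[usable] <- sxy_c[usable] / sxx_c[usable]
  ss_res <- syy_c[usable] - sxy_c[usable]^2 / sxx_c[usable]
  ss_res <- pmax(ss_res, 0)
  ss_tot <- syy_c[usable]
  l <- ifelse(ss_tot <= 0, 0,
              ifelse(ss_res <= ss_tot * 1e-12, lod_ceiling,
                     (n_k[usable] / 2) * log10(ss_tot / ss_res)))
  lod[usable] <- pmin(l, lod_ceiling)
  pve[usable] <- ifelse(ss_tot <= 0, 0, 100 * (1 - ss_res / ss_tot))

  out <- data.frame(marker = map_use$marker, chrom = map_use$chrom,
                    pos = map_use$pos, n = n_k, lod = lod, pve = pve,
                    add = add, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- map_use$marker[!usable]
  out <- out[usable, , drop = FALSE]
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype across lines `n_perm` times, records the
#' genome-wide maximum LOD of each permuted scan, and returns the empirical
#' `1 - alpha` quantile (type-7 interpolation). Reproducible for a fixed
#' seed.
#'
#' @inheritParams single_marker_scan
#' @param n_perm Number of permutations (>= 100; 1000 is the conventional
#'   choice).
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @param seed Integer seed (required: the threshold is part of the analysis
#'   record).
#' @return The LOD threshold (scalar), with attribute `max_lods` holding the
#'   permutation null distribution.
#' @export
permutation_threshold <- function(geno, map, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed, min_lines = 10,
                                  lod_ceiling = 50) {
  if (missing(seed)) stop("seed is required for permutation_threshold")
  if (n_perm < 100) stop("n_perm must be >= 100")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  max_lods <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(phenotype)
    names(yp) <- names(phenotype)
    sc <- single_marker_scan(geno, map, yp, min_lines = min_lines,
                             lod_ceiling = lod_ceiling)
    if (nrow(sc) == 0) 0 else max(sc$lod)
  }, numeric(1))
  thr <- unname(stats::quantile(max_lods, 1 - alpha, type = 7))
  attr(thr, "max_lods") <- max_lods
  thr
}

# save/restore the RNG state so seeded helpers do not perturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }
}

#' 1-LOD-drop support interval around a peak marker
#'
#' Walks outward from the peak along its chromosome until the LOD profile
#' falls below `peak - drop`; the boundary is linearly interpolated between
#' the last marker above and the first marker below the cut, and truncated
#' at the chromosome ends.
#'
#' @param scan A `"qtl_scan"`.
#' @param peak_marker Marker name of the peak.
#' @param drop LOD units to descend (default 1).
#' @return Numeric `c(ci_left, ci_right)` in cM.
#' @export
support_interval <- function(scan, peak_marker, drop = 1) {
  i <- match(peak_marker, scan$marker)
  if (is.na(i)) stop("peak marker not in scan")
  chr <- scan$chrom[i]
  prof <- scan[scan$chrom == chr, , drop = FALSE]
  prof <- prof[order(prof$pos), , drop = FALSE]
  k <- match(peak_marker, prof$marker)
  cut <- prof$lod[k] - drop

  interp <- function(from, to) {
    # position where the profile crosses `cut` between two markers
    p1 <- prof$pos[from]; p2 <- prof$pos[to]
    l1 <- prof$lod[from]; l2 <- prof$lod[to]
    p1 + (cut - l1) * (p2 - p1) / (l2 - l1)
  }
  left <- prof$pos[1]
  for (j in seq(k, 1)) {
    if (prof$lod[j] < cut) { left <- interp(j + 1, j); break }
  }
  right <- prof$pos[nrow(prof)]
  for (j in seq(k, nrow(prof))) {
    if (prof$lod[j] < cut) { right <- interp(j - 1, j); break }
  }
  c(ci_left = left, ci_right = right)
}

#' Call, merge and classify QTLs from a scan
#'
#' Markers with `lod > threshold` are grouped per chromosome; markers whose
#' 1-LOD support intervals overlap are merged into a single QTL reported at
#' the peak marker. Flanking markers are the map neighbours bracketing the
#' peak. QTLs are classified by the variance they explain: `very_strong`
#' (PVE >= 20), `major` (10 <= PVE < 20), `minor` otherwise. Identifiers
#' follow the `Q<trait>_<env><chrom>` convention (e.g. `QSL_D2A`).
#'
#' @param scan A `"qtl_scan"`.
#' @param threshold LOD threshold; markers must exceed it strictly.
#' @param trait Trait name (without treatment suffix), e.g. `"SL"`.
#' @param environment Treatment code `"C"`, `"D"`, `"CN"` or `"DN"`.
#' @param map Optional `"genetic_map"` supplying neighbours for the flanking
#'   markers (defaults to the scanned markers themselves).
#' @param drop LOD drop for the support intervals (default 1).
#' @return Data frame of class `"qtl_calls"` with columns `qtl`, `trait`,
#'   `chrom`, `pos`, `left_marker`, `right_marker`, `lod`, `pve`, `add`,
#'   `ci_left`, `ci_right`, `environment`, `strength`.
#' @export
call_qtls <- function(scan, threshold, trait, environment = c("C", "D", "CN", "DN"),
                      map = NULL, drop = 1) {
  environment <- match.arg(environment)
  env_label <- c(C = "Control", D = "Drought", CN = "Control and Nano",
                 DN = "Drought and Nano")[[environment]]
  empty <- data.frame(qtl = character(), trait = character(), chrom = character(),
                      pos = numeric(), left_marker = character(),
                      right_marker = character(), lod = numeric(),
                      pve = numeric(), add = numeric(), ci_left = numeric(),
                      ci_right = numeric(), environment = character(),
                      strength = character(), stringsAsFactors = FALSE)
  sig <- scan[!is.na(scan$lod) & scan$lod > threshold, , drop = FALSE]
  if (nrow(sig) == 0) { class(empty) <- c("qtl_calls", "data.frame"); return(empty) }

  calls <- empty
  for (chr in unique(sig$chrom)) {
    sc <- sig[sig$chrom == chr, , drop = FALSE]
    sc <- sc[order(sc$pos), , drop = FALSE]
    ivs <- t(vapply(sc$marker, function(m) support_interval(scan, m, drop),
                    numeric(2)))
    # merge markers with overlapping support intervals into one QTL
    grp <- integer(nrow(sc)); grp[1] <- 1L
    if (nrow(sc) > 1) {
      hi <- ivs[1, 2]
      for (j in 2:nrow(sc)) {
        if (ivs[j, 1] <= hi) { grp[j] <- grp[j - 1] }
        else grp[j] <- grp[j - 1] + 1L
        hi <- max(hi, ivs[j, 2])
      }
    }
    for (gid in unique(grp)) {
      blk <- sc[grp == gid, , drop = FALSE]
      peak <- blk[which.max(blk$lod), ]
      ci <- support_interval(scan, peak$marker, drop)
      fl <- flanking_markers(map %||% scan, peak$marker)
      calls <- rbind(calls, data.frame(
        qtl = paste0("Q", trait, "_", environment, chr),
        trait = trait, chrom = chr, pos = peak$pos,
        left_marker = fl[1], right_marker = fl[2],
        lod = peak$lod, pve = peak$pve, add = peak$add,
        ci_left = unname(ci[1]), ci_right = unname(ci[2]),
        environment = env_label,
        strength = classify_qtl(peak$pve),
        stringsAsFactors = FALSE))
    }
  }
  rownames(calls) <- NULL
  class(calls) <- c("qtl_calls", "data.frame")
  calls
}

#' Classify QTL strength from the variance explained
#'
#' `very_strong` for PVE >= 20 percent, `major` for 10 <= PVE < 20,
#' `minor` below 10.
#'
#' @param pve Percent variance explained (vectorized).
#' @return Character vector.
#' @export
classify_qtl <- function(pve) {
  ifelse(pve >= 20, "very_strong", ifelse(pve >= 10, "major", "minor"))
}

flanking_markers <- function(map, peak_marker) {
  i <- match(peak_marker, map$marker)
  chr <- map$chrom[i]
  mm <- map[map$chrom == chr, , drop = FALSE]
  mm <- mm[order(mm$pos), , drop = FALSE]
  k <- match(peak_marker, mm$marker)
  c(mm$marker[max(k - 1, 1)], mm$marker[min(k + 1, nrow(mm))])
}

#' Linkage-map summary with genome-group rollups
#'
#' Per chromosome: marker count, map length (position of the last marker,
#' cM) and density (markers per cM). Chromosomes are grouped into the A/B/D
#' sub-genomes by the final letter of their name; for each group and for the
#' whole map the summary reports summed counts, summed lengths and -- by the
#' reporting convention used for dense wheat DH maps -- a rollup density
#' equal to the *sum of the unrounded per-chromosome densities*. The
#' markers-per-cM ratio (`count / length`) is also provided for every row as
#' `density_ratio`.
#'
#' @param map A `"genetic_map"` or data frame with `chrom`, `marker`, `pos`;
#'   alternatively a template with columns `chrom`, `n_markers`,
#'   `length_cM`.
#' @param rollup_density `"sum"` (default, the wheat-report convention) or
#'   `"ratio"` for `sum(count)/sum(length)` in the `density` column of
#'   rollup rows.
#' @return Data frame with columns `chrom`, `n_markers`, `length_cM`,
#'   `density`, `density_ratio` and a final block of rollup rows
#'   (`A genome`, `B genome`, `D genome`, `Total`).
#' @examples
#' map_summary(wheat_map_template())
#' @export
map_summary <- function(map, rollup_density = c("sum", "ratio")) {
  rollup_density <- match.arg(rollup_density)
  if (all(c("n_markers", "length_cM") %in% names(map))) {
    per <- data.frame(chrom = as.character(map$chrom),
                      n_markers = map$n_markers,
                      length_cM = map$length_cM, stringsAsFactors = FALSE)
  } else {
    agg_n <- tapply(map$marker, map$chrom, length)
    agg_l <- tapply(map$pos, map$chrom, max)
    chroms <- unique(as.character(map$chrom))
    per <- data.frame(chrom = chroms,
                      n_markers = as.integer(agg_n[chroms]),
                      length_cM = as.numeric(agg_l[chroms]),
                      stringsAsFactors = FALSE)
  }
  per$density <- ifelse(per$length_cM > 0, per$n_markers / per$length_cM, NA)
  per$density_ratio <- per$density

  genome <- toupper(substr(per$chrom, nchar(per$chrom), nchar(per$chrom)))
  roll_one <- function(rows, label) {
    dens_sum <- sum(rows$density, na.rm = TRUE)
    dens_ratio <- sum(rows$n_markers) / sum(rows$length_cM)
    data.frame(chrom = label, n_markers = sum(rows$n_markers),
               length_cM = sum(rows$length_cM),
               density = if (rollup_density == "sum") dens_sum else dens_ratio,
               density_ratio = dens_ratio, stringsAsFactors = FALSE)
  }
  rolls <- do.call(rbind, lapply(intersect(c("A", "B", "D"), genome), function(gg)
    roll_one(per[genome == gg, , drop = FALSE], paste(gg, "genome"))))
  total <- roll_one(per, "Total")
  out <- rbind(per, rolls, total)
  rownames(out) <- NULL
  out
}

#' Reference linkage-map layout for a wheat DH population
#'
#' The 21-chromosome SNP map layout used as the default simulation template:
#' 3,567 markers over 3,150.71 cM across the A, B and D sub-genomes of
#' hexaploid wheat. Marker counts range from 4 (4D) to 373 (1B).
#'
#' @return Data frame with columns `chrom`, `n_markers`, `length_cM` (21
#'   rows).
#' @examples
#' sum(wheat_map_template()$n_markers)  # 3567
#' @export
wheat_map_template <- function() {
  data.frame(
    chrom = c("1A", "1B", "1D", "2A", "2B", "2D", "3A", "3B", "3D",
              "4A", "4B", "4D", "5A", "5B", "5D", "6A", "6B", "6D",
              "7A", "7B", "7D"),
    n_markers = c(143L, 373L, 127L, 266L, 320L, 85L, 179L, 103L, 22L,
                  88L, 173L, 4L, 316L, 299L, 33L, 230L, 247L, 67L,
                  225L, 240L, 27L),
    length_cM = c(177.29, 144.39, 94.39, 281.13, 200.77, 111.91, 199.84,
                  174.65, 45.19, 163.54, 131.02, 22.23, 258.94, 200.54,
                  67.04, 173.31, 136.15, 14.54, 270.24, 184.26, 99.34),
    stringsAsFactors = FALSE)
}
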