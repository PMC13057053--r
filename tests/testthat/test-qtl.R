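test_that("Kosambi transforms satisfy the closed form and round trip", {
  expect_equal(kosambi(0, "r_to_d"), 0)
  expect_equal(kosambi(0.25, "r_to_d"), 25 * log(3))
  # saturation: large distances approach r = 0.5
  expect_lt(abs(kosambi(200, "d_to_r") - 0.5), 1e-3)
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(kosambi(kosambi(r, "r_to_d"), "d_to_r"), r, tolerance = 1e-12)
  d <- seq(0, 150, by = 5)
  expect_equal(kosambi(kosambi(d, "d_to_r"), "r_to_d"), d, tolerance = 1e-9)
  expect_error(kosambi(0.5, "r_to_d"), "0.5")
  expect_error(kosambi(-1, "d_to_r"), "non-negative")
})

test_that("single-marker regression matches hand least squares and lm", {
  map <- genetic_map("1A", "m1", 0)
  g <- matrix(c(1, 1, -1, -1), 4, 1, dimnames = list(paste0("L", 1:4), "m1"))
  y <- c(2, 1, 0, 1)
  sc <- single_marker_scan(g, map, y, min_lines = 2)
  expect_equal(sc$add, 0.5)
  expect_equal(sc$lod, 2 * log10(2))
  expect_equal(sc$pve, 50)
  # constant phenotype: null scan
  sc0 <- single_marker_scan(g, map, rep(3, 4), min_lines = 2)
  expect_equal(sc0$lod, 0)
  expect_equal(sc0$pve, 0)
  # flipping codes negates the additive effect only
  scf <- single_marker_scan(-g, map, y, min_lines = 2)
  expect_equal(scf$add, -sc$add)
  expect_equal(scf$lod, sc$lod)
  expect_equal(scf$pve, sc$pve)
})

test_that("vectorized scan agrees with per-marker lm under missing data", {
  set.seed(101)
  cfg_map <- simulate_map(small_map_spec(2, 30), seed = 5)
  g <- simulate_dh_genotypes(cfg_map, 40, seed = 6)
  g[sample(length(g), 100)] <- NA
  y <- rnorm(40) + 0.8 * ifelse(is.na(g[, 10]), 0, g[, 10])
  names(y) <- rownames(g)
  sc <- single_marker_scan(g, cfg_map, y)
  for (mk in sample(sc$marker, 12)) {
    x <- g[, mk]
    ok <- !is.na(x)
    fit <- stats::lm(y[ok] ~ x[ok])
    n <- sum(ok)
    r2 <- summary(fit)$r.squared
    row <- sc[sc$marker == mk, ]
    expect_equal(row$add, unname(stats::coef(fit)[2]), tolerance = 1e-9)
    expect_equal(row$pve, 100 * r2, tolerance = 1e-9)
    expect_equal(row$lod, (n / 2) * log10(1 / (1 - r2)), tolerance = 1e-9)
    expect_equal(row$n, n)
  }
  # definitional LOD-PVE link on every record
  expect_equal(sc$pve, 100 * (1 - 10^(-2 * sc$lod / sc$n)), tolerance = 1e-9)
})

test_that("scan output is invariant to line and marker ordering", {
  set.seed(102)
  map <- simulate_map(small_map_spec(2, 25), seed = 7)
  g <- simulate_dh_genotypes(map, 30, seed = 8)
  y <- stats::setNames(rnorm(30), rownames(g))
  sc1 <- single_marker_scan(g, map, y)
  rp <- sample(nrow(g)); cp <- sample(ncol(g))
  sc2 <- single_marker_scan(g[rp, cp], map, y[rp])
  sc2 <- sc2[match(sc1$marker, sc2$marker), ]
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-12)
  expect_equal(sc1$add, sc2$add, tolerance = 1e-12)
})

test_that("monomorphic and under-covered markers are skipped with a record", {
  map <- genetic_map(c("1A", "1A"), c("m1", "m2"), c(0, 10))
  g <- cbind(m1 = c(1, 1, 1, 1), m2 = c(1, -1, 1, -1))
  rownames(g) <- paste0("L", 1:4)
  sc <- single_marker_scan(g, map, c(1, 2, 3, 4), min_lines = 2)
  expect_equal(sc$marker, "m2")
  expect_equal(attr(sc, "skipped"), "m1")
})

test_that("permutation threshold is deterministic and null for flat data", {
  map <- simulate_map(small_map_spec(1, 20), seed = 9)
  g <- simulate_dh_genotypes(map, 30, seed = 10)
  y <- stats::setNames(rnorm(30), rownames(g))
  t1 <- permutation_threshold(g, map, y, n_perm = 100, seed = 42)
  t2 <- permutation_threshold(g, map, y, n_perm = 100, seed = 42)
  expect_equal(as.numeric(t1), as.numeric(t2))
  expect_length(attr(t1, "max_lods"), 100)
  yc <- stats::setNames(rep(1, 30), rownames(g))
  t0 <- permutation_threshold(g, map, yc, n_perm = 100, seed = 43)
  expect_equal(as.numeric(t0), 0)
  expect_error(permutation_threshold(g, map, y, n_perm = 50, seed = 1), "100")
  expect_error(permutation_threshold(g, map, y, n_perm = 100), "seed")
})

test_that("support intervals interpolate the LOD-drop crossing", {
  # piecewise-linear profile around a peak at 50 cM
  scan <- data.frame(marker = paste0("m", 1:5), chrom = "1A",
                     pos = c(10, 30, 50, 70, 90), n = 60,
                     lod = c(0.5, 2, 4, 2, 0.5), pve = 10, add = 1)
  class(scan) <- c("qtl_scan", "data.frame")
  ci <- support_interval(scan, "m3", drop = 1)
  # cut at 3: crossing between (30,2) and (50,4) -> 40; symmetric right -> 60
  expect_equal(unname(ci), c(40, 60))
  # symmetric profile gives a symmetric interval
  expect_equal(50 - ci[["ci_left"]], ci[["ci_right"]] - 50)
  # truncation at the chromosome ends
  ci2 <- support_interval(scan, "m3", drop = 10)
  expect_equal(unname(ci2), c(10, 90))
  # single-marker chromosome: degenerate interval at the marker
  s1 <- data.frame(marker = "s1", chrom = "2A", pos = 5, n = 60,
                   lod = 3, pve = 10, add = 1)
  scan2 <- rbind(scan, s1)
  class(scan2) <- c("qtl_scan", "data.frame")
  expect_equal(unname(support_interval(scan2, "s1")), c(5, 5))
})

test_that("QTL calling merges overlapping intervals and classifies by PVE", {
  lod <- c(0.2, 2.6, 3.0, 2.7, 0.2, 0.1, 2.2, 0.3)
  scan <- data.frame(marker = paste0("m", 1:8), chrom = rep(c("1A", "2B"), c(5, 3)),
                     pos = c(0, 10, 11, 12, 40, 0, 20, 40), n = 60,
                     lod = lod, pve = 100 * (1 - 10^(-2 * lod / 60)), add = 0.5)
  class(scan) <- c("qtl_scan", "data.frame")
  calls <- call_qtls(scan, threshold = 2, trait = "SL", environment = "D")
  # three significant markers 1-2 cM apart merge into one QTL; 2B separate
  expect_equal(nrow(calls), 2)
  expect_equal(calls$qtl, c("QSL_D1A", "QSL_D2B"))
  expect_equal(calls$pos[1], 11)
  expect_equal(calls$left_marker[1], "m2")
  expect_equal(calls$right_marker[1], "m4")
  expect_true(all(calls$ci_left <= calls$pos & calls$pos <= calls$ci_right))
  expect_equal(calls$environment[1], "Drought")
  # nothing above threshold -> empty frame with the full schema
  none <- call_qtls(scan, threshold = 10, trait = "SL", environment = "C")
  expect_equal(nrow(none), 0)
  expect_true(all(c("qtl", "strength", "ci_left") %in% names(none)))
  # classification boundaries
  expect_equal(classify_qtl(c(21.72, 19.9, 20, 10, 9.99, 3.44)),
               c("very_strong", "major", "very_strong", "major", "minor", "minor"))
})

test_that("map summary reproduces per-chromosome and rollup arithmetic", {
  tmpl <- wheat_map_template()
  ms <- map_summary(tmpl)
  expect_equal(nrow(ms), 25)  # 21 chromosomes + 3 genomes + total
  expect_equal(round(ms$density[ms$chrom == "1B"], 2), 2.58)
  a <- ms[ms$chrom == "A genome", ]
  expect_equal(a$n_markers, 1447)
  expect_equal(a$length_cM, 1524.29)
  expect_equal(round(a$density, 2), 6.57)
  tot <- ms[ms$chrom == "Total", ]
  expect_equal(tot$n_markers, 3567)
  expect_equal(tot$length_cM, 3150.71)
  expect_equal(round(tot$density, 2), 25.41)
  # ratio convention stays available
  ms2 <- map_summary(tmpl, rollup_density = "ratio")
  expect_equal(ms2$density[ms2$chrom == "Total"], 3567 / 3150.71)
  # simple case from positions rather than a template
  map <- genetic_map(rep("1A", 10), paste0("m", 1:10), seq(0, 100, length.out = 10))
  ms3 <- map_summary(map)
  expect_equal(ms3$density[1], 0.10)
})
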