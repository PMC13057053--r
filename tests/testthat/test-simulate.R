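test_that("simulated maps honour the template and the seed", {
  map <- simulate_map(wheat_map_template(), seed = 1)
  expect_equal(nrow(map), 3567)
  expect_equal(sum(tapply(map$pos, map$chrom, max)), 3150.71)
  # per chromosome: first marker at 0, last at the specified length, sorted
  for (chr in c("1B", "4D", "7D")) {
    p <- map$pos[map$chrom == chr]
    expect_equal(p[1], 0)
    expect_equal(p[length(p)],
                 wheat_map_template()$length_cM[wheat_map_template()$chrom == chr])
    expect_true(!is.unsorted(p))
  }
  expect_identical(map, simulate_map(wheat_map_template(), seed = 1))
  expect_false(identical(map, simulate_map(wheat_map_template(), seed = 2)))
  tiny <- simulate_map(data.frame(chrom = "1A", n_markers = 2L, length_cM = 50),
                       seed = 3)
  expect_equal(tiny$pos, c(0, 50))
  expect_error(simulate_map(data.frame(chrom = "1A", n_markers = 1L,
                                       length_cM = 50), seed = 3), ">= 2")
})

test_that("DH genotypes are homozygous with Kosambi-linked neighbours", {
  map <- genetic_map(rep("1A", 3), c("a", "b", "c"), c(0, 0, 1000))
  g <- simulate_dh_genotypes(map, 400, seed = 4)
  expect_true(all(g %in% c(-1L, 1L)))
  # zero-cM interval: always identical
  expect_equal(g[, "a"], g[, "b"])
  # 1000-cM interval: flip probability ~ 0.5
  flip <- mean(g[, "b"] != g[, "c"])
  expect_lt(abs(flip - 0.5), 3 * sqrt(0.25 / 400))
  # allele frequency ~ 0.5 at every marker
  map2 <- simulate_map(small_map_spec(2, 20), seed = 5)
  g2 <- simulate_dh_genotypes(map2, 500, seed = 6)
  freq <- colMeans(g2 == 1)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 500)))
  # short intervals flip at close to the Kosambi rate
  map3 <- genetic_map(rep("1A", 2), c("x", "y"), c(0, 10))
  g3 <- simulate_dh_genotypes(map3, 4000, seed = 7)
  r_expect <- kosambi(10, "d_to_r")
  r_obs <- mean(g3[, 1] != g3[, 2])
  expect_lt(abs(r_obs - r_expect), 3 * sqrt(r_expect * (1 - r_expect) / 4000))
})

test_that("phenotypes degenerate to the QTL signal when variances vanish", {
  map <- simulate_map(data.frame(chrom = "2A", n_markers = 10L, length_cM = 281),
                      seed = 8)
  g <- simulate_dh_genotypes(map, 20, seed = 9)
  ts <- data.frame(trait = "SL", mu = 10, sg2 = 0, se2 = 0,
                   t_C = 0, t_D = 0, t_CN = 0, t_DN = 0)
  qs <- data.frame(trait = "SL", chrom = "2A", pos = 100,
                   a_C = 1, a_D = 1, a_CN = 1, a_DN = 1)
  cfg <- sim_config(seed = 10, n_lines = 20,
                    map_spec = data.frame(chrom = "2A", n_markers = 10L,
                                          length_cM = 281),
                    trait_spec = ts, qtl_spec = qs, sigma2_rep = 0)
  ph <- simulate_phenotypes(g, map, cfg)
  mk <- attr(ph, "truth")$qtl$marker[1]
  x <- g[ph$genotype[ph$trait == "SL" & ph$treatment == "C" & ph$replicate == 1], mk]
  y <- ph$value[ph$trait == "SL" & ph$treatment == "C" & ph$replicate == 1]
  expect_equal(y, unname(10 + x))
})

test_that("germination counts respect the dish geometry and failure model", {
  cfg <- sim_config(seed = 11, n_lines = 10,
                    map_spec = small_map_spec(4, 10) |>
                      transform(chrom = c("2A", "3B", "1A", "2B"),
                                length_cM = c(281.13, 174.65, 177.29, 200.77)))
  germ <- simulate_germination(cfg)
  day_cols <- paste0("d", 1:12)
  expect_true(all(rowSums(germ[day_cols]) <= germ$total_seeds))
  expect_true(all(as.matrix(germ[day_cols]) >= 0))
  expect_equal(nrow(germ), 10 * 4 * 3)
  # deterministic for fixed seed
  expect_identical(germ, simulate_germination(cfg))
  # zero spread, fixed mean day: everything on day 3
  cfg2 <- cfg
  cfg2$germ_spec$seed_sd <- 0
  cfg2$germ_spec$genotype_sd <- 0
  cfg2$germ_spec$mean_day <- c(C = 3, CN = 3, D = 3, DN = 3)
  cfg2$germ_spec$fail_prob <- c(C = 0, CN = 0, D = 0, DN = 0)
  g2 <- simulate_germination(cfg2, line_shifts = rep(0, 10))
  expect_true(all(g2$d3 == 20))
  expect_true(all(g2[setdiff(day_cols, "d3")] == 0))
  # total failure: nothing germinates
  cfg3 <- cfg
  cfg3$germ_spec$fail_prob <- c(C = 1, CN = 1, D = 1, DN = 1)
  g3 <- simulate_germination(cfg3)
  expect_true(all(g3[day_cols] == 0))
})

test_that("the default study plants drought-ordered germination behaviour", {
  ord_ok <- replicate(20, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(seed = seed, n_lines = 15,
                      map_spec = data.frame(chrom = c("2A", "3B", "1A", "2B"),
                                            n_markers = 15L,
                                            length_cM = c(281.13, 174.65,
                                                          177.29, 200.77)))
    st <- simulate_study(cfg)
    tt <- suppressWarnings(assemble_trait_table(st$germination, st$seedlings))
    m <- trait_matrix(tt)
    c(mean(m[, "MGT_C"], na.rm = TRUE) < mean(m[, "MGT_DN"], na.rm = TRUE),
      mean(m[, "MGT_DN"], na.rm = TRUE) < mean(m[, "MGT_D"], na.rm = TRUE),
      mean(m[, "FWDTI_D"], na.rm = TRUE) < 100,
      mean(m[, "RFW_D"], na.rm = TRUE) > 0)
  })
  # planted ordering control < nano-drought < drought recovered by majority
  expect_true(all(rowMeans(ord_ok) > 0.5))
})

test_that("simulate_study is fully reproducible and reports truth", {
  cfg <- sim_config(seed = 12, n_lines = 20,
                    map_spec = data.frame(chrom = c("2A", "3B", "1A", "2B"),
                                          n_markers = 20L,
                                          length_cM = c(281.13, 174.65,
                                                        177.29, 200.77)))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$germination, s2$germination)
  expect_identical(s1$seedlings, s2$seedlings)
  expect_true(all(c("qtl", "h2", "germ_qtl", "line_shifts") %in% names(s1$truth)))
  expect_true(all(s1$truth$qtl$realized_pve >= 0 &
                    s1$truth$qtl$realized_pve <= 100))
  expect_true(all(s1$truth$h2 >= 0 & s1$truth$h2 <= 1))
})
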