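test_that("a fixed seed makes every generator bit-identical", {
  a <- simulate_f2_cross(cross_config(n_f2 = 60, n_markers = 8, seed = 9))
  b <- simulate_f2_cross(cross_config(n_f2 = 60, n_markers = 8, seed = 9))
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$trait_genotype, b$trait_genotype)

  p1 <- simulate_breed_panel(panel_config(seed = 9))
  p2 <- simulate_breed_panel(panel_config(seed = 9))
  expect_identical(p1$genotypes$geno, p2$genotypes$geno)
  expect_identical(p1$truth$interval, p2$truth$interval)

  c1 <- simulate_pool_counts(pool_config(seed = 9))
  c2 <- simulate_pool_counts(pool_config(seed = 9))
  expect_identical(c1$alt, c2$alt)

  e1 <- simulate_aei_table(seed = 9)
  e2 <- simulate_aei_table(seed = 9)
  expect_identical(e1, e2)
  expect_false(identical(simulate_aei_table(seed = 1)$major_fraction,
                         simulate_aei_table(seed = 2)$major_fraction))
})

test_that("child seeds are deterministic, distinct and in range", {
  expect_identical(child_seed(1, "pool"), child_seed(1, "pool"))
  expect_false(child_seed(1, "pool") == child_seed(1, "panel"))
  expect_false(child_seed(1, "pool") == child_seed(2, "pool"))
  s <- vapply(1:50, function(i) child_seed(i, "x"), integer(1))
  expect_true(all(s >= 0 & s < 2^31 - 1))
})

test_that("unlinked markers segregate independently at 1:2:1", {
  x <- simulate_f2_cross(cross_config(n_f2 = 10000, n_markers = 4,
                                      marker_spacing_cM = Inf, seed = 31))
  g <- x$genotypes$geno
  # marginal genotype classes ~ 1/4 : 1/2 : 1/4
  for (j in 1:4) {
    gof <- chisq.test(table(factor(g[, j], levels = 0:2)),
                      p = c(.25, .5, .25))
    expect_gt(gof$p.value, 1e-4)
  }
  # independence between marker pairs: genotype correlation ~ 0
  for (j in 2:4) expect_lt(abs(cor(g[, 1], g[, j])), 3.5 / sqrt(nrow(g)))
  expect_true(all(x$theta_true == 0.5))
})

test_that("a marker on top of the trait locus cosegregates perfectly", {
  x <- simulate_f2_cross(cross_config(n_f2 = 229, n_markers = 12,
                                      causal_index = 5, seed = 17))
  expect_equal(unname(x$theta_true["M05"]), 0)
  cases <- x$genotypes$geno[x$genotypes$individuals$phenotype == "case", ]
  expect_true(all(cases[, 5] == 2L))
  expect_true(all(x$trait_genotype[
    x$genotypes$individuals$phenotype == "case"] == 2L))
})

test_that("case counts follow Binomial(n, 1/4) under full penetrance", {
  lo <- qbinom(0.005, 229, 0.25)
  hi <- qbinom(0.995, 229, 0.25)
  outside <- vapply(1:200, function(s) {
    x <- simulate_f2_cross(cross_config(n_f2 = 229, n_markers = 2, seed = s))
    n_case <- sum(x$genotypes$individuals$phenotype == "case")
    n_case < lo || n_case > hi
  }, logical(1))
  # nominal exceedance of the central 99% interval is ~1%
  expect_lte(mean(outside), 0.05)
  # penetrance 0 produces no cases at all
  x0 <- simulate_f2_cross(cross_config(n_f2 = 100, n_markers = 2,
                                       penetrance = 0, seed = 1))
  expect_equal(sum(x0$genotypes$individuals$phenotype == "case"), 0)
})

test_that("genotyping error and missingness hit at the stated rates", {
  x <- simulate_f2_cross(cross_config(n_f2 = 2000, n_markers = 10,
                                      missing_rate = 0.1, seed = 23))
  miss <- mean(is.na(x$genotypes$geno))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("breed panel without erosion plants the exact shared interval", {
  cfg <- panel_config(n_cases = 10, n_controls = 10, erosion_cM = 0, seed = 3)
  p <- simulate_breed_panel(cfg)
  expect_equal(p$truth$interval$start, cfg$shared_interval$start)
  expect_equal(p$truth$interval$end, cfg$shared_interval$end)
  inside <- p$genotypes$map$pos >= cfg$shared_interval$start &
    p$genotypes$map$pos <= cfg$shared_interval$end
  cases <- p$genotypes$geno[p$genotypes$individuals$phenotype == "case", ]
  expect_true(all(cases[, inside] == 2L))
})

test_that("a single case's homozygous run is the recoverable truth", {
  p <- simulate_breed_panel(panel_config(n_cases = 1, n_controls = 0,
                                         seed = 41))
  blocks <- shared_homozygous_blocks(p$genotypes)
  spans <- vapply(blocks, function(b)
    c(b$interval$start, b$interval$end), numeric(2))
  covering <- which(spans[1, ] <= p$truth$causal_pos &
                      spans[2, ] >= p$truth$causal_pos)
  expect_equal(length(covering), 1)
  # the covering block spans at least every marker inside the eroded truth
  inside <- markers_in_interval(p$genotypes$map, p$truth$interval)
  expect_true(all(inside$pos >= spans[1, covering] &
                    inside$pos <= spans[2, covering]))
})

test_that("panel config rejects inconsistent geometry", {
  expect_error(panel_config(shared_interval = genomic_interval("3", 1, 10)),
               "outside")
  expect_error(panel_config(causal_pos = 1), "causal")
  expect_error(panel_config(background_freq = c(0.5, 0.5)), "background_freq")
})

test_that("pool counts: fixation inside the planted interval, flags elsewhere", {
  pc <- simulate_pool_counts(pool_config(seed = 8))
  fx <- attr(pc, "truth")
  inside <- pc$pos >= fx$start & pc$pos <= fx$end
  expect_true(all(pc$ref[inside] == 0))   # alt reads = coverage when p = 1

  # near-zero coverage: sites are flagged undefined, not frequency 0
  thin <- simulate_pool_counts(pool_config(mean_coverage = 0.1, seed = 8))
  v <- site_vaf(thin)
  expect_gt(sum(!v$defined), nrow(thin) * 0.9)
  expect_true(all(is.na(v$vaf[!v$defined])))
})

test_that("background VAF concentrates on the simulated frequency", {
  cfg <- pool_config(n_sites = 10000,
                     region = genomic_interval("3", 1, 10000000),
                     fixed_interval = genomic_interval("3", 20000000, 20000001),
                     bg_shape1 = 5e5, bg_shape2 = 5e5,  # frequency ~ 0.5
                     mean_coverage = 30, seed = 12)
  v <- site_vaf(simulate_pool_counts(cfg))
  vaf <- v$vaf[v$defined]
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.5), 3 * se)
})

test_that("expression generators honour SD 0 and pairing structure", {
  ct <- simulate_ct_table(data.frame(group = "g", target_mean = 24,
                                     target_sd = 0, ref_mean = 18,
                                     ref_sd = 0, n = 4), seed = 2)
  expect_true(all(ct$ct[ct$gene == "target"] == 24))
  expect_true(all(ct$ct[ct$gene == "reference"] == 18))

  aei <- simulate_aei_table(n = 6, gdna_sd = 0, cdna_sd = 0, seed = 2)
  expect_equal(sort(unique(aei$major_fraction)), c(0.5, 0.65))
  expect_equal(sum(aei$template == "gDNA"), 6)
  expect_setequal(aei$id[aei$template == "gDNA"],
                  aei$id[aei$template == "cDNA"])

  lum <- simulate_luciferase_table(cv = 0, seed = 2)
  act <- luciferase_fold(lum)$activity
  expect_equal(act$mean[act$construct == "H"], 46, tolerance = 1e-9)
  expect_equal(act$sd[act$construct == "H"], 0, tolerance = 1e-9)
})
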