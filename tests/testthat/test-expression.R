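two_group_ct <- function(case_target = 25, seed = 1, n = 7, sd = 0.3) {
  simulate_ct_table(data.frame(group = c("HH", "hh"),
                               target_mean = c(24, case_target),
                               target_sd = sd,
                               ref_mean = 18, ref_sd = sd,
                               n = n), seed = seed)
}

test_that("ddCt: identical groups give fold 1 and p = 1", {
  ct <- two_group_ct(case_target = 24, sd = 0.4, seed = 5)
  # make the hh group's dCt values literally identical to HH's
  ct$ct[ct$group == "hh"] <- ct$ct[ct$group == "HH"]
  res <- ddct_fold_change(ct, reference_group = "HH")
  expect_equal(res$groups$fold, c(1, 1))
  expect_equal(res$groups$p_value[res$groups$group == "hh"], 1)
})

test_that("ddCt: +1 target cycle halves the fold change", {
  ct <- two_group_ct(case_target = 25, sd = 0, seed = 2)
  res <- ddct_fold_change(ct, reference_group = "HH")
  expect_equal(res$groups$fold[res$groups$group == "hh"], 0.5)
  expect_equal(res$groups$fold[res$groups$group == "HH"], 1)
})

test_that("ddCt: the reference group's fold is 1 for any data", {
  set.seed(61)
  for (rep in 1:5) {
    ct <- two_group_ct(case_target = runif(1, 20, 30), sd = runif(1, 0, 1),
                       seed = rep)
    res <- ddct_fold_change(ct, reference_group = "HH")
    expect_identical(res$groups$fold[res$groups$group == "HH"], 1)
  }
})

test_that("ddCt recovers a true 0.4-fold reduction", {
  # fold 0.4 = 2^-ddCt  =>  case target Ct higher by log2(1/0.4)
  shift <- log2(1 / 0.4)
  folds <- vapply(1:100, function(s) {
    ct <- two_group_ct(case_target = 24 + shift, sd = 0.3, seed = 200 + s)
    res <- ddct_fold_change(ct, reference_group = "HH")
    res$groups$fold[res$groups$group == "hh"]
  }, numeric(1))
  expect_gt(mean(folds), 0.3)
  expect_lt(mean(folds), 0.53)
})

test_that("ddCt flags tiny groups and absent references", {
  ct <- two_group_ct(seed = 3)
  ct <- ct[!(ct$group == "hh" & ct$id != "hh_01"), ]
  res <- ddct_fold_change(ct, reference_group = "HH")
  expect_true(is.na(res$groups$p_value[res$groups$group == "hh"]))
  expect_error(ddct_fold_change(ct, reference_group = "XX"), "reference group")
})

test_that("AEI: no imbalance when cDNA mirrors gDNA", {
  aei <- simulate_aei_table(n = 8, cdna_mean = 0.5, cdna_sd = 0,
                            gdna_mean = 0.5, gdna_sd = 0, seed = 4)
  res <- aei_test(aei)
  expect_equal(res$within$p_value, 1)
  expect_equal(res$within$n_pairs, 8)
})

test_that("AEI: a cDNA shift is detected and is complement-invariant", {
  aei <- simulate_aei_table(n = 11, seed = 9)   # 0.65 vs 0.50
  res <- aei_test(aei)
  expect_lt(res$within$p_value, 0.001)
  flipped <- aei
  flipped$major_fraction <- 1 - flipped$major_fraction
  res2 <- aei_test(flipped)
  expect_equal(res2$within$p_value, res$within$p_value)
})

test_that("AEI: unpaired individuals are dropped with a warning; one genotype has no between test", {
  aei <- simulate_aei_table(n = 6, seed = 10)
  aei <- aei[!(aei$id == "het_03" & aei$template == "cDNA"), ]
  expect_warning(res <- aei_test(aei), "unpaired")
  expect_equal(res$within$n_pairs, 5)
  expect_null(res$between)
})

test_that("AEI: between-genotype cDNA comparison for multiple genotypes", {
  het <- simulate_aei_table(n = 8, seed = 11, genotype = "H/h")
  hom <- simulate_aei_table(n = 8, cdna_mean = 0.5, cdna_sd = 0.02,
                            seed = 12, genotype = "H/H")
  res <- aei_test(rbind(het, hom))
  expect_equal(nrow(res$between), 1)
  expect_lt(res$between$p_value, 0.01)
})

test_that("luciferase: reference-equal constructs score activity 1 +/- 0", {
  lum <- simulate_luciferase_table(activities = c("pGL3-Basic" = 1,
                                                  "same" = 1),
                                   cv = 0, seed = 13)
  res <- luciferase_fold(lum)
  act <- res$activity[res$activity$construct == "same", ]
  expect_equal(act$mean, 1)
  expect_equal(act$sd, 0)
})

test_that("luciferase: replicate order and per-repeat rescaling do not matter", {
  lum <- simulate_luciferase_table(seed = 14)
  res1 <- luciferase_fold(lum)
  shuffled <- lum[sample(nrow(lum)), ]
  res2 <- luciferase_fold(shuffled)
  expect_equal(res1$activity, res2$activity)

  scaled <- lum
  one_rep <- scaled$bio_rep == 2
  scaled$firefly[one_rep] <- scaled$firefly[one_rep] * 7.3
  scaled$renilla[one_rep] <- scaled$renilla[one_rep] * 7.3
  res3 <- luciferase_fold(scaled)
  expect_equal(res1$activity, res3$activity)
})

test_that("luciferase: promoter-allele contrast lands near the true fold", {
  folds <- vapply(1:100, function(s) {
    lum <- simulate_luciferase_table(seed = 300 + s)
    res <- luciferase_fold(lum)
    a <- res$activity
    a$mean[a$construct == "H"] / a$mean[a$construct == "h"]
  }, numeric(1))
  expect_gt(mean(folds), 4)     # true contrast 46 / 8 = 5.75
  expect_lt(mean(folds), 8)
})

test_that("luciferase: a repeat missing the reference is excluded with a warning", {
  lum <- simulate_luciferase_table(seed = 15)
  lum <- lum[!(lum$construct == "pGL3-Basic" & lum$bio_rep == 3), ]
  expect_warning(res <- luciferase_fold(lum), "excluded")
  expect_true(all(res$per_repeat$bio_rep %in% 1:2))
})
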