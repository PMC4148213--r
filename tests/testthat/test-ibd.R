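toy_map <- function(m) marker_map(sprintf("m%02d", 1:m), "3",
                                  seq(1000, by = 1000, length.out = m))

test_that("shared blocks are maximal runs of case-wide homozygosity", {
  # 3 cases homozygous-alt at markers 2-5; case 1 heterozygous at 6;
  # marker 1 mixed homozygotes
  g <- rbind(c(0L, 2L, 2L, 2L, 2L, 1L),
             c(2L, 2L, 2L, 2L, 2L, 2L),
             c(2L, 2L, 2L, 2L, 2L, 2L))
  blocks <- shared_homozygous_blocks(g, toy_map(6))
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$marker_indices, 2:5)
  expect_equal(unname(blocks[[1]]$shared_alleles), rep(2L, 4))
  expect_equal(blocks[[1]]$n_supporting_cases, 3L)
  expect_equal(blocks[[1]]$interval$start, 2000)
  expect_equal(blocks[[1]]$interval$end, 5000)
})

test_that("a heterozygous case splits sharing into two blocks", {
  # the two-block structure: blocks at 1-3 and 5-7, broken by a het at 4
  g <- rbind(c(2L, 2L, 2L, 1L, 0L, 0L, 0L),
             c(2L, 2L, 2L, 2L, 0L, 0L, 0L),
             c(2L, 2L, 2L, 2L, 0L, 0L, 0L))
  blocks <- shared_homozygous_blocks(g, toy_map(7))
  expect_length(blocks, 2)
  expect_equal(blocks[[1]]$marker_indices, 1:3)
  expect_equal(blocks[[2]]$marker_indices, 5:7)
  # with one tolerated exception the blocks fuse
  fused <- shared_homozygous_blocks(g, toy_map(7), max_case_exceptions = 1)
  expect_length(fused, 1)
  expect_equal(fused[[1]]$marker_indices, 1:7)
})

test_that("missing policies: compatible bridges, breaking breaks", {
  g <- rbind(c(2L, NA, 2L),
             c(2L, 2L, 2L))
  compat <- shared_homozygous_blocks(g, toy_map(3))
  expect_length(compat, 1)
  expect_equal(compat[[1]]$marker_indices, 1:3)
  strict <- shared_homozygous_blocks(g, toy_map(3),
                                     missing_policy = "breaking")
  expect_length(strict, 2)
})

test_that("block finder matches the brute-force window oracle", {
  set.seed(19)
  map_cache <- lapply(1:20, toy_map)
  for (rep in 1:300) {
    g <- random_case_matrix()
    got <- shared_homozygous_blocks(g, map_cache[[ncol(g)]])
    got_idx <- lapply(got, function(b) range(b$marker_indices))
    want <- oracle_shared_blocks(g)
    expect_equal(got_idx, want)
  }
})

test_that("control exclusion requires a full homozygous match", {
  cases <- rbind(c(2L, 2L, 2L, 1L, 0L, 0L),
                 c(2L, 2L, 2L, 2L, 0L, 0L))
  map <- toy_map(6)
  blocks <- shared_homozygous_blocks(cases, map)
  expect_length(blocks, 2)

  # control homozygous across block 1 only -> block 1 excluded, block 2 lives
  ctrl <- matrix(c(2L, 2L, 2L, 0L, 1L, 1L), 1)
  rownames(ctrl) <- "WPR_1"
  out <- exclude_control_matches(blocks, ctrl)
  expect_equal(out[[1]]$excluded_by, "WPR_1")
  expect_length(out[[2]]$excluded_by, 0)

  # a het anywhere in the block spoils the match
  ctrl2 <- matrix(c(2L, 1L, 2L, 0L, 1L, 1L), 1)
  out2 <- exclude_control_matches(blocks, ctrl2)
  expect_length(out2[[1]]$excluded_by, 0)

  # missing cells in the control are compatible with matching
  ctrl3 <- matrix(c(2L, NA, 2L, 0L, 1L, 1L), 1)
  out3 <- exclude_control_matches(blocks, ctrl3)
  expect_length(out3[[1]]$excluded_by, 1)

  # no controls -> no exclusions
  out4 <- exclude_control_matches(blocks, matrix(integer(0), 0, 6))
  expect_length(out4[[1]]$excluded_by, 0)
})

test_that("heterozygous panel birds narrow the boundary het-exclusively", {
  toy <- boundary_toy()
  blocks <- shared_homozygous_blocks(toy$cases, toy$map)
  expect_length(blocks, 1)
  nb <- narrow_boundaries(blocks[[1]], toy$panel, toy$map)
  expect_equal(nb$interval$start, 70460739)   # boundary marker + 1 bp
  expect_equal(nb$interval$end, 70504365)     # distal side stays open
  expect_true(nb$proximal_closed)
  expect_false(nb$distal_closed)
  expect_equal(nb$boundary_markers$proximal, "T2")
})

test_that("a fully concordant panel leaves the block open on both sides", {
  toy <- boundary_toy()
  blocks <- shared_homozygous_blocks(toy$cases, toy$map)
  panel <- matrix(2L, 2, 6)
  nb <- narrow_boundaries(blocks[[1]], panel, toy$map)
  expect_equal(nb$interval, blocks[[1]]$interval)
  expect_false(nb$proximal_closed)
  expect_false(nb$distal_closed)
})

test_that("an interior discordant panel bird splits the block consistently", {
  map <- toy_map(9)
  cases <- matrix(2L, 3, 9)
  panel <- matrix(2L, 1, 9)
  panel[1, 5] <- 1L
  block <- shared_homozygous_blocks(cases, map)[[1]]
  nb <- narrow_boundaries(block, panel, map)
  # the two concordant runs agree with re-running the block finder on the
  # pooled case set
  pooled <- shared_homozygous_blocks(rbind(cases, panel), map)
  expect_equal(nb$runs,
               lapply(pooled, function(b) b$marker_indices))
  # the longest-run rule keeps one side and closes at the split marker
  expect_equal(length(nb$runs), 2)
  expect_true(nb$proximal_closed || nb$distal_closed)
})

test_that("adding cases never widens blocks; adding controls never grows survivors", {
  set.seed(29)
  map <- toy_map(15)
  for (rep in 1:20) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 8 * 15, replace = TRUE,
                       prob = c(.3, .15, .45, .1)), 8, 15)
    b_small <- shared_homozygous_blocks(g[1:4, ], map)
    b_big <- shared_homozygous_blocks(g, map)
    for (b in b_big) {
      containing <- any(vapply(b_small, function(s)
        all(b$marker_indices %in% s$marker_indices), logical(1)))
      expect_true(containing)
    }
    ctrl <- matrix(sample(c(0L, 1L, 2L), 6 * 15, replace = TRUE), 6, 15)
    surv1 <- Filter(function(b) length(b$excluded_by) == 0,
                    exclude_control_matches(b_big, ctrl[1:3, ]))
    surv2 <- Filter(function(b) length(b$excluded_by) == 0,
                    exclude_control_matches(b_big, ctrl))
    expect_lte(length(surv2), length(surv1))
  }
})

test_that("pipeline recovers the planted causal position from a panel", {
  p <- simulate_breed_panel(panel_config(seed = 77))
  rep_ <- run_ibd_pipeline(subset_phenotype(p$genotypes, "case"),
                           subset_phenotype(p$genotypes, "control"))
  expect_false(is_empty_interval(rep_$interval))
  expect_true(rep_$interval$start <= p$truth$causal_pos &&
                rep_$interval$end >= p$truth$causal_pos)
  expect_s3_class(rep_$steps, "data.frame")
  expect_gt(nrow(rep_$steps), 1)
})

test_that("pipeline degenerates sensibly: identical cases/controls, single case", {
  map <- toy_map(8)
  # cases share everything, but an identical control matches the whole block
  rep_ <- run_ibd_pipeline(matrix(2L, 2, 8), matrix(2L, 1, 8), map = map)
  expect_true(is_empty_interval(rep_$interval))

  # single case, no controls: the candidate is its longest homozygous run
  single <- matrix(c(1L, 2L, 2L, 2L, 0L, 2L, 1L, 1L), 1)
  rep2 <- run_ibd_pipeline(single, NULL, map = map)
  expect_equal(rep2$interval$start, 2000)
  expect_equal(rep2$interval$end, 6000)
})
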