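test_that("all three generators are byte-deterministic under a fixed seed", {
  part <- make_partition(3, 4)
  s1 <- simulate_genealogy_set(genealogy_sim_params(part, seed = 5,
                                                    concordance_prob = 0.7))
  s2 <- simulate_genealogy_set(genealogy_sim_params(part, seed = 5,
                                                    concordance_prob = 0.7))
  expect_identical(s1$newick, s2$newick)
  s3 <- simulate_genealogy_set(genealogy_sim_params(part, seed = 6,
                                                    concordance_prob = 0.7))
  expect_false(identical(s1$newick, s3$newick))

  m1 <- simulate_marker_sequences(marker_sim_params(seed = 5))
  m2 <- simulate_marker_sequences(marker_sim_params(seed = 5))
  expect_identical(vapply(m1$records, `[[`, "", "sequence"),
                   vapply(m2$records, `[[`, "", "sequence"))
  expect_identical(m1$truth, m2$truth)

  p1 <- simulate_spore_measurements(spore_sim_params(seed = 5))
  p2 <- simulate_spore_measurements(spore_sim_params(seed = 5))
  expect_identical(p1, p2)
})

test_that("planted microsatellite and minisatellite geometry is exact", {
  motif66 <- motif_of("H. rubroreticulatus")
  sim <- simulate_marker_sequences(marker_sim_params(
    minis_consensus = motif66, minis_copies = 2.0,
    minis_sub_rate = 0, minis_indel_rate = 0, n_sequences = 2, seed = 3))
  t2 <- sim$truth[sim$truth$region == "ITS2", ]
  expect_equal(unique(t2$end - t2$start), 132L)     # 2.0 x 66
  expect_equal(unique(t2$planted), strrep(motif66, 2))
  t1 <- sim$truth[sim$truth$region == "ITS1", ]
  expect_equal(unique(t1$planted), strrep("AC", 13))
  expect_equal(unique(t1$copies), 13)
  # fractional copies: floor(2.8 * 80) = 224
  m80 <- substr(motif_of("H. bubalinus", "2-7-7"), 1, 80)
  sim2 <- simulate_marker_sequences(marker_sim_params(
    minis_consensus = m80, minis_copies = 2.8,
    minis_sub_rate = 0, minis_indel_rate = 0, n_sequences = 1, seed = 3))
  tt <- sim2$truth[sim2$truth$region == "ITS2", ]
  expect_equal(tt$end - tt$start, 224L)
  expect_equal(tt$planted,
               paste0(strrep(m80, 2), substr(m80, 1, 64)))
})

test_that("truth records are consistent with the emitted sequences", {
  # without mutation the emitted substring equals the tiled consensus
  sim <- simulate_marker_sequences(marker_sim_params(
    minis_sub_rate = 0, minis_indel_rate = 0, n_sequences = 3, seed = 11))
  for (i in seq_along(sim$records)) {
    r <- sim$records[[i]]
    tr <- sim$truth[sim$truth$seq_id == r$seq_id, ]
    for (k in seq_len(nrow(tr)))
      expect_equal(substr(r$sequence, tr$start[k] + 1, tr$end[k]),
                   tr$planted[k])
    # annotation intervals must tile the record
    ann <- r$annotation
    expect_equal(ann$start[1], 0L)
    expect_equal(ann$end[3], nchar(r$sequence))
    expect_true(all(ann$end[-3] == ann$start[-1]))
    # planted arrays sit inside their annotated regions
    for (k in seq_len(nrow(tr))) {
      reg <- ann[ann$region == tr$region[k], ]
      expect_gte(tr$start[k], reg$start)
      expect_lte(tr$end[k], reg$end)
    }
  }
  # with mutation the pre-mutation planted string is still the tiled consensus
  simm <- simulate_marker_sequences(marker_sim_params(n_sequences = 2, seed = 12))
  t2 <- simm$truth[simm$truth$region == "ITS2", ]
  p <- nchar(t2$consensus[1])
  expect_equal(substr(t2$planted[1], 1, p), t2$consensus[1])
  expect_equal(substr(t2$planted[1], p + 1, 2 * p), t2$consensus[1])
})

test_that("spore generator honours degenerate and large-sample limits", {
  # zero covariance, zero jitter: every observation is exactly the mean
  ms <- simulate_spore_measurements(spore_sim_params(
    cov = matrix(0, 2, 2), between_collection_sd = 0,
    n_per_collection = 8, p_collections = 3, seed = 4))
  expect_true(all(ms$length_um == 11.6))
  expect_true(all(ms$width_um == 5.0))
  # CLT: sample means within 3 standard errors at n = 10000
  ms2 <- simulate_spore_measurements(spore_sim_params(
    cov = diag(c(0.36, 0.04)), between_collection_sd = 0,
    n_per_collection = 10000, p_collections = 1, seed = 4))
  expect_lt(abs(mean(ms2$length_um) - 11.6), 3 * 0.6 / sqrt(10000))
  expect_lt(abs(mean(ms2$width_um) - 5.0), 3 * 0.2 / sqrt(10000))
  # all observations positive even with a huge covariance (redraw rule)
  ms3 <- simulate_spore_measurements(spore_sim_params(
    mean_length = 2, mean_width = 1, cov = diag(c(4, 1)),
    n_per_collection = 200, p_collections = 2, seed = 4))
  expect_true(all(ms3$length_um > 0 & ms3$width_um > 0))
})

test_that("generator parameter validation rejects inconsistent settings", {
  expect_error(genealogy_sim_params(character(0)), "non-empty")
  part2 <- stats::setNames(c("sp1", "sp2"), c("x1", "x2"))
  expect_error(genealogy_sim_params(part2), "3 specimens")
  part <- make_partition(2, 2)
  expect_error(genealogy_sim_params(part, concordance_prob = 1.5), "\\[0, 1\\]")
  expect_error(genealogy_sim_params(
    part, masking = list(ITS = c("sp1_1", "sp1_2"), LSU = c("sp1_1", "sp1_2"),
                         tef1 = c("sp1_1", "sp1_2"),
                         rpb2 = c("sp1_1", "sp1_2"))),
    "every member")
  expect_error(marker_sim_params(minis_consensus = "ACGU"), "A, C, G, T")
  expect_error(marker_sim_params(micro_length = 25), "even")
  expect_error(marker_sim_params(minis_copies = 0.5), ">= 1")
  expect_error(marker_sim_params(minis_sub_rate = 1.2), "rates")
  expect_error(spore_sim_params(cov = matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
  expect_error(spore_sim_params(mean_length = -1), "positive")
})

test_that("fully concordant simulations are recovered end-to-end by GCPSR", {
  for (seed in 1:5) {
    set.seed(seed)
    part <- make_partition(sample(2:4, 1), sample(3:5, 1))
    sim <- simulate_genealogy_set(genealogy_sim_params(part, seed = seed))
    d <- delimit_species(sim$genealogies)
    got <- sort(vapply(d$lineages, function(l) paste(l$taxa, collapse = ","),
                       ""))
    want <- sort(vapply(split(names(part), part), function(x)
      paste(sort(x), collapse = ","), ""))
    expect_equal(got, unname(want))
    expect_true(all(vapply(d$lineages, `[[`, "", "status") ==
                      "phylogenetic_species"))
    expect_equal(length(d$unassigned), 0L)
  }
})
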