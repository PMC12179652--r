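test_that("two exact copies of the printed 66-bp consensus reproduce its table row", {
  motif <- motif_of("H. rubroreticulatus")
  expect_equal(nchar(motif), 66L)
  h <- detect_tandem_repeats(strrep(motif, 2))
  expect_equal(nrow(h), 1L)
  expect_equal(h$period, 66L)
  expect_equal(h$copy_number, 2.0)
  expect_equal(h$percent_matches, 100L)
  expect_equal(h$percent_indels, 0L)
  expect_equal(h$score, 2L * 132L)
  expect_equal(h$consensus, motif)
  expect_equal(c(h$start, h$end), c(0L, 132L))
})

test_that("non-repetitive sequences yield no hits and empty input an empty table", {
  expect_equal(nrow(detect_tandem_repeats("ACGT")), 0L)
  expect_equal(nrow(detect_tandem_repeats("")), 0L)
  expect_equal(nrow(detect_tandem_repeats(nonrepetitive_flank(150, 11))), 0L)
})

test_that("AC-run detection floor sits at 26 bp under 2-7-7 / min score 50", {
  fl1 <- nonrepetitive_flank(100, 1)
  fl2 <- nonrepetitive_flank(100, 2)
  h24 <- detect_tandem_repeats(paste0(fl1, strrep("AC", 12), fl2))
  h26 <- detect_tandem_repeats(paste0(fl1, strrep("AC", 13), fl2))
  expect_equal(nrow(h24), 0L)
  expect_equal(nrow(h26), 1L)
  expect_equal(h26$period, 2L)
  expect_equal(h26$score, 52L)
  expect_equal(h26$copy_number, 13.0)
  # score arithmetic 2*L for perfect arrays, against the brute-force scorer
  expect_equal(oracle_best_score(strrep("AC", 13)), 52L)
  expect_equal(oracle_best_score(strrep("AC", 12)), 48L)
  expect_equal(best_array_score(strrep("AC", 13)), 52L)
})

test_that("perfect-array law: period (not a multiple), copies, 100%/0%, score 2L", {
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  # copy numbers chosen so every array reaches the 50-score reporting floor
  kappas <- list(`5` = c(5.2, 7.5), `11` = c(2.5, 3.8),
                 `23` = c(2.0, 3.8), `40` = c(2.0, 2.5))
  for (p in c(5L, 11L, 23L, 40L)) {
    repeat {  # a primitive pattern: no rotation equals another rotation
      pat <- paste(sample(bases, p, TRUE), collapse = "")
      rots <- vapply(seq_len(p) - 1L, function(k)
        paste0(substr(pat, k + 1, p), substr(pat, 1, k)), character(1))
      if (!anyDuplicated(rots)) break
    }
    for (kappa in kappas[[as.character(p)]]) {
      L <- floor(kappa * p)
      arr <- substr(strrep(pat, ceiling(kappa) + 1L), 1L, L)
      fl1 <- nonrepetitive_flank(100, 3)
      fl2 <- nonrepetitive_flank(100, 4)
      # junction bases must not extend the array phase
      if (substr(fl1, 100, 100) == substr(pat, p, p))
        substr(fl1, 100, 100) <- "T"
      nxt <- substr(pat, (L %% p) + 1L, (L %% p) + 1L)
      if (substr(fl2, 1, 1) == nxt) substr(fl2, 1, 1) <- if (nxt == "T") "G" else "T"
      h <- detect_tandem_repeats(paste0(fl1, arr, fl2))
      expect_equal(nrow(h), 1L)
      expect_equal(h$period, p)
      expect_equal(h$copy_number, round(L / p, 1))
      expect_equal(h$percent_matches, 100L)
      expect_equal(h$percent_indels, 0L)
      expect_equal(h$score, 2L * L)
      expect_equal(c(h$start, h$end), c(100L, 100L + L))
      expect_equal(compare_consensus(h$consensus, pat, cyclic = TRUE), 100)
    }
  }
})

test_that("lowering mismatch/indel penalties never lowers the best array score", {
  set.seed(7)
  sim <- simulate_marker_sequences(marker_sim_params(
    minis_sub_rate = 0.08, minis_indel_rate = 0.02, n_sequences = 6, seed = 7))
  for (r in sim$records) {
    its2 <- r$annotation[r$annotation$region == "ITS2", ]
    win <- substr(r$sequence, its2$start + 1, its2$end)
    s277 <- max(0L, boletax:::scan_arrays_cpp(win, 2, 7, 7, 1, 200, FALSE)$score)
    s235 <- max(0L, boletax:::scan_arrays_cpp(win, 2, 3, 5, 1, 200, FALSE)$score)
    expect_gte(s235, s277)
  }
  # and on short {A,C} sequences via the exhaustive path
  set.seed(8)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C"), 18, TRUE), collapse = "")
    expect_gte(best_array_score(s, scoring_weights(2, 3, 5)),
               best_array_score(s, scoring_weights(2, 7, 7)))
  }
})

test_that("scan of a window equals the window of a full scan (coordinate lifting)", {
  motif <- motif_of("H. rubroreticulatus")
  fl <- nonrepetitive_flank(220, 5)
  seqstr <- paste0(substr(fl, 1, 110), strrep(motif, 2), substr(fl, 111, 220))
  ann <- data.frame(start = c(0L, 60L, 100L), end = c(60L, 100L, nchar(seqstr)),
                    region = c("ITS1", "5.8S", "ITS2"))
  rec <- marker_record("w1", seqstr, ann)
  tp <- two_pass_its_scan(rec)
  expect_equal(nrow(tp$pass1), 1L)
  expect_equal(nrow(tp$pass2), 1L)
  expect_equal(tp$pass1$period, 66L)
  expect_equal(tp$pass2$period, 66L)
  expect_equal(tp$pass1[, c("start", "end")], tp$pass2[, c("start", "end")])
  expect_equal(tp$pass1$start, 110L)
  # lifted hit must reproduce on the extracted substring
  sub <- substr(seqstr, tp$pass2$start + 1, tp$pass2$end)
  expect_equal(detect_tandem_repeats(sub)$score, tp$pass2$score)
})

test_that("an array in ITS1 only is reported by pass 1 and absent from pass 2", {
  fl1 <- nonrepetitive_flank(60, 6)
  fl2 <- nonrepetitive_flank(200, 7)
  seqstr <- paste0(fl1, strrep("AC", 14), fl2)
  ann <- data.frame(start = c(0L, 100L, 140L),
                    end = c(100L, 140L, nchar(seqstr)),
                    region = c("ITS1", "5.8S", "ITS2"))
  tp <- two_pass_its_scan(marker_record("m1", seqstr, ann))
  expect_equal(tp$pass1$period, 2L)
  expect_equal(nrow(tp$pass2), 0L)
  expect_error(two_pass_its_scan(marker_record("m2", "ACGTACGT"),
                                 its2_window = c(4, 400)),
               "window")
})

test_that("pass-2 consensus recovers a mutated planted minisatellite", {
  # 82-bp consensus, 2.8 copies, 5% substitutions; expect the recovered motif
  # within rotational edit distance 4 of the planted one in >= 95% of runs
  planted <- motif_of("H. bubalinus", "2-7-7")
  ok <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    sim <- simulate_marker_sequences(marker_sim_params(
      minis_consensus = planted, minis_copies = 2.8,
      minis_sub_rate = 0.05, minis_indel_rate = 0, n_sequences = 1, seed = i))
    rec <- sim$records[[1]]
    tp <- two_pass_its_scan(rec)
    h <- tp$pass2
    if (nrow(h) == 0L) next
    h <- h[which.max(h$score), ]
    if (abs(h$period - 82L) <= 4L &&
        rotational_edit_dist(h$consensus, planted) <= 4) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("the 5% non-ATGC quality screen refuses poor records unless overridden", {
  s <- paste0(strrep("N", 12), strrep("AC", 20), nonrepetitive_flank(100, 9))
  rec <- marker_record("q1", s)
  expect_gt(rec$non_atgc_fraction, 0.05)
  expect_error(detect_tandem_repeats(rec), "non-ATGC")
  h <- detect_tandem_repeats(rec, override_quality = TRUE)
  expect_equal(h$period, 2L)
})

test_that("overlapping candidate arrays resolve to the best score, then smaller period", {
  # a perfect AC run is also matched by period-4+ candidates at equal score;
  # the reported hit must be the period-2 one
  h <- detect_tandem_repeats(strrep("AC", 30))
  expect_equal(nrow(h), 1L)
  expect_equal(h$period, 2L)
})
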