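test_that("agreement accuracy, abstentions and bootstrap behave", {
  rep_ <- axb_accuracy(c(TRUE, TRUE, TRUE, FALSE), method = "hand",
                       n_boot = 200, seed = 1)
  expect_equal(rep_$accuracy, 0.75)
  expect_equal(rep_$n_scored, 4)
  expect_lte(rep_$ci_low, rep_$accuracy)
  expect_gte(rep_$ci_high, rep_$accuracy)
  # abstentions excluded from the denominator but counted
  rep2 <- axb_accuracy(c(TRUE, NA, FALSE, NA), n_boot = 50, seed = 1)
  expect_equal(rep2$accuracy, 0.5)
  expect_equal(rep2$n_abstained, 2)
  expect_error(axb_accuracy(c(NA, NA)), "zero scorable")
  # self-agreement is exactly 1
  study <- small_study()
  expect_equal(axb_accuracy(rep(TRUE, 50), n_boot = 50, seed = 1)$accuracy,
               1)
  # a coin flip sits near chance
  set.seed(9)
  coin <- sample(c(TRUE, FALSE), 600, replace = TRUE)
  rep3 <- axb_accuracy(coin, n_boot = 300, seed = 2)
  expect_lt(abs(rep3$accuracy - 0.5), 3 * sqrt(0.25 / 600) + 1e-9)
})

test_that("attainable bounds match hand-computed values", {
  acc <- data.frame(bird_id = c("x", "y"), cycle_id = c("c", "c"),
                    accuracy = c(0.7, 0.8), n_trials = c(10, 10))
  dec <- data.frame(bird_id = c("x", "x", "y"), cycle_id = "c",
                    probe_id = c("p", "q", "p"),
                    n_decisions = c(3L, 1L, 2L),
                    n_L = c(2L, 1L, 1L), n_R = c(1L, 0L, 1L),
                    majority_side = c("L", "L", "L"),
                    consistency = c(2 / 3, 1, 0.5),
                    stimulus_set_id = "s", stringsAsFactors = FALSE)
  b <- attainable_bounds(acc, dec)
  expect_equal(b$bound_cycle, 0.75)               # unweighted mean
  expect_equal(b$bound_consistency, (2 / 3 + 0.5) / 2)  # multi-decision only
  # weighted variant: x contributes 2 decisions, y contributes 1
  bw <- attainable_bounds(acc, dec, weighted = TRUE)
  expect_equal(bw$bound_cycle, (0.7 * 2 + 0.8 * 1) / 3)
  # perfectly consistent birds give a consistency bound of 1
  dec1 <- dec
  dec1$consistency <- 1
  expect_equal(attainable_bounds(acc, dec1)$bound_consistency, 1)
  # no multi-decision triplets: consistency bound missing
  b0 <- attainable_bounds(acc, dec[dec$n_decisions == 1, , drop = FALSE])
  expect_true(is.na(b0$bound_consistency))
})

test_that("the consistency bound dominates methods scored on noiseless data", {
  study0 <- simulate_axb_study(n_syllables = 60, n_sets = 1, n_probes = 10,
                               n_birds = 4, noise_scale = 0, seed = 77)
  lat <- planted_distances(study0$corpus$space)
  expect_equal(study0$bounds$bound_consistency, 1)
  md <- method_decisions(lat, study0$split$eval)
  expect_gte(study0$bounds$bound_consistency,
             mean(md$agree, na.rm = TRUE))
})

test_that("disagreement MDS reproduces hand-built disagreement structure", {
  # duplicate methods coincide; a label-flipped copy is at distance 1
  dec <- list(m1 = c("A", "A", "B", "B"),
              m2 = c("A", "A", "B", "B"),
              m3 = c("B", "B", "A", "A"))
  fit <- disagreement_mds(dec, include_birds = FALSE)
  expect_equal(fit$distances["m1", "m2"], 0)
  expect_equal(fit$distances["m1", "m3"], 1)
  expect_lt(sqrt(sum((fit$coords["m1", ] - fit$coords["m2", ])^2)), 1e-6)
  # three methods: coordinates reproduce the disagreement matrix exactly
  dec3 <- list(a = c("A", "A", "A", "A", "B", "B"),
               b = c("A", "A", "B", "B", "B", "B"),
               c = c("B", "A", "A", "B", "A", "B"))
  fit3 <- disagreement_mds(dec3, include_birds = FALSE)
  D <- fit3$distances
  emb_d <- as.matrix(stats::dist(fit3$coords))
  expect_equal(unname(emb_d), unname(as.matrix(D)), tolerance = 1e-8)
  # and the coordinates match the explicit eigendecomposition oracle
  oracle <- cmds_oracle(unname(as.matrix(D)))
  expect_equal(unname(as.matrix(stats::dist(oracle))), unname(as.matrix(D)),
               tolerance = 1e-8)
  # the birds' labels enter as a method
  fit_b <- disagreement_mds(dec3, include_birds = TRUE)
  expect_true("BIRDS" %in% rownames(fit_b$coords))
  expect_error(disagreement_mds(dec[1:2], include_birds = FALSE),
               "at least three")
})

test_that("choice calibration bins equally and respects symmetry", {
  study <- small_study()
  lat <- planted_distances(study$corpus$space)
  pt <- probe_trial_table(study$trials, study$cycles, study$sets)
  cal <- choice_calibration(pt, lat, n_bins = 12)
  expect_equal(nrow(cal), 12)
  expect_equal(sum(cal$n), nrow(pt))
  expect_lte(max(cal$n) - min(cal$n), 1)
  expect_true(all(diff(cal$x_center) >= 0))
  # 40 trials over 20 bins -> exactly 2 per bin
  cal2 <- choice_calibration(pt[1:40, ], lat, n_bins = 20)
  expect_equal(unique(cal2$n), 2L)
  expect_error(choice_calibration(pt[1:5, ], lat, n_bins = 20), "fewer")
})

test_that("external matrices ingest, convert and flag zero similarities", {
  ids <- c("p", "a", "b", "c")
  S <- matrix(c(1, 0.6, 0, 0,
                0.6, 1, 0.3, 0.1,
                0, 0.3, 1, 0,
                0, 0.1, 0, 1), 4, 4, dimnames = list(ids, ids))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(S), path, row.names = TRUE)
  D <- ingest_external_matrix(path, kind = "similarity")
  expect_s3_class(D, "dissimilarity_matrix")
  expect_true(all(diag(as.matrix(D)) == 0))
  expect_equal(as.matrix(D)["p", "a"], max(S) - 0.6)
  expect_equal(as.matrix(D)["p", "b"], max(S))
  # triplet where the probe has zero similarity to both sides is flagged
  trip <- data.frame(anchor_id = c("p", "p"),
                     positive_ids = I(list("b", "a")),
                     negative_ids = I(list("c", "b")))
  flags <- flag_zero_similarity_triplets(D, trip)
  expect_identical(flags, c(TRUE, FALSE))
  # round trip preserves values to full precision
  D2path <- withr::local_tempfile(fileext = ".csv")
  write_dissimilarity_matrix(D, D2path)
  D2 <- ingest_external_matrix(D2path, kind = "dissimilarity")
  expect_equal(as.matrix(D2), as.matrix(D), tolerance = 1e-12)
  # asymmetry is rejected
  S_bad <- S
  S_bad[1, 2] <- 0.9
  utils::write.csv(as.data.frame(S_bad), path, row.names = TRUE)
  expect_error(ingest_external_matrix(path, kind = "similarity"),
               "asymmetric")
})
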