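test_that("trial logs parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  trials <- hand_trial_log()
  write_trials(trials, path)
  back <- parse_trials(path)
  expect_equal(nrow(back), nrow(trials))
  expect_equal(back$chosen_side, trials$chosen_side)
  expect_equal(back$rewarded, trials$rewarded)
  # empty file with header
  empty <- trials[0, ]
  write_trials(empty, path)
  expect_equal(nrow(parse_trials(path)), 0)
  # malformed rows are reported with line numbers
  bad <- trials
  bad$correct_side[3] <- "X"
  write_trials(bad, path)
  expect_error(parse_trials(path), "line 4")
  bad <- trials
  bad$correct_side[bad$role == "probe"][1] <- "L"
  write_trials(bad, path)
  expect_error(parse_trials(path), "probe")
  # missing column
  writeLines("bird_id,cycle_id", path)
  expect_error(parse_trials(path), "missing required column")
})

test_that("cycle accuracy counts only answered training trials", {
  trials <- hand_trial_log()
  expect_equal(cycle_accuracy(trials, "good", "c1"), 0.8)
  expect_equal(cycle_accuracy(trials, "poor", "c1"), 0.6)
  # probes, unanswered and device-fault trials are excluded
  extra <- trials[trials$role == "training" & trials$bird_id == "good", ][1:2, ]
  extra$chosen_side <- "none"
  extra2 <- extra
  extra2$chosen_side <- "R"
  extra2$device_ok <- FALSE
  expect_equal(cycle_accuracy(rbind(trials, extra, extra2), "good", "c1"),
               0.8)
  expect_error(cycle_accuracy(trials, "nobody", "c1"), "no answered")
  tab <- cycle_accuracy_table(trials)
  expect_equal(sort(tab$accuracy), c(0.6, 0.8))
})

test_that("probe decisions consolidate with majority, consistency and ties", {
  dec <- consolidate_probe_decisions(hand_trial_log(), hand_cycle_sets())
  g <- dec[dec$bird_id == "good", ]
  p3 <- g[g$probe_id == "p3", ]
  expect_equal(p3$n_decisions, 3L)
  expect_equal(p3$majority_side, "L")
  expect_equal(p3$consistency, 2 / 3)
  p4 <- g[g$probe_id == "p4", ]   # tie resolves to L, consistency 0.5
  expect_equal(p4$majority_side, "L")
  expect_equal(p4$consistency, 0.5)
  p5 <- g[g$probe_id == "p5", ]   # single decision
  expect_equal(p5$n_decisions, 1L)
  expect_equal(p5$consistency, 1)
  expect_equal(unique(dec$stimulus_set_id), "setX")
})

test_that("triplet datasets apply the behavioural filters exactly", {
  trials <- hand_trial_log()
  dec <- consolidate_probe_decisions(trials, hand_cycle_sets())
  acc <- cycle_accuracy_table(trials)
  sets <- hand_stimulus_sets()
  tds <- build_triplet_datasets(dec, acc, sets)
  # hand enumeration: good bird only (poor at 0.60 < 0.65 is discarded);
  # p1 (1.0, n3) and p2 (0.75, n4) unambiguous; p3 (2/3) and p4 (0.5)
  # ambiguous; p5 single decision in neither
  expect_equal(nrow(tds$unambiguous), 2)
  expect_equal(sort(tds$unambiguous$anchor_id), c("p1", "p2"))
  expect_equal(nrow(tds$ambiguous), 2)
  expect_equal(sort(tds$ambiguous$anchor_id), c("p3", "p4"))
  expect_true(all(tds$unambiguous$u == 1))
  expect_true(all(tds$ambiguous$u == 0))
  expect_equal(tds$unambiguous$weight[tds$unambiguous$anchor_id == "p2"], 4L)
  # orientation: majority L = side A of setX
  expect_equal(tds$unambiguous$positive_ids[[1]], sets$setX$side_A_ids)
  expect_equal(tds$unambiguous$negative_ids[[1]], sets$setX$side_B_ids)
  # partition property
  ku <- paste(tds$unambiguous$bird_id, tds$unambiguous$cycle_id,
              tds$unambiguous$anchor_id)
  ka <- paste(tds$ambiguous$bird_id, tds$ambiguous$cycle_id,
              tds$ambiguous$anchor_id)
  expect_length(intersect(ku, ka), 0)
  expect_error(build_triplet_datasets(dec, acc, sets,
                                      accuracy_threshold = 0.3),
               "thresholds")
})

test_that("the exact consistency boundary of 70% falls in the ambiguous set", {
  trials <- rbind(
    hand_trial_log()[hand_trial_log()$role == "training" &
                       hand_trial_log()$bird_id == "good", ],
    data.frame(bird_id = "good", cycle_id = "c1", stimulus_id = "p9",
               role = "probe", correct_side = "none",
               chosen_side = c(rep("L", 7), rep("R", 3)),
               rewarded = TRUE, timestamp = 200 + 1:10, device_ok = TRUE,
               stringsAsFactors = FALSE))
  dec <- consolidate_probe_decisions(trials, hand_cycle_sets())
  tds <- build_triplet_datasets(dec, cycle_accuracy_table(trials),
                                hand_stimulus_sets())
  expect_equal(nrow(tds$unambiguous), 0)  # 0.70 is not > 0.70
  expect_equal(nrow(tds$ambiguous), 1)
})

test_that("raising the accuracy threshold never grows the datasets", {
  study <- small_study()
  sizes <- sapply(c(0.5, 0.65, 0.77, 0.85), function(th) {
    tds <- build_triplet_datasets(study$decisions, study$accuracies,
                                  study$sets, accuracy_threshold = th)
    c(nrow(tds$unambiguous), nrow(tds$ambiguous))
  })
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))
})

test_that("device-fault trials are discarded everywhere", {
  trials <- hand_trial_log()
  trials$device_ok[trials$stimulus_id == "p1"] <- FALSE
  dec <- consolidate_probe_decisions(trials, hand_cycle_sets())
  expect_false("p1" %in% dec$probe_id[dec$bird_id == "good"])
})

test_that("train/eval splits never share anchors and honour the 77% filter", {
  study <- small_study()
  tds <- study$datasets
  sp <- split_triplets(tds$unambiguous, eval_fraction = 0.3, seed = 2)
  key <- function(d) paste(d$stimulus_set_id, d$anchor_id)
  expect_length(intersect(key(sp$train), key(sp$eval)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$eval), nrow(tds$unambiguous))
  sp77 <- split_triplets(tds$unambiguous, eval_fraction = 0.3, seed = 2,
                         eval_accuracy = 0.77)
  expect_true(all(sp77$eval$cycle_accuracy >= 0.77))
  expect_identical(sp77$train, sp$train)
})

test_that("stimulus sets respect rank windows and invariants", {
  study <- small_study()
  lat <- planted_distances(study$corpus$space)
  M <- as.matrix(lat)
  set1 <- select_stimulus_set(lat, seed = 5, n_side = 4,
                              rank_B = c(15, 45), probe_ranks = c(5, 55),
                              n_probes = 6, id = "t")
  set2 <- select_stimulus_set(lat, seed = 5, n_side = 4,
                              rank_B = c(15, 45), probe_ranks = c(5, 55),
                              n_probes = 6, id = "t")
  expect_identical(set1, set2)
  expect_length(intersect(set1$side_A_ids, set1$side_B_ids), 0)
  expect_length(set1$side_A_ids, 4)
  # brute-force rank check: every probe within [5, 55] of both exemplars
  rank_of <- function(ex, s) {
    others <- setdiff(rownames(M), ex)
    match(s, others[order(M[ex, others])])
  }
  for (p in set1$probe_ids) {
    expect_true(rank_of(set1$exemplar_A, p) >= 5 &&
                  rank_of(set1$exemplar_A, p) <= 55)
    expect_true(rank_of(set1$exemplar_B, p) >= 5 &&
                  rank_of(set1$exemplar_B, p) <= 55)
  }
  # sides are the exemplar plus its nearest neighbours
  nn <- setdiff(rownames(M), set1$exemplar_A)[
    order(M[set1$exemplar_A, setdiff(rownames(M), set1$exemplar_A)])][1:3]
  expect_setequal(set1$side_A_ids, c(set1$exemplar_A, nn))
  expect_error(select_stimulus_set(lat, seed = 1),
               "corpus too small")
})

test_that("triplet datasets round-trip through JSON lines", {
  trials <- hand_trial_log()
  dec <- consolidate_probe_decisions(trials, hand_cycle_sets())
  tds <- build_triplet_datasets(dec, cycle_accuracy_table(trials),
                                hand_stimulus_sets())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_triplets(tds$unambiguous, path)
  back <- read_triplets(path)
  expect_equal(nrow(back), nrow(tds$unambiguous))
  expect_equal(back$anchor_id, tds$unambiguous$anchor_id)
  expect_equal(back$positive_ids[[1]], tds$unambiguous$positive_ids[[1]])
  expect_equal(back$u, tds$unambiguous$u)
  expect_equal(back$consistency, tds$unambiguous$consistency)
})
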