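test_that("loss functions match their closed forms and zero cases", {
  expect_equal(triplet_loss(0.3, 0.9, 0.5), 0)
  expect_equal(triplet_loss(0.9, 0.3, 0.5), 1.1)
  expect_equal(triplet_loss(0.4, 0.4, 0), 0)
  expect_error(triplet_loss(0.3, 0.9, -0.1), "delta")
  # margin exactly met
  expect_equal(mixed_loss(d_ap = 1, d_an = sqrt(1 + 0.5), delta = 0.5,
                          u = 1), 0)
  # perfectly ambiguous placement
  expect_equal(mixed_loss(0.7, 0.7, 0.5, u = 0), 0)
  expect_equal(mixed_loss(1, 1, 0.5, u = 1), 1 - exp(-0.5))
  expect_error(mixed_loss(1, 1, 0.5, u = 0.5), "u")
  # bounds: u=1 loss <= 1; u=0 loss in [0, 1)
  set.seed(2)
  dap <- stats::runif(200, 0, 2)
  dan <- stats::runif(200, 0, 2)
  l1 <- mixed_loss(dap, dan, 0.3, 1)
  l0 <- mixed_loss(dap, dan, 0.3, 0)
  expect_true(all(l1 >= 0 & l1 <= 1))
  expect_true(all(l0 >= 0 & l0 < 1))
  expect_true(all((l1 == 0) == (dan^2 - dap^2 >= 0.3)))
  expect_true(all((l0 == 0) == (dan == dap)))
})

test_that("embeddings are unit-norm, deterministic and collision-free", {
  cfg <- network_config(d = 8, channels = c(4, 8), input_shape = c(30, 34))
  model <- init_embedder(cfg, seed = 3)
  set.seed(4)
  X <- array(stats::rnorm(30 * 34 * 20), c(30, 34, 20),
             dimnames = list(NULL, NULL, paste0("s", 1:20)))
  e1 <- embed_syllables(model, X)
  e2 <- embed_syllables(model, X)
  expect_identical(e1, e2)
  expect_equal(unname(sqrt(rowSums(e1^2))), rep(1, 20), tolerance = 1e-6)
  # distinct inputs map to distinct vectors under a random initialisation
  dmin <- min(stats::dist(e1))
  expect_gt(dmin, 1e-4)
  expect_error(embed_syllables(model, X[1:10, , , drop = FALSE]),
               "input shape")
})

test_that("training reduces the loss on a learnable toy problem", {
  cfg <- network_config(d = 4, channels = c(4, 8), input_shape = c(30, 34))
  # two planted clusters of inputs
  set.seed(5)
  n <- 16
  X <- array(0, c(30, 34, n), dimnames = list(NULL, NULL, paste0("s", 1:n)))
  for (i in seq_len(n)) {
    base <- matrix(stats::rnorm(30 * 34, sd = 0.3), 30, 34)
    if (i <= n / 2) base[1:15, ] <- base[1:15, ] + 2 else
      base[16:30, ] <- base[16:30, ] + 2
  X[, , i] <- base
  }
  grp <- rep(c("a", "b"), each = n / 2)
  trips <- do.call(rbind, lapply(1:40, function(k) {
    a <- sample(which(grp == "a"), 1)
    p <- sample(setdiff(which(grp == "a"), a), 1)
    ng <- sample(which(grp == "b"), 1)
    data.frame(anchor_id = paste0("s", a), u = 1L,
               positive_ids = I(list(paste0("s", p))),
               negative_ids = I(list(paste0("s", ng))))
  }))
  model <- init_embedder(cfg, seed = 6)
  cfg_t <- train_config(sources = "U", epochs = 30, margin = 0.2,
                        learning_rate = 3e-3, holdout_fraction = 0,
                        seed = 7)
  trained <- train_embedder(model, X, list(U = trips), cfg_t)
  log <- trained$log
  expect_equal(nrow(log), 30)
  # running minimum decreases substantially
  expect_lt(min(log$train_loss), 0.5 * log$train_loss[1])
  # the embedding separates the planted clusters
  emb <- trained$embeddings
  within <- mean(stats::dist(emb[grp == "a", ])) +
    mean(stats::dist(emb[grp == "b", ]))
  between <- mean(as.matrix(stats::dist(emb))[grp == "a", grp == "b"])
  expect_gt(between, within / 2)
})

test_that("the source audit reflects the training configuration", {
  study <- small_study()
  X <- study_input_array(study)
  datasets <- list(U = study$split$train, A = study$datasets$ambiguous)
  model <- init_embedder(network_config(d = 4, channels = c(4, 8)), seed = 1)
  m_u <- train_embedder(model, X, datasets,
                        train_config(sources = "U", epochs = 2, seed = 1))
  expect_identical(names(attr(m_u$log, "sources")), "U")
  expect_equal(attr(m_u$log, "sources")[["U"]], nrow(datasets$U))
  expect_equal(unique(m_u$log$loss_type), "hinge_sq")
  m_ua <- train_embedder(model, X, datasets,
                         train_config(sources = c("U", "A"), epochs = 2,
                                      seed = 1))
  expect_setequal(names(attr(m_ua$log, "sources")), c("U", "A"))
  expect_equal(unique(m_ua$log$loss_type), "mixed")
  expect_error(train_embedder(model, X, list(U = datasets$U[0, ]),
                              train_config(sources = "U", epochs = 1)),
               "empty pooled dataset")
})

test_that("pre-training runs the L phase before the main phase", {
  study <- small_study()
  X <- study_input_array(study)
  lat <- planted_distances(study$corpus$space)
  L <- generate_machine_triplets(lat, study$sets, min_margin = 0.1)
  model <- init_embedder(network_config(d = 4, channels = c(4, 8)), seed = 2)
  m <- train_embedder(model, X,
                      list(U = study$split$train, L = L),
                      train_config(sources = c("U", "L"),
                                   pretrain_on_L = TRUE, epochs = 2,
                                   seed = 3))
  expect_equal(nrow(m$log), 4)  # two phases of two epochs
  expect_setequal(names(attr(m$log, "sources")), "U")
})

test_that("embedding AXB decisions are rotation-invariant and near chance at random init", {
  set.seed(11)
  emb <- matrix(stats::rnorm(20 * 6), 20, 6,
                dimnames = list(paste0("s", 1:20), NULL))
  rot <- qr.Q(qr(matrix(stats::rnorm(36), 6, 6)))
  emb_rot <- emb %*% rot
  rownames(emb_rot) <- rownames(emb)
  for (i in 1:8) {
    ids <- sample(rownames(emb), 5)
    d1 <- embedding_axb(emb, ids[1], ids[2:3], ids[4:5])
    d2 <- embedding_axb(emb_rot, ids[1], ids[2:3], ids[4:5])
    expect_equal(d1$side, d2$side)
    expect_equal(d1$Xp, d2$Xp, tolerance = 1e-10)
  }
  # random embeddings decide at chance on random triplets
  set.seed(12)
  agree <- replicate(400, {
    ids <- sample(rownames(emb), 3)
    embedding_axb(emb, ids[1], ids[2], ids[3])$side == "A"
  })
  expect_lt(abs(mean(agree) - 0.5), 3 * sqrt(0.25 / 400) + 0.02)
  # a probe identical to a side-A exemplar decides A
  emb2 <- emb
  emb2["s1", ] <- emb2["s2", ]
  expect_equal(embedding_axb(emb2, "s1", c("s2", "s3"), c("s10", "s11"))$side,
               "A")
})
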