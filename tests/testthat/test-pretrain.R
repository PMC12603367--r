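# Mask sampling, the MLM objective, the LR schedule, gradient
# correctness, and the training loop contracts.

test_that("mask sampling selects exactly max(1, floor(rate*n)) residue positions", {
  st <- random_structure(100, seed = 1)
  b <- tokenize_sequence(st$sequence)
  ms <- sample_mask(b, 0.15, seed = 2)
  expect_length(ms$mask$masked_positions, 15L)
  v <- pst_vocab()
  # specials never masked; corrupted positions hold the mask token
  expect_true(all(ms$mask$masked_positions %in% b$residue_rows))
  expect_true(all(ms$batch$token_ids[ms$mask$masked_positions] == v$mask_id))
  # unmasked tokens are untouched: the conditioning context is intact
  untouched <- setdiff(seq_along(b$token_ids), ms$mask$masked_positions)
  expect_identical(ms$batch$token_ids[untouched], b$token_ids[untouched])
  expect_identical(sample_mask(b, 0.15, seed = 2), ms)
  # floor rule never selects zero positions
  b3 <- tokenize_sequence("ACD")
  expect_length(sample_mask(b3, 0.1, seed = 1)$mask$masked_positions, 1L)
  expect_error(sample_mask(b, 0), "rate")
})

test_that("the MLM loss matches analytic anchors and a by-hand softmax", {
  v <- 25L
  logits <- matrix(0, 6, v)
  spec <- structure(list(masked_positions = c(2L, 4L), original_tokens = c(1L, 5L)),
                    class = "mask_spec")
  expect_equal(mlm_loss(logits, spec), log(25), tolerance = 1e-9)
  logits2 <- logits; logits2[2, 1] <- 100; logits2[4, 5] <- 100
  expect_lt(mlm_loss(logits2, spec), 1e-6)
  # two masked positions with hand-set 3-class logits
  l3 <- rbind(c(1, 2, 0.5), c(-1, 0, 3))
  spec3 <- structure(list(masked_positions = 1:2, original_tokens = c(2L, 1L)),
                     class = "mask_spec")
  manual <- mean(c(-log(exp(2) / sum(exp(c(1, 2, 0.5)))),
                   -log(exp(-1) / sum(exp(c(-1, 0, 3))))))
  expect_equal(mlm_loss(l3, spec3), manual, tolerance = 1e-12)
  expect_error(mlm_loss(logits, structure(list(masked_positions = integer(),
                                               original_tokens = integer()),
                                          class = "mask_spec")), "empty")
})

test_that("a uniformized LM head anchors the loss at ln(vocab)", {
  model <- tiny_model(seed = 1)
  model$backbone$lm_w[] <- 0
  model$backbone$lm_b[] <- 0
  st <- random_structure(20, seed = 2)
  b <- tokenize_sequence(st$sequence)
  ms <- sample_mask(b, 0.2, seed = 3)
  fw <- forward_pst(ms$batch, build_graph(st), model)
  expect_equal(mlm_loss(fw$logits, ms$mask), log(25), tolerance = 1e-9)
})

test_that("the LR schedule matches its closed form at the anchor steps", {
  cfg <- pretrain_config(base_lr = 0.002, warmup_steps = 100)
  expect_equal(lr_at(100, cfg), 0.002)
  expect_equal(lr_at(50, cfg), 0.001)
  expect_equal(lr_at(400, cfg), 0.001)
  expect_equal(lr_at(7, cfg), 0.002 * 7 / 100)
  expect_equal(lr_at(250, cfg), 0.002 * sqrt(100 / 250))
  expect_error(lr_at(0, cfg), "step")
})

test_that("analytic gradients match finite differences on a 5-residue toy", {
  model <- nudged_model(seed = 5, scale = 0.05)
  st <- random_structure(5, seed = 9)
  g <- build_graph(st)
  b <- tokenize_sequence(st$sequence)
  ms <- sample_mask(b, 0.4, seed = 1)
  flat_g <- analytic_mlm_grads(model, ms$batch, g, ms$mask)
  check <- list(c("adapter.1.wqs", 10L), c("adapter.2.wvs", 3L),
                c("adapter.1.gin.rounds.1.w1", 2L),
                c("backbone.layers.1.wq", 7L), c("backbone.emb", 25L),
                c("backbone.layers.2.w2", 11L))
  for (ck in check) {
    nm <- ck[[1]]; k <- as.integer(ck[[2]])
    num <- numeric_mlm_grad(model, ms$batch, g, ms$mask, nm, k)
    ana <- flat_g[[nm]][k]
    expect_lt(abs(ana - num) / max(abs(num), 1e-6), 1e-4)
  }
})

test_that("pretraining is seed-reproducible and the struct-only strategy freezes the backbone", {
  corp <- make_corpus(6, c(8, 14), seed = 3)
  model <- tiny_model(seed = 2)
  cfg <- pretrain_config(total_steps = 12, warmup_steps = 4, batch_size = 2, seed = 5)
  s1 <- pretrain(corp, model, cfg)
  s2 <- pretrain(corp, model, cfg)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$model$backbone, s2$model$backbone)
  cfg_so <- pretrain_config(total_steps = 12, warmup_steps = 4, batch_size = 2,
                            seed = 5, strategy = "struct_only")
  so <- pretrain(corp, model, cfg_so)
  expect_identical(so$model$backbone, model$backbone)  # bitwise frozen
  expect_false(identical(so$model$adapter, model$adapter))
  full <- pretrain(corp, model, cfg)
  expect_false(identical(full$model$backbone, model$backbone))
  expect_equal(nrow(so$trace), 12L)
  expect_error(pretrain(list(), model, cfg), "empty")
})

test_that("BERT-style corruption leaves some selected positions unmasked", {
  st <- random_structure(200, seed = 4)
  b <- tokenize_sequence(st$sequence)
  v <- pst_vocab()
  ms <- sample_mask(b, 0.5, seed = 6, scheme = "bert")
  corrupted <- ms$batch$token_ids[ms$mask$masked_positions]
  expect_true(any(corrupted == v$mask_id))
  expect_true(any(corrupted != v$mask_id))
  expect_identical(ms$mask$original_tokens, b$token_ids[ms$mask$masked_positions])
})
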