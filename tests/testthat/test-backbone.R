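# Tokenization, rotary embeddings, attention, the backbone forward pass,
# and parameter counting.

test_that("tokenization wraps residues in cls/eos and round-trips", {
  b <- tokenize_sequence("ACD")
  v <- pst_vocab()
  expect_length(b$token_ids, 5L)
  expect_identical(b$token_ids[c(1, 5)], c(v$cls_id, v$eos_id))
  expect_identical(detokenize(b), "ACD")
  withr::with_seed(1, {
    for (k in 1:10) {
      s <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
                        sample(1:40, 1), replace = TRUE), collapse = "")
      expect_identical(detokenize(tokenize_sequence(s)), s)
    }
  })
  expect_warning(bb <- tokenize_sequence("AB"), "non-canonical")
  expect_identical(detokenize(bb), "AX")
  expect_error(tokenize_sequence(""), "empty")
})

test_that("rotary map is the identity at position 0 and preserves norms", {
  withr::with_seed(2, {
    x <- matrix(rnorm(6 * 8), 6, 8)
    expect_equal(rotary_transform(x, rep(0, 6)), x)
    y <- rotary_transform(x, 0:5)
    expect_equal(sqrt(rowSums(y^2)), sqrt(rowSums(x^2)), tolerance = 1e-12)
    # inverse rotation undoes the forward map
    expect_equal(rotary_transform(y, 0:5, inverse = TRUE), x, tolerance = 1e-12)
  })
  expect_error(rotary_transform(matrix(0, 2, 3), 0:1), "even")
})

test_that("rotated query-key dot products depend only on relative position", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      q <- rnorm(8); k <- rnorm(8)
      i <- sample(0:50, 1); j <- sample(0:50, 1); s <- sample(1:40, 1)
      d1 <- sum(rotary_transform(matrix(q, 1), i) * rotary_transform(matrix(k, 1), j))
      d2 <- sum(rotary_transform(matrix(q, 1), i + s) * rotary_transform(matrix(k, 1), j + s))
      expect_equal(d1, d2, tolerance = 1e-6)
    }
  })
})

test_that("a single-token attention puts weight 1 on itself", {
  cfg <- tiny_config(n_layers = 1L)
  bb <- init_backbone(cfg, seed = 4)
  lp <- bb$params$layers[[1]]
  X <- matrix(rnorm(8, 0, 1), 1, 8)
  out <- self_attention(X, lp, cfg)
  v <- X %*% lp$wv + matrix(lp$bv, 1)
  expect_equal(out, v %*% lp$wo + matrix(lp$bo, 1), tolerance = 1e-12)
  expect_error(self_attention(X, lp, cfg, pad_mask = TRUE), "all-pad")
})

test_that("a 2-token single-head attention matches a step-by-step manual computation", {
  cfg <- backbone_config(n_layers = 1, model_dim = 2, n_heads = 1, ffn_dim = 4)
  bb <- init_backbone(cfg, seed = 5)
  lp <- bb$params$layers[[1]]
  lp$wq <- matrix(c(1, 0, 0, 1), 2); lp$bq <- c(0, 0)
  lp$wk <- matrix(c(0, 1, 1, 0), 2); lp$bk <- c(0, 0)
  lp$wv <- matrix(c(1, 1, 0, 1), 2); lp$bv <- c(0, 0)
  lp$wo <- diag(2); lp$bo <- c(0, 0)
  X <- matrix(c(0.5, -1, 0.25, 2), 2, 2)
  # manual: rotary at positions 0 and 1, then softmax(QK'/sqrt(2)) V
  rot <- function(v, p) {
    th <- p * 1  # base^0 frequency for the single coordinate pair
    c(v[1] * cos(th) - v[2] * sin(th), v[1] * sin(th) + v[2] * cos(th))
  }
  Q <- X %*% lp$wq; K <- X %*% lp$wk; V <- X %*% lp$wv
  Qr <- rbind(rot(Q[1, ], 0), rot(Q[2, ], 1))
  Kr <- rbind(rot(K[1, ], 0), rot(K[2, ], 1))
  S <- Qr %*% t(Kr) / sqrt(2)
  P <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  manual <- P %*% V
  expect_equal(self_attention(X, lp, cfg), manual, tolerance = 1e-12)
})

test_that("the backbone forward returns L block states and is deterministic", {
  cfg <- tiny_config(n_layers = 3L)
  bb <- init_backbone(cfg, seed = 6)
  b <- tokenize_sequence("ACDEFGHIK")
  out1 <- forward_backbone(b, bb)
  out2 <- forward_backbone(b, bb)
  expect_length(out1$hidden, 3L)
  for (H in out1$hidden) expect_equal(dim(H), c(11L, 8L))
  expect_equal(dim(out1$logits), c(11L, 25L))
  expect_identical(out1, out2)
})

test_that("zeroing the FFN reduces a block to its skip + attention term", {
  cfg <- tiny_config(n_layers = 1L)
  bb <- init_backbone(cfg, seed = 7)
  bb$params$layers[[1]]$w1[] <- 0
  bb$params$layers[[1]]$w2[] <- 0
  b <- tokenize_sequence("ACDEF")
  out <- forward_backbone(b, bb)
  lp <- bb$params$layers[[1]]
  X0 <- bb$params$emb[b$token_ids, ]
  A <- pst:::ln_fwd(X0, lp$ln1_g, lp$ln1_b)$y
  expect_equal(out$hidden[[1]], X0 + self_attention(A, lp, cfg), tolerance = 1e-12)
})

test_that("the forward pass carries positional information", {
  cfg <- tiny_config()
  bb <- init_backbone(cfg, seed = 8)
  s <- "ACDEFGHIKL"
  b1 <- tokenize_sequence(s)
  b2 <- tokenize_sequence(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  o1 <- forward_backbone(b1, bb)
  o2 <- forward_backbone(b2, bb)
  # with positional information, residue states of a reversed sequence are
  # not simply the reversed residue states
  expect_gt(max(abs(o1$logits[b1$residue_rows, ] -
                      o2$logits[rev(b2$residue_rows), ])), 1e-6)
  # over-length inputs are rejected, not cropped
  cfg_short <- backbone_config(1, 8, 2, max_len = 6)
  bbs <- init_backbone(cfg_short, seed = 1)
  expect_error(forward_backbone(tokenize_sequence("ACDEFGH"), bbs), "exceeds")
})

test_that("parameter counts match a closed-form shape oracle", {
  cfg <- backbone_config(n_layers = 2, model_dim = 8, n_heads = 2, ffn_dim = 16,
                         vocab_size = 25)
  bb <- init_backbone(cfg, seed = 9)
  d <- 8; f <- 16; v <- 25; L <- 2
  per_layer <- 2 * d +            # ln1
    4 * (d * d + d) +             # q, k, v, o projections with biases
    2 * d +                       # ln2
    (d * f + f) + (f * d + d)     # ffn
  expected <- v * d + L * per_layer + 2 * d + (d * v + v)
  expect_identical(count_parameters(bb), expected)
  model <- tiny_model(cfg, seed = 9)
  expect_gte(count_parameters(model), count_parameters(bb))
})

test_that("structure-augmented variants stay under twice the backbone size", {
  # shapes mirroring the published 6-, 12-, 30- and 33-layer backbones
  shapes <- list(c(6, 320, 20), c(12, 480, 20), c(30, 640, 20), c(33, 1280, 20))
  for (sh in shapes) {
    cfg <- backbone_config(sh[1], sh[2], sh[3])
    d <- sh[2]; L <- sh[1]; f <- 4 * d; v <- 25
    n_backbone <- v * d + L * (2 * d + 4 * (d * d + d) + 2 * d +
                                 (d * f + f) + (f * d + d)) + 2 * d + (d * v + v)
    gin_per_layer <- 2 * ((d * d + d) + (d * d + d))   # two rounds of 2-layer MLPs
    n_adapter <- L * (gin_per_layer + 3 * d * d)
    ratio <- (n_backbone + n_adapter) / n_backbone
    expect_lt(ratio, 2)
  }
  # and the counted (not just closed-form) ratio for a small instantiation
  cfg <- backbone_config(6, 64, 4)
  bb <- init_backbone(cfg, seed = 1)
  model <- assemble_pst(bb, adapter_config(), seed = 2)
  expect_lt(count_parameters(model) / count_parameters(bb), 2)
})
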