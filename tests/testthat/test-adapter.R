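# The structure adapter: GIN extractors, zero-initialized injection,
# bypass equivalence, locality, and the weight import contract.

test_that("GIN with identity MLPs and no edges is the identity map", {
  st <- protein_structure("iso", rep("A", 4),
                          cbind(c(0, 100, 200, 300), 0, 0))
  g <- build_graph(st, graph_config(threshold = 8))
  expect_equal(nrow(g$edges), 0L)
  H <- matrix(abs(rnorm(4 * 3)), 4, 3)  # non-negative: ReLU is identity
  theta <- identity_gin(3, rounds = 1L)
  expect_equal(gin_extract(H, g, theta, adapter_config(gin_layers = 1)), H)
})

test_that("one GIN round on a path sums each node with its neighbors", {
  g <- path_graph(3)
  H <- matrix(abs(rnorm(9)), 3, 3)
  out <- gin_extract(H, g, identity_gin(3), adapter_config(gin_layers = 1))
  expect_equal(out[2, ], H[1, ] + H[2, ] + H[3, ])
  expect_equal(out[1, ], H[1, ] + H[2, ])
  expect_equal(out[3, ], H[2, ] + H[3, ])
  expect_error(gin_extract(H[1:2, ], g, identity_gin(3), adapter_config()),
               "shape error")
})

test_that("extractors default to two message-passing rounds", {
  expect_identical(adapter_config()$gin_layers, 2L)
  model <- tiny_model()
  expect_length(model$adapter[[1]]$gin$rounds, 2L)
})

test_that("a 2-round extractor has a graph-distance-2 receptive field", {
  n <- 9
  g <- path_graph(n)
  H <- matrix(abs(rnorm(n * 3)), n, 3)
  theta <- identity_gin(3, rounds = 2L)
  cfg <- adapter_config(gin_layers = 2)
  base <- gin_extract(H, g, theta, cfg)
  H2 <- H; H2[5, ] <- H2[5, ] + 1  # perturb the center node's state
  out <- gin_extract(H2, g, theta, cfg)
  changed <- rowSums(abs(out - base)) > 1e-12
  expect_identical(which(changed), 3:7)  # within distance 2 of node 5 only
})

test_that("assembly zero-initializes every injection matrix and copies the backbone", {
  bb <- init_backbone(tiny_config(), seed = 1)
  model <- assemble_pst(bb, adapter_config(), seed = 2)
  for (l in seq_along(model$adapter)) {
    expect_true(all(model$adapter[[l]]$wqs == 0))
    expect_true(all(model$adapter[[l]]$wks == 0))
    expect_true(all(model$adapter[[l]]$wvs == 0))
  }
  expect_identical(model$backbone, bb$params)
})

test_that("a freshly assembled model mirrors its backbone on random fixtures", {
  model <- tiny_model(seed = 3)
  for (s in 1:10) {
    st <- random_structure(sample(5:25, 1), seed = s)
    b <- tokenize_sequence(st$sequence)
    g <- build_graph(st)
    fs <- forward_pst(b, g, model)
    fb <- forward_backbone(b, model)
    expect_lt(max(abs(fs$logits - fb$logits)), 1e-5)
    for (l in seq_along(fs$hidden)) {
      expect_lt(max(abs(fs$hidden[[l]] - fb$hidden[[l]])), 1e-5)
    }
  }
})

test_that("adapter parameter count follows the shape formula", {
  cfg <- tiny_config()
  bb <- init_backbone(cfg, seed = 1)
  model <- assemble_pst(bb, adapter_config(), seed = 2)
  d <- cfg$model_dim; L <- cfg$n_layers
  theta_count <- 2 * ((d * d + d) + (d * d + d))
  expect_identical(count_parameters(model),
                   count_parameters(bb) + L * (theta_count + 3 * d * d))
})

test_that("bypass equals the backbone bitwise at any parameter state", {
  model <- nudged_model(seed = 4)  # nonzero injections: a 'trained' state
  st <- random_structure(12, seed = 5)
  b <- tokenize_sequence(st$sequence)
  g <- build_graph(st)
  expect_identical(forward_pst(b, g, model, bypass = TRUE),
                   forward_backbone(b, model))
  # and the structural path now genuinely differs from the backbone
  expect_gt(max(abs(forward_pst(b, g, model)$logits -
                      forward_backbone(b, model)$logits)), 0)
})

test_that("a single nonzero injection entry breaks backbone equivalence", {
  model <- tiny_model(seed = 6)
  st <- make_chain("extended", 3, seed = 1, bond_length = 5)  # a 2-edge graph
  b <- tokenize_sequence(st$sequence)
  g <- build_graph(st)
  expect_equal(nrow(g$edges), 2L)
  model$adapter[[1]]$wqs[1, 1] <- 0.1
  expect_gt(max(abs(forward_pst(b, g, model)$logits -
                      forward_backbone(b, model)$logits)), 0)
})

test_that("structural output is sensitive to graph perturbations", {
  model <- nudged_model(seed = 7)
  st <- make_chain("helix", 15, seed = 2)
  b <- tokenize_sequence(st$sequence)
  g <- build_graph(st)
  for (mode in c("sequential_only", "rewired", "fully_connected")) {
    gp <- perturb_graph(g, mode, seed = 1)
    expect_gt(max(abs(forward_pst(b, g, model)$logits -
                        forward_pst(b, gp, model)$logits)), 0)
  }
})

test_that("backbone weight export/import is a bitwise round trip with strict shapes", {
  cfg <- tiny_config()
  bb <- init_backbone(cfg, seed = 8)
  arc <- export_backbone_weights(bb)
  back <- import_backbone_weights(arc, cfg)
  expect_identical(back$params, bb$params)
  # missing key errors by name
  arc2 <- arc; arc2[["layers.1.wq"]] <- NULL
  expect_error(import_backbone_weights(arc2, cfg), "missing weight: layers.1.wq")
  # transposed shape errors (no silent transpose)
  arc3 <- arc; arc3[["layers.1.w1"]] <- t(arc3[["layers.1.w1"]])
  expect_error(import_backbone_weights(arc3, cfg), "shape error for 'layers.1.w1'")
  # unknown keys are reported
  arc4 <- arc; arc4[["mystery"]] <- 1
  expect_warning(import_backbone_weights(arc4, cfg), "unknown keys: mystery")
})

test_that("model checkpoints round-trip bitwise through the JSON archive", {
  model <- nudged_model(seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$backbone, model$backbone)
  expect_identical(back$adapter, model$adapter)
  expect_identical(unclass(back$config), unclass(model$config))
  bb <- init_backbone(tiny_config(), seed = 10)
  f2 <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(bb, f2)
  expect_identical(load_checkpoint(f2)$params, bb$params)
})

test_that("edge-feature (GINE) extractors run and respond to edge features", {
  st <- make_chain("helix", 10, seed = 3)
  g <- build_graph(st, graph_config(edge_features = TRUE))
  bb <- init_backbone(tiny_config(), seed = 11)
  model <- assemble_pst(bb, adapter_config(use_edge_features = TRUE), seed = 12)
  b <- tokenize_sequence(st$sequence)
  # still mirrors the backbone at assembly (zero injections)
  expect_lt(max(abs(forward_pst(b, g, model)$logits -
                      forward_backbone(b, model)$logits)), 1e-5)
  # a graph without features is rejected
  g0 <- build_graph(st)
  model$adapter[[1]]$wqs[1, 1] <- 0.1
  expect_error(forward_pst(b, g0, model), "edge features")
})
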