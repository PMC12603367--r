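# Small model fixtures shared by the tests.  Everything is generated in
# code under fixed seeds.

tiny_config <- function(n_layers = 2L, model_dim = 8L, n_heads = 2L,
                        ffn_dim = 16L) {
  backbone_config(n_layers, model_dim, n_heads, ffn_dim)
}

tiny_model <- function(config = tiny_config(), seed = 1L,
                       adapter = adapter_config()) {
  assemble_pst(init_backbone(config, seed = seed), adapter, seed = seed + 1L)
}

# A model whose injection matrices are nonzero, so the structural path
# influences the output (emulates a trained state).
nudged_model <- function(config = tiny_config(), seed = 1L, scale = 0.05) {
  model <- tiny_model(config, seed)
  d <- config$model_dim
  withr::with_seed(seed + 7L, {
    for (l in seq_along(model$adapter)) {
      model$adapter[[l]]$wqs <- matrix(rnorm(d * d, 0, scale), d, d)
      model$adapter[[l]]$wks <- matrix(rnorm(d * d, 0, scale), d, d)
      model$adapter[[l]]$wvs <- matrix(rnorm(d * d, 0, scale), d, d)
    }
  })
  model
}

random_structure <- function(n, seed) make_chain("coil", n, seed = seed)

# GIN parameters acting as the identity map on each round (for
# non-negative inputs, since the hidden activation is ReLU).
identity_gin <- function(d, rounds = 1L) {
  list(rounds = lapply(seq_len(rounds), function(r) {
    list(w1 = diag(d), b1 = rep(0, d), w2 = diag(d), b2 = rep(0, d))
  }))
}

path_graph <- function(n, labels = rep("A", n)) {
  st <- protein_structure("path", labels,
                          cbind(seq_len(n) * 3.8, 0, 0))
  build_graph(st, graph_config(threshold = 4))
}
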