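# Assembling and running the structure-augmented model.  The single
# forward core serves both the plain backbone (no structural terms) and
# the full model; the bypass path executes literally the same operations
# as the backbone forward, so bypass output is bitwise-equal to it.

#' Assemble a structure-augmented model from a backbone
#'
#' Attaches, to every transformer block, a GIN structure extractor
#' (randomly initialized under `seed`) and three `d x d` injection
#' matrices `wqs`, `wks`, `wvs` initialized exactly at zero.  Because the
#' injections are zero, the assembled model's forward pass reproduces the
#' backbone's to machine precision until training moves them.
#'
#' @param backbone A `pst_backbone` from [init_backbone()] or
#'   [import_backbone_weights()].
#' @param adapter An [adapter_config()].
#' @param seed Integer seed for extractor initialization.
#' @param init_std Standard deviation for extractor weights.
#' @return A `pst_model`: list with `config`, `backbone` (parameters,
#'   copied unchanged), `adapter_config` and `adapter` (per-layer
#'   extractor + injection parameters).
#' @export
assemble_pst <- function(backbone, adapter = adapter_config(), seed = 1L,
                         init_std = 0.02) {
  stopifnot(inherits(backbone, "pst_backbone"), inherits(adapter, "adapter_config"))
  d <- backbone$config$model_dim
  L <- backbone$config$n_layers
  adapter_params <- withr::with_seed(seed, {
    if (adapter$share_across_layers) {
      shared <- init_gin_params(d, adapter, init_std)
      lapply(seq_len(L), function(l) {
        list(gin = shared,
             wqs = matrix(0, d, d), wks = matrix(0, d, d), wvs = matrix(0, d, d))
      })
    } else {
      lapply(seq_len(L), function(l) {
        list(gin = init_gin_params(d, adapter, init_std),
             wqs = matrix(0, d, d), wks = matrix(0, d, d), wvs = matrix(0, d, d))
      })
    }
  })
  structure(list(config = backbone$config, backbone = backbone$params,
                 adapter_config = adapter, adapter = adapter_params),
            class = "pst_model")
}

#' @export
print.pst_model <- function(x, ...) {
  cat(sprintf("<pst_model> L=%d d=%d h=%d | %d params (backbone %d)\n",
              x$config$n_layers, x$config$model_dim, x$config$n_heads,
              count_parameters(x), count_list(x$backbone)))
  invisible(x)
}

# Shared forward core.  `adapter = NULL` or `bypass = TRUE` gives the
# sequence-only computation.
pst_forward_core <- function(batch, config, backbone, adapter, adapter_cfg,
                             graph, bypass, want_cache = FALSE) {
  stopifnot(inherits(batch, "token_batch"))
  ids <- batch$token_ids
  Tn <- length(ids)
  if (Tn > config$max_len) {
    stop(sprintf("sequence of %d tokens exceeds the configured maximum of %d",
                 Tn, config$max_len), call. = FALSE)
  }
  if (all(batch$pad_mask)) stop("all-pad input", call. = FALSE)
  use_struct <- !bypass && !is.null(adapter)
  if (use_struct) {
    if (is.null(graph)) stop("structural forward requires a graph", call. = FALSE)
    if (graph$n_nodes != batch$n_residues) {
      stop(sprintf("alignment error: %d graph nodes vs %d residues",
                   graph$n_nodes, batch$n_residues), call. = FALSE)
    }
  }
  res <- batch$residue_rows
  X <- backbone$emb[ids, , drop = FALSE]
  L <- config$n_layers
  hidden <- vector("list", L)
  layer_caches <- if (want_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    lp <- backbone$layers[[l]]
    X_in <- X
    ln1 <- ln_fwd(X, lp$ln1_g, lp$ln1_b)
    A <- ln1$y
    S <- NULL; gin_cache <- NULL
    if (use_struct) {
      gf <- gin_fwd(A[res, , drop = FALSE], graph, adapter[[l]]$gin,
                    adapter_cfg, want_cache = want_cache)
      S <- matrix(0, Tn, config$model_dim)
      S[res, ] <- gf$out
      gin_cache <- gf$cache
    }
    at <- attn_fwd(A, lp, config, batch$pad_mask, S = S,
                   adapter_l = if (use_struct) adapter[[l]] else NULL,
                   want_cache = want_cache)
    X1 <- X + at$out
    ln2 <- ln_fwd(X1, lp$ln2_g, lp$ln2_b)
    B <- ln2$y
    pre <- add_bias(B %*% lp$w1, lp$b1)
    Hact <- act_fwd(pre, config$activation)
    X <- X1 + add_bias(Hact %*% lp$w2, lp$b2)
    hidden[[l]] <- X
    if (want_cache) {
      layer_caches[[l]] <- list(X_in = X_in, ln1 = ln1, A = A,
                                gin = gin_cache, attn = at$cache,
                                X1 = X1, ln2 = ln2, B = B,
                                pre = pre, Hact = Hact)
    }
  }
  lnf <- ln_fwd(X, backbone$lnf_g, backbone$lnf_b)
  logits <- add_bias(lnf$y %*% backbone$lm_w, backbone$lm_b)
  cache <- if (want_cache) {
    list(ids = ids, pad_mask = batch$pad_mask, res = res, use_struct = use_struct,
         layers = layer_caches, lnf = lnf, Yf = lnf$y, X_top = X)
  } else NULL
  list(hidden = hidden, logits = logits, cache = cache)
}

#' Forward pass of the sequence backbone
#'
#' Runs the encoder over a token batch and returns all block outputs plus
#' LM-head logits.  Inference is deterministic (no dropout).
#'
#' @param batch A `token_batch` from [tokenize_sequence()].
#' @param backbone A `pst_backbone`, or a `pst_model` (whose backbone
#'   parameters are then used, ignoring the adapter).
#' @return List with `hidden` (length-`L` list of `T x d` matrices, one
#'   per block) and `logits` (`T x vocab_size`).
#' @export
forward_backbone <- function(batch, backbone) {
  if (inherits(backbone, "pst_model")) {
    cfg <- backbone$config; par <- backbone$backbone
  } else {
    stopifnot(inherits(backbone, "pst_backbone"))
    cfg <- backbone$config; par <- backbone$params
  }
  out <- pst_forward_core(batch, cfg, par, adapter = NULL, adapter_cfg = NULL,
                          graph = NULL, bypass = TRUE)
  out["cache"] <- NULL
  out
}

#' Forward pass of the structure-augmented model
#'
#' At every block, the structure extractor runs on that block's normalized
#' residue states over the contact graph; its output, through the
#' `wqs`/`wks`/`wvs` projections, is added to the query, key and value
#' matrices at residue positions (special tokens receive a zero structural
#' term) before rotary and softmax.  With `bypass = TRUE` all structural
#' terms are skipped and the computation is exactly the backbone's.
#'
#' @param batch A `token_batch`; residue rows must align with graph nodes.
#' @param graph A `protein_graph` with `n_nodes == batch$n_residues`
#'   (ignored when `bypass = TRUE`).
#' @param model A `pst_model`.
#' @param bypass Skip the structure extractors.
#' @return List with `hidden` (length-`L` list of `T x d`) and `logits`.
#' @export
forward_pst <- function(batch, graph, model, bypass = FALSE) {
  stopifnot(inherits(model, "pst_model"))
  out <- pst_forward_core(batch, model$config, model$backbone, model$adapter,
                          model$adapter_config, graph, bypass = bypass)
  out["cache"] <- NULL
  out
}
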