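# GIN structure extractors: per-attention-block graph neural networks
# computing local-structure features from the residue states feeding that
# block.  Each round applies MLP((1 + eps) * h_i + sum_{j in N(i)} m_ij)
# with m_ij = h_j, or (with edge features) m_ij = relu(h_j + e_ij W_e)
# (GINE-style modulation).

#' Structure-extractor (adapter) configuration
#'
#' @param gin_layers Number of message-passing rounds per extractor
#'   (default 2).
#' @param gin_hidden_dim Hidden width of each round's 2-layer MLP;
#'   default `NULL` means the model width `d`.
#' @param gin_epsilon Fixed (non-learnable) GIN epsilon; default 0.
#' @param use_edge_features Use GINE-style edge-feature modulation of
#'   messages; requires graphs built with `edge_features = TRUE`.
#' @param edge_dim Edge-feature dimension (default 16, matching the
#'   radial-basis distance expansion).
#' @param share_across_layers If `TRUE`, a single extractor is shared by
#'   all attention blocks (inference-time ablation; extractors are
#'   independent per layer by default and during pretraining).
#' @return An `adapter_config` list.
#' @export
adapter_config <- function(gin_layers = 2L, gin_hidden_dim = NULL,
                           gin_epsilon = 0, use_edge_features = FALSE,
                           edge_dim = 16L, share_across_layers = FALSE) {
  gin_layers <- as.integer(gin_layers)
  if (gin_layers < 1L) stop("gin_layers must be >= 1", call. = FALSE)
  structure(list(gin_layers = gin_layers, gin_hidden_dim = gin_hidden_dim,
                 gin_epsilon = gin_epsilon,
                 use_edge_features = isTRUE(use_edge_features),
                 edge_dim = as.integer(edge_dim),
                 share_across_layers = isTRUE(share_across_layers)),
            class = "adapter_config")
}

init_gin_params <- function(d, adapter_cfg, init_std = 0.02) {
  gh <- adapter_cfg$gin_hidden_dim %||% d
  rounds <- lapply(seq_len(adapter_cfg$gin_layers), function(r) {
    p <- list(w1 = rand_mat(d, gh, init_std), b1 = rep(0, gh),
              w2 = rand_mat(gh, d, init_std), b2 = rep(0, d))
    if (adapter_cfg$use_edge_features) {
      p$we <- rand_mat(adapter_cfg$edge_dim, d, init_std)
      p$be <- rep(0, d)
    }
    p
  })
  list(rounds = rounds)
}

# Directed edge expansion: each unordered pair contributes both directions.
graph_directed <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(list(src = integer(), dst = integer(), feat = graph$edge_feats))
  }
  list(src = c(e[, 1L], e[, 2L]), dst = c(e[, 2L], e[, 1L]),
       feat = if (!is.null(graph$edge_feats)) rbind(graph$edge_feats, graph$edge_feats) else NULL)
}

# Sum rows of `msgs` into groups given by `dst`, returning an n x d matrix.
scatter_sum <- function(msgs, dst, n) {
  out <- matrix(0, n, ncol(msgs))
  if (length(dst) == 0L) return(out)
  rs <- rowsum(msgs, group = dst)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

gin_fwd <- function(H, graph, theta, adapter_cfg, want_cache = FALSE) {
  n <- nrow(H)
  de <- graph_directed(graph)
  use_e <- adapter_cfg$use_edge_features
  if (use_e && is.null(de$feat) && length(de$src) > 0L) {
    stop("adapter expects edge features but the graph carries none", call. = FALSE)
  }
  eps <- adapter_cfg$gin_epsilon
  rounds_cache <- if (want_cache) vector("list", length(theta$rounds)) else NULL
  for (r in seq_along(theta$rounds)) {
    p <- theta$rounds[[r]]
    if (length(de$src) > 0L) {
      if (use_e) {
        msg_pre <- H[de$src, , drop = FALSE] + add_bias(de$feat %*% p$we, p$be)
        msgs <- pmax(msg_pre, 0)
      } else {
        msg_pre <- NULL
        msgs <- H[de$src, , drop = FALSE]
      }
      agg <- scatter_sum(msgs, de$dst, n)
    } else {
      msg_pre <- NULL
      agg <- matrix(0, n, ncol(H))
    }
    Z <- (1 + eps) * H + agg
    pre1 <- add_bias(Z %*% p$w1, p$b1)
    A1 <- pmax(pre1, 0)
    out <- add_bias(A1 %*% p$w2, p$b2)
    if (want_cache) {
      rounds_cache[[r]] <- list(H_in = H, msg_pre = msg_pre, Z = Z,
                                pre1 = pre1, A1 = A1)
    }
    H <- out
  }
  list(out = H, cache = if (want_cache) list(rounds = rounds_cache, de = de) else NULL)
}

gin_bwd <- function(dOut, cache, theta, adapter_cfg) {
  de <- cache$de
  eps <- adapter_cfg$gin_epsilon
  use_e <- adapter_cfg$use_edge_features
  grads <- list(rounds = vector("list", length(theta$rounds)))
  dH <- dOut
  for (r in rev(seq_along(theta$rounds))) {
    p <- theta$rounds[[r]]
    cc <- cache$rounds[[r]]
    dA1 <- dH %*% t(p$w2)
    g <- list(w1 = NULL, b1 = NULL,
              w2 = t(cc$A1) %*% dH, b2 = colSums(dH))
    dpre1 <- dA1 * (cc$pre1 > 0)
    g$w1 <- t(cc$Z) %*% dpre1
    g$b1 <- colSums(dpre1)
    dZ <- dpre1 %*% t(p$w1)
    dH_in <- (1 + eps) * dZ
    if (length(de$src) > 0L) {
      dmsg <- dZ[de$dst, , drop = FALSE]
      if (use_e) {
        gate <- cc$msg_pre > 0
        dmsg_pre <- dmsg * gate
        g$we <- t(de$feat) %*% dmsg_pre
        g$be <- colSums(dmsg_pre)
        dH_in <- dH_in + scatter_sum(dmsg_pre, de$src, nrow(dH_in))
      } else {
        dH_in <- dH_in + scatter_sum(dmsg, de$src, nrow(dH_in))
      }
    } else if (use_e) {
      g$we <- matrix(0, adapter_cfg$edge_dim, ncol(dH))
      g$be <- rep(0, ncol(dH))
    }
    grads$rounds[[r]] <- g
    dH <- dH_in
  }
  list(dH = dH, grads = grads)
}

#' Run a structure extractor over residue states
#'
#' Applies `gin_layers` rounds of GIN message passing on the contact
#' graph, each round an aggregation `(1 + eps) h_i + sum_{j in N(i)} m_ij`
#' followed by a 2-layer MLP.  This is the `phi_theta(X, G)` whose output,
#' after zero-initialized projections, augments the query/key/value
#' matrices of the corresponding attention block.
#'
#' @param X_res `n x d` residue-state matrix (`n = graph$n_nodes`).
#' @param graph A `protein_graph`.
#' @param theta Extractor parameters (one element of a model's `adapter`,
#'   i.e. a list with `rounds`; see [assemble_pst()]).
#' @param config An [adapter_config()].
#' @return `n x d` matrix of structure-aware residue features.
#' @export
gin_extract <- function(X_res, graph, theta, config = adapter_config()) {
  stopifnot(inherits(graph, "protein_graph"))
  if (nrow(X_res) != graph$n_nodes) {
    stop(sprintf("shape error: %d state rows vs %d graph nodes",
                 nrow(X_res), graph$n_nodes), call. = FALSE)
  }
  gin_fwd(X_res, graph, theta, config, want_cache = FALSE)$out
}
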