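# Encoder-only transformer backbone: pre-layer-norm blocks, multi-head
# self-attention with rotary position embeddings, GELU (or ReLU) FFN,
# and a masked-LM head.  All parameters are plain base-R matrices so the
# analytic backward pass in backward.R can mirror the forward exactly.

#' Backbone transformer configuration
#'
#' @param n_layers Number of transformer blocks (>= 1).
#' @param model_dim Model width `d`; must be divisible by `n_heads`, and
#'   the per-head width must be even (rotary embeddings rotate coordinate
#'   pairs).
#' @param n_heads Number of attention heads.
#' @param ffn_dim Feed-forward hidden width; default `4 * model_dim`.
#' @param vocab_size Vocabulary size; default 25 (see [pst_vocab()]).
#' @param rotary_base Rotary frequency base.
#' @param activation FFN activation, `"gelu"` (default) or `"relu"`.
#' @param max_len Maximum token-sequence length; longer inputs are
#'   rejected rather than cropped.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(n_layers, model_dim, n_heads,
                            ffn_dim = 4L * model_dim, vocab_size = 25L,
                            rotary_base = 10000, activation = c("gelu", "relu"),
                            max_len = 1024L) {
  activation <- match.arg(activation)
  n_layers <- as.integer(n_layers); model_dim <- as.integer(model_dim)
  n_heads <- as.integer(n_heads); ffn_dim <- as.integer(ffn_dim)
  if (n_layers < 1L || model_dim < 1L || n_heads < 1L || ffn_dim < 1L || vocab_size < 1L) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (model_dim %% n_heads != 0L) stop("model_dim must be divisible by n_heads", call. = FALSE)
  if ((model_dim %/% n_heads) %% 2L != 0L) {
    stop("per-head dimension must be even for rotary embeddings", call. = FALSE)
  }
  structure(list(n_layers = n_layers, model_dim = model_dim, n_heads = n_heads,
                 ffn_dim = ffn_dim, vocab_size = as.integer(vocab_size),
                 rotary_base = as.numeric(rotary_base), activation = activation,
                 max_len = as.integer(max_len)),
            class = "backbone_config")
}

rand_mat <- function(nr, nc, std) matrix(rnorm(nr * nc, 0, std), nr, nc)

#' Initialize backbone parameters
#'
#' Scaled-normal initialization (sd `init_std`) under `seed`; layer-norm
#' gains start at 1, biases at 0.  In practice backbones are imported
#' pretrained ([import_backbone_weights()]); random initialization is the
#' defined fallback for self-contained experiments.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed.
#' @param init_std Standard deviation of weight entries.
#' @return A `pst_backbone`: list with `config` and `params`.
#' @export
init_backbone <- function(config, seed = 1L, init_std = 0.02) {
  stopifnot(inherits(config, "backbone_config"))
  d <- config$model_dim; f <- config$ffn_dim; v <- config$vocab_size
  params <- withr::with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(ln1_g = rep(1, d), ln1_b = rep(0, d),
           wq = rand_mat(d, d, init_std), bq = rep(0, d),
           wk = rand_mat(d, d, init_std), bk = rep(0, d),
           wv = rand_mat(d, d, init_std), bv = rep(0, d),
           wo = rand_mat(d, d, init_std), bo = rep(0, d),
           ln2_g = rep(1, d), ln2_b = rep(0, d),
           w1 = rand_mat(d, f, init_std), b1 = rep(0, f),
           w2 = rand_mat(f, d, init_std), b2 = rep(0, d))
    })
    list(emb = rand_mat(v, d, init_std),
         layers = layers,
         lnf_g = rep(1, d), lnf_b = rep(0, d),
         lm_w = rand_mat(d, v, init_std), lm_b = rep(0, v))
  })
  structure(list(config = config, params = params), class = "pst_backbone")
}

#' Count scalar parameters of a backbone or assembled model
#'
#' @param x A `pst_backbone`, `pst_model`, or bare parameter list.
#' @return Total number of scalar parameters (integer-valued double).
#' @export
count_parameters <- function(x) {
  if (inherits(x, "pst_model")) {
    return(count_list(x$backbone) + count_list(x$adapter))
  }
  if (inherits(x, "pst_backbone")) return(count_list(x$params))
  count_list(x)
}

count_list <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (is.list(x)) return(sum(vapply(x, count_list, 0)))
  0
}

#' Apply the rotary position map to per-head vectors
#'
#' Rotates each consecutive coordinate pair `(x_{2k-1}, x_{2k})` of row
#' `t` by angle `positions[t] * rotary_base^(-2(k-1)/d_head)`.  Rotations
#' preserve norms, and rotated query/key dot products depend only on
#' relative position.
#'
#' @param x `T x d_head` matrix; `d_head` must be even.
#' @param positions Integer positions, one per row (0-based by convention).
#' @param base Rotary frequency base.
#' @param inverse If `TRUE`, apply the inverse rotation (used by the
#'   backward pass).
#' @return Matrix of the same shape.
#' @export
rotary_transform <- function(x, positions, base = 10000, inverse = FALSE) {
  dh <- ncol(x)
  if (dh %% 2L != 0L) stop("rotary requires an even per-head dimension", call. = FALSE)
  k <- seq_len(dh %/% 2L)
  ang <- outer(positions, base^(-(2 * (k - 1)) / dh))
  if (inverse) ang <- -ang
  cs <- cos(ang); sn <- sin(ang)
  odd <- seq.int(1L, dh, 2L); even <- odd + 1L
  x1 <- x[, odd, drop = FALSE]; x2 <- x[, even, drop = FALSE]
  out <- x
  out[, odd] <- x1 * cs - x2 * sn
  out[, even] <- x1 * sn + x2 * cs
  out
}

# --- numerical primitives (forward + backward) ------------------------------

row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

log_softmax_vec <- function(z) {
  m <- max(z)
  z - m - log(sum(exp(z - m)))
}

LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, "*")
  y <- sweep(y, 2L, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

act_fwd <- function(x, activation) {
  if (activation == "gelu") x * pnorm(x) else pmax(x, 0)
}

act_bwd <- function(dy, x, activation) {
  if (activation == "gelu") dy * (pnorm(x) + x * dnorm(x)) else dy * (x > 0)
}

add_bias <- function(x, b) sweep(x, 2L, b, "+")

#' One multi-head self-attention layer (inference view)
#'
#' Projects `X` to queries, keys and values, applies the rotary map to
#' queries and keys per head, computes `softmax(Q Kᵀ / sqrt(d_head)) V`
#' per head with padded keys masked out, concatenates heads, and applies
#' the output projection.  This is the standalone sequence-only view; the
#' full model forward additionally injects structure terms into Q/K/V.
#'
#' @param X `T x d` input matrix.
#' @param layer_params One element of `init_backbone()$params$layers`.
#' @param config The [backbone_config()].
#' @param pad_mask Logical length-`T` vector flagging padding rows.
#' @return `T x d` attention output.
#' @export
self_attention <- function(X, layer_params, config, pad_mask = NULL) {
  if (is.null(pad_mask)) pad_mask <- rep(FALSE, nrow(X))
  if (all(pad_mask)) stop("attention over an all-pad input is undefined", call. = FALSE)
  attn_fwd(X, layer_params, config, pad_mask, S = NULL, adapter_l = NULL,
           want_cache = FALSE)$out
}

NEG_BIG <- -1e30  # additive mask for padded keys; finite to keep softmax NaN-free

attn_fwd <- function(A, lp, config, pad_mask, S = NULL, adapter_l = NULL,
                     want_cache = FALSE) {
  Tn <- nrow(A); d <- config$model_dim
  h <- config$n_heads; dh <- d %/% h
  Q <- add_bias(A %*% lp$wq, lp$bq)
  K <- add_bias(A %*% lp$wk, lp$bk)
  V <- add_bias(A %*% lp$wv, lp$bv)
  if (!is.null(S)) {
    Q <- Q + S %*% adapter_l$wqs
    K <- K + S %*% adapter_l$wks
    V <- V + S %*% adapter_l$wvs
  }
  positions <- seq_len(Tn) - 1
  pad_cols <- which(pad_mask)
  concat <- matrix(0, Tn, d)
  heads <- if (want_cache) vector("list", h) else NULL
  for (hh in seq_len(h)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    Qr <- rotary_transform(Q[, idx, drop = FALSE], positions, config$rotary_base)
    Kr <- rotary_transform(K[, idx, drop = FALSE], positions, config$rotary_base)
    Sc <- (Qr %*% t(Kr)) / sqrt(dh)
    if (length(pad_cols)) Sc[, pad_cols] <- NEG_BIG
    P <- row_softmax(Sc)
    concat[, idx] <- P %*% V[, idx, drop = FALSE]
    if (want_cache) heads[[hh]] <- list(Qr = Qr, Kr = Kr, P = P)
  }
  out <- add_bias(concat %*% lp$wo, lp$bo)
  cache <- if (want_cache) {
    list(A = A, Q = Q, K = K, V = V, S = S, heads = heads, concat = concat,
         positions = positions)
  } else NULL
  list(out = out, cache = cache)
}
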