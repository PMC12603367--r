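# Flat parameter views and the AdamW optimizer.  Parameter trees are
# nested named lists of numeric arrays; flattening joins path components
# with '.' (unnamed list positions contribute their index), so gradients
# produced by pst_backward align with parameters name-for-name.

flatten_params <- function(x, prefix = "") {
  if (is.numeric(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    out <- list()
    for (i in seq_along(x)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      path <- if (nzchar(prefix)) paste(prefix, key, sep = ".") else key
      out <- c(out, flatten_params(x[[i]], path))
    }
    return(out)
  }
  list()
}

unflatten_params <- function(template, flat, prefix = "") {
  if (is.numeric(template)) {
    v <- flat[[prefix]]
    if (is.null(v)) stop("missing weight: ", prefix, call. = FALSE)
    return(v)
  }
  if (is.list(template)) {
    nms <- names(template)
    out <- template
    for (i in seq_along(template)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      path <- if (nzchar(prefix)) paste(prefix, key, sep = ".") else key
      out[[i]] <- unflatten_params(template[[i]], flat, path)
    }
    return(out)
  }
  template
}

adamw_init <- function(flat) {
  list(m = lapply(flat, zero_like), v = lapply(flat, zero_like), t = 0L)
}

# Decoupled weight decay, applied to weight matrices only (biases and
# layer-norm gains are excluded, the usual transformer convention).
adamw_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.98,
                       eps = 1e-8, weight_decay = 0.01, update_names = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  nms <- update_names %||% names(flat)
  for (nm in nms) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (is.matrix(flat[[nm]])) upd <- upd + weight_decay * flat[[nm]]
    flat[[nm]] <- flat[[nm]] - lr * upd
  }
  list(flat = flat, state = state)
}
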