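# Independent brute-force oracles.  Deliberately written with naive loops
# and none of the package's vectorized code paths.

# All residue pairs within `threshold`, by explicit O(n^2) enumeration.
brute_force_edges <- function(coords, threshold) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= threshold) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(), 0L, 2L) else out
}

# Protein-centric Fmax by exhaustive threshold sweep with per-protein loops.
fmax_oracle <- function(truth, scores) {
  best <- -Inf
  for (t in seq(0, 1, by = 0.01)) {
    precs <- c(); recs <- c()
    for (p in seq_len(nrow(truth))) {
      pred <- which(scores[p, ] >= t)
      pos <- which(truth[p, ] == 1)
      if (length(pred) > 0) precs <- c(precs, length(intersect(pred, pos)) / length(pred))
      if (length(pos) > 0) recs <- c(recs, length(intersect(pred, pos)) / length(pos))
    }
    f <- if (length(precs) == 0) 0 else {
      pr <- mean(precs); rc <- mean(recs)
      if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    }
    if (f > best) best <- f
  }
  best
}

# Micro AUPR by looping over distinct thresholds and counting from scratch.
aupr_oracle <- function(truth, scores) {
  ts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth == 1)
  area <- 0; prev_r <- 0
  for (t in ts) {
    tp <- sum(truth == 1 & scores >= t)
    fp <- sum(truth == 0 & scores >= t)
    p <- tp / (tp + fp)
    r <- tp / n_pos
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

mcc_oracle <- function(tp, fp, fn, tn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
}

# Central finite-difference gradient of the masked-LM loss with respect to
# a single flat-parameter entry of a model.
numeric_mlm_grad <- function(model, batch, graph, mask, name, k, h = 1e-5) {
  template <- list(backbone = model$backbone, adapter = model$adapter)
  flat <- pst:::flatten_params(template)
  eval_at <- function(delta) {
    fp <- flat
    fp[[name]][k] <- fp[[name]][k] + delta
    filled <- pst:::unflatten_params(template, fp)
    fw <- pst:::pst_forward_core(batch, model$config, filled$backbone,
                                 filled$adapter, model$adapter_config, graph,
                                 bypass = FALSE, want_cache = FALSE)
    mlm_loss(fw$logits, mask)
  }
  (eval_at(h) - eval_at(-h)) / (2 * h)
}

analytic_mlm_grads <- function(model, batch, graph, mask) {
  fw <- pst:::pst_forward_core(batch, model$config, model$backbone, model$adapter,
                               model$adapter_config, graph,
                               bypass = FALSE, want_cache = TRUE)
  dlogits <- pst:::mlm_loss_grad(fw$logits, mask$masked_positions,
                                 mask$original_tokens)
  gr <- pst:::pst_backward(fw$cache, dlogits, model$config, model$backbone,
                           model$adapter, model$adapter_config)
  pst:::flatten_params(list(backbone = gr$backbone, adapter = gr$adapter))
}
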