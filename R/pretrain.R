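# Masked-language-model pretraining: mask sampling, the MLM objective,
# the warmup/inverse-sqrt learning-rate schedule, and the AdamW training
# loop with full or structure-extractor-only update strategies.

#' Pretraining configuration
#'
#' @param mask_rate Fraction of residue positions masked per sequence, in
#'   (0, 1].  Exactly `max(1, floor(mask_rate * n_residues))` positions
#'   are masked, sampled without replacement.
#' @param strategy `"full"` updates every parameter; `"struct_only"`
#'   updates only the structure extractors and injection matrices, leaving
#'   every backbone parameter bitwise unchanged.
#' @param base_lr Peak learning rate (reached at `warmup_steps`).
#' @param warmup_steps Linear warmup length (>= 1).
#' @param total_steps Number of optimizer steps.
#' @param batch_size Proteins per step.
#' @param seed Seed for batch and mask sampling.
#' @param corruption `"mask_only"` replaces each selected position with
#'   the mask token; `"bert"` uses the 80/10/10 mask/random/keep split.
#' @param adam_beta1,adam_beta2,adam_eps,weight_decay AdamW
#'   hyperparameters (decay applies to weight matrices only).
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(mask_rate = 0.15, strategy = c("full", "struct_only"),
                            base_lr = 1e-3, warmup_steps = 10L, total_steps = 100L,
                            batch_size = 4L, seed = 0L,
                            corruption = c("mask_only", "bert"),
                            adam_beta1 = 0.9, adam_beta2 = 0.98,
                            adam_eps = 1e-8, weight_decay = 0.01) {
  strategy <- match.arg(strategy)
  corruption <- match.arg(corruption)
  if (!(mask_rate > 0 && mask_rate <= 1)) stop("mask_rate must be in (0, 1]", call. = FALSE)
  warmup_steps <- as.integer(warmup_steps)
  if (warmup_steps < 1L) stop("warmup_steps must be >= 1", call. = FALSE)
  structure(list(mask_rate = mask_rate, strategy = strategy, base_lr = base_lr,
                 warmup_steps = warmup_steps, total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 corruption = corruption, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 weight_decay = weight_decay),
            class = "pretrain_config")
}

#' Sample a masking pattern and corrupt a token batch
#'
#' Selects exactly `max(1, floor(rate * n_residues))` residue positions
#' without replacement (special tokens are never eligible) and corrupts
#' them; originals are recorded so the MLM loss can score them.
#'
#' @param batch A `token_batch`.
#' @param rate Mask rate in (0, 1].
#' @param seed Optional seed; `NULL` (default) draws from the current RNG
#'   stream (as the training loop does).
#' @param scheme `"mask_only"` or `"bert"` (80/10/10).
#' @param vocab Vocabulary from [pst_vocab()].
#' @return List with `mask` (a `mask_spec`: `masked_positions` as token
#'   rows, `original_tokens`) and `batch` (the corrupted `token_batch`).
#' @export
sample_mask <- function(batch, rate, seed = NULL,
                        scheme = c("mask_only", "bert"), vocab = pst_vocab()) {
  scheme <- match.arg(scheme)
  if (!(rate > 0 && rate <= 1)) stop("mask rate must be in (0, 1]", call. = FALSE)
  if (batch$n_residues < 1L) stop("batch has no residue positions", call. = FALSE)
  n_mask <- max(1L, floor(rate * batch$n_residues))
  draw <- function() {
    pos <- sort(sample(batch$residue_rows, n_mask))
    u <- runif(n_mask)
    rnd <- sample(vocab$residue_ids, n_mask, replace = TRUE)
    list(pos = pos, u = u, rnd = rnd)
  }
  dr <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  original <- batch$token_ids[dr$pos]
  new_ids <- batch$token_ids
  if (scheme == "mask_only") {
    new_ids[dr$pos] <- vocab$mask_id
  } else {
    new_ids[dr$pos] <- ifelse(dr$u < 0.8, vocab$mask_id,
                              ifelse(dr$u < 0.9, dr$rnd, original))
  }
  batch$token_ids <- new_ids
  list(mask = structure(list(masked_positions = dr$pos,
                             original_tokens = original),
                        class = "mask_spec"),
       batch = batch)
}

#' Masked-language-model loss
#'
#' Mean over masked positions of the negative log-probability the LM head
#' assigns to the original token: `mean_i -log softmax(logits_i)[x_i]`.
#'
#' @param logits `T x vocab_size` logit matrix.
#' @param spec A `mask_spec` from [sample_mask()].
#' @return Scalar loss.
#' @export
mlm_loss <- function(logits, spec) {
  pos <- spec$masked_positions
  if (length(pos) == 0L) stop("mask specification is empty", call. = FALSE)
  nll <- vapply(seq_along(pos), function(k) {
    -log_softmax_vec(logits[pos[k], ])[spec$original_tokens[k]]
  }, 0)
  mean(nll)
}

#' Learning rate at a given step
#'
#' Linear warmup to `base_lr` over `warmup_steps`, then inverse-square-root
#' decay: `base_lr * min(step / warmup, sqrt(warmup / step))`.
#'
#' @param step Step number (>= 1); vectorized.
#' @param config A [pretrain_config()] (or any list with `base_lr` and
#'   `warmup_steps`).
#' @return Learning rate(s).
#' @export
lr_at <- function(step, config) {
  if (any(step < 1)) stop("step must be >= 1", call. = FALSE)
  w <- config$warmup_steps
  config$base_lr * pmin(step / w, sqrt(w / step))
}

normalize_corpus <- function(corpus, graph_cfg = graph_config()) {
  if (is.list(corpus) && !is.null(corpus$structures)) corpus <- corpus$structures
  lapply(corpus, function(el) {
    if (inherits(el, "protein_structure")) {
      list(structure = el, graph = build_graph(el, graph_cfg))
    } else if (is.list(el) && inherits(el$structure, "protein_structure") &&
               inherits(el$graph, "protein_graph")) {
      el
    } else stop("corpus elements must be structures or (structure, graph) pairs",
                call. = FALSE)
  })
}

#' Pretrain a structure-augmented model with masked language modeling
#'
#' Runs `total_steps` of mask -> structural forward -> MLM loss -> AdamW
#' under the warmup/inverse-sqrt schedule.  Per step, `batch_size`
#' proteins are drawn; per-protein gradients are combined weighted by
#' masked-position counts, so the step objective is the mean
#' negative log-likelihood over all masked positions in the batch.
#' Graphs of different proteins stay disjoint.  With
#' `strategy = "struct_only"` only extractor and injection parameters are
#' ever touched: the backbone remains bitwise identical.
#'
#' @param corpus A list of `protein_structure`s (graphs built with the
#'   default [graph_config()]), a list of `list(structure, graph)` pairs,
#'   or the output of [make_corpus()].
#' @param model A `pst_model`.
#' @param config A [pretrain_config()].
#' @param graph_cfg Graph configuration used when `corpus` contains bare
#'   structures.
#' @return A `pst_train_state`: list with the updated `model`, the loss
#'   `trace` (data.frame: step, lr, loss) and `config`.
#' @export
pretrain <- function(corpus, model, config = pretrain_config(),
                     graph_cfg = graph_config()) {
  stopifnot(inherits(model, "pst_model"), inherits(config, "pretrain_config"))
  if (model$adapter_config$share_across_layers) {
    stop("pretraining with shared extractors is not supported; assemble with share_across_layers = FALSE",
         call. = FALSE)
  }
  items <- normalize_corpus(corpus, graph_cfg)
  if (length(items) == 0L) stop("corpus is empty", call. = FALSE)
  batches <- lapply(items, function(it) {
    b <- tokenize_sequence(it$structure$sequence)
    if (it$graph$n_nodes != b$n_residues) stop("graph/sequence length mismatch", call. = FALSE)
    b
  })

  template <- list(backbone = model$backbone, adapter = model$adapter)
  flat <- flatten_params(template)
  opt <- adamw_init(flat)
  update_names <- if (config$strategy == "struct_only") {
    grep("^adapter\\.", names(flat), value = TRUE)
  } else names(flat)

  n_prot <- length(items)
  trace <- data.frame(step = integer(config$total_steps),
                      lr = numeric(config$total_steps),
                      loss = numeric(config$total_steps))
  set.seed(config$seed)
  cur <- unflatten_params(template, flat)
  for (step in seq_len(config$total_steps)) {
    take <- sample.int(n_prot, min(config$batch_size, n_prot),
                       replace = config$batch_size > n_prot)
    grad_acc <- NULL
    loss_num <- 0; n_masked <- 0L
    for (i in take) {
      ms <- sample_mask(batches[[i]], config$mask_rate, seed = NULL,
                        scheme = config$corruption)
      fw <- pst_forward_core(ms$batch, model$config, cur$backbone, cur$adapter,
                             model$adapter_config, items[[i]]$graph,
                             bypass = FALSE, want_cache = TRUE)
      li <- mlm_loss(fw$logits, ms$mask)
      ni <- length(ms$mask$masked_positions)
      loss_num <- loss_num + li * ni
      n_masked <- n_masked + ni
      dlogits <- mlm_loss_grad(fw$logits, ms$mask$masked_positions,
                               ms$mask$original_tokens)
      gr <- pst_backward(fw$cache, dlogits, model$config, cur$backbone,
                         cur$adapter, model$adapter_config)
      gf <- flatten_params(list(backbone = gr$backbone, adapter = gr$adapter))
      if (is.null(grad_acc)) {
        grad_acc <- lapply(gf, function(g) g * ni)
      } else {
        for (nm in names(gf)) grad_acc[[nm]] <- grad_acc[[nm]] + gf[[nm]] * ni
      }
    }
    loss <- loss_num / n_masked
    if (!is.finite(loss)) {
      stop(sprintf("non-finite loss at step %d (lr %.3g); aborting",
                   step, lr_at(step, config)), call. = FALSE)
    }
    grad_acc <- lapply(grad_acc, function(g) g / n_masked)
    lr <- lr_at(step, config)
    upd <- adamw_step(flat, grad_acc, opt, lr,
                      beta1 = config$adam_beta1, beta2 = config$adam_beta2,
                      eps = config$adam_eps, weight_decay = config$weight_decay,
                      update_names = update_names)
    flat <- upd$flat; opt <- upd$state
    cur <- unflatten_params(template, flat)
    trace$step[step] <- step; trace$lr[step] <- lr; trace$loss[step] <- loss
  }
  model$backbone <- cur$backbone
  model$adapter <- cur$adapter
  structure(list(model = model, trace = trace, config = config),
            class = "pst_train_state")
}

#' @export
print.pst_train_state <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("<pst_train_state> %d steps (%s); loss %.4f -> %.4f\n",
              n, x$config$strategy, x$trace$loss[1L], x$trace$loss[n]))
  invisible(x)
}

#' Plot a pretraining loss trace
#'
#' @param state A `pst_train_state` (or its `trace` data.frame).
#' @return A ggplot object if ggplot2 is installed, otherwise plots with
#'   base graphics and returns the trace invisibly.
#' @export
plot_loss_trace <- function(state) {
  trace <- if (inherits(state, "pst_train_state")) state$trace else state
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(trace, ggplot2::aes(x = step, y = loss)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "step", y = "masked-LM loss")
  } else {
    plot(trace$step, trace$loss, type = "l", xlab = "step", ylab = "masked-LM loss")
    invisible(trace)
  }
}
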