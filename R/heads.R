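# Task heads over fixed embeddings: a 3-layer MLP (hidden widths halved
# each layer, dropout after each activation) for multi-label tasks, or a
# single linear map, trained with binary cross-entropy, AdamW and
# plateau learning-rate reduction on the validation metric.

#' Head training configuration
#'
#' @param kind `"mlp"` (3 affine layers, hidden widths `D/2` then `D/4`)
#'   or `"linear"` (single affine map).
#' @param dropout Dropout rate after each MLP activation; 0 or 0.5.
#' @param epochs Training epochs (default 100).
#' @param lr Initial learning rate.
#' @param plateau_factor LR multiplier applied on plateau (default 0.5).
#' @param plateau_patience Epochs without validation improvement before
#'   the LR is reduced (default 5).
#' @param task `"multilabel"` (validation metric Fmax) or `"multiclass"`
#'   (validation metric accuracy by arg-max).
#' @param seed Seed for initialization and dropout.
#' @param weight_decay AdamW weight decay (matrices only).
#' @return A `head_config` list.
#' @export
head_config <- function(kind = c("mlp", "linear"), dropout = 0, epochs = 100L,
                        lr = 0.01, plateau_factor = 0.5, plateau_patience = 5L,
                        task = c("multilabel", "multiclass"), seed = 0L,
                        weight_decay = 0.01) {
  kind <- match.arg(kind); task <- match.arg(task)
  if (!dropout %in% c(0, 0.5)) stop("dropout must be 0 or 0.5", call. = FALSE)
  structure(list(kind = kind, dropout = dropout, epochs = as.integer(epochs),
                 lr = lr, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience), task = task,
                 seed = as.integer(seed), weight_decay = weight_decay),
            class = "head_config")
}

# Convert a label table data.frame (protein_id + binary term columns) to a
# binary matrix.
label_matrix <- function(labels) {
  if (is.matrix(labels)) return(labels)
  stopifnot(is.data.frame(labels))
  cols <- setdiff(names(labels), "protein_id")
  m <- as.matrix(labels[, cols, drop = FALSE])
  rownames(m) <- labels$protein_id
  storage.mode(m) <- "double"
  m
}

head_forward <- function(params, X, config, dropout_active = FALSE) {
  caches <- list(X = X)
  H <- X
  nlay <- length(params$w)
  for (i in seq_len(nlay)) {
    Z <- add_bias(H %*% params$w[[i]], params$b[[i]])
    if (i < nlay) {
      A <- pmax(Z, 0)
      if (dropout_active && config$dropout > 0) {
        mask <- matrix(runif(length(A)) >= config$dropout, nrow(A)) / (1 - config$dropout)
        A <- A * mask
        caches[[paste0("mask", i)]] <- mask
      }
      caches[[paste0("Z", i)]] <- Z
      caches[[paste0("A", i)]] <- A
      H <- A
    } else {
      caches$out <- Z
    }
  }
  caches
}

head_backward <- function(params, caches, dZ_out, config) {
  nlay <- length(params$w)
  gw <- vector("list", nlay); gb <- vector("list", nlay)
  dZ <- dZ_out
  for (i in rev(seq_len(nlay))) {
    Hin <- if (i == 1L) caches$X else caches[[paste0("A", i - 1L)]]
    gw[[i]] <- t(Hin) %*% dZ
    gb[[i]] <- colSums(dZ)
    if (i > 1L) {
      dA <- dZ %*% t(params$w[[i]])
      mask <- caches[[paste0("mask", i - 1L)]]
      if (!is.null(mask)) dA <- dA * mask
      dZ <- dA * (caches[[paste0("Z", i - 1L)]] > 0)
    }
  }
  list(w = gw, b = gb)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

head_val_metric <- function(scores, truth, task) {
  if (task == "multilabel") {
    fmax(truth, scores)$fmax
  } else {
    accuracy(max.col(truth, ties.method = "first"),
             max.col(scores, ties.method = "first"))
  }
}

#' Train a classification head on fixed embeddings
#'
#' Trains either a 3-layer MLP (hidden widths `floor(D/2)` and
#' `floor(D/4)`, ReLU, dropout after each activation) or a linear map
#' with binary cross-entropy and AdamW for up to `epochs` epochs
#' (full-batch).  The learning rate is multiplied by `plateau_factor`
#' when the validation metric has not increased for `plateau_patience`
#' epochs.  The parameters achieving the best validation metric are
#' returned.  Dropout is active only during training; a fixed seed makes
#' the run fully reproducible.
#'
#' @param embeddings `N x D` numeric matrix (rows align with labels).
#' @param labels Binary `N x K` matrix, or a label-table data.frame with
#'   a `protein_id` column followed by binary term columns.
#' @param splits List with integer index vectors `train` and `val`
#'   (disjoint, non-empty).
#' @param config A [head_config()].
#' @return A `pst_head`: list with `params`, `config`, `trace`
#'   (data.frame: epoch, lr, train_loss, val_metric), `best_epoch`,
#'   `best_metric`.
#' @export
fit_head <- function(embeddings, labels, splits, config = head_config()) {
  stopifnot(inherits(config, "head_config"))
  X <- as.matrix(embeddings)
  Y <- label_matrix(labels)
  if (nrow(X) != nrow(Y)) stop("alignment error: embeddings and labels disagree on rows",
                               call. = FALSE)
  tr <- splits$train; va <- splits$val
  if (length(tr) == 0L || length(va) == 0L) stop("empty split", call. = FALSE)
  if (length(intersect(tr, va)) > 0L) stop("train and val splits overlap", call. = FALSE)
  D <- ncol(X); K <- ncol(Y)
  dims <- if (config$kind == "mlp") c(D, max(1L, D %/% 2L), max(1L, D %/% 4L), K) else c(D, K)

  set.seed(config$seed)
  params <- list(
    w = lapply(seq_len(length(dims) - 1L),
               function(i) rand_mat(dims[i], dims[i + 1L], 0.02)),
    b = lapply(seq_len(length(dims) - 1L), function(i) rep(0, dims[i + 1L]))
  )
  flat <- flatten_params(params)
  opt <- adamw_init(flat)
  lr <- config$lr
  best_metric <- -Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L
  trace <- data.frame(epoch = integer(0), lr = numeric(0),
                      train_loss = numeric(0), val_metric = numeric(0))
  Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  Xva <- X[va, , drop = FALSE]; Yva <- Y[va, , drop = FALSE]
  for (epoch in seq_len(config$epochs)) {
    fw <- head_forward(params, Xtr, config, dropout_active = TRUE)
    z <- fw$out
    loss <- bce_with_logits(z, Ytr)
    dZ <- (sigmoid(z) - Ytr) / length(z)
    gr <- head_backward(params, fw, dZ, config)
    upd <- adamw_step(flat, flatten_params(gr), opt, lr,
                      weight_decay = config$weight_decay)
    flat <- upd$flat; opt <- upd$state
    params <- unflatten_params(params, flat)

    val_scores <- sigmoid(head_forward(params, Xva, config)$out)
    vm <- head_val_metric(val_scores, Yva, config$task)
    trace <- rbind(trace, data.frame(epoch = epoch, lr = lr,
                                     train_loss = loss, val_metric = vm))
    if (vm > best_metric) {
      best_metric <- vm; best_params <- params; best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        stall <- 0L
      }
    }
  }
  structure(list(params = best_params, config = config, trace = trace,
                 best_epoch = best_epoch, best_metric = best_metric,
                 input_dim = D, n_classes = K),
            class = "pst_head")
}

#' Predict scores from a trained head
#'
#' @param object A `pst_head`.
#' @param newdata `N x D` embedding matrix.
#' @param type `"response"` for sigmoid scores, `"link"` for raw logits.
#' @param ... Unused.
#' @return `N x K` score matrix.
#' @export
predict.pst_head <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  z <- head_forward(object$params, as.matrix(newdata), object$config)$out
  if (type == "response") sigmoid(z) else z
}

#' @export
print.pst_head <- function(x, ...) {
  cat(sprintf("<pst_head> %s (%s): %d -> %d; best val %.4f at epoch %d\n",
              x$config$kind, x$config$task, x$input_dim, x$n_classes,
              x$best_metric, x$best_epoch))
  invisible(x)
}
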