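# Fixed representations and zero-shot variant scoring.

#' Extract fixed protein and residue representations
#'
#' Runs the structural forward pass and, for each transformer block,
#' mean-pools the residue-position states (cls/eos/pad excluded); the `L`
#' per-block means are concatenated into a length `L*d` protein vector.
#' Residue-level rows concatenate the per-block states of each residue.
#' With `bypass = TRUE` the extractors are skipped and the result is the
#' backbone's sequence representation (`mode = "seq"`).
#'
#' @param model A `pst_model`.
#' @param structure A [protein_structure()].
#' @param bypass Skip structure extractors (sequence mode).
#' @param graph Optional prebuilt `protein_graph`; built with `graph_cfg`
#'   otherwise.
#' @param graph_cfg [graph_config()] used when `graph` is `NULL`.
#' @return A `protein_embedding`: list with `vector` (length `L*d`),
#'   `residue_matrix` (`n x L*d`), `mode` (`"struct"`/`"seq"`/`"fused"`),
#'   `protein_id`, `n_layers`, `model_dim`.
#' @export
embed_protein <- function(model, structure, bypass = FALSE, graph = NULL,
                          graph_cfg = graph_config()) {
  stopifnot(inherits(model, "pst_model"), inherits(structure, "protein_structure"))
  batch <- tokenize_sequence(structure$sequence)
  if (is.null(graph) && !bypass) graph <- build_graph(structure, graph_cfg)
  out <- forward_pst(batch, graph, model, bypass = bypass)
  res <- batch$residue_rows
  per_block_mean <- lapply(out$hidden, function(Hl) colMeans(Hl[res, , drop = FALSE]))
  per_block_res <- lapply(out$hidden, function(Hl) Hl[res, , drop = FALSE])
  structure(list(
    vector = unlist(per_block_mean, use.names = FALSE),
    residue_matrix = do.call(cbind, per_block_res),
    mode = if (bypass) "seq" else "struct",
    protein_id = structure$id,
    n_layers = model$config$n_layers,
    model_dim = model$config$model_dim
  ), class = "protein_embedding")
}

#' @export
print.protein_embedding <- function(x, ...) {
  cat(sprintf("<protein_embedding> %s [%s]: length %d (%d blocks x %d)\n",
              x$protein_id, x$mode, length(x$vector), x$n_layers, x$model_dim))
  invisible(x)
}

#' Fuse structure and sequence representations
#'
#' Elementwise mean of a structural embedding and the sequence embedding
#' obtained by bypassing the extractors on the same protein — the
#' inference-time fusion available when only the extractors were trained.
#'
#' @param e_struct,e_seq `protein_embedding`s of equal length for the same
#'   protein.
#' @return A fused `protein_embedding` (`mode = "fused"`).
#' @export
fuse_struct_seq <- function(e_struct, e_seq) {
  stopifnot(inherits(e_struct, "protein_embedding"),
            inherits(e_seq, "protein_embedding"))
  if (length(e_struct$vector) != length(e_seq$vector)) {
    stop("embedding length mismatch", call. = FALSE)
  }
  if (!identical(e_struct$protein_id, e_seq$protein_id)) {
    stop("embeddings belong to different proteins", call. = FALSE)
  }
  out <- e_struct
  out$vector <- (e_struct$vector + e_seq$vector) / 2
  out$residue_matrix <- (e_struct$residue_matrix + e_seq$residue_matrix) / 2
  out$mode <- "fused"
  out
}

#' Zero-shot variant-effect score for one substitution
#'
#' `masked_marginal` (default): the token at the variant position is
#' replaced by the mask token, the structural forward runs with the
#' wild-type contact graph (geometry and topology unchanged), and the
#' score is `log p(mut | context) - log p(wt | context)` from that
#' position's LM-head distribution.  `wt_marginal`: same log-ratio from
#' the unmasked wild-type forward.  Higher scores mean the substitution
#' is better tolerated.
#'
#' @param model A `pst_model`.
#' @param structure The wild-type [protein_structure()].
#' @param position 1-based residue position.
#' @param wt,mut Wild-type and mutant one-letter codes; `wt` must match
#'   the structure.
#' @param method `"masked_marginal"` or `"wt_marginal"`.
#' @param graph Optional prebuilt wild-type `protein_graph`.
#' @param graph_cfg [graph_config()] used when `graph` is `NULL`.
#' @return One-row data.frame: `position`, `wt`, `mut`, `score`, `method`.
#' @export
score_variant <- function(model, structure, position, wt, mut,
                          method = c("masked_marginal", "wt_marginal"),
                          graph = NULL, graph_cfg = graph_config()) {
  method <- match.arg(method)
  stopifnot(inherits(model, "pst_model"), inherits(structure, "protein_structure"))
  position <- as.integer(position)
  n <- length(structure$sequence)
  if (position < 1L || position > n) {
    stop(sprintf("position %d out of range [1, %d]", position, n), call. = FALSE)
  }
  if (structure$sequence[position] != wt) {
    stop(sprintf("wildtype mismatch at position %d: structure has '%s', variant states '%s'",
                 position, structure$sequence[position], wt), call. = FALSE)
  }
  vocab <- pst_vocab()
  if (!mut %in% names(vocab$index)) stop("unknown mutant code: ", mut, call. = FALSE)
  batch <- tokenize_sequence(structure$sequence)
  if (is.null(graph)) graph <- build_graph(structure, graph_cfg)
  row <- batch$residue_rows[position]
  if (method == "masked_marginal") batch$token_ids[row] <- vocab$mask_id
  out <- forward_pst(batch, graph, model, bypass = FALSE)
  ls <- log_softmax_vec(out$logits[row, ])
  score <- ls[vocab$index[[mut]]] - ls[vocab$index[[wt]]]
  data.frame(position = position, wt = wt, mut = mut, score = unname(score),
             method = method, stringsAsFactors = FALSE)
}

#' Score every variant of a mutagenesis set
#'
#' @param model A `pst_model`.
#' @param mutset A `mutagenesis_set` from [make_mutagenesis()].
#' @param method Passed to [score_variant()].
#' @param graph_cfg [graph_config()] for the wild-type graph.
#' @return data.frame with one row per variant: `position`, `wt`, `mut`,
#'   `score`, `method`, and the set's `planted` score for convenience.
#' @export
score_mutagenesis <- function(mutset, model,
                              method = c("masked_marginal", "wt_marginal"),
                              graph_cfg = graph_config()) {
  stopifnot(inherits(mutset, "mutagenesis_set"))
  method <- match.arg(method)
  graph <- build_graph(mutset$structure, graph_cfg)
  rows <- lapply(seq_len(nrow(mutset$variants)), function(k) {
    v <- mutset$variants[k, ]
    score_variant(model, mutset$structure, v$position, v$wt, v$mut,
                  method = method, graph = graph)
  })
  out <- do.call(rbind, rows)
  out$planted <- mutset$planted_scores
  out
}
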