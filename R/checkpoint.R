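# Checkpoint archives: a flat name -> array mapping serialized as JSON
# (17 significant digits: doubles round-trip exactly) with a metadata
# block carrying configs, vocabulary and format version.

#' Export backbone parameters as a flat name-to-array map
#'
#' Keys follow the documented schema: `emb`, `layers.<l>.<name>` for
#' `ln1_g, ln1_b, wq, bq, wk, bk, wv, bv, wo, bo, ln2_g, ln2_b, w1, b1,
#' w2, b2`, then `lnf_g`, `lnf_b`, `lm_w`, `lm_b`.
#'
#' @param backbone A `pst_backbone`.
#' @return Named list of numeric arrays.
#' @export
export_backbone_weights <- function(backbone) {
  stopifnot(inherits(backbone, "pst_backbone"))
  flatten_params(backbone$params)
}

#' Import backbone parameters from a flat name-to-array map
#'
#' Generic named-weight import contract: any source that provides arrays
#' under the schema of [export_backbone_weights()] with shapes matching
#' `config` can initialize a backbone (e.g. converted published
#' checkpoints).  Missing keys and shape mismatches are hard errors
#' naming the offending key; there is no silent transposition.  Unknown
#' keys are reported with a warning and ignored.
#'
#' @param archive Named list of numeric arrays.
#' @param config A [backbone_config()] the shapes must match.
#' @return A `pst_backbone`.
#' @export
import_backbone_weights <- function(archive, config) {
  stopifnot(inherits(config, "backbone_config"))
  template <- init_backbone(config, seed = 0L)$params
  tflat <- flatten_params(template)
  for (nm in names(tflat)) {
    if (!nm %in% names(archive)) stop("missing weight: ", nm, call. = FALSE)
    a <- archive[[nm]]
    tm <- tflat[[nm]]
    if (is.matrix(tm)) {
      if (!is.matrix(a) || !all(dim(a) == dim(tm))) {
        stop(sprintf("shape error for '%s': expected %s, got %s", nm,
                     paste(dim(tm), collapse = "x"),
                     paste(if (is.matrix(a)) dim(a) else length(a), collapse = "x")),
             call. = FALSE)
      }
    } else if (length(a) != length(tm) || is.matrix(a)) {
      stop(sprintf("shape error for '%s': expected length %d", nm, length(tm)),
           call. = FALSE)
    }
  }
  unknown <- setdiff(names(archive), names(tflat))
  if (length(unknown) > 0L) {
    warning("ignoring unknown keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  params <- unflatten_params(template, archive)
  structure(list(config = config, params = params), class = "pst_backbone")
}

array_to_json <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.vector(x))
}

array_from_json <- function(rec) {
  d <- as.integer(unlist(rec$dim))
  v <- as.numeric(unlist(rec$data))
  if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
}

#' Save a model or backbone checkpoint
#'
#' @param model A `pst_model` or `pst_backbone`.
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "pst_model")) {
    flat <- flatten_params(list(backbone = model$backbone, adapter = model$adapter))
    meta <- list(format = "pst-checkpoint", version = 1L, type = "pst_model",
                 config = unclass(model$config),
                 adapter_config = unclass(model$adapter_config),
                 vocab = pst_vocab()$tokens)
  } else if (inherits(model, "pst_backbone")) {
    flat <- flatten_params(model$params)
    meta <- list(format = "pst-checkpoint", version = 1L, type = "pst_backbone",
                 config = unclass(model$config), vocab = pst_vocab()$tokens)
  } else stop("expected a pst_model or pst_backbone", call. = FALSE)
  jsonlite::write_json(list(metadata = meta, arrays = lapply(flat, array_to_json)),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return A `pst_model` or `pst_backbone`, bit-identical to what was saved.
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  meta <- raw$metadata
  cfg_args <- meta$config[c("n_layers", "model_dim", "n_heads", "ffn_dim",
                            "vocab_size", "rotary_base", "activation", "max_len")]
  config <- do.call(backbone_config, cfg_args)
  flat <- lapply(raw$arrays, array_from_json)
  if (identical(meta$type, "pst_backbone")) {
    template <- init_backbone(config, seed = 0L)$params
    params <- unflatten_params(template, flat)
    return(structure(list(config = config, params = params), class = "pst_backbone"))
  }
  ac <- meta$adapter_config
  gh <- ac$gin_hidden_dim
  if (length(gh) == 0L) gh <- NULL  # NULL serializes as {} in JSON
  adapter_cfg <- adapter_config(
    gin_layers = ac$gin_layers, gin_hidden_dim = gh,
    gin_epsilon = ac$gin_epsilon, use_edge_features = ac$use_edge_features,
    edge_dim = ac$edge_dim, share_across_layers = ac$share_across_layers
  )
  template_model <- assemble_pst(init_backbone(config, seed = 0L), adapter_cfg,
                                 seed = 0L)
  filled <- unflatten_params(list(backbone = template_model$backbone,
                                  adapter = template_model$adapter), flat)
  template_model$backbone <- filled$backbone
  template_model$adapter <- filled$adapter
  template_model
}
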