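# Token vocabulary: 20 canonical amino acids + 'X' (unknown residue) +
# four special tokens.  Indices are stable and 1-based.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid token vocabulary
#'
#' Fixed 25-token vocabulary: the 20 canonical one-letter amino-acid codes,
#' the unknown-residue token `"X"`, and the special tokens `<mask>`,
#' `<cls>`, `<eos>`, `<pad>`.  `X` counts as a residue token (it can occupy
#' a sequence position); the four specials never do.
#'
#' @return A list with `tokens` (ordered character vector), `index`
#'   (named integer vector token -> id), `size`, `residue_ids` and the ids
#'   of the special tokens (`mask_id`, `cls_id`, `eos_id`, `pad_id`).
#' @export
#' @examples
#' v <- pst_vocab()
#' v$size
pst_vocab <- function() {
  tokens <- c(AA20, "X", "<mask>", "<cls>", "<eos>", "<pad>")
  index <- seq_along(tokens)
  names(index) <- tokens
  list(
    tokens = tokens,
    index = index,
    size = length(tokens),
    residue_ids = index[c(AA20, "X")],
    mask_id = index[["<mask>"]],
    cls_id = index[["<cls>"]],
    eos_id = index[["<eos>"]],
    pad_id = index[["<pad>"]]
  )
}

#' Tokenize an amino-acid sequence
#'
#' Maps a sequence to `<cls>` + residue tokens + `<eos>`.  Characters
#' outside the canonical 20-letter alphabet are mapped to `"X"` with a
#' warning.  `residue_rows[t]` gives the token row holding residue `t`, so
#' token positions align with contact-graph nodes.
#'
#' @param sequence Character scalar or character vector of one-letter codes.
#' @param vocab Vocabulary from [pst_vocab()].
#' @return A `token_batch`: list with `token_ids`, `pad_mask`,
#'   `residue_rows`, `n_residues`.
#' @export
tokenize_sequence <- function(sequence, vocab = pst_vocab()) {
  chars <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    strsplit(sequence, "")[[1L]]
  } else {
    as.character(sequence)
  }
  if (length(chars) == 0L || identical(chars, "")) {
    stop("cannot tokenize an empty sequence", call. = FALSE)
  }
  bad <- !(chars %in% c(AA20, "X"))
  if (any(bad)) {
    warning(sprintf("mapping %d non-canonical residue code(s) to 'X': %s",
                    sum(bad), paste(unique(chars[bad]), collapse = ", ")),
            call. = FALSE)
    chars[bad] <- "X"
  }
  n <- length(chars)
  ids <- c(vocab$cls_id, unname(vocab$index[chars]), vocab$eos_id)
  structure(list(
    token_ids = as.integer(ids),
    pad_mask = rep(FALSE, n + 2L),
    residue_rows = seq.int(2L, n + 1L),
    n_residues = n
  ), class = "token_batch")
}

#' Recover the residue sequence from a token batch
#'
#' @param batch A `token_batch` from [tokenize_sequence()].
#' @param vocab Vocabulary from [pst_vocab()].
#' @return A single character string of one-letter codes.
#' @export
detokenize <- function(batch, vocab = pst_vocab()) {
  paste(vocab$tokens[batch$token_ids[batch$residue_rows]], collapse = "")
}

# Append n_pad <pad> tokens (used in batching tests; pooling and attention
# must be invariant to them).
pad_batch <- function(batch, n_pad, vocab = pst_vocab()) {
  if (n_pad <= 0L) return(batch)
  batch$token_ids <- c(batch$token_ids, rep(vocab$pad_id, n_pad))
  batch$pad_mask <- c(batch$pad_mask, rep(TRUE, n_pad))
  batch
}
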