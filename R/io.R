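# Structure / sequence / table I/O.  PDB parsing goes through bio3d;
# FASTA through Biostrings.  The toy PDB writer emits minimal single-chain
# ATOM records so reader round-trips can be tested in-package.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_1TO3 <- setNames(names(AA_3TO1), unname(AA_3TO1))

#' Write a structure as a minimal PDB file
#'
#' Emits one `ATOM` record per residue (atom name `CA`, chain `A`,
#' 1-based residue numbering, coordinates at 3 decimals), then `TER`/`END`.
#' Unknown residues (`X`) are written as `UNK`.
#'
#' @param structure A [protein_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  res3 <- ifelse(structure$sequence == "X", "UNK", AA_1TO3[structure$sequence])
  n <- length(structure$sequence)
  lines <- sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(n), res3, seq_len(n),
                   structure$coords[, 1L], structure$coords[, 2L], structure$coords[, 3L])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' Parses `ATOM` records (first model; altloc blank or `'A'`), selects one
#' representative CA atom per residue, orders residues by author residue
#' number, and maps 3-letter residue names to 1-letter codes (unknown
#' names map to `"X"`).  Residues that lack a CA atom are skipped with a
#' warning.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier; default uses all chains in the
#'   file (in chain, residue-number order).
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% at$chain) {
      stop(sprintf("chain not found: '%s'", chain), call. = FALSE)
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no parseable residues in file", call. = FALSE)
  # residue key = chain + residue number (+ insertion code passthrough)
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
  key <- paste(at$chain, at$resno, ins, sep = "|")
  ord <- order(at$chain, at$resno)
  at <- at[ord, , drop = FALSE]; key <- key[ord]
  all_res <- unique(key)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno,
                  if ("insert" %in% names(ca)) ifelse(is.na(ca$insert), "", ca$insert) else "",
                  sep = "|")
  missing_ca <- setdiff(all_res, ca_key)
  if (length(missing_ca) > 0L) {
    warning(sprintf("skipping %d residue(s) without a CA atom: %s",
                    length(missing_ca),
                    paste(utils::head(missing_ca, 5L), collapse = ", ")),
            call. = FALSE)
  }
  if (nrow(ca) == 0L) stop("no parseable residues in file", call. = FALSE)
  ca <- ca[!duplicated(ca_key), , drop = FALSE]
  one <- unname(AA_3TO1[ca$resid])
  one[is.na(one)] <- "X"
  protein_structure(
    id = sub("\\.[^.]*$", "", basename(path)),
    sequence = one,
    coords = cbind(ca$x, ca$y, ca$z),
    source = path
  )
}

#' Write sequences of one or more structures to FASTA
#'
#' @param structures A [protein_structure()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(structures, path) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  seqs <- vapply(structures, function(s) paste(s$sequence, collapse = ""), "")
  names(seqs) <- vapply(structures, `[[`, "", "id")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a label table or variant list as tab-separated text
#'
#' @param x A data.frame (e.g. the `labels` element of [make_corpus()] or
#'   the `variants` element of [make_mutagenesis()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
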