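# Protein structures at the representative-atom level: one CA coordinate
# per residue.  This is all the epsilon-neighborhood contact graph needs.

#' Construct a protein structure object
#'
#' @param id Protein identifier.
#' @param sequence Character vector of one-letter residue codes
#'   (canonical 20 or `"X"`), one per residue.
#' @param coords Numeric n x 3 matrix of representative-atom (CA)
#'   coordinates in Angstrom.
#' @param source Free-text provenance tag.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(id, sequence, coords, source = "synthetic") {
  sequence <- as.character(sequence)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(sequence) < 1L) stop("structure must contain at least one residue", call. = FALSE)
  if (nrow(coords) != length(sequence) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix matching the sequence length", call. = FALSE)
  }
  if (!all(sequence %in% c(AA20, "X"))) {
    stop("sequence codes must be canonical one-letter codes or 'X'", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, coords = coords, source = source),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues (%s)\n",
              x$id, length(x$sequence), x$source))
  invisible(x)
}

#' Generate a synthetic protein chain
#'
#' Deterministic generator of idealized single-chain structures with a
#' uniformly random sequence: an alpha-helix-like parametric helix
#' `(r cos(i*tau), r sin(i*tau), i*rise)`, an extended (collinear) chain
#' with fixed spacing, or a fixed-step random-walk coil.  Identical
#' arguments always give byte-identical output.
#'
#' @param kind One of `"helix"`, `"extended"`, `"coil"`.
#' @param n_residues Number of residues (>= 1).
#' @param seed Integer seed controlling sequence and coil geometry.
#' @param bond_length Consecutive-residue spacing in Angstrom (extended and
#'   coil step length); the canonical CA-CA distance is about 3.8.
#' @param helix_rise Rise per residue along the helix axis (Angstrom).
#' @param helix_twist Twist per residue in degrees.
#' @param helix_radius Helix radius in Angstrom.
#' @param id Optional identifier; defaults to a descriptive one.
#' @return A [protein_structure()].
#' @export
#' @examples
#' make_chain("helix", 12, seed = 1)
make_chain <- function(kind = c("helix", "extended", "coil"), n_residues,
                       seed = 1L, bond_length = 3.8, helix_rise = 1.5,
                       helix_twist = 100, helix_radius = 2.3, id = NULL) {
  kind <- match.arg(kind)
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 1L) {
    stop("invalid spec: n_residues must be a positive integer", call. = FALSE)
  }
  if (bond_length <= 0) stop("invalid spec: bond_length must be positive", call. = FALSE)
  i <- seq_len(n_residues) - 1
  coords <- withr::with_seed(seed, {
    seqc <- sample(AA20, n_residues, replace = TRUE)
    xyz <- switch(kind,
      helix = {
        tau <- helix_twist * pi / 180
        cbind(helix_radius * cos(i * tau), helix_radius * sin(i * tau), i * helix_rise)
      },
      extended = cbind(i * bond_length, 0, 0),
      coil = {
        # fixed-step random walk, steps uniform on the sphere; no
        # self-avoidance -- dense neighborhoods are a feature for testing
        z <- runif(n_residues - 1L, -1, 1)
        phi <- runif(n_residues - 1L, 0, 2 * pi)
        r <- sqrt(pmax(0, 1 - z^2))
        steps <- bond_length * cbind(r * cos(phi), r * sin(phi), z)
        if (n_residues == 1L) matrix(0, 1L, 3L) else
          rbind(0, apply(steps, 2L, cumsum))
      })
    list(seq = seqc, xyz = matrix(as.numeric(xyz), ncol = 3L))
  })
  protein_structure(
    id = id %||% sprintf("%s_n%d_s%d", kind, n_residues, seed),
    sequence = coords$seq, coords = coords$xyz,
    source = sprintf("synthetic:%s", kind)
  )
}

#' Generate a corpus of mixed synthetic structures with class labels
#'
#' Draws chain kinds and lengths uniformly, generates each chain under a
#' derived seed, and returns a one-hot label table mapping each protein to
#' its generator kind -- a structure-determined label usable for head
#' smoke tests.
#'
#' @param n_proteins Number of structures (>= 1).
#' @param length_range Integer vector `c(min, max)` of residue counts.
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return A list with `structures` (list of [protein_structure()]) and
#'   `labels` (data.frame: `protein_id`, then one binary column per kind).
#' @export
make_corpus <- function(n_proteins, length_range = c(10L, 30L), seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  lo <- as.integer(length_range[1L]); hi <- as.integer(length_range[2L])
  if (lo > hi) stop("invalid range: min length exceeds max length", call. = FALSE)
  kinds <- c("helix", "extended", "coil")
  draw <- withr::with_seed(seed, {
    list(kind = sample(kinds, n_proteins, replace = TRUE),
         len = sample(seq.int(lo, hi), n_proteins, replace = TRUE),
         sub_seed = sample.int(.Machine$integer.max %/% 2L, n_proteins))
  })
  structures <- lapply(seq_len(n_proteins), function(i) {
    make_chain(draw$kind[i], draw$len[i], seed = draw$sub_seed[i],
               id = sprintf("protein_%03d", i))
  })
  labels <- data.frame(protein_id = vapply(structures, `[[`, "", "id"))
  for (k in kinds) labels[[k]] <- as.integer(draw$kind == k)
  list(structures = structures, labels = labels)
}

# Kyte-Doolittle hydropathy index (published residue-level lookup).
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' Generate a deep-mutational-scanning-style variant set with planted scores
#'
#' Samples substitutions on a structure and assigns each a planted
#' "experimental" score: the negative absolute Kyte-Doolittle hydropathy
#' difference between mutant and wild type (conservative substitutions
#' score higher, i.e. are more tolerated) plus seeded Gaussian noise.
#' With `noise_sd = 0` the planted scores are a deterministic monotone
#' function of the hydropathy component, so a scoring pipeline can be
#' ranked against them.
#'
#' @param structure A [protein_structure()].
#' @param n_variants Number of variants (>= 1).
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the additive noise (score units).
#' @return A `mutagenesis_set`: list with `structure`, `variants`
#'   (data.frame `position`, `wt`, `mut`), `planted_scores` and the
#'   noise-free `hydropathy_component`.
#' @export
make_mutagenesis <- function(structure, n_variants, seed = 1L, noise_sd = 0.25) {
  stopifnot(inherits(structure, "protein_structure"))
  n <- length(structure$sequence)
  if (n < 1L) stop("structure must contain at least one residue", call. = FALSE)
  n_variants <- as.integer(n_variants)
  if (is.na(n_variants) || n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  out <- withr::with_seed(seed, {
    position <- sample.int(n, n_variants, replace = n_variants > n)
    wt <- structure$sequence[position]
    mut <- vapply(wt, function(w) sample(setdiff(AA20, w), 1L), "")
    noise <- rnorm(n_variants, 0, noise_sd)
    list(position = position, wt = wt, mut = unname(mut), noise = noise)
  })
  # wild-type 'X' has no hydropathy entry; treat as 0 (neutral reference)
  kd <- function(a) ifelse(a %in% names(KYTE_DOOLITTLE), KYTE_DOOLITTLE[a], 0)
  hydro <- -abs(kd(out$mut) - kd(out$wt))
  structure(list(
    structure = structure,
    variants = data.frame(position = out$position, wt = out$wt, mut = out$mut,
                          stringsAsFactors = FALSE),
    planted_scores = unname(hydro + out$noise),
    hydropathy_component = unname(hydro)
  ), class = "mutagenesis_set")
}
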