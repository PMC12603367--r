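Package: pst
Title: Structure-Aware Protein Language Models with Graph Adapters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a protein structure transformer: a BERT-style
    encoder-only protein language model with rotary position embeddings
    whose every self-attention block is augmented by a graph isomorphism
    network (GIN) structure extractor over a residue contact graph, fused
    through zero-initialized query/key/value projections. Provides
    residue contact-graph construction from PDB structures (8 Angstrom
    epsilon-neighborhood, optional radial-basis distance edge features,
    graph perturbation modes), masked-language-model pretraining with
    AdamW and an inverse-square-root schedule (full or structure-extractor
    -only strategies), fixed protein/residue representation extraction
    with structure/sequence fusion, zero-shot variant-effect scoring by
    masked or wild-type marginals, multi-label and linear evaluation
    heads, and brute-force-verified Fmax, AUPR, MCC and Spearman metrics.
    A synthetic-structure generator (helices, extended chains, coils)
    makes every stage runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
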