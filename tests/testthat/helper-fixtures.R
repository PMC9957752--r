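# small hand-built fixtures shared across test files

# a 10-transcript library with a biotype mix and isoform groups
tiny_library <- function() {
  expression_library(
    library_id = "tiny",
    gene_ids = paste0("tx", 1:10),
    raw_counts = c(10, 40, 5, 100, 0, 7, 3, 12, 60, 9),
    length_kb = c(1, 2, 1, 2.5, 1, 0.5, 3, 1, 4, 2),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "rRNA", "rRNA", "miRNA", "protein_coding",
                "protein_coding", "protein_coding", "Mt_rRNA"),
    isoform_group = c("geneA", "geneA", "geneA", "geneB", "geneB",
                      "geneC", "geneD", "geneD", "geneE", "geneF"))
}

# profile built directly from named molecule counts
profile_from_counts <- function(id, counts) {
  lib <- expression_library(id, names(counts), counts,
                            rep(1, length(counts)))
  to_molecule_counts(lib)
}

# independent Pearson correlation from first principles
brute_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# independent AUC: pairwise wins + half-ties over all pos/neg pairs
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# independent hypergeometric upper tail by direct pmf summation
brute_hyper_tail <- function(k, n_a, n_b, n_universe) {
  kk <- k:min(n_a, n_b)
  sum(choose(n_a, kk) * choose(n_universe - n_a, n_b - kk) /
        choose(n_universe, n_b))
}
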