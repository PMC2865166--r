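# Shared fixture builders: tiny alignments and trees constructed in code.

toy_codon_aln <- function(reference = NULL) {
  codon_alignment(c(
    t1 = "ATGGCTACTGCA",
    t2 = "ATGGCAACTGCC",
    t3 = "ATGTCTACAGCA",
    t4 = "ATG---ACTGCA"
  ), reference = reference)
}

toy_aa_aln <- function() {
  aa_alignment(c(
    a = "MKLVISAG",
    b = "MKLVISAG",
    c = "MKIVMSAG",
    d = "MRIVMSTG"
  ))
}

# random rooted tree with seeded lengths
rand_tree <- function(n, seed = 1, lo = 0.1, hi = 0.4) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), lo, hi)
  tr
}

# additive distance matrix from a tree (patristic distances)
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

textConnection_path <- function(text) {
  p <- tempfile(fileext = ".nwk")
  writeLines(text, p)
  p
}

write_temp_fasta <- function(seqs, ...) {
  p <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), p)
  p
}
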