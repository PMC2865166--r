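test_that("ancestral reconstruction is exact on closed-form cases", {
  # invariant site: every node's MAP state is the shared codon
  tr <- rand_tree(5, seed = 33, lo = 0.1, hi = 0.3)
  aln <- codon_alignment(setNames(rep("ATGGCTAAA", 5), tr$tip.label))
  fit <- suppressWarnings(fit_mg94_global(aln, tree = tr))
  anc <- reconstruct_ancestral(aln, fit)
  cods <- sense_codons()
  for (v in seq_along(anc$post)) {
    maps <- cods[apply(anc$post[[v]], 2, which.max)]
    expect_equal(maps, c("ATG", "GCT", "AAA"))
    expect_equal(colSums(anc$post[[v]]), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("two-leaf root posterior matches the closed-form two-branch oracle", {
  tr <- ape::read.tree(text = "(x:0.2,y:0.2);")
  aln <- codon_alignment(c(x = "ATGAAA", y = "ATGAAG"))
  pi61 <- setNames(rep(1 / 61, 61), sense_codons())
  fit <- structure(list(omega = 1, scale = 1,
                        rho = setNames(rep(1, 6), c("AC","AG","AT","CG","CT","GT")),
                        pi = pi61, tree = tr, logLik = NA), class = "mg94_fit")
  anc <- reconstruct_ancestral(aln, fit)
  root <- anc$post[[anc$trav$root]]
  Q <- build_codon_model(1, 1, pi = pi61)
  Q <- Q / -sum(pi61 * diag(Q))   # unit-rate normalization, as fitted
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * 0.2)))
  i <- which(sense_codons() == "AAA"); j <- which(sense_codons() == "AAG")
  oracle <- pi61 * P[, i] * P[, j]
  oracle <- oracle / sum(oracle)
  expect_equal(unname(root[, 2]), unname(oracle), tolerance = 1e-6)
  # the two single-step reconstructions dominate near-symmetrically
  expect_gt(root[i, 2], 0.4)
  expect_gt(root[j, 2], 0.4)
})

test_that("substitution mapping flags branch-level amino-acid changes", {
  # a change confined to one long terminal branch must map there
  tr <- ape::read.tree(text = "((a:0.4,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  base <- "ATGGCTAAACCTGGT"
  changed <- "ATGCGTAAACCTGGT"   # codon 2 GCT(A) -> CGT(R) on taxon a
  aln <- codon_alignment(c(a = changed, b = base, c = base, d = base))
  fit <- suppressWarnings(fit_mg94_global(aln, tree = tr))
  anc <- reconstruct_ancestral(aln, fit)
  map <- map_nonsyn_substitutions(anc)
  term_a <- which(anc$trav$edge[, 2] ==
                    which(anc$trav$tip.label == "a"))
  expect_equal(map$indicator[term_a, 2], 1)
  # invariant sites have all-zero columns
  expect_true(all(map$indicator[, c(1, 3, 4, 5)] == 0))
  expect_equal(map$site_counts, colSums(map$indicator))
})

test_that("site filtering applies the inclusive count threshold", {
  m <- structure(list(site_counts = c(0, 2, 3, 5),
                      indicator = NULL), class = "substitution_map")
  expect_equal(filter_sites(m, 3), c(3, 4))
  X <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0), 4)
  expect_equal(filter_sites(X, 3), 2)
})

test_that("MCMC edge posteriors match exhaustive enumeration on small graphs", {
  set.seed(44)
  n <- 40
  x1 <- rbinom(n, 1, 0.3); x2 <- x1; x2[sample(n, 5)] <- rbinom(5, 1, 0.5)
  X <- cbind(x1, x2, rbinom(n, 1, 0.25), rbinom(n, 1, 0.25))
  colnames(X) <- NULL
  ex <- bgm_exact_posteriors(X)
  mc <- suppressWarnings(
    bgm_edge_posteriors(X, bgm_config(chain_length = 1e5, seed = 6)))
  expect_lt(max(abs(ex$posterior - mc$posterior)), 0.05)
  # strongly associated identical-ish columns reach high posterior
  p12 <- ex$posterior[ex$site1 == 1 & ex$site2 == 2]
  expect_gt(p12, 0.9)
})

test_that("independent Bernoulli columns rarely exceed the edge threshold", {
  set.seed(45)
  hits <- vapply(1:20, function(r) {
    X <- matrix(rbinom(40 * 10, 1, 0.2), 40, 10)
    e <- suppressWarnings(
      bgm_edge_posteriors(X, bgm_config(chain_length = 2e4, seed = r)))
    mean(e$posterior >= 0.5)
  }, 0)
  expect_lte(mean(hits), 0.05)
})

test_that("grouping pairs yields connected components", {
  edges <- tibble::tibble(site1 = c(1, 2, 4), site2 = c(2, 3, 5),
                          posterior = c(0.9, 0.8, 0.7))
  g <- group_coevolving(edges, 0.5)
  expect_equal(length(g), 2)
  expect_equal(sort(vapply(g, length, 0L)), c(2, 3))
  # below-threshold pairs are ignored
  g2 <- group_coevolving(tibble::tibble(site1 = 1, site2 = 2,
                                        posterior = 0.4))
  expect_equal(length(g2), 0)
})

test_that("published-style pair tables group as printed", {
  chi18_13 <- tibble::tibble(
    site1 = c("S51", "T97", "T97", "V121", "S129", "S132", "S132", "G230",
              "Y270", "N281", "S332", "D335", "V121"),
    site2 = c("T159", "A9", "N281", "Q125", "G130", "I312", "T241", "N369",
              "S332", "K347", "L18", "L18", "K104"),
    posterior = c(0.84, 0.79, 0.71, 0.63, 0.86, 0.64, 0.72, 0.90, 0.89,
                  0.83, 0.60, 0.56, 0.58))
  expect_equal(length(group_coevolving(chi18_13, 0.5)), 7)
  chi18_15 <- tibble::tibble(
    site1 = c("S86", "V90", "Q229", "S249"),
    site2 = c("A178", "A254", "Q225", "A178"),
    posterior = c(0.59, 0.65, 0.59, 0.56))
  expect_equal(length(group_coevolving(chi18_15, 0.5)), 3)
})

test_that("degenerate retentions raise the documented errors", {
  X <- matrix(0, 10, 1)
  expect_error(bgm_edge_posteriors(X, bgm_config()), "BGM-eligible")
  expect_error(bgm_config(edge_threshold = 1.2), "edge_threshold")
  expect_error(bgm_config(max_parents = 0), "max_parents")
})
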