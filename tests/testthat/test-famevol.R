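test_that("bd_transition matches closed-form hand calculations", {
  # no time: identity
  expect_equal(bd_transition(3, 3, 0, 0.5), 1)
  expect_equal(bd_transition(3, 2, 0, 0.5), 0)
  # single-gene extinction: P = alpha = lam*t/(1+lam*t)
  expect_equal(bd_transition(1, 0, 1, 0.5), 1 / 3, tolerance = 1e-12)
  # lam*t = 1 is outside the closed form but alpha = 1/2 limit: split path
  expect_equal(bd_transition(1, 0, 2, 0.5, max_size = 50), 0.5,
               tolerance = 1e-3)
  # s = 2 -> c = 1 at alpha = 1/4 (lam*t = 1/3): 2a^3 + 2a(1-2a)
  a <- 0.25
  expect_equal(bd_transition(2, 1, 1 / 3, 1),
               2 * a^3 + 2 * a * (1 - 2 * a), tolerance = 1e-12)
  expect_error(bd_transition(2, 1, 5, 1, split = FALSE), "domain")
})

test_that("bd_transition rows sum to one over all child sizes", {
  for (s in c(1, 3, 7)) for (lt in c(0.1, 0.5, 0.9)) {
    total <- sum(bd_transition(s, 0:400, lt, 1))
    expect_lt(abs(total - 1), 1e-8)
  }
})

test_that("bd_transition agrees with event-level Monte-Carlo simulation", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  grid <- expand.grid(s = c(1, 4), lam = c(0.2, 0.6))
  for (k in seq_len(nrow(grid))) {
    s <- grid$s[k]; lam <- grid$lam[k]
    fam <- simulate_family_counts(tree, lam, s, 4000, seed = 50 + k)
    for (c0 in c(0, s, s + 1)) {
      p_hat <- mean(fam$counts$A == c0)
      p_true <- bd_transition(s, c0, 1, lam)
      se <- sqrt(max(p_true * (1 - p_true), 1e-6) / 4000)
      expect_lt(abs(p_hat - p_true), 3.5 * se)
    }
  }
})

test_that("family likelihood reduces correctly in degenerate cases", {
  # lambda = 0: likelihood concentrates on counts == root size
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 2, 3)
  ll_eq <- family_likelihood(tree, c(A = 5, B = 5, C = 5), 0, max_size = 20)
  # uniform root prior: probability 1/20 on the matching root size
  expect_equal(ll_eq, log(1 / 20), tolerance = 1e-10)
  ll_neq <- family_likelihood(tree, c(A = 5, B = 4, C = 5), 0, max_size = 20)
  expect_equal(ll_neq, -Inf)
})

test_that("pruning equals brute force over ancestral assignments on 3 leaves", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 1, 1.5)
  counts <- c(A = 2, B = 3, C = 1)
  lam <- 0.3; ms <- 8
  got <- family_likelihood(tree, counts, lam, max_size = ms)
  # brute force: root r and inner node m over 0..ms
  tot <- 0
  for (r in 1:ms) for (m in 0:ms) {
    tot <- tot + (1 / ms) *
      bd_transition(r, m, 0.5, lam) *       # root -> inner (1.5 - 1)
      bd_transition(m, counts["A"], 1, lam) *
      bd_transition(m, counts["B"], 1, lam) *
      bd_transition(r, counts["C"], 1.5, lam)
  }
  expect_equal(got, unname(log(tot)), tolerance = 1e-8)
})

test_that("lambda estimation recovers the generating rate within a factor of 2", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 90, 100)
  lam0 <- 0.002
  fam <- simulate_family_counts(tree, lam0, 10, 200, seed = 61)
  est <- estimate_lambda(fam$counts, tree)
  expect_gt(est$lam, lam0 / 2)
  expect_lt(est$lam, lam0 * 2)
  # MLE property: likelihood at the estimate beats halved/doubled rates
  cm <- fam$counts
  ll_at <- function(l) {
    sum(vapply(seq_len(nrow(cm)), function(i) {
      v <- unlist(cm[i, c("A", "B", "C")])
      family_likelihood(tree, v, l, max_size = est$max_size)
    }, 0))
  }
  expect_gte(ll_at(est$lam), ll_at(est$lam / 2))
  expect_gte(ll_at(est$lam), ll_at(est$lam * 2))
})

test_that("constant tables give a flagged zero estimate", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 2, 3)
  counts <- tibble::tibble(family = c("f1", "f2"),
                           A = c(4L, 6L), B = c(4L, 6L), C = c(4L, 6L))
  est <- estimate_lambda(counts, tree)
  expect_equal(est$lam, 0)
  expect_true(est$degenerate)
})

test_that("family p-values are deterministic, bounded and powered", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 50, 60)
  lam <- 0.004
  p1 <- family_pvalue(c(A = 3, B = 3, C = 3), tree, lam, M = 100, seed = 4)
  p2 <- family_pvalue(c(A = 3, B = 3, C = 3), tree, lam, M = 100, seed = 4)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 101)
  # wildly expanded family is flagged
  p3 <- family_pvalue(c(A = 30, B = 28, C = 3), tree, lam, M = 200, seed = 5,
                      root_max = 3)
  expect_lte(p3$p, 0.05)
  expect_error(family_pvalue(c(A = 1, B = 1, C = 1), tree, lam, M = 0), "M")
})

test_that("null family p-values are approximately uniform", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 50, 60)
  lam <- 0.004
  set.seed(71)
  trav <- molevolkit:::tree_traversal(tree)
  ps <- vapply(1:120, function(r) {
    root <- sample.int(6, 1)
    fam <- molevolkit:::sim_family_once(trav, root, lam)
    family_pvalue(fam, tree, lam, M = 120, seed = 1000 + r,
                  max_size = 30, root_max = 6)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})

test_that("Viterbi assignment matches brute-force argmax on a 3-leaf toy", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 1, 1.5)
  counts <- c(A = 4, B = 4, C = 1)
  lam <- 0.3; ms <- 8
  br <- identify_branches(counts, tree, lam, max_size = ms)
  # brute force over (root, inner)
  best <- -Inf; best_rm <- c(NA, NA)
  for (r in 1:ms) for (m in 0:ms) {
    lp <- log(1 / ms) +
      log(bd_transition(r, m, 0.5, lam)) +
      log(bd_transition(m, 4, 1, lam)) * 2 +
      log(bd_transition(r, 1, 1.5, lam))
    if (lp > best) { best <- lp; best_rm <- c(r, m) }
  }
  inner_size <- br$parent_size[br$child_label %in% c("A", "B")][1]
  expect_equal(inner_size, best_rm[2])
})

test_that("symmetric counts yield symmetric branch scores", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 1, 2)
  br <- identify_branches(c(A = 6, B = 6, C = 2), tree, 0.2, max_size = 16)
  pa <- br$p_exceed[br$child_label == "A"]
  pb <- br$p_exceed[br$child_label == "B"]
  expect_equal(pa, pb, tolerance = 1e-10)
})

test_that("a lambda-0 family with one discordant leaf flags that branch", {
  tree <- dated_three_taxon_tree(c("A", "B"), "C", 1, 2)
  br <- identify_branches(c(A = 5, B = 5, C = 9), tree, 0.01, max_size = 20)
  worst <- br$child_label[which.min(br$p_exceed)]
  expect_equal(worst, "C")
})
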