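test_that("the codon generator is a proper reversible rate matrix", {
  pi <- codon_freq_f3x4(toy_codon_aln())
  rho <- setNames(c(1, 2.5, 0.7, 1.1, 3.2, 0.9),
                  c("AC", "AG", "AT", "CG", "CT", "GT"))
  Q <- build_codon_model(dN = 0.4, dS = 1, rho = rho, pi = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # detailed balance
  db <- (pi %o% rep(1, 61)) * Q - t((pi %o% rep(1, 61)) * Q)
  expect_lt(max(abs(db)), 1e-14)
  # only single-nucleotide moves
  cods <- sense_codons()
  for (k in sample(61, 5)) {
    diff_count <- vapply(cods, function(c2)
      sum(strsplit(cods[k], "")[[1]] != strsplit(c2, "")[[1]]), 0L)
    expect_true(all(Q[k, diff_count > 1] == 0))
  }
})

test_that("dN = 0 generators never change the amino acid", {
  Q <- build_codon_model(dN = 0, dS = 1)
  aa <- codon_to_aa(sense_codons())
  moves <- which(Q > 0, arr.ind = TRUE)
  moves <- moves[moves[, 1] != moves[, 2], , drop = FALSE]
  expect_true(all(aa[moves[, 1]] == aa[moves[, 2]]))
})

test_that("nucleotide model specs collapse exchanges onto shared labels", {
  sp <- nuc_model_spec(CT = "RCT")
  expect_equal(unclass(sp)[["CT"]], "RCT")
  expect_equal(sum(unclass(sp) == "ref"), 5)
  sp2 <- nuc_model_spec(AC = "RAC", AT = "RAC", CG = "RCG", CT = "RCT",
                        GT = "RCG")
  rho <- setNames(c(2, 1, 4, 6, 9, 8), c("AC", "AG", "AT", "CG", "CT", "GT"))
  out <- molevolkit:::collapse_rho(rho, sp2)
  expect_equal(unname(out[["AC"]]), unname(out[["AT"]]))
  expect_equal(unname(out[["CG"]]), unname(out[["GT"]]))
  expect_equal(unname(out[["AG"]]), 1)   # reference normalized
  expect_equal(unname(out[["AC"]]), 3)   # mean of 2 and 4
  expect_error(nuc_model_spec(XX = "a"), "unknown")
})

test_that("Bayes factor arithmetic matches the definition", {
  expect_equal(bayes_factor(0.9, 0.2), (0.9 / 0.1) / (0.2 / 0.8))
  expect_equal(bayes_factor(0.9, 0.2), 36)
  expect_equal(bayes_factor(0.37, 0.37), 1)
})

test_that("REL fit collapses to the generating class on single-class data", {
  tr <- rand_tree(10, seed = 27, lo = 0.15, hi = 0.4)
  sim <- simulate_codon_alignment(tr, 500, site_class_spec(1, 1), seed = 28)
  fit <- suppressWarnings(fit_rel(sim$alignment, tree = tr, starts = 2,
                                  seed = 2, maxit = 400))
  g <- fit$grid
  top <- g[which.max(g$weight), ]
  expect_gt(top$dN / top$dS, 0.7)
  expect_lt(top$dN / top$dS, 1.4)
  expect_gt(sum(g$weight * g$dN) / sum(g$weight * g$dS), 0.8)
  expect_lt(sum(g$weight * g$dN) / sum(g$weight * g$dS), 1.25)
  # posterior class probabilities sum to one at every site
  sel <- site_bayes_factor(fit)
  expect_true(all(sel$posterior_positive >= 0 & sel$posterior_positive <= 1))
  expect_true(all(sel$bayes_factor_positive >= 0))
  # grid weights are a probability distribution
  expect_equal(sum(g$weight), 1, tolerance = 1e-8)
  # prior-mean synonymous rate normalized to one
  expect_equal(sum(g$weight * g$dS), 1, tolerance = 1e-6)
})

test_that("a conserved control gene yields no strong positive calls", {
  tr <- rand_tree(10, seed = 41, lo = 0.1, hi = 0.3)
  sim <- simulate_codon_alignment(tr, 150, site_class_spec(0.1, 1),
                                  seed = 42)
  fit <- suppressWarnings(fit_rel(sim$alignment, tree = tr, starts = 2,
                                  seed = 4, maxit = 300))
  sel <- site_bayes_factor(fit)
  expect_equal(sum(sel$class == "positive_strong"), 0)
})

test_that("refitting with permuted taxon order gives the same likelihood", {
  tr <- rand_tree(6, seed = 29, lo = 0.2, hi = 0.4)
  sim <- simulate_codon_alignment(tr, 90, site_class_spec(c(0.3, 1),
                                                          c(0.5, 0.5)),
                                  seed = 30)
  aln <- unclass(sim$alignment)
  perm <- codon_alignment(aln[rev(names(aln))])
  f1 <- suppressWarnings(fit_rel(sim$alignment, tree = tr, starts = 1,
                                 seed = 3, maxit = 200))
  f2 <- suppressWarnings(fit_rel(perm, tree = tr, starts = 1, seed = 3,
                                 maxit = 200))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-4)
})

test_that("top-class ratio reporting reproduces printed-style arithmetic", {
  grid <- tibble::tibble(dN = c(0.05, 0.2, 0.49), dS = c(0.9, 0.5, 0.21))
  expect_equal(round(top_class_ratio(grid), 2), 2.33)
})

test_that("site classification responds to the Bayes-factor cutoffs", {
  # construct a synthetic fit object exercising the classifier only
  grid <- tibble::tibble(class = 1:4,
                         dN = c(0.1, 0.1, 2, 2), dS = c(1, 0.1, 1, 0.1),
                         weight = c(0.4, 0.2, 0.2, 0.2))
  ll <- log(rbind(
    c(1e-3, 1e-3, 1, 1),      # strongly positive site
    c(1, 1e-3, 1e-3, 1e-3),   # strongly purifying site
    c(1, 1, 1, 1)             # uninformative site
  ))
  fit <- structure(list(grid = grid, .site_class_loglik = ll),
                   class = "rel_fit")
  sel <- site_bayes_factor(fit)
  expect_equal(sel$class[1], "positive_strong")
  expect_equal(sel$class[2], "purifying")
  expect_equal(sel$class[3], "neutral")
  expect_equal(sel$bayes_factor_positive[3], 1, tolerance = 1e-10)
  # dN = dS classes count toward neither side
  grid2 <- tibble::tibble(class = 1:2, dN = c(1, 1), dS = c(1, 0.2),
                          weight = c(0.5, 0.5))
  fit2 <- structure(list(grid = grid2,
                         .site_class_loglik = matrix(0, 2, 2)),
                    class = "rel_fit")
  sel2 <- site_bayes_factor(fit2)
  expect_equal(unique(sel2$prior_positive), 0.5)
})

test_that("tidy and glance expose the grid and fit summary", {
  grid <- tibble::tibble(class = 1:2, dN = c(0.2, 1.5), dS = c(1, 0.5),
                         weight = c(0.7, 0.3))
  fit <- structure(list(grid = grid, logLik = -12.3, scale = 2,
                        convergence = 0,
                        .site_class_loglik = matrix(0, 1, 2)),
                   class = "rel_fit")
  td <- tidy(fit)
  expect_true(all(c("dN", "dS", "weight", "ratio") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$prior_positive, 0.3)
})
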