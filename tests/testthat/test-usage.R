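test_that("codon counts follow the universal code and exclude stops", {
  cc <- codon_counts(c(g1 = "ATGATG"))
  expect_equal(cc$ATG, 2)
  expect_equal(sum(as.matrix(cc[, -1])), 2)
  # terminal stop tolerated, not counted
  cc2 <- codon_counts(c(g = "ATGAAATAA"))
  expect_equal(sum(as.matrix(cc2[, -1])), 2)
  expect_error(codon_counts(c(g = "ATGTAAGCT")), "internal stop")
  expect_error(codon_counts(c(g = "ATGA")), "frame")
})

test_that("codon counts are additive under concatenation", {
  a <- "ATGGCTAAAGGG"; b <- "CCCGTTATGATG"
  ca <- as.matrix(codon_counts(c(g = a))[, -1])
  cb <- as.matrix(codon_counts(c(g = b))[, -1])
  cab <- as.matrix(codon_counts(c(g = paste0(a, b)))[, -1])
  expect_equal(cab, ca + cb)
})

test_that("CA of proportional rows has zero inertia and coordinates", {
  X <- tibble::tibble(gene = c("a", "b"),
                      AAA = c(10L, 20L), AAC = c(5L, 10L), AAG = c(1L, 2L))
  ca <- correspondence_analysis(X, k = 2, frequencies = FALSE)
  expect_lt(ca$total_inertia, 1e-20)
  expect_true(all(abs(as.matrix(ca$coords[, -1])) < 1e-8))
})

test_that("CA coordinates match a direct eigen-decomposition oracle", {
  X <- matrix(c(10, 2, 5, 3,
                1, 12, 3, 6,
                4, 3, 11, 1), 3, byrow = TRUE)
  d <- tibble::tibble(gene = c("g1", "g2", "g3"),
                      c1 = X[, 1], c2 = X[, 2], c3 = X[, 3], c4 = X[, 4])
  ca <- correspondence_analysis(d, k = 2, frequencies = FALSE)
  # oracle: eigen-decomposition of S'S where S is the standardized residual
  P <- X / sum(X); r <- rowSums(P); cc <- colSums(P)
  S <- (P - r %o% cc) / sqrt(r %o% cc)
  ev <- eigen(S %*% t(S))
  coords_oracle <- diag(1 / sqrt(r)) %*% ev$vectors[, 1:2] %*%
    diag(sqrt(ev$values[1:2]))
  got <- as.matrix(ca$coords[, -1])
  for (j in 1:2) {
    # axis sign is arbitrary in the oracle
    err <- min(max(abs(got[, j] - coords_oracle[, j])),
               max(abs(got[, j] + coords_oracle[, j])))
    expect_lt(err, 1e-8)
  }
  expect_equal(ca$inertia, ev$values[1:2], tolerance = 1e-10)
})

test_that("CA row coordinates are scale-invariant for frequency analysis", {
  set.seed(14)
  m <- matrix(rpois(5 * 8, 10) + 1, 5, 8)
  d1 <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:5)),
                         tibble::as_tibble(m, .name_repair = "unique"))
  m2 <- m; m2[2, ] <- m2[2, ] * 7
  d2 <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:5)),
                         tibble::as_tibble(m2, .name_repair = "unique"))
  c1 <- correspondence_analysis(d1, frequencies = TRUE)
  c2 <- correspondence_analysis(d2, frequencies = TRUE)
  expect_equal(as.matrix(c1$coords[, -1]), as.matrix(c2$coords[, -1]),
               tolerance = 1e-10)
})

test_that("GC3- vs AT3-biased gene sets separate on axis 1", {
  set.seed(15)
  tab <- codon_tables()
  third <- substr(tab$codons, 3, 3)
  gc3 <- third %in% c("G", "C")
  make_gene <- function(bias_gc) {
    w <- ifelse(gc3, bias_gc, 1 - bias_gc)
    cods <- sample(tab$codons, 300, TRUE, prob = w)
    paste(cods, collapse = "")
  }
  genes <- c(setNames(replicate(4, make_gene(0.9)), paste0("gc", 1:4)),
             setNames(replicate(4, make_gene(0.1)), paste0("at", 1:4)))
  ca <- correspondence_analysis(codon_counts(genes))
  ax1 <- ca$coords$axis1
  grp <- rep(c(1, 2), each = 4)
  expect_true(max(ax1[grp == 1]) < min(ax1[grp == 2]) ||
              max(ax1[grp == 2]) < min(ax1[grp == 1]))
})

test_that("pairwise identity matches hand values and brute force", {
  pid <- pairwise_identity(c(a = "AAAA", b = "AAAT"))
  expect_equal(pid$pairs$identity, 75)
  pid2 <- pairwise_identity(c(a = "AAAA", b = "AAAA"))
  expect_equal(pid2$mean, 100)
  # gapped positions excluded
  pid3 <- pairwise_identity(c(a = "AA-A", b = "AAAA"))
  expect_equal(pid3$pairs$identity, 100)
  set.seed(16)
  seqs <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T", "-"),
                                             40, TRUE), collapse = "")),
                   paste0("s", 1:5))
  pid4 <- pairwise_identity(seqs)
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    a <- strsplit(seqs[[i]], "")[[1]]; b <- strsplit(seqs[[j]], "")[[1]]
    ok <- a != "-" & b != "-"
    v <- 100 * mean(a[ok] == b[ok])
    vals <- c(vals, v)
    expect_equal(pid4$matrix[i, j], v)
  }
  expect_equal(pid4$mean, mean(vals))
  expect_equal(pid4$sd, sd(vals))
  expect_true(isSymmetric(pid4$matrix))
  expect_true(all(diag(pid4$matrix) == 100))
})
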