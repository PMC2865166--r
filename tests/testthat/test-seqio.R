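test_that("FASTA parsing returns one record per header with ids and residues", {
  p <- write_temp_fasta(list(s1 = "ATGGCT", s2 = "ATGAAA"))
  d <- read_fasta(p)
  expect_equal(nrow(d), 2)
  expect_equal(d$id, c("s1", "s2"))
  expect_equal(d$residues, c("ATGGCT", "ATGAAA"))
})

test_that("FASTA round-trips through write_fasta", {
  d <- tibble::tibble(id = c("x", "y"), description = c("", "desc here"),
                      residues = c("ATGGCTACTGCAATGGCT", "ATGAAACCCGGGTTTAAA"))
  p <- tempfile(fileext = ".fa")
  write_fasta(d, p, width = 10)
  d2 <- read_fasta(p)
  expect_equal(d2$id, d$id)
  expect_equal(d2$residues, d$residues)
  expect_equal(d2$description, d$description)
})

test_that("FASTA errors name the offending record", {
  p <- write_temp_fasta(list(dup = "ATG", dup = "AAA"))
  expect_error(read_fasta(p), "dup")
  expect_error(read_fasta(tempfile()), "exist")
  p2 <- tempfile(fileext = ".fa"); file.create(p2)
  expect_error(read_fasta(p2), "FASTA|empty")
  p3 <- write_temp_fasta(list(bad = "AT!G"))
  expect_error(read_fasta(p3), "bad")
})

test_that("codon alignment enforces frame, whole-codon gaps and stop rules", {
  expect_s3_class(toy_codon_aln(), "codon_alignment")
  expect_error(codon_alignment(c(a = "ATGG", b = "ATGG")), "multiple of 3")
  expect_error(codon_alignment(c(a = "ATGA-CTAA", b = "ATGACCTAA")), "triplet")
  expect_error(codon_alignment(c(a = "ATGTAAGCT", b = "ATGAAAGCT")),
               "internal stop codon in taxon a at codon 2")
})

test_that("translation follows the universal code and drops terminal stops", {
  aln <- codon_alignment(c(a = "ATGGCT", b = "ATGGCA"))
  aa <- translate_alignment(aln)
  expect_equal(unname(unclass(aa)["a"]), "MA")
  aln2 <- codon_alignment(c(a = "ATGGCTTAA", b = "ATGGCATAA"))
  expect_equal(unname(unclass(translate_alignment(aln2))["a"]), "MA")
  # gap triplets become single gap characters
  aln3 <- codon_alignment(c(a = "ATG---GCT", b = "ATGAAAGCT"))
  expect_equal(unname(unclass(translate_alignment(aln3))["a"]), "M-A")
})

test_that("reference-space masking maps through the reference row's ungapped positions", {
  # reference has a gap at alignment codon 2: reference positions skip it
  aln <- codon_alignment(c(ref = "ATG---GCTACTGCA", oth = "ATGAAAGCAACAGCG"),
                         reference = "ref")
  m <- region_mask(2, 3, space = "reference")  # ref codons 2-3 = aln cols 3-4
  out <- mask_regions(aln, m)
  expect_equal(unname(unclass(out)["ref"]), "ATG---GCA")
  expect_equal(unname(unclass(out)["oth"]), "ATGAAAGCG")
})

test_that("masking removes exactly the covered columns (printed-interval check)", {
  # two reference intervals of 18 and 8 residues remove 26 positions
  n <- 400
  set.seed(1)
  row <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  aa <- aa_alignment(c(r = paste(rep("K", n), collapse = ""),
                       s = paste(rep("R", n), collapse = "")), reference = "r")
  m <- region_mask(c(320, 373), c(337, 380), space = "reference")
  out <- mask_regions(aa, m)
  expect_equal(nchar(unclass(out)[["r"]]), n - 26)
})

test_that("masking edge cases: empty mask is identity, full mask errors, out of range errors", {
  aln <- toy_codon_aln()
  empty <- region_mask(integer(0), integer(0))
  expect_identical(unclass(mask_regions(aln, empty)), unclass(aln))
  expect_error(mask_regions(aln, region_mask(1, 4)), "all columns")
  expect_error(mask_regions(aln, region_mask(1, 99)), "exceeds")
  expect_error(mask_regions(aln, region_mask(1, 1, space = "reference")),
               "reference")
})

test_that("masking commutes with translation on codon-boundary intervals", {
  aln <- toy_codon_aln()
  m_codon <- region_mask(2, 3, space = "alignment")
  a <- translate_alignment(mask_regions(aln, m_codon))
  b <- mask_regions(translate_alignment(aln), m_codon)
  expect_identical(unclass(a), unclass(b))
})

test_that("region mask TSV round-trip and validation", {
  m <- region_mask(c(5, 1), c(9, 2))   # sorts
  expect_equal(m$start, c(1, 5))
  expect_error(region_mask(3, 2), "<=")
  expect_error(region_mask(c(1, 2), c(3, 4)), "overlap")
  p <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(space = "alignment", start = c(1, 5),
                                end = c(2, 9)),
                     p, sep = "\t", row.names = FALSE, quote = FALSE)
  m2 <- read_region_mask(p)
  expect_equal(m2$start, c(1, 5))
  expect_equal(m2$space[1], "alignment")
})

test_that("Newick parse/write round-trips topology, labels and lengths", {
  tr <- read_newick(textConnection_path("((A:1,B:1):1,C:2);"))
  expect_equal(length(tr$tip.label), 3)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  p <- tempfile(fileext = ".nwk")
  set.seed(4)
  t0 <- ape::rtree(10)
  write_newick(t0, p)
  t1 <- read_newick(p)
  expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  expect_equal(sum(t0$edge.length), sum(t1$edge.length), tolerance = 1e-8)
})

test_that("Newick errors: unbalanced parentheses and duplicate leaves", {
  expect_error(read_newick(textConnection_path("((A,B)")))
  expect_error(read_newick(textConnection_path("((A:1,A:1):1,C:2);")),
               "duplicate")
})
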