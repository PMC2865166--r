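# Distance-based phylogenetics: Poisson-corrected and JTT maximum
# likelihood pairwise distances, neighbour joining (via ape, with
# negative-branch clamping), and bootstrap support.

#' Poisson-corrected amino-acid distance matrix
#'
#' `d = -ln(1 - p)` with `p` the proportion of differing residues over
#' comparable (gap-free) columns. `complete` deletion removes columns with
#' a gap in any taxon; `pairwise` removes them per pair.
#'
#' @param aln an [aa_alignment].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
poisson_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "aa_alignment"))
  rows <- lapply(unclass(aln), function(s) strsplit(s, "")[[1]])
  taxa <- names(rows)
  if (length(taxa) < 2) stop("need at least 2 taxa")
  is_res <- function(v) v %in% AA20
  if (deletion == "complete") {
    keep <- Reduce(`&`, lapply(rows, is_res))
    if (!any(keep)) stop("no comparable columns after complete deletion")
    rows <- lapply(rows, function(v) v[keep])
  }
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    ok <- is_res(a) & is_res(b)
    if (!any(ok)) stop("no comparable columns for pair ", taxa[i], "/", taxa[j])
    p <- mean(a[ok] != b[ok])
    if (p >= 1) stop("undefined Poisson distance (p >= 1) for pair ",
                     taxa[i], "/", taxa[j])
    D[i, j] <- D[j, i] <- -log(1 - p)
  }
  D
}

#' JTT maximum-likelihood pairwise distance matrix
#'
#' For each pair, the time `t` maximizing `sum log(pi_x P_xy(t))` under
#' the JTT model over comparable columns.
#'
#' @inheritParams poisson_distance
#' @param max_dist upper bound of the distance search (default 10).
#' @return A symmetric matrix with zero diagonal.
#' @export
jtt_distance <- function(aln, deletion = c("pairwise", "complete"),
                         max_dist = 10) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "aa_alignment"))
  model <- aa_model_jtt()
  ed <- rev_eigen(aa_generator(model), model$pi)
  idx <- setNames(seq_along(AA20), AA20)
  rows <- lapply(unclass(aln), function(s) strsplit(s, "")[[1]])
  taxa <- names(rows)
  if (deletion == "complete") {
    keep <- Reduce(`&`, lapply(rows, function(v) v %in% AA20))
    rows <- lapply(rows, function(v) v[keep])
  }
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    ok <- a %in% AA20 & b %in% AA20
    if (!any(ok)) stop("no comparable columns for pair ", taxa[i], "/", taxa[j])
    ia <- idx[a[ok]]; ib <- idx[b[ok]]
    nll <- function(t) {
      P <- prob_matrix(ed, t)
      -sum(log(model$pi[ia] * pmax(P[cbind(ia, ib)], 1e-300)))
    }
    D[i, j] <- D[j, i] <- optimize(nll, c(1e-6, max_dist))$minimum
  }
  D
}

#' Neighbour-joining tree
#'
#' Standard neighbour joining (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' adjacent branch, so path lengths between leaves are preserved where
#' possible.
#'
#' @param dist symmetric distance matrix with taxa dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  if (nrow(dist) < 3) stop("need at least 3 taxa for neighbour joining")
  tr <- ape::nj(as.dist(dist))
  # clamp negative estimates: zero the edge, push the deficit onto the
  # edges incident to the child node so leaf-to-leaf paths are preserved
  if (any(tr$edge.length < 0)) {
    for (e in which(tr$edge.length < 0)) {
      def <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      child <- tr$edge[e, 2]
      down <- which(tr$edge[, 1] == child)
      if (length(down) > 0)
        tr$edge.length[down] <- tr$edge.length[down] + def
      tr$edge.length[tr$edge.length < 0] <- 0
    }
  }
  tr
}

#' Bootstrap support for a tree-building pipeline
#'
#' Resamples alignment columns with replacement, rebuilds a tree with
#' `builder` on each replicate, and reports for each internal bipartition
#' of the point-estimate tree the percentage of replicates containing it.
#'
#' @param aln an [aa_alignment] (or any alignment whose rows split into
#'   single-character columns).
#' @param builder a function `alignment -> phylo` (deterministic).
#' @param n number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return The point-estimate tree with `node.label` set to support
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(aln, builder, n = 1000, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  rows <- lapply(unclass(aln), function(s) strsplit(s, "")[[1]])
  L <- length(rows[[1]])
  make_aln <- function(cols) {
    out <- vapply(rows, function(v) paste(v[cols], collapse = ""), "")
    aa_alignment(out, reference = attr(aln, "reference"))
  }
  point <- builder(aln)
  set.seed(seed)
  boots <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- builder(make_aln(cols))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- as.character(round(100 * counts / n))
  point$node.label[1] <- ""
  point
}
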