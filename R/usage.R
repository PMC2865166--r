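# Codon-usage composition analyses: per-gene codon counting,
# correspondence analysis of usage frequencies, and pairwise nucleotide
# identity statistics.

#' Codon usage counts
#'
#' Counts the 61 sense codons in each in-frame coding sequence (stop
#' codons excluded from the table; a terminal stop is tolerated, an
#' internal stop is an error).
#'
#' @param genes named character vector of in-frame CDS (or a tibble with
#'   `id` and `residues` columns, e.g. from [read_fasta()]).
#' @return A tibble of class `codon_usage`: column `gene` plus one
#'   integer column per sense codon.
#' @export
codon_counts <- function(genes) {
  if (is.data.frame(genes)) genes <- setNames(genes$residues, genes$id)
  genes <- toupper(genes)
  tab <- codon_tables()
  rows <- lapply(names(genes), function(g) {
    s <- gsub("-", "", genes[[g]], fixed = TRUE)
    if (nchar(s) %% 3 != 0)
      stop("frame violation: length of ", g, " is not a multiple of 3")
    cods <- split_codons(s)
    aa <- codon_to_aa(cods)
    stops <- which(!is.na(aa) & aa == "*")
    if (length(stops) > 0 && any(stops < length(cods)))
      stop("internal stop codon in gene ", g, " at codon ",
           stops[stops < length(cods)][1])
    cnt <- table(factor(cods, levels = tab$codons))
    as.integer(cnt)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- tab$codons
  out <- dplyr::bind_cols(tibble(gene = names(genes)), as_tibble(m))
  class(out) <- c("codon_usage", class(out))
  out
}

#' Correspondence analysis of codon usage
#'
#' Standard correspondence analysis — singular decomposition of the
#' chi-square standardized residuals of the relative-frequency matrix —
#' on within-gene relative codon frequencies (the default) or raw
#' counts. Axis signs are canonicalized so each axis's largest-magnitude
#' gene coordinate is positive.
#'
#' @param usage a `codon_usage` tibble from [codon_counts()], or any
#'   gene-by-category count matrix/tibble with a `gene` column.
#' @param k number of axes to return (default 2).
#' @param frequencies normalize rows to relative frequencies before the
#'   analysis (default TRUE, matching usage-frequency CA).
#' @param rscu use relative synonymous codon usage instead of
#'   frequencies (default FALSE).
#' @return A list of class `ca_result`: `coords` (tibble: gene, axis1,
#'   ..., axisk), `inertia` (per-axis), `total_inertia`.
#' @export
correspondence_analysis <- function(usage, k = 2, frequencies = TRUE,
                                    rscu = FALSE) {
  d <- as.data.frame(usage)
  genes <- d$gene
  X <- as.matrix(d[, setdiff(names(d), "gene"), drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 genes")
  if (rscu) {
    tab <- codon_tables()
    aa <- tab$aa[match(colnames(X), tab$codons)]
    for (a in unique(aa)) {
      sel <- aa == a
      syn <- sum(sel)
      rs <- rowSums(X[, sel, drop = FALSE])
      rs[rs == 0] <- 1
      X[, sel] <- X[, sel, drop = FALSE] / rs * syn
    }
  } else if (frequencies) {
    rs <- rowSums(X)
    if (any(rs == 0)) stop("all-zero gene row(s)")
    X <- X / rs
  }
  X <- X[, colSums(X) > 0, drop = FALSE]
  if (ncol(X) == 0 || sum(X) == 0) stop("rank-0 table")
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - r %o% cc) / sqrt(r %o% cc)
  sv <- svd(S)
  pos <- sv$d > 1e-12
  k_eff <- min(k, sum(pos))
  coords <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(k_eff), drop = FALSE] %*%
    diag(sv$d[seq_len(k_eff)], k_eff)
  if (k_eff > 0) for (j in seq_len(k_eff)) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  if (k_eff < k)
    coords <- cbind(coords, matrix(0, nrow(coords), k - k_eff))
  colnames(coords) <- paste0("axis", seq_len(k))
  out <- list(
    coords = dplyr::bind_cols(tibble(gene = genes), as_tibble(coords)),
    inertia = sv$d[seq_len(k_eff)]^2,
    total_inertia = sum(sv$d^2)
  )
  class(out) <- "ca_result"
  out
}

#' @export
print.ca_result <- function(x, ...) {
  cat("correspondence analysis:", nrow(x$coords), "genes; total inertia",
      format(x$total_inertia, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.ca_result <- function(x, ...) x$coords

#' @export
glance.ca_result <- function(x, ...) {
  tibble(total_inertia = x$total_inertia,
         inertia_axis1 = x$inertia[1],
         inertia_axis2 = if (length(x$inertia) > 1) x$inertia[2] else NA_real_)
}

#' @export
autoplot.ca_result <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2,
                               label = .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "CA axis 1", y = "CA axis 2")
}

#' Pairwise nucleotide identity
#'
#' Percent identity for every unordered pair of aligned sequences:
#' matches over compared positions (positions where either sequence has
#' a gap are excluded) times 100.
#'
#' @param aln a [codon_alignment], named character vector of aligned
#'   nucleotide sequences, or tibble with `id`/`residues`.
#' @return A list of class `identity_stats`: `matrix` (symmetric, 100 on
#'   the diagonal), `pairs` (tibble: id1, id2, identity), `mean`, `sd`
#'   (sample sd over unordered pairs).
#' @export
pairwise_identity <- function(aln) {
  if (is.data.frame(aln)) aln <- setNames(aln$residues, aln$id)
  x <- toupper(unclass(aln))
  if (length(x) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(x))) != 1) stop("sequences must be aligned")
  rows <- lapply(x, function(s) strsplit(s, "")[[1]])
  ids <- names(x)
  n <- length(ids)
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  p1 <- character(0); p2 <- character(0); idt <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    ok <- a != "-" & b != "-"
    if (!any(ok)) stop("no comparable positions for pair ",
                       ids[i], "/", ids[j])
    v <- 100 * mean(a[ok] == b[ok])
    M[i, j] <- M[j, i] <- v
    p1 <- c(p1, ids[i]); p2 <- c(p2, ids[j]); idt <- c(idt, v)
  }
  structure(list(matrix = M,
                 pairs = tibble(id1 = p1, id2 = p2, identity = idt),
                 mean = mean(idt), sd = sd(idt)),
            class = "identity_stats")
}

#' @export
print.identity_stats <- function(x, ...) {
  cat("pairwise nucleotide identity: mean",
      format(x$mean, digits = 4), "+/-", format(x$sd, digits = 3),
      "(sd) over", nrow(x$pairs), "pairs\n")
  invisible(x)
}
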