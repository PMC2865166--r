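# Codon-level machinery shared by the simulator, the REL scan and the
# co-evolution mapper: the 61 sense codons of the universal code, their
# single-nucleotide neighbourhood, and MG94-style generator construction.

NUC <- c("A", "C", "G", "T")

# unordered nucleotide exchange classes, alphabetical within pair
EXCHANGES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons (stop codons excluded),
#'   in lexicographic order.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

#' Genetic-code translation of codons
#'
#' @param codons character vector of codon strings.
#' @return Character vector of one-letter amino acids ("*" for stop).
#' @export
codon_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# Build (and cache) the codon state tables: codons, amino acids, and the
# single-nucleotide neighbour list with exchange class and synonymy.
codon_tables <- function() {
  if (!is.null(.mek_cache$codon_tables)) return(.mek_cache$codon_tables)
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  codons <- sort(all64[gc != "*"])
  aa <- unname(gc[codons])
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)
  # neighbour table: from, to (indices), position changed, exchange, syn
  from <- integer(0); to <- integer(0); pos <- integer(0)
  exch <- character(0); syn <- logical(0)
  split3 <- do.call(rbind, strsplit(codons, ""))
  for (i in seq_len(n)) {
    for (p in 1:3) {
      for (b in NUC) {
        if (b == split3[i, p]) next
        cand <- split3[i, ]
        cand[p] <- b
        cs <- paste(cand, collapse = "")
        j <- idx[cs]
        if (is.na(j)) next   # stop codon: not a sense state
        from <- c(from, i); to <- c(to, unname(j)); pos <- c(pos, p)
        exch <- c(exch, paste(sort(c(split3[i, p], b)), collapse = ""))
        syn <- c(syn, aa[i] == aa[unname(j)])
      }
    }
  }
  tab <- list(
    codons = codons, aa = aa, index = idx,
    nb = data.frame(from = from, to = to, pos = pos,
                    exchange = exch, syn = syn, stringsAsFactors = FALSE)
  )
  .mek_cache$codon_tables <- tab
  tab
}

#' MG94-style codon rate generator
#'
#' Builds the 61x61 instantaneous rate matrix of a Muse-Gaut style codon
#' model: only single-nucleotide moves between sense codons have positive
#' rate, `rate(i -> j) = rho[exchange] * pi[j] * (dS or dN)` according to
#' whether the move is synonymous. The matrix is reversible with stationary
#' distribution `pi`.
#'
#' @param dN non-synonymous rate multiplier (>= 0).
#' @param dS synonymous rate multiplier (>= 0).
#' @param rho named numeric vector of relative exchange rates; names must
#'   cover `c("AC","AG","AT","CG","CT","GT")`.
#' @param pi stationary codon frequencies over the 61 sense codons
#'   (positive, summing to 1). Default: uniform.
#' @param scale if `TRUE` (default `FALSE`), divide the generator by the
#'   stationary expected substitution rate so branch lengths are expected
#'   substitutions per codon.
#' @return 61x61 matrix with rows summing to zero; rownames/colnames are
#'   codons.
#' @export
build_codon_model <- function(dN, dS, rho = NULL, pi = NULL, scale = FALSE) {
  tab <- codon_tables()
  n <- length(tab$codons)
  if (is.null(rho)) rho <- setNames(rep(1, 6), EXCHANGES)
  if (!all(EXCHANGES %in% names(rho)))
    stop("rho must name all six nucleotide exchanges: ",
         paste(EXCHANGES, collapse = ", "))
  if (is.null(pi)) pi <- rep(1 / n, n)
  if (length(pi) != n || any(pi <= 0))
    stop("pi must be a positive vector over the 61 sense codons")
  pi <- pi / sum(pi)
  if (dN < 0 || dS < 0) stop("dN and dS must be non-negative")
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  nb <- tab$nb
  r <- rho[nb$exchange] * pi[nb$to] * ifelse(nb$syn, dS, dN)
  Q[cbind(nb$from, nb$to)] <- r
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

#' F3x4 codon frequency estimator
#'
#' Estimates codon frequencies as the product of position-specific
#' nucleotide frequencies, renormalized over the 61 sense codons.
#'
#' @param aln a [codon_alignment].
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
codon_freq_f3x4 <- function(aln) {
  rows <- unclass(aln)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  L <- ncol(mat)
  posfreq <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  for (p in 1:3) {
    cols <- seq(p, L, by = 3)
    chars <- mat[, cols]
    chars <- chars[chars %in% NUC]
    tabp <- table(factor(chars, levels = NUC))
    posfreq[p, ] <- as.numeric(tabp) / sum(tabp)
  }
  tab <- codon_tables()
  split3 <- do.call(rbind, strsplit(tab$codons, ""))
  f <- posfreq[1, split3[, 1]] * posfreq[2, split3[, 2]] * posfreq[3, split3[, 3]]
  # floor: degenerate alignments (few distinct codons) must still give a
  # usable stationary distribution
  f <- pmax(f, 1e-6)
  f <- f / sum(f)
  setNames(f, tab$codons)
}

#' Empirical codon frequencies
#'
#' Observed relative frequency of each sense codon across the whole
#' alignment (gap triplets ignored), with a small pseudo-count so every
#' codon has positive frequency.
#'
#' @inheritParams codon_freq_f3x4
#' @param pseudo pseudo-count added per codon (default 0.5).
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
codon_freq_empirical <- function(aln, pseudo = 0.5) {
  tab <- codon_tables()
  cods <- unlist(lapply(unclass(aln), split_codons))
  cods <- cods[cods %in% tab$codons]
  cnt <- table(factor(cods, levels = tab$codons))
  f <- (as.numeric(cnt) + pseudo)
  setNames(f / sum(f), tab$codons)
}

split_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# Expected substitution rate of the dN = dS = 1 generator under pi;
# dividing class generators by this constant puts branch lengths on the
# "expected substitutions per codon at omega = 1" scale for any (rho, pi).
unit_rate_constant <- function(rho, pi) {
  Q <- build_codon_model(1, 1, rho = rho, pi = pi)
  -sum(pi * diag(Q))
}

# Eigen machinery for reversible generators: symmetrize with pi^(1/2),
# decompose once, then P(t) for any t is two dense products.
rev_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2       # clean numeric asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(vals = e$values, U = e$vectors, sp = sp)
}

prob_matrix <- function(ed, t) {
  expl <- exp(ed$vals * t)
  P <- ed$U %*% (expl * t(ed$U))
  P <- P * ((1 / ed$sp) %o% ed$sp)
  P[P < 0] <- 0
  P / rowSums(P)
}
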