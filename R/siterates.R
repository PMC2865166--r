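# Empirical-Bayes per-site evolutionary rates on amino-acid alignments:
# the conservation-score engine behind reverse conservation analysis.
# Likelihood model: JTT exchangeabilities (optionally with alignment-wide
# empirical frequencies), gamma-distributed rate categories discretized by
# equal-probability category means, posterior-mean rate per column.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' JTT amino-acid substitution model
#'
#' Returns the JTT exchangeability matrix and stationary frequencies,
#' obtained through phangorn's model machinery and cached. Frequencies can
#' be replaced by alignment-wide empirical frequencies.
#'
#' @param freqs optional length-20 vector of amino-acid frequencies (in
#'   ARNDCQEGHILKMFPSTWYV order); default: the model's own frequencies.
#' @return A list with `R` (20x20 symmetric exchangeabilities), `pi`
#'   (frequencies) and `states`.
#' @export
aa_model_jtt <- function(freqs = NULL) {
  if (is.null(.mek_cache$jtt)) {
    tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
    dat <- phangorn::phyDat(matrix(c("A", "R", "N", "A", "R", "N"),
                                   nrow = 3,
                                   dimnames = list(c("A", "B", "C"), NULL)),
                            type = "AA")
    fit <- phangorn::pml(tr, dat, model = "JTT")
    R <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
    R[lower.tri(R)] <- fit$Q
    R <- R + t(R)
    bf <- fit$bf
    .mek_cache$jtt <- list(R = R, pi = setNames(as.numeric(bf), AA20))
  }
  m <- .mek_cache$jtt
  pi <- if (is.null(freqs)) m$pi else {
    stopifnot(length(freqs) == 20)
    f <- as.numeric(freqs) / sum(freqs)
    setNames(pmax(f, 1e-6) / sum(pmax(f, 1e-6)), AA20)
  }
  list(R = m$R, pi = pi, states = AA20)
}

# generator from exchangeabilities + freqs, scaled to 1 expected subst/unit
aa_generator <- function(model) {
  Q <- model$R %*% diag(model$pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(model$pi * diag(Q))
  Q / mu
}

aa_empirical_freqs <- function(aln) {
  ch <- unlist(strsplit(unclass(aln), ""))
  ch <- ch[ch %in% AA20]
  tab <- table(factor(ch, levels = AA20))
  (as.numeric(tab) + 1) / sum(as.numeric(tab) + 1)
}

aln_obs_aa <- function(aln) {
  lapply(unclass(aln), function(s) strsplit(s, "")[[1]])
}

#' Likelihood of one alignment column at a fixed rate
#'
#' Felsenstein pruning over the tree with branch lengths multiplied by
#' `rate`. Gaps and ambiguous residues are summed over all states.
#'
#' @param column named character vector of single residues, one per leaf.
#' @param tree an [ape::phylo] tree whose tips cover `names(column)`.
#' @param rate positive rate scalar.
#' @param model an amino-acid model from [aa_model_jtt()].
#' @return The column likelihood (not log).
#' @export
column_likelihood <- function(column, tree, rate, model = aa_model_jtt()) {
  if (rate <= 0) stop("rate must be > 0")
  trav <- tree_traversal(tree)
  if (!all(trav$tip.label %in% names(column)))
    stop("column must name every tree leaf")
  tipp <- tip_partials(lapply(column[trav$tip.label], identity),
                       model$states)
  ed <- rev_eigen(aa_generator(model), model$pi)
  Pm <- lapply(trav$edge.length, function(t) prob_matrix(ed, rate * t))
  exp(prune_loglik(trav, tipp, Pm, model$pi))
}

#' Empirical-Bayes site rates and conservation scores
#'
#' Fits a discretized gamma distribution of rates across sites (shape
#' estimated by maximizing the marginal log-likelihood), then reports each
#' column's posterior-mean rate and its standardized score S (mean 0, sd
#' 1 over scored columns; high S = low conservation).
#'
#' @param aln an [aa_alignment].
#' @param tree optional [ape::phylo]; when `NULL` a neighbour-joining tree
#'   on Poisson-corrected distances is built internally.
#' @param model amino-acid model, see [aa_model_jtt()].
#' @param K number of gamma rate categories (default 16).
#' @param gap_flag_threshold columns with a gap fraction above this are
#'   flagged (still scored).
#' @return A tibble of class `site_rate_profile` with columns `column`,
#'   `ref_pos` (ungapped position in the reference row, `NA` if the
#'   alignment has no reference or the reference is gapped), `rate`
#'   (posterior mean), `S`, `gap_fraction`, `flagged`. Attributes: `alpha`
#'   (gamma shape), `logLik`, `K`.
#' @export
eb_site_rates <- function(aln, tree = NULL, model = NULL, K = 16,
                          gap_flag_threshold = 0.5) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (K < 2) stop("constant rates: K must be >= 2 to standardize scores")
  if (is.null(model)) model <- aa_model_jtt(aa_empirical_freqs(aln))
  if (is.null(tree)) {
    d <- poisson_distance(aln, deletion = "pairwise")
    tree <- nj_tree(d)
  }
  trav <- tree_traversal(tree)
  if (!all(trav$tip.label %in% names(aln)))
    stop("tree leaves not all present in alignment")
  obs <- aln_obs_aa(aln)[trav$tip.label]
  cp <- compress_patterns(obs)
  obs_u <- lapply(obs, function(o) o[cp$cols])
  tipp <- tip_partials(obs_u, model$states)
  ed <- rev_eigen(aa_generator(model), model$pi)

  cat_loglik <- function(alpha) {
    rates <- phangorn::discrete.gamma(alpha, K)
    ll <- vapply(rates, function(r) {
      Pm <- lapply(trav$edge.length, function(t)
        prob_matrix(ed, max(r, 1e-8) * t))
      prune_loglik(trav, tipp, Pm, model$pi)
    }, numeric(length(cp$cols)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
    ll   # patterns x K
  }
  marginal <- function(alpha) {
    ll <- cat_loglik(alpha)
    m <- apply(ll, 1, max)
    sum(cp$weights * (m + log(rowMeans(exp(ll - m)))))
  }
  opt <- optimize(marginal, interval = c(0.05, 20), maximum = TRUE,
                  tol = 1e-3)
  alpha <- opt$maximum
  rates <- phangorn::discrete.gamma(alpha, K)
  ll <- cat_loglik(alpha)
  m <- apply(ll, 1, max)
  w <- exp(ll - m)                     # unnormalized posterior weights
  post <- w / rowSums(w)
  rhat_u <- as.numeric(post %*% rates)
  rhat <- rhat_u[cp$map]
  if (sd(rhat) == 0)
    stop("constant rates across all columns; S scores undefined")
  S <- (rhat - mean(rhat)) / sd(rhat)

  gapfrac <- colMeans(do.call(rbind, lapply(obs, function(o) o == "-" | o == "X")))
  refid <- attr(aln, "reference")
  nsites <- length(gapfrac)
  ref_pos <- rep(NA_integer_, nsites)
  if (!is.null(refid) && refid %in% names(aln)) {
    rr <- strsplit(unclass(aln)[[refid]], "")[[1]]
    ref_pos[rr != "-"] <- seq_len(sum(rr != "-"))
  }
  out <- tibble(
    column = seq_len(nsites), ref_pos = ref_pos,
    rate = rhat, S = S, gap_fraction = gapfrac,
    flagged = gapfrac > gap_flag_threshold
  )
  attr(out, "alpha") <- alpha
  attr(out, "logLik") <- opt$objective
  attr(out, "K") <- K
  class(out) <- c("site_rate_profile", class(out))
  out
}

#' @export
glance.site_rate_profile <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"), logLik = attr(x, "logLik"),
         K = attr(x, "K"), n_columns = nrow(x),
         n_flagged = sum(x$flagged))
}
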