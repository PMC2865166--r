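# Birth-death analysis of gene-family size evolution along a dated
# species tree: closed-form transition probabilities (equal birth and
# death rate lambda per gene per time unit), family likelihoods by
# pruning over ancestral sizes, maximum-likelihood estimation of lambda,
# Monte-Carlo family p-values, and branch identification by Viterbi and
# likelihood-ratio scores.

#' Birth-death transition probability
#'
#' Probability that a family of size `s` evolves to size `c` over time
#' `t` under a linear birth-death process with equal birth and death rate
#' `lam`: with `a = lam*t/(1 + lam*t)`,
#' `P = sum_j C(s,j) C(s+c-j-1, s-1) a^(s+c-2j) (1-2a)^j`.
#' The closed form requires `lam*t < 1` (`a < 0.5`); longer branches are
#' split into segments combined by Chapman-Kolmogorov products unless
#' `split = FALSE`, in which case a domain error is raised.
#'
#' @param s parent size (>= 0; 0 is absorbing).
#' @param c child size (>= 0); may be a vector.
#' @param t branch length in time units (>= 0).
#' @param lam birth = death rate per gene per time unit.
#' @param split auto-split long branches (default TRUE).
#' @param max_size truncation bound used when splitting (default 200).
#' @return Probability vector, same length as `c`.
#' @export
bd_transition <- function(s, c, t, lam, split = TRUE, max_size = 200) {
  if (s < 0 || any(c < 0) || t < 0 || lam < 0) stop("invalid arguments")
  if (t == 0 || lam == 0) return(as.numeric(c == s))
  if (s == 0) return(as.numeric(c == 0))
  if (lam * t >= 1) {
    if (!split)
      stop("domain error: closed form requires lam*t < 1 (alpha < 0.5)")
    if (s > max_size) stop("parent size exceeds truncation bound")
    Mt <- bd_kernel(t, lam, max_size)
    out <- Mt[s + 1, pmin(c, max_size) + 1]
    out[c > max_size] <- 0
    return(unname(out))
  }
  a <- lam * t / (1 + lam * t)
  la <- log(a); l12a <- log1p(-2 * a)
  vapply(c, function(ci) {
    j <- 0:min(s, ci)
    terms <- lchoose(s, j) + lchoose(s + ci - j - 1, s - 1) +
      (s + ci - 2 * j) * la + j * l12a
    sum(exp(terms))
  }, 0)
}

# Transition matrix over sizes 0..max_size (rows = parent size), with
# automatic Chapman-Kolmogorov splitting of long branches. Mass beyond
# the truncation bound is dropped (conservative); max_size at least
# twice the largest observed count keeps the loss negligible.
bd_kernel <- function(t, lam, max_size) {
  if (lam == 0 || t == 0) return(diag(max_size + 1))
  nseg <- if (lam * t >= 0.9) ceiling(lam * t / 0.5) else 1
  tseg <- t / nseg
  M <- matrix(0, max_size + 1, max_size + 1)
  M[1, 1] <- 1
  for (s in 1:max_size)
    M[s + 1, ] <- bd_transition(s, 0:max_size, tseg, lam, split = FALSE)
  Mt <- M
  if (nseg > 1) for (k in seq_len(nseg - 1)) Mt <- Mt %*% M
  Mt
}

make_bd_kernels <- function(trav, lam, max_size, override = NULL) {
  lapply(seq_len(nrow(trav$edge)), function(e) {
    rate <- if (!is.null(override) && e == override$branch) override$lam else lam
    bd_kernel(trav$edge.length[e], rate, max_size)
  })
}

uniform_root_prior <- function(max_size) c(0, rep(1 / max_size, max_size))

# fast pruning given precomputed kernels
family_ll_kern <- function(trav, kern, counts, max_size,
                           root_prior = NULL) {
  nn <- trav$ntip + trav$nnode
  partial <- vector("list", nn)
  for (i in seq_len(trav$ntip)) {
    v <- numeric(max_size + 1)
    v[counts[[trav$tip.label[i]]] + 1] <- 1
    partial[[i]] <- v
  }
  for (e in seq_len(nrow(trav$edge))) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    msg <- as.numeric(kern[[e]] %*% partial[[ch]])
    partial[[par]] <- if (is.null(partial[[par]])) msg
                      else partial[[par]] * msg
  }
  if (is.null(root_prior)) root_prior <- uniform_root_prior(max_size)
  log(sum(root_prior * partial[[trav$root]]))
}

#' Log-likelihood of one family's counts
#'
#' Prunes over ancestral sizes 0..`max_size` with birth-death transition
#' kernels; the root size is marginalized under a uniform prior on
#' 1..`max_size` (the default) or a supplied prior vector over
#' 0..`max_size`.
#'
#' @param tree ultrametric species [ape::phylo]; tip labels must match
#'   `names(counts)`.
#' @param counts named integer vector of extant sizes, one per leaf.
#' @param lam birth-death rate.
#' @param max_size truncation bound; must be at least twice the maximum
#'   observed count (default: exactly that, at least 20).
#' @param root_prior `"uniform"` or a numeric vector over sizes
#'   0..`max_size`.
#' @return Log-likelihood (scalar).
#' @export
family_likelihood <- function(tree, counts, lam, max_size = NULL,
                              root_prior = "uniform") {
  trav <- tree_traversal(tree)
  if (!all(trav$tip.label %in% names(counts)))
    stop("counts must name every leaf")
  mx <- max(counts)
  if (is.null(max_size)) max_size <- max(2 * mx, 20)
  if (mx > 0 && max_size < 2 * mx)
    stop("truncation bound exceeded by data: max_size must be >= ", 2 * mx)
  rp <- if (identical(root_prior, "uniform")) NULL else {
    stopifnot(length(root_prior) == max_size + 1)
    root_prior / sum(root_prior)
  }
  kern <- make_bd_kernels(trav, lam, max_size)
  family_ll_kern(trav, kern, counts, max_size, rp)
}

#' Estimate the birth-death rate lambda
#'
#' Maximizes the summed family log-likelihood over `lam` by bounded 1-D
#' search. Families extinct everywhere (all-zero counts) are excluded.
#'
#' @param counts family-count tibble (column `family` plus one column per
#'   species) or a data frame / matrix of species columns.
#' @param tree species tree.
#' @param interval search interval for `lam` (per gene per time unit).
#' @param max_size truncation bound (default from the data).
#' @return A list of class `bd_params`: `lam`, `logLik`, `max_size`,
#'   `degenerate` (TRUE when the data are constant and the estimate
#'   collapses to 0).
#' @export
estimate_lambda <- function(counts, tree, interval = c(1e-6, 0.1),
                            max_size = NULL) {
  cm <- family_count_matrix(counts, tree)
  keep <- rowSums(cm) > 0
  cm <- cm[keep, , drop = FALSE]
  if (nrow(cm) == 0) stop("no families with any surviving genes")
  if (is.null(max_size)) max_size <- max(2 * max(cm), 20)
  trav <- tree_traversal(tree)
  total_ll <- function(lam) {
    kern <- make_bd_kernels(trav, lam, max_size)
    sum(vapply(seq_len(nrow(cm)), function(i)
      family_ll_kern(trav, kern, cm[i, ], max_size), 0))
  }
  constant <- all(apply(cm, 1, function(r) length(unique(r)) == 1))
  if (constant) {
    return(structure(list(lam = 0, logLik = total_ll(1e-9),
                          max_size = max_size, degenerate = TRUE),
                     class = "bd_params"))
  }
  o <- optimize(total_ll, interval = interval, maximum = TRUE, tol = 1e-7)
  structure(list(lam = o$maximum, logLik = o$objective,
                 max_size = max_size, degenerate = FALSE),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat("birth-death rate lambda =", format(x$lam, digits = 4),
      if (x$degenerate) "(degenerate: constant data)" else "", "\n")
  invisible(x)
}

family_count_matrix <- function(counts, tree) {
  d <- as.data.frame(counts)
  fam <- if ("family" %in% names(d)) d$family else rownames(d)
  d <- d[, setdiff(names(d), "family"), drop = FALSE]
  miss <- setdiff(tree$tip.label, names(d))
  if (length(miss) > 0)
    stop("counts missing species: ", paste(miss, collapse = ", "))
  m <- as.matrix(d[, tree$tip.label, drop = FALSE])
  rownames(m) <- fam
  storage.mode(m) <- "integer"
  m
}

#' Monte-Carlo p-value for one family
#'
#' Simulates `M` families under the null (root size uniform on
#' 1..`root_max`, birth-death with rate `lam`) and reports the fraction
#' whose likelihood is at most the observed family's likelihood, with an
#' add-one correction (so `p >= 1/(M+1)`).
#'
#' @param counts named vector of observed sizes per species.
#' @param tree species tree.
#' @param lam birth-death rate.
#' @param M number of resamplings (default 1000).
#' @param seed integer seed.
#' @param max_size truncation bound.
#' @param root_max root sizes are drawn uniformly from 1..`root_max`
#'   (default: max observed count, at least 2).
#' @return A list of class `family_test`: `p`, `logLik_obs`, `M`.
#' @export
family_pvalue <- function(counts, tree, lam, M = 1000, seed = 1,
                          max_size = NULL, root_max = NULL) {
  if (M < 1) stop("M must be >= 1")
  if (is.null(max_size)) max_size <- max(2 * max(counts), 20)
  if (is.null(root_max)) root_max <- max(2, max(counts))
  trav <- tree_traversal(tree)
  kern <- make_bd_kernels(trav, lam, max_size)
  ll_obs <- family_ll_kern(trav, kern, counts, max_size)
  set.seed(seed)
  nleq <- 0
  for (m in seq_len(M)) {
    root <- sample.int(root_max, 1)
    sim <- sim_family_once(trav, root, lam)
    if (max(sim) > max_size) { nleq <- nleq + 1; next }  # more extreme than observable
    llm <- family_ll_kern(trav, kern, sim, max_size)
    if (llm <= ll_obs) nleq <- nleq + 1
  }
  structure(list(p = (nleq + 1) / (M + 1), logLik_obs = ll_obs, M = M),
            class = "family_test")
}

sim_family_once <- function(trav, root, lam) {
  nn <- trav$ntip + trav$nnode
  st <- integer(nn)
  st[trav$root] <- root
  for (e in rev(seq_len(nrow(trav$edge)))) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    st[ch] <- sim_bd_branch(st[par], trav$edge.length[e], lam)
  }
  setNames(st[seq_len(trav$ntip)], trav$tip.label)
}

#' Identify branches driving a family-size deviation
#'
#' Computes the Viterbi (max-product) joint assignment of ancestral
#' sizes, then scores each branch two ways: an exceedance p-value (the
#' probability, under the branch's parent size and global `lam`, of a
#' child size whose transition probability is at most that of the
#' Viterbi transition) and a likelihood ratio (family likelihood with
#' that branch's rate refit freely over a branch-specific lambda,
#' divided by the likelihood under the global lambda).
#'
#' @inheritParams family_pvalue
#' @param p_cutoff significance cutoff on the exceedance p (default
#'   0.05).
#' @param lr_cutoff significance cutoff on the likelihood ratio (default
#'   50).
#' @return A tibble of class `branch_scores`: `branch`, `parent_node`,
#'   `child`, `child_label`, `parent_size`, `child_size`, `t`,
#'   `p_exceed`, `lik_ratio`, `significant`.
#' @export
identify_branches <- function(counts, tree, lam, max_size = NULL,
                              p_cutoff = 0.05, lr_cutoff = 50) {
  trav <- tree_traversal(tree)
  if (is.null(max_size)) max_size <- max(2 * max(counts), 20)
  kern <- make_bd_kernels(trav, lam, max_size)
  nn <- trav$ntip + trav$nnode
  delta <- vector("list", nn)
  for (i in seq_len(trav$ntip)) {
    v <- rep(-Inf, max_size + 1)
    v[counts[[trav$tip.label[i]]] + 1] <- 0
    delta[[i]] <- v
  }
  best_child <- vector("list", nrow(trav$edge))
  for (e in seq_len(nrow(trav$edge))) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    lK <- log(kern[[e]])
    m <- lK + rep(delta[[ch]], each = max_size + 1)
    m[!is.finite(m)] <- -1e300
    bc <- max.col(m, ties.method = "first")
    val <- m[cbind(seq_len(max_size + 1), bc)]
    best_child[[e]] <- bc - 1
    delta[[par]] <- if (is.null(delta[[par]])) val else delta[[par]] + val
  }
  rootv <- delta[[trav$root]] + log(uniform_root_prior(max_size))
  assign <- integer(nn)
  assign[trav$root] <- which.max(rootv) - 1
  for (e in rev(seq_len(nrow(trav$edge)))) {
    assign[trav$edge[e, 2]] <- best_child[[e]][assign[trav$edge[e, 1]] + 1]
  }
  ll_global <- family_ll_kern(trav, kern, counts, max_size)
  res <- lapply(seq_len(nrow(trav$edge)), function(e) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    s <- assign[par]; c2 <- assign[ch]
    pv <- kern[[e]][s + 1, ]
    p_obs <- pv[c2 + 1]
    p_exc <- sum(pv[pv <= p_obs + 1e-15])
    t_e <- trav$edge.length[e]
    upper <- if (t_e > 0) min(2, 5 / t_e) else 2
    llb <- function(lb) {
      kb <- kern
      kb[[e]] <- bd_kernel(t_e, lb, max_size)
      family_ll_kern(trav, kb, counts, max_size)
    }
    ob <- optimize(llb, c(1e-8, upper), maximum = TRUE, tol = 1e-5)
    lr <- exp(max(ob$objective, ll_global) - ll_global)
    tibble(branch = e, parent_node = par, child = ch,
           parent_size = s, child_size = c2,
           t = t_e, p_exceed = p_exc, lik_ratio = lr)
  })
  out <- dplyr::bind_rows(res)
  out$significant <- out$p_exceed <= p_cutoff | out$lik_ratio > lr_cutoff
  out$child_label <- ifelse(out$child <= trav$ntip,
                            trav$tip.label[out$child], NA_character_)
  class(out) <- c("branch_scores", class(out))
  out
}

#' Birth-death test of a whole family table
#'
#' Estimates lambda, computes a Monte-Carlo p-value per family, and
#' branch scores for families below the significance cutoff.
#'
#' @param counts family-count tibble (column `family` + species columns).
#' @param tree dated species tree.
#' @param M resamplings per family (default 1000).
#' @param seed integer seed.
#' @param alpha family-level significance cutoff (default 0.05).
#' @return A list of class `bd_test`: `params`, `families` (tibble:
#'   family, p, significant), `branches` (branch-score tibbles for
#'   significant families).
#' @export
bd_family_test <- function(counts, tree, M = 1000, seed = 1, alpha = 0.05) {
  params <- estimate_lambda(counts, tree)
  cm <- family_count_matrix(counts, tree)
  ps <- vapply(seq_len(nrow(cm)), function(i)
    family_pvalue(cm[i, ], tree, params$lam, M = M, seed = seed + i,
                  max_size = params$max_size)$p, 0)
  fams <- tibble(family = rownames(cm), p = ps, significant = ps <= alpha)
  branches <- list()
  for (i in which(fams$significant)) {
    branches[[fams$family[i]]] <-
      identify_branches(cm[i, ], tree, params$lam,
                        max_size = params$max_size)
  }
  structure(list(params = params, families = fams, branches = branches),
            class = "bd_test")
}

#' @export
tidy.bd_test <- function(x, ...) x$families

#' @export
glance.bd_test <- function(x, ...) {
  tibble(lam = x$params$lam, logLik = x$params$logLik,
         n_families = nrow(x$families),
         n_significant = sum(x$families$significant))
}

#' Dated three-species tree builder
#'
#' Convenience fixture for a dated three-taxon species tree: two sister
#' species diverging `t_sisters` time units ago, joined by an outgroup
#' species at `t_outgroup` (total age; both readings of "separated by a
#' further x units" are covered by passing the intended total).
#'
#' @param sisters character vector of the two sister species names.
#' @param outgroup outgroup species name.
#' @param t_sisters sister divergence time.
#' @param t_outgroup total root age (> `t_sisters`).
#' @return An ultrametric [ape::phylo].
#' @export
dated_three_taxon_tree <- function(sisters, outgroup,
                                   t_sisters = 180, t_outgroup = 190) {
  stopifnot(t_outgroup > t_sisters)
  txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g);",
                 sisters[1], t_sisters, sisters[2], t_sisters,
                 t_outgroup - t_sisters, outgroup, t_outgroup)
  ape::read.tree(text = txt)
}
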