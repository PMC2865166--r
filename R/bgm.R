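# Co-evolving codon detection: marginal ancestral reconstruction under a
# single-ratio MG94 fit, mapping of non-synonymous substitutions onto
# branches, filtering by per-site substitution counts, and a Bayesian
# network over sites whose edge posteriors flag correlated substitution
# histories.

#' Marginal ancestral codon reconstruction
#'
#' Computes, for every internal node and site, the marginal posterior
#' distribution over the 61 sense codons under a fitted single-ratio
#' MG94 model. Ambiguous tip states are averaged over compatible codons.
#'
#' @param aln a [codon_alignment].
#' @param fit a [fit_mg94_global()] result on the same data.
#' @return A list of class `ancestral_states` with `post` (list over
#'   nodes of 61 x sites posterior matrices; tip nodes hold their —
#'   possibly ambiguous — normalized state distributions), `tree`,
#'   `trav`, `Pmats`, and `joint_diff` helpers used by the mapper.
#' @export
reconstruct_ancestral <- function(aln, fit) {
  stopifnot(inherits(fit, "mg94_fit"))
  tab <- codon_tables()
  tree <- fit$tree
  trav <- tree_traversal(tree)
  if (!all(trav$tip.label %in% names(aln)))
    stop("alignment does not cover tree leaves")
  obs <- lapply(unclass(aln), split_codons)[trav$tip.label]
  tipp <- tip_partials(obs, tab$codons, expand = codon_expand())
  Q <- build_codon_model(fit$omega, 1, rho = fit$rho, pi = fit$pi) /
    unit_rate_constant(fit$rho, fit$pi)
  ed <- rev_eigen(Q, fit$pi)
  Pm <- lapply(trav$edge.length, function(t) prob_matrix(ed, t))
  up <- prune_partials(trav, tipp, Pm, fit$pi)
  nn <- trav$ntip + trav$nnode
  nsites <- ncol(tipp[[1]])
  # "above" partials A[v]: likelihood contribution of everything outside
  # the subtree of v, as a function of v's state (includes pi at root)
  A <- vector("list", nn)
  A[[trav$root]] <- matrix(fit$pi, length(fit$pi), nsites)
  eord <- rev(seq_len(nrow(trav$edge)))   # preorder
  for (e in eord) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    sib <- A[[par]]
    # product of messages from siblings of ch into par
    for (e2 in which(trav$edge[, 1] == par)) {
      if (e2 == e) next
      sib <- sib * up$msgs[[e2]]
    }
    A[[ch]] <- t(Pm[[e]]) %*% sib
  }
  post <- vector("list", nn)
  for (v in seq_len(nn)) {
    m <- A[[v]] * up$partial[[v]]
    cs <- colSums(m)
    cs[cs == 0] <- 1
    post[[v]] <- sweep(m, 2, cs, "/")
  }
  structure(list(post = post, tree = tree, trav = trav, Pmats = Pm,
                 up = up, A = A, pi = fit$pi, nsites = nsites),
            class = "ancestral_states")
}

#' Map non-synonymous substitutions onto branches
#'
#' For every branch and site, the posterior probability that the parent
#' and child codons translate to different amino acids; indicators are
#' the probabilities binarized at 0.5.
#'
#' @param anc an [reconstruct_ancestral()] result.
#' @return A list of class `substitution_map` with `indicator`
#'   (branches x sites 0/1 matrix), `expected` (the underlying
#'   probabilities), `site_counts` (column sums of `indicator`), `trav`.
#' @export
map_nonsyn_substitutions <- function(anc) {
  stopifnot(inherits(anc, "ancestral_states"))
  tab <- codon_tables()
  aa_idx <- as.integer(factor(tab$aa))
  same_aa <- outer(aa_idx, aa_idx, "==")
  trav <- anc$trav
  nE <- nrow(trav$edge)
  nsites <- anc$nsites
  expected <- matrix(0, nE, nsites)
  for (e in seq_len(nE)) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    # joint posterior over (parent i, child j):
    #   above(par) * prod_{siblings} msgs * P_ij * partial(child)
    rest <- anc$A[[par]]
    for (e2 in which(trav$edge[, 1] == par)) {
      if (e2 == e) next
      rest <- rest * anc$up$msgs[[e2]]
    }
    P <- anc$Pmats[[e]]
    Lch <- anc$up$partial[[ch]]
    for (s in seq_len(nsites)) {
      J <- (rest[, s] %o% Lch[, s]) * P
      tot <- sum(J)
      if (tot <= 0) next
      expected[e, s] <- 1 - sum(J[same_aa]) / tot
    }
  }
  indicator <- (expected >= 0.5) * 1L
  structure(list(indicator = indicator, expected = expected,
                 site_counts = colSums(indicator), trav = trav),
            class = "substitution_map")
}

#' Filter sites by non-synonymous branch count
#'
#' @param map a [map_nonsyn_substitutions()] result (or a 0/1 matrix).
#' @param min_subs minimum column sum to retain a site (default 3).
#' @return Integer vector of retained site indices, order preserved.
#' @export
filter_sites <- function(map, min_subs = 3) {
  counts <- if (inherits(map, "substitution_map")) map$site_counts
            else colSums(map)
  which(counts >= min_subs)
}

#' BGM configuration
#'
#' @param max_parents maximum in-degree (default 2).
#' @param min_subs substitution-count filter threshold (default 3).
#' @param chain_length structure-MCMC moves per chain (default 1e5).
#' @param burn_in fraction discarded (default 0.2).
#' @param n_chains independent chains (default 2).
#' @param edge_threshold association call threshold (default 0.5).
#' @param edge_prior sparsity prior: structure prior proportional to
#'   `edge_prior ^ n_edges` (default 0.3; 1 = uniform over structures).
#' @param seed integer seed.
#' @return A list of class `bgm_config`.
#' @export
bgm_config <- function(max_parents = 2, min_subs = 3, chain_length = 1e5,
                       burn_in = 0.2, n_chains = 2, edge_threshold = 0.5,
                       edge_prior = 0.3, seed = 1) {
  if (max_parents < 1) stop("max_parents must be >= 1")
  if (edge_threshold <= 0 || edge_threshold >= 1)
    stop("edge_threshold must be in (0,1)")
  if (edge_prior <= 0 || edge_prior > 1)
    stop("edge_prior must be in (0,1]")
  structure(list(max_parents = max_parents, min_subs = min_subs,
                 chain_length = chain_length, burn_in = burn_in,
                 n_chains = n_chains, edge_threshold = edge_threshold,
                 edge_prior = edge_prior, seed = seed),
            class = "bgm_config")
}

# Local marginal log-likelihood of node v given parent set (columns of
# X): Bernoulli likelihood under the BDeu prior with equivalent sample
# size 1 (Beta(a, a) per parent configuration, a = 1 / (2 * 2^p)).
# Unrealized configurations contribute nothing (their Beta terms cancel).
bgm_local_score <- function(xv, Xpa, ess = 1) {
  p <- if (is.null(Xpa)) 0 else ncol(Xpa)
  a <- ess / (2 * 2^p)
  if (p == 0) {
    n1 <- sum(xv); n0 <- length(xv) - n1
    return(lbeta(n1 + a, n0 + a) - lbeta(a, a))
  }
  cfg <- as.integer(Xpa %*% (2^(seq_len(p) - 1)))
  sc <- 0
  for (c0 in unique(cfg)) {
    sel <- cfg == c0
    n1 <- sum(xv[sel]); n0 <- sum(sel) - n1
    sc <- sc + lbeta(n1 + a, n0 + a) - lbeta(a, a)
  }
  sc
}

# Precompute scores of every parent set of size <= max_parents for every
# node (local marginal likelihood plus the sparsity-prior term
# |parents| * log(edge_prior)). Returns list over nodes: named numeric
# vector, names = parent-set keys ("0", "2", "2,5", ...).
bgm_score_table <- function(X, max_parents = 2, edge_prior = 0.5) {
  n <- ncol(X)
  lapply(seq_len(n), function(v) {
    others <- setdiff(seq_len(n), v)
    sets <- list(integer(0))
    if (max_parents >= 1) sets <- c(sets, as.list(others))
    if (max_parents >= 2 && length(others) >= 2) {
      cmb <- combn(others, 2)
      sets <- c(sets, lapply(seq_len(ncol(cmb)), function(k) cmb[, k]))
    }
    sc <- vapply(sets, function(pa)
      bgm_local_score(X[, v], X[, pa, drop = FALSE]) +
        length(pa) * log(edge_prior), 0)
    names(sc) <- vapply(sets, set_key, "")
    sc
  })
}

set_key <- function(pa) {
  if (length(pa) == 0) "0" else paste(sort(pa), collapse = ",")
}

# acyclicity check of adjacency list (parents[[v]] = integer vector)
is_acyclic <- function(parents) {
  n <- length(parents)
  indeg_children <- vector("list", n)
  for (v in seq_len(n)) for (p in parents[[v]])
    indeg_children[[p]] <- c(indeg_children[[p]], v)
  indeg <- lengths(parents)
  queue <- which(indeg == 0)
  seen <- 0
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1
    for (ch in indeg_children[[v]]) {
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  seen == n
}

#' Exact BGM edge posteriors by structure enumeration
#'
#' Enumerates every directed acyclic structure with in-degree at most
#' `max_parents` on the columns of `X` (feasible for <= 5 sites), scores
#' each under the Bernoulli-Dirichlet marginal likelihood with a uniform
#' structure prior, and returns exact direction-marginalized pair
#' association posteriors.
#'
#' @param X branches x sites 0/1 matrix (already filtered).
#' @param max_parents maximum in-degree (default 2).
#' @param edge_prior sparsity prior base, as in [bgm_config()].
#' @return A tibble with columns `site1`, `site2`, `posterior`.
#' @export
bgm_exact_posteriors <- function(X, max_parents = 2, edge_prior = 0.3) {
  n <- ncol(X)
  if (n < 2) stop("need >= 2 sites")
  if (n > 5) stop("exact enumeration supported for <= 5 sites")
  scores <- bgm_score_table(X, max_parents, edge_prior)
  sets_of <- lapply(seq_len(n), function(v) {
    keys <- names(scores[[v]])
    lapply(strsplit(keys, ","), function(k) as.integer(k[k != "0"]))
  })
  counts <- vapply(sets_of, length, 0L)
  ncombo <- prod(counts)
  logw <- numeric(ncombo)
  masks <- vector("list", ncombo)
  nkept <- 0L
  idx <- rep(1L, n)
  repeat {
    parents <- lapply(seq_len(n), function(v) sets_of[[v]][[idx[v]]])
    if (is_acyclic(parents)) {
      nkept <- nkept + 1L
      logw[nkept] <- sum(vapply(seq_len(n),
                                function(v) scores[[v]][[idx[v]]], 0))
      pm <- matrix(FALSE, n, n)
      for (v in seq_len(n)) for (p in parents[[v]]) {
        pm[min(v, p), max(v, p)] <- TRUE
      }
      masks[[nkept]] <- pm
    }
    k <- 1L
    repeat {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= counts[k]) break
      idx[k] <- 1L; k <- k + 1L
      if (k > n) break
    }
    if (k > n) break
  }
  logw <- logw[seq_len(nkept)]
  masks <- masks[seq_len(nkept)]
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  pairmass <- matrix(0, n, n)
  for (m in seq_len(nkept)) pairmass <- pairmass + w[m] * masks[[m]]
  pairs <- which(upper.tri(pairmass), arr.ind = TRUE)
  tibble(site1 = pairs[, 1], site2 = pairs[, 2],
         posterior = pairmass[pairs])
}

#' BGM edge posteriors by structure MCMC
#'
#' Metropolis-Hastings over directed acyclic structures with in-degree at
#' most `max_parents` (single-edge add/delete/reverse proposals, uniform
#' structure prior, Bernoulli-Dirichlet local marginal likelihoods).
#' Edge posteriors are direction-marginalized pair association
#' probabilities averaged over post-burn-in samples of all chains; chains
#' disagreeing by more than 0.1 on any pair raise a warning.
#'
#' @param X branches x sites 0/1 matrix restricted to retained sites.
#' @param config a [bgm_config()].
#' @param site_names optional site labels (default column indices).
#' @return A tibble of class `edge_posterior` with columns `site1`,
#'   `site2`, `posterior`; attribute `chain_disagreement`.
#' @export
bgm_edge_posteriors <- function(X, config = bgm_config(),
                                site_names = NULL) {
  n <- ncol(X)
  if (n < 2) stop("no BGM-eligible sites: need >= 2 retained sites")
  if (is.null(site_names)) site_names <- colnames(X)
  if (is.null(site_names)) site_names <- as.character(seq_len(n))
  scores <- bgm_score_table(X, config$max_parents, config$edge_prior)
  set.seed(config$seed)
  # Pairwise three-state move: for a random ordered pair (u, v) the edge
  # between them is in state none / u->v / v->u; propose one of the other
  # two states uniformly (symmetric kernel), subject to the in-degree cap
  # and acyclicity.
  run_chain <- function() {
    parents <- replicate(n, integer(0), simplify = FALSE)
    keys <- vapply(parents, set_key, "")
    sc <- vapply(seq_len(n), function(v) scores[[v]][[keys[v]]], 0)
    acc <- matrix(0, n, n)
    kept <- 0
    burn <- floor(config$chain_length * config$burn_in)
    for (it in seq_len(config$chain_length)) {
      u <- sample.int(n, 1); v <- sample.int(n, 1)
      valid <- u != v
      if (valid) {
        has_uv <- u %in% parents[[v]]
        has_vu <- v %in% parents[[u]]
        state <- if (has_uv) 1L else if (has_vu) 2L else 0L
        target <- sample(setdiff(0:2, state), 1)
        p2 <- parents
        if (state == 1L) p2[[v]] <- setdiff(p2[[v]], u)
        if (state == 2L) p2[[u]] <- setdiff(p2[[u]], v)
        if (target == 1L) p2[[v]] <- c(p2[[v]], u)
        if (target == 2L) p2[[u]] <- c(p2[[u]], v)
        if (length(p2[[v]]) > config$max_parents ||
            length(p2[[u]]) > config$max_parents) valid <- FALSE
        if (valid && target != 0L && !is_acyclic(p2)) valid <- FALSE
      }
      if (valid) {
        delta <- 0
        newsc <- sc
        for (w in unique(c(v, u))) {
          if (!identical(sort(p2[[w]]), sort(parents[[w]]))) {
            s2 <- scores[[w]][[set_key(p2[[w]])]]
            delta <- delta + s2 - sc[w]
            newsc[w] <- s2
          }
        }
        if (log(runif(1)) < delta) {
          parents <- p2
          sc <- newsc
        }
      }
      if (it > burn && it %% 10 == 0) {
        kept <- kept + 1
        for (w in seq_len(n)) for (p in parents[[w]]) {
          i <- min(w, p); j <- max(w, p)
          acc[i, j] <- acc[i, j] + 1
        }
      }
    }
    acc / kept
  }
  chains <- lapply(seq_len(config$n_chains), function(i) run_chain())
  avg <- Reduce(`+`, chains) / length(chains)
  disagree <- 0
  if (length(chains) > 1) {
    for (i in seq_len(length(chains) - 1))
      disagree <- max(disagree,
                      max(abs(chains[[i]] - chains[[length(chains)]])))
    if (disagree > 0.1)
      warning("BGM chains disagree by ", round(disagree, 3),
              " on at least one edge; consider longer chains",
              call. = FALSE)
  }
  pairs <- which(upper.tri(avg), arr.ind = TRUE)
  out <- tibble(site1 = site_names[pairs[, 1]],
                site2 = site_names[pairs[, 2]],
                posterior = avg[pairs])
  attr(out, "chain_disagreement") <- disagree
  class(out) <- c("edge_posterior", class(out))
  out
}

#' Group co-evolving sites
#'
#' Connected components of the graph on site pairs whose association
#' posterior reaches the threshold.
#'
#' @param edges a tibble with columns `site1`, `site2`, `posterior` (e.g.
#'   from [bgm_edge_posteriors()] or a printed pair table).
#' @param threshold posterior cutoff (default 0.5).
#' @return A list of class `coevol_groups`: character vectors of member
#'   sites, each of size >= 2.
#' @export
group_coevolving <- function(edges, threshold = 0.5) {
  keep <- edges$posterior >= threshold
  if (!any(keep)) return(structure(list(), class = "coevol_groups"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$site1[keep]),
               to = as.character(edges$site2[keep])),
    directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- unname(lapply(groups, sort))
  structure(groups, class = "coevol_groups")
}

#' @export
print.coevol_groups <- function(x, ...) {
  cat(length(x), "co-evolving group(s)\n")
  for (k in seq_along(x))
    cat("  group", k, ":", paste(x[[k]], collapse = ", "), "\n")
  invisible(x)
}

#' Full co-evolution scan
#'
#' Convenience wrapper: single-ratio fit, ancestral reconstruction,
#' substitution mapping, filtering and BGM, returning edge posteriors and
#' groups.
#'
#' @param aln a [codon_alignment].
#' @param tree optional tree passed to [fit_mg94_global()].
#' @param spec nucleotide-model constraints.
#' @param config a [bgm_config()].
#' @return A list with `fit`, `map`, `retained`, `edges`, `groups`.
#' @export
detect_coevolution <- function(aln, tree = NULL, spec = nuc_model_spec(),
                               config = bgm_config()) {
  fit <- fit_mg94_global(aln, tree, spec)
  anc <- reconstruct_ancestral(aln, fit)
  map <- map_nonsyn_substitutions(anc)
  retained <- filter_sites(map, config$min_subs)
  if (length(retained) < 2)
    stop("no BGM-eligible sites: fewer than 2 sites with >= ",
         config$min_subs, " non-synonymous substitutions")
  X <- map$indicator[, retained, drop = FALSE]
  colnames(X) <- as.character(retained)
  edges <- bgm_edge_posteriors(X, config)
  groups <- group_coevolving(edges, config$edge_threshold)
  list(fit = fit, map = map, retained = retained, edges = edges,
       groups = groups)
}
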