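# Felsenstein pruning over arbitrary state spaces, shared by the
# amino-acid site-rate machinery (20 states) and the codon models (61
# states). Likelihoods are computed for all sites at once as dense
# state-by-site partial matrices with per-column rescaling.

# Postorder edge traversal of an ape tree; returns a list with the edge
# matrix ordered tips-first, node count, and root index.
tree_traversal <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, edge.length = tree$edge.length,
       ntip = length(tree$tip.label), tip.label = tree$tip.label,
       nnode = tree$Nnode, root = length(tree$tip.label) + 1L)
}

# Tip partial matrices: for each taxon a nstate x nsites 0/1 matrix.
# Unobserved states (gap, ambiguity) are all-ones columns (sum over
# compatible states); partial ambiguity resolved via `expand`, a function
# mapping one observed symbol to the compatible state indices.
tip_partials <- function(obs, states, expand = NULL) {
  nstate <- length(states)
  idx <- setNames(seq_len(nstate), states)
  lapply(obs, function(symbols) {
    m <- matrix(0, nstate, length(symbols))
    for (k in seq_along(symbols)) {
      s <- symbols[k]
      j <- idx[s]
      if (!is.na(j)) {
        m[j, k] <- 1
      } else if (!is.null(expand)) {
        comp <- expand(s)
        if (length(comp) == 0) m[, k] <- 1 else m[comp, k] <- 1
      } else {
        m[, k] <- 1
      }
    }
    m
  })
}

# Codon-symbol expansion: codons containing ambiguity codes match every
# sense codon compatible with the IUPAC letters; full gap matches all.
codon_expand <- function() {
  tab <- codon_tables()
  iupac <- Biostrings::IUPAC_CODE_MAP
  function(sym) {
    if (sym == "---") return(integer(0))
    ch <- strsplit(sym, "")[[1]]
    if (any(!ch %in% names(iupac))) return(integer(0))
    sets <- lapply(ch, function(c1) strsplit(iupac[[c1]], "")[[1]])
    cands <- as.vector(outer(outer(sets[[1]], sets[[2]], paste0),
                             sets[[3]], paste0))
    unname(tab$index[cands[cands %in% tab$codons]])
  }
}

# Per-site log-likelihood by pruning. `Pmats` is a list over edges (in the
# same order as trav$edge rows) of nstate x nstate transition matrices.
# Returns the vector of per-site log-likelihoods.
prune_loglik <- function(trav, tipp, Pmats, root_freq) {
  nsites <- ncol(tipp[[1]])
  nstate <- length(root_freq)
  nn <- trav$ntip + trav$nnode
  partial <- vector("list", nn)
  logscale <- rep(0, nsites)
  for (i in seq_len(trav$ntip)) partial[[i]] <- tipp[[trav$tip.label[i]]]
  for (e in seq_len(nrow(trav$edge))) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    msg <- Pmats[[e]] %*% partial[[ch]]
    if (is.null(partial[[par]])) {
      partial[[par]] <- msg
    } else {
      p <- partial[[par]] * msg
      # rescale by column sums (any positive per-column factor works)
      cs <- .colSums(p, nstate, nsites)
      cs[cs == 0] <- 1
      partial[[par]] <- p * rep(1 / cs, each = nstate)
      logscale <- logscale + log(cs)
    }
  }
  lik <- colSums(root_freq * partial[[trav$root]])
  log(lik) + logscale
}

# As prune_loglik but also returns all node partials and the traversal,
# for ancestral-state machinery.
prune_partials <- function(trav, tipp, Pmats, root_freq) {
  nn <- trav$ntip + trav$nnode
  partial <- vector("list", nn)
  scale_log <- rep(0, ncol(tipp[[1]]))
  for (i in seq_len(trav$ntip)) partial[[i]] <- tipp[[trav$tip.label[i]]]
  msgs <- vector("list", nrow(trav$edge))  # message child -> parent per edge
  for (e in seq_len(nrow(trav$edge))) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    msgs[[e]] <- Pmats[[e]] %*% partial[[ch]]
    if (is.null(partial[[par]])) partial[[par]] <- msgs[[e]]
    else partial[[par]] <- partial[[par]] * msgs[[e]]
  }
  list(partial = partial, msgs = msgs, trav = trav)
}

# Pattern compression: collapse identical site columns. Returns index of
# unique patterns, weights, and the map back to sites.
compress_patterns <- function(obs_by_taxon) {
  mat <- do.call(rbind, obs_by_taxon)
  key <- apply(mat, 2, paste, collapse = "\r")
  uk <- unique(key)
  map <- match(key, uk)
  first <- match(uk, key)
  list(cols = first, weights = tabulate(map, nbins = length(uk)), map = map)
}
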