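# Synthetic-data generators: codon alignments evolved site-by-site under
# an MG94-style process with selection classes, optional event-conditional
# coupling between codon pairs, and per-site overall rate multipliers;
# plus gene-family size vectors under a linear birth-death process.
# Every realized substitution is recorded as ground truth.

#' Site-class specification for the codon simulator
#'
#' @param omega non-negative dN/dS values, one per class.
#' @param proportion class proportions (must sum to 1).
#' @return A tibble of class `site_class_spec`.
#' @export
site_class_spec <- function(omega, proportion) {
  if (length(omega) != length(proportion)) stop("length mismatch")
  if (any(omega < 0)) stop("omega values must be >= 0")
  if (abs(sum(proportion) - 1) > 1e-8) stop("proportions must sum to 1")
  out <- tibble(omega = as.numeric(omega), proportion = as.numeric(proportion))
  class(out) <- c("site_class_spec", class(out))
  out
}

#' Co-evolving pair specification
#'
#' While a branch carries a non-synonymous substitution at the driver
#' site, the partner site's non-synonymous rates are multiplied by
#' `coupling` for the remainder of that branch.
#'
#' @param driver,partner distinct site indices.
#' @param coupling multiplier >= 1.
#' @return A tibble of class `coevol_spec`.
#' @export
coevol_spec <- function(driver, partner, coupling = 10) {
  if (length(driver) != length(partner)) stop("length mismatch")
  if (any(driver == partner)) stop("driver and partner sites must differ")
  if (any(coupling < 1)) stop("coupling must be >= 1")
  if (any(partner %in% driver))
    stop("a partner site may not itself be a driver site")
  out <- tibble(driver = as.integer(driver), partner = as.integer(partner),
                coupling = rep_len(as.numeric(coupling), length(driver)))
  class(out) <- c("coevol_spec", class(out))
  out
}

# Precompute, per codon state, its neighbour moves with base rates
# rho * pi_target, split syn/nonsyn. Used by the event simulator.
sim_rate_tables <- function(rho, pi) {
  tab <- codon_tables()
  nb <- tab$nb
  base <- unname(rho[nb$exchange] * pi[nb$to])
  # normalization: expected total rate at omega = 1 under pi equals 1
  tot_by_from <- tapply(base, nb$from, sum)
  tot <- rep(0, length(tab$codons)); tot[as.integer(names(tot_by_from))] <- tot_by_from
  mu <- sum(pi * tot)
  base <- base / mu
  by_from <- split(seq_len(nrow(nb)), nb$from)
  list(nb = nb, base = base, by_from = by_from, codons = tab$codons,
       aa = tab$aa)
}

# simulate one site along one branch (homogeneous rates); returns final
# state + event log with times offset by `t0`
sim_branch_site <- function(state, t_total, omega, mult, rt, t0 = 0) {
  events <- list()
  time <- 0
  repeat {
    rows <- rt$by_from[[as.character(state)]]
    if (is.null(rows)) rows <- integer(0)
    syn <- rt$nb$syn[rows]
    rates <- rt$base[rows] * mult * ifelse(syn, 1, omega)
    R <- sum(rates)
    if (R <= 0) break
    dt <- rexp(1, R)
    if (time + dt > t_total) break
    time <- time + dt
    k <- rows[sample.int(length(rows), 1, prob = rates)]
    newstate <- rt$nb$to[k]
    events[[length(events) + 1]] <- list(time = t0 + time, from = state,
                                         to = newstate,
                                         syn = rt$nb$syn[k])
    state <- newstate
  }
  list(state = state, events = events)
}

# partner site: plain rates until the driver's first non-synonymous event
# at `dtime`, then non-synonymous rates boosted by `coupling` for the
# remainder of the branch (piecewise-homogeneous simulation)
sim_branch_site_coupled <- function(state, t_total, omega, mult, rt,
                                    dtime, coupling) {
  if (!is.finite(dtime) || dtime >= t_total)
    return(sim_branch_site(state, t_total, omega, mult, rt))
  a <- sim_branch_site(state, dtime, omega, mult, rt)
  b <- sim_branch_site(a$state, t_total - dtime, omega * coupling, mult,
                       rt, t0 = dtime)
  list(state = b$state, events = c(a$events, b$events))
}

#' Simulate a codon alignment with known ground truth
#'
#' Each site evolves independently (except engineered coupled pairs) by an
#' exact event-by-event continuous-time Markov process on the 61 sense
#' codons with MG94-style rates: single-nucleotide moves only,
#' non-synonymous moves scaled by the site's omega (times any coupling
#' boost), and an optional per-site overall rate multiplier. The root
#' sequence is drawn from the stationary codon distribution `pi`.
#'
#' @param tree an [ape::phylo] with >= 3 leaves (2 accepted for degenerate
#'   tests) and branch lengths in expected substitutions per codon at
#'   omega = 1.
#' @param n_codons number of codons (>= 10 recommended).
#' @param classes a [site_class_spec()].
#' @param coevol optional [coevol_spec()].
#' @param rho named exchange-rate vector (default: all 1).
#' @param pi stationary codon frequencies (default uniform).
#' @param rate_alpha optional gamma shape; when given, per-site overall
#'   rate multipliers are drawn from a mean-1 gamma with this shape.
#' @param class_assignment optional integer vector (length `n_codons`)
#'   fixing each site's class instead of sampling from the proportions —
#'   used to engineer controlled scenarios.
#' @param rate_multipliers optional numeric vector (length `n_codons`) of
#'   fixed per-site overall rate scalars; overrides `rate_alpha`.
#' @param seed integer seed; identical inputs give identical output.
#' @return A list with `alignment` (a [codon_alignment]), and `truth`, a
#'   list with `site_class` (tibble: site, class, omega, multiplier),
#'   `events` (tibble: branch, site, time, from, to, syn),
#'   `nonsyn_branch_matrix` (branches x sites 0/1), and `tree`.
#' @export
simulate_codon_alignment <- function(tree, n_codons, classes,
                                     coevol = NULL, rho = NULL, pi = NULL,
                                     rate_alpha = NULL,
                                     class_assignment = NULL,
                                     rate_multipliers = NULL, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("tree needs >= 2 leaves")
  if (abs(sum(classes$proportion) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  tab <- codon_tables()
  if (is.null(rho)) rho <- setNames(rep(1, 6), EXCHANGES)
  if (is.null(pi)) pi <- setNames(rep(1 / 61, 61), tab$codons)
  pi <- pi / sum(pi)
  if (!is.null(coevol)) {
    if (any(coevol$coupling < 1)) stop("coupling must be >= 1")
    if (any(c(coevol$driver, coevol$partner) > n_codons))
      stop("coevol sites outside alignment")
  }
  set.seed(seed)
  rt <- sim_rate_tables(rho, pi)
  cls <- if (!is.null(class_assignment)) {
    stopifnot(length(class_assignment) == n_codons,
              all(class_assignment %in% seq_len(nrow(classes))))
    as.integer(class_assignment)
  } else {
    sample.int(nrow(classes), n_codons, replace = TRUE,
               prob = classes$proportion)
  }
  omega_site <- classes$omega[cls]
  mult_site <- if (!is.null(rate_multipliers)) {
    stopifnot(length(rate_multipliers) == n_codons,
              all(rate_multipliers >= 0))
    as.numeric(rate_multipliers)
  } else if (is.null(rate_alpha)) rep(1, n_codons)
  else rgamma_mean1(n_codons, rate_alpha)
  root_seq <- sample.int(61, n_codons, replace = TRUE, prob = pi)

  trav <- tree_traversal(tree)
  nn <- trav$ntip + trav$nnode
  nodestates <- matrix(NA_integer_, nn, n_codons)
  nodestates[trav$root, ] <- root_seq
  # preorder: visit edges parent-before-child
  eord <- rev(seq_len(nrow(trav$edge)))
  ev_branch <- integer(0); ev_site <- integer(0); ev_time <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0); ev_syn <- logical(0)

  driver_of <- if (is.null(coevol)) integer(0) else coevol$driver
  for (e in eord) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    tlen <- trav$edge.length[e]
    start <- nodestates[par, ]
    end <- start
    # driver sites (and all uncoupled sites) first
    driver_nonsyn_time <- rep(Inf, n_codons)
    partner_sites <- if (is.null(coevol)) integer(0) else coevol$partner
    plain_sites <- setdiff(seq_len(n_codons), partner_sites)
    for (s in plain_sites) {
      r <- sim_branch_site(start[s], tlen, omega_site[s], mult_site[s], rt)
      end[s] <- r$state
      for (evt in r$events) {
        ev_branch <- c(ev_branch, e); ev_site <- c(ev_site, s)
        ev_time <- c(ev_time, evt$time); ev_from <- c(ev_from, evt$from)
        ev_to <- c(ev_to, evt$to); ev_syn <- c(ev_syn, evt$syn)
        if (!evt$syn && s %in% driver_of)
          driver_nonsyn_time[s] <- min(driver_nonsyn_time[s], evt$time)
      }
    }
    if (!is.null(coevol)) {
      for (k in seq_len(nrow(coevol))) {
        s <- coevol$partner[k]
        r <- sim_branch_site_coupled(start[s], tlen, omega_site[s],
                                     mult_site[s], rt,
                                     driver_nonsyn_time[coevol$driver[k]],
                                     coevol$coupling[k])
        end[s] <- r$state
        for (evt in r$events) {
          ev_branch <- c(ev_branch, e); ev_site <- c(ev_site, s)
          ev_time <- c(ev_time, evt$time); ev_from <- c(ev_from, evt$from)
          ev_to <- c(ev_to, evt$to); ev_syn <- c(ev_syn, evt$syn)
        }
      }
    }
    nodestates[ch, ] <- end
  }
  rowseq <- apply(nodestates[seq_len(trav$ntip), , drop = FALSE], 1,
                  function(ix) paste(tab$codons[ix], collapse = ""))
  names(rowseq) <- trav$tip.label
  aln <- codon_alignment(rowseq)
  events <- tibble(branch = ev_branch, site = ev_site, time = ev_time,
                   from = tab$codons[ev_from], to = tab$codons[ev_to],
                   syn = ev_syn)
  nb_mat <- matrix(0L, nrow(trav$edge), n_codons)
  if (nrow(events) > 0) {
    ns <- events[!events$syn, ]
    if (nrow(ns) > 0) nb_mat[cbind(ns$branch, ns$site)] <- 1L
  }
  truth <- list(
    site_class = tibble(site = seq_len(n_codons), class = cls,
                        omega = omega_site, multiplier = mult_site),
    events = events,
    nonsyn_branch_matrix = nb_mat,
    tree = tree
  )
  list(alignment = aln, truth = truth)
}

rgamma_mean1 <- function(n, shape) stats::rgamma(n, shape = shape, rate = shape)

#' Simulate gene-family sizes under a linear birth-death process
#'
#' Each lineage's size evolves along the species tree by a linear
#' birth-death process with equal per-gene birth and death rate `lam`
#' per time unit; size 0 is absorbing.
#'
#' @param species_tree ultrametric [ape::phylo] with branch lengths in
#'   time units.
#' @param lam birth = death rate per gene per time unit (>= 0).
#' @param root_size integer >= 1 size at the root.
#' @param n_families number of independent families.
#' @param seed integer seed.
#' @return A list with `counts` (tibble: family x species columns),
#'   `histories` (matrix families x nodes of sizes at every node), and
#'   `tree`.
#' @export
simulate_family_counts <- function(species_tree, lam, root_size,
                                   n_families, seed = 1) {
  if (lam < 0) stop("lam must be >= 0")
  if (root_size < 1) stop("root_size must be >= 1")
  set.seed(seed)
  trav <- tree_traversal(species_tree)
  nn <- trav$ntip + trav$nnode
  eord <- rev(seq_len(nrow(trav$edge)))
  hist <- matrix(NA_integer_, n_families, nn)
  hist[, trav$root] <- root_size
  for (e in eord) {
    par <- trav$edge[e, 1]; ch <- trav$edge[e, 2]
    tlen <- trav$edge.length[e]
    hist[, ch] <- vapply(hist[, par], function(sz)
      sim_bd_branch(sz, tlen, lam), integer(1))
  }
  counts <- as.data.frame(hist[, seq_len(trav$ntip), drop = FALSE])
  names(counts) <- trav$tip.label
  counts <- dplyr::bind_cols(tibble(family = paste0("fam", seq_len(n_families))),
                             counts)
  list(counts = as_tibble(counts), histories = hist, tree = species_tree)
}

sim_bd_branch <- function(size, t_total, lam) {
  time <- 0
  n <- as.integer(size)
  if (lam == 0) return(n)
  repeat {
    if (n == 0) return(0L)
    rate <- 2 * lam * n
    dt <- rexp(1, rate)
    if (time + dt > t_total) return(n)
    time <- time + dt
    n <- n + sample(c(-1L, 1L), 1)
  }
}
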