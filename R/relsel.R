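# Random-effects-likelihood (REL) scan for site-level selection.
# An MG94-style codon model is crossed with a constrained reversible
# nucleotide model; dN and dS each follow a fitted 3-point discrete
# distribution, giving a 9-class grid; per-site empirical-Bayes factors
# classify sites. Fitting follows a two-stage protocol: nucleotide rates
# and branch lengths from a GTR fit on the nucleotide data, then the
# grid, weights and a tree-scale factor by direct likelihood
# maximization.

#' Constrained nucleotide-exchange specification
#'
#' Maps each of the six unordered nucleotide exchanges to a named rate
#' parameter; exchanges sharing a name share a rate, and every exchange
#' not named in `...` maps to the reference rate (fixed at 1).
#'
#' @param ... named assignments among `AC`, `AG`, `AT`, `CG`, `CT`, `GT`,
#'   each a parameter label, e.g. `nuc_model_spec(CT = "RCT")`.
#' @return A named character vector of class `nuc_model_spec` mapping all
#'   six exchanges to parameter labels (`"ref"` = reference).
#' @export
nuc_model_spec <- function(...) {
  args <- list(...)
  map <- setNames(rep("ref", 6), EXCHANGES)
  if (length(args) > 0) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("arguments must be named by exchange")
    bad <- setdiff(names(args), EXCHANGES)
    if (length(bad) > 0) stop("unknown exchange(s): ", paste(bad, collapse = ", "))
    for (nm in names(args)) map[nm] <- as.character(args[[nm]])
  }
  if (!any(map == "ref"))
    stop("at least one exchange must map to the reference rate")
  structure(map, class = "nuc_model_spec")
}

# collapse a full 6-vector of fitted exchange rates onto the constraint
# map (shared labels averaged, reference normalized to 1)
collapse_rho <- function(rho, spec) {
  labs <- unclass(spec)
  out <- rho
  for (lb in unique(labs)) {
    sel <- labs == lb
    out[sel] <- mean(rho[sel])
  }
  out / mean(out[labs == "ref"])
}

# Stage 1: nucleotide GTR fit (rates + branch lengths) via phangorn.
fit_nuc_stage <- function(aln, tree) {
  rows <- unclass(aln)
  mat <- do.call(rbind, strsplit(toupper(unname(rows)), ""))
  rownames(mat) <- names(rows)
  dat <- phangorn::phyDat(mat, type = "DNA")
  fit <- phangorn::pml(tree, dat, model = "GTR")
  fit <- quiet(phangorn::optim.pml(fit, optQ = TRUE, optEdge = TRUE,
                                   optBf = TRUE,
                                   control = phangorn::pml.control(trace = 0)))
  # phangorn rate order: AC AG AT CG CT GT
  rho <- setNames(fit$Q, EXCHANGES)
  list(rho = rho / rho["AG"], tree = fit$tree, logLik = fit$logLik)
}

quiet <- function(expr) {
  withCallingHandlers(suppressMessages(expr),
                      warning = function(w) invokeRestart("muffleWarning"))
}

# per-site log-likelihood matrix under a list of (dN, dS) classes
class_site_logliks <- function(trav, tipp, classes_dn, classes_ds,
                               rho, pi, scale) {
  ns <- ncol(tipp[[1]])
  K <- length(classes_dn)
  out <- matrix(NA_real_, ns, K)
  mu0 <- unit_rate_constant(rho, pi)
  for (k in seq_len(K)) {
    Q <- build_codon_model(classes_dn[k], classes_ds[k], rho = rho,
                           pi = pi) / mu0
    ed <- rev_eigen(Q, pi)
    Pm <- lapply(trav$edge.length, function(t) prob_matrix(ed, scale * t))
    out[, k] <- prune_loglik(trav, tipp, Pm, pi)
  }
  out
}

#' Fit the REL positive-selection model
#'
#' Fits the 3x3 random-effects grid of dN and dS rate classes on top of a
#' constrained reversible nucleotide model. Nucleotide exchange rates and
#' branch lengths come from a GTR fit on the nucleotide data (collapsed
#' onto `spec`); the grid values, grid weights and a global tree-scale
#' factor are then optimized by multi-start direct search. The grid is
#' normalized so the prior-mean synonymous rate is 1.
#'
#' @param aln a [codon_alignment].
#' @param tree optional [ape::phylo]; built by neighbour joining on the
#'   translated alignment when `NULL`.
#' @param spec a [nuc_model_spec()] (default: single reference rate).
#' @param bins number of dN (and dS) classes (default 3).
#' @param starts random restarts (default 3).
#' @param seed integer seed for the restarts' jitter.
#' @param freq codon-frequency estimator: `"F3x4"` (default) or
#'   `"empirical"`.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `rel_fit`: list with `grid` (tibble: class,
#'   dN, dS, weight), `rho`, `pi`, `tree` (branch lengths scaled),
#'   `logLik`, `convergence`, `spec`, and cached site-class likelihoods.
#' @export
fit_rel <- function(aln, tree = NULL, spec = nuc_model_spec(), bins = 3,
                    starts = 3, seed = 1, freq = c("F3x4", "empirical"),
                    maxit = 400) {
  freq <- match.arg(freq)
  stopifnot(inherits(aln, "codon_alignment"))
  ntaxa <- length(aln)
  if (ntaxa < 3) stop("need at least 3 taxa")
  if (ntaxa < 10)
    warning("fewer than 10 sequences; REL results may be unreliable",
            call. = FALSE)
  if (is.null(tree)) {
    tree <- nj_tree(poisson_distance(translate_alignment(aln)))
  }
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  nuc <- fit_nuc_stage(aln, tree)
  rho <- collapse_rho(nuc$rho, spec)
  pi <- if (freq == "F3x4") codon_freq_f3x4(aln) else codon_freq_empirical(aln)
  tree_s <- nuc$tree
  tree_s$edge.length[tree_s$edge.length < 1e-8] <- 1e-8

  tab <- codon_tables()
  trav <- tree_traversal(tree_s)
  obs <- lapply(unclass(aln), split_codons)[trav$tip.label]
  cp <- compress_patterns(obs)
  obs_u <- lapply(obs, function(o) o[cp$cols])
  tipp <- tip_partials(obs_u, tab$codons, expand = codon_expand())
  wts <- cp$weights

  nb <- bins
  gidx <- expand.grid(a = seq_len(nb), b = seq_len(nb))
  # weights are profiled out by EM at fixed grid values: with the
  # site-by-class likelihood matrix in hand, the optimal product weights
  # p (x) q satisfy simple responsibility averages
  em_weights <- function(L, wts, iter = 60) {
    n <- nrow(L)
    p <- rep(1 / nb, nb); q <- rep(1 / nb, nb)
    mx <- apply(L, 1, max)
    E <- exp(L - mx)
    for (it in seq_len(iter)) {
      w <- p[gidx$a] * q[gidx$b]
      R <- E * rep(w, each = n)
      R <- R / rowSums(R)
      R <- R * wts
      p <- vapply(seq_len(nb), function(a)
        sum(R[, gidx$a == a]), 0)
      q <- vapply(seq_len(nb), function(b)
        sum(R[, gidx$b == b]), 0)
      p <- p / sum(p); q <- q / sum(q)
    }
    w <- p[gidx$a] * q[gidx$b]
    ll <- sum(wts * (mx + log(as.numeric(E %*% w))))
    list(p = p, q = q, loglik = ll)
  }
  # parameters: log dN (nb), log raw dS (nb), log scale; dS is
  # renormalized inside so the prior-mean synonymous rate is 1
  unpack <- function(par, q) {
    dn <- exp(par[seq_len(nb)])
    ds_raw <- exp(par[nb + seq_len(nb)])
    ds <- ds_raw / sum(q * ds_raw)
    list(dn = dn, ds = ds, scale = exp(par[2 * nb + 1]))
  }
  cur_q <- rep(1 / nb, nb)
  cur_w <- NULL
  nll <- function(par) {
    th <- unpack(par, cur_q)
    if (th$scale > 1e3 || th$scale < 1e-6) return(1e10)
    if (any(th$dn > 100) || any(th$ds > 100)) return(1e10)
    L <- class_site_logliks(trav, tipp, th$dn[gidx$a], th$ds[gidx$b],
                            rho, pi, th$scale)
    em <- em_weights(L, wts)
    cur_q <<- em$q
    cur_w <<- em
    val <- -em$loglik
    if (!is.finite(val)) 1e10 else val
  }
  set.seed(seed)
  # single-ratio pre-fit pins down (omega, tree scale) cheaply and
  # anchors the grid start; Nelder-Mead stalls badly when the scale
  # starts an order of magnitude off
  nll1 <- function(par) {
    om <- exp(par[1]); sc <- exp(par[2])
    if (om > 50 || sc > 1e3) return(1e10)
    v <- -sum(wts * class_site_logliks(trav, tipp, om, 1, rho, pi, sc))
    if (!is.finite(v)) 1e10 else v
  }
  o1 <- optim(c(log(0.5), log(3)), nll1, method = "Nelder-Mead",
              control = list(maxit = 150, reltol = 1e-6))
  om_hat <- min(exp(o1$par[1]), 5); sc_hat <- exp(o1$par[2])
  base_par <- c(log(pmax(om_hat * seq(0.25, 3, length.out = nb), 1e-3)),
                log(seq(0.7, 1.4, length.out = nb)), log(sc_hat))
  best <- NULL; best_em <- NULL
  for (s in seq_len(starts)) {
    cur_q <- rep(1 / nb, nb)
    p0 <- base_par + if (s == 1) 0 else stats::rnorm(length(base_par), 0, 0.6)
    o <- optim(p0, nll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-7))
    # restart from the solution: a fresh simplex escapes NM stagnation
    o <- optim(o$par, nll, method = "Nelder-Mead",
               control = list(maxit = ceiling(maxit / 2), reltol = 1e-7))
    o$value <- nll(o$par)   # refresh cur_q/cur_w at the optimum
    if (is.null(best) || o$value < best$value) {
      best <- o
      best_em <- cur_w
    }
  }
  if (is.null(best) || best$value >= 1e10)
    stop("REL fit failed to converge from any start")
  th <- unpack(best$par, best_em$q)
  # exact renormalization: (dN, dS, scale) -> (dN/m, dS/m, scale*m)
  # leaves the likelihood untouched and sets the prior-mean dS to 1
  m <- sum(best_em$p[gidx$a] * best_em$q[gidx$b] * th$ds[gidx$b])
  th$dn <- th$dn / m; th$ds <- th$ds / m; th$scale <- th$scale * m
  # sort each marginal ascending for identifiability
  od <- order(th$dn); os <- order(th$ds)
  dn <- th$dn[od]; pw <- best_em$p[od]
  ds <- th$ds[os]; qw <- best_em$q[os]
  grid <- tibble(class = seq_len(nb^2),
                 dN = dn[gidx$a], dS = ds[gidx$b],
                 weight = pw[gidx$a] * qw[gidx$b])
  ll_cache <- class_site_logliks(trav, tipp, grid$dN, grid$dS, rho, pi,
                                 th$scale)
  tree_out <- tree_s
  tree_out$edge.length <- tree_out$edge.length * th$scale
  structure(list(
    grid = grid, rho = rho, pi = pi, tree = tree_out,
    logLik = -best$value, scale = th$scale,
    convergence = best$convergence, counts = best$counts,
    spec = spec, nuc_logLik = nuc$logLik,
    .site_class_loglik = ll_cache[cp$map, , drop = FALSE]
  ), class = "rel_fit")
}

#' @export
print.rel_fit <- function(x, ...) {
  cat("REL fit:", nrow(x$grid), "rate classes, logLik =",
      formatC(x$logLik, digits = 6), "\n")
  print(as.data.frame(x$grid), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.rel_fit <- function(x, ...) {
  dplyr::mutate(x$grid, ratio = .data$dN / .data$dS)
}

#' @export
glance.rel_fit <- function(x, ...) {
  pos <- x$grid$dN > x$grid$dS + 1e-9
  tibble(logLik = x$logLik, n_classes = nrow(x$grid),
         prior_positive = sum(x$grid$weight[pos]),
         scale = x$scale, convergence = x$convergence)
}

#' dN/dS ratio of the top rate class
#'
#' Reporting arithmetic for a fitted (or printed) rate-class grid: the
#' ratio dN/dS of the class with the largest dN/dS.
#'
#' @param grid a tibble with columns `dN` and `dS` (e.g. `fit$grid`).
#' @return The maximal dN/dS ratio.
#' @export
top_class_ratio <- function(grid) {
  max(grid$dN / grid$dS)
}

#' Per-site empirical-Bayes selection classification
#'
#' For each codon site, the posterior over the 9 grid classes is the
#' prior weight times the site likelihood, normalized. `P+` is the
#' posterior mass on classes with dN > dS; the Bayes factor is the
#' posterior odds over the prior odds, and symmetrically for dN < dS.
#' Classes with dN = dS (within 1e-9) contribute to neither side.
#'
#' @param fit a [fit_rel()] result.
#' @param bf_strong,bf_weak Bayes-factor cutoffs (defaults 50 and 10).
#' @return A tibble of class `site_selection` with columns `site`,
#'   `posterior_positive`, `prior_positive`, `bayes_factor_positive`,
#'   `bayes_factor_negative`, `class` (one of `positive_strong`,
#'   `positive_weak`, `purifying`, `neutral`).
#' @export
site_bayes_factor <- function(fit, bf_strong = 50, bf_weak = 10) {
  stopifnot(inherits(fit, "rel_fit"))
  ll <- fit$.site_class_loglik
  w <- fit$grid$weight
  pos <- fit$grid$dN > fit$grid$dS + 1e-9
  neg <- fit$grid$dS > fit$grid$dN + 1e-9
  prior_pos <- sum(w[pos]); prior_neg <- sum(w[neg])
  mx <- apply(ll, 1, max)
  po <- exp(ll - mx) * rep(w, each = nrow(ll))
  po <- po / rowSums(po)
  p_pos <- rowSums(po[, pos, drop = FALSE])
  p_neg <- rowSums(po[, neg, drop = FALSE])
  odds <- function(p) p / (1 - p)
  bf <- function(post, prior) {
    if (prior <= 0) return(ifelse(post > 0, Inf, 0))
    if (prior >= 1) return(ifelse(post < 1, 0, Inf))
    ifelse(post >= 1, Inf, odds(post) / odds(prior))
  }
  bf_pos <- bf(p_pos, prior_pos)
  bf_neg <- bf(p_neg, prior_neg)
  cls <- dplyr::case_when(
    bf_pos >= bf_strong ~ "positive_strong",
    bf_pos >= bf_weak ~ "positive_weak",
    bf_neg >= bf_strong ~ "purifying",
    TRUE ~ "neutral"
  )
  out <- tibble(site = seq_len(nrow(ll)),
                posterior_positive = p_pos, prior_positive = prior_pos,
                bayes_factor_positive = bf_pos,
                bayes_factor_negative = bf_neg,
                class = cls)
  if (prior_pos <= 0 || prior_pos >= 1)
    attr(out, "degenerate_prior") <- TRUE
  class(out) <- c("site_selection", class(out))
  out
}

#' Bayes factor from prior and posterior probabilities
#'
#' @param posterior,prior probabilities in (0,1).
#' @return `odds(posterior) / odds(prior)`.
#' @export
bayes_factor <- function(posterior, prior) {
  (posterior / (1 - posterior)) / (prior / (1 - prior))
}

#' @export
autoplot.site_selection <- function(object, bf_strong = 50, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$site,
                               y = .data$bayes_factor_positive)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = bf_strong, linetype = "dashed") +
    ggplot2::labs(x = "codon site", y = "Bayes factor (dN > dS)")
}

#' Single-ratio MG94 fit
#'
#' Fits one global dN/dS (with the same two-stage protocol as
#' [fit_rel()]) — the model the co-evolution mapper uses for ancestral
#' reconstruction.
#'
#' @inheritParams fit_rel
#' @return A list of class `mg94_fit` with `omega`, `scale`, `rho`, `pi`,
#'   `tree` (scaled), `logLik`.
#' @export
fit_mg94_global <- function(aln, tree = NULL, spec = nuc_model_spec(),
                            freq = c("F3x4", "empirical")) {
  freq <- match.arg(freq)
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(tree)) tree <- nj_tree(poisson_distance(translate_alignment(aln)))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  nuc <- fit_nuc_stage(aln, tree)
  rho <- collapse_rho(nuc$rho, spec)
  pi <- if (freq == "F3x4") codon_freq_f3x4(aln) else codon_freq_empirical(aln)
  tree_s <- nuc$tree
  tree_s$edge.length[tree_s$edge.length < 1e-8] <- 1e-8
  tab <- codon_tables()
  trav <- tree_traversal(tree_s)
  obs <- lapply(unclass(aln), split_codons)[trav$tip.label]
  cp <- compress_patterns(obs)
  tipp <- tip_partials(lapply(obs, function(o) o[cp$cols]),
                       tab$codons, expand = codon_expand())
  nll <- function(par) {
    om <- exp(par[1]); sc <- exp(par[2])
    if (om > 50 || sc > 1e3) return(1e10)
    ll <- class_site_logliks(trav, tipp, om, 1, rho, pi, sc)
    v <- -sum(cp$weights * ll)
    if (!is.finite(v)) 1e10 else v
  }
  o <- optim(c(log(0.3), log(1)), nll, method = "Nelder-Mead",
             control = list(maxit = 300, reltol = 1e-8))
  tree_out <- tree_s
  tree_out$edge.length <- tree_out$edge.length * exp(o$par[2])
  structure(list(omega = exp(o$par[1]), scale = exp(o$par[2]),
                 rho = rho, pi = pi, tree = tree_out,
                 logLik = -o$value, spec = spec),
            class = "mg94_fit")
}
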