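# Pipeline orchestration: a flat configuration object, staged execution
# with dependency checking, TSV/JSON outputs and a machine-readable run
# manifest.

#' Pipeline configuration
#'
#' Collects inputs and settings for the staged analysis. All thresholds
#' default to the published settings of the workflow this package
#' implements: window `n = 7`, intensity 0.5, Bayes-factor cutoffs
#' 50/10, substitution-count threshold 3, edge posterior 0.5, 1000
#' resamplings.
#'
#' @param alignment path to an aligned in-frame FASTA (or a
#'   [codon_alignment]).
#' @param tree optional Newick path (or [ape::phylo]).
#' @param mask optional region-mask TSV path (or [region_mask()]).
#' @param family_counts optional TSV path (rows = families, columns =
#'   species) or tibble.
#' @param reference optional reference taxon id.
#' @param nuc_spec a [nuc_model_spec()].
#' @param window_n,intensity RCA settings.
#' @param bins,bf_strong,bf_weak REL settings.
#' @param bgm a [bgm_config()].
#' @param resamplings birth-death Monte-Carlo resamplings.
#' @param seed integer seed used by every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment = NULL, tree = NULL, mask = NULL,
                            family_counts = NULL, reference = NULL,
                            nuc_spec = nuc_model_spec(),
                            window_n = 7, intensity = 0.5,
                            bins = 3, bf_strong = 50, bf_weak = 10,
                            bgm = bgm_config(), resamplings = 1000,
                            seed = 1) {
  for (p in c(alignment, tree, mask, family_counts)) {
    if (is.character(p) && !file.exists(p))
      stop("configured file does not exist: ", p)
  }
  structure(list(alignment = alignment, tree = tree, mask = mask,
                 family_counts = family_counts, reference = reference,
                 nuc_spec = nuc_spec, window_n = window_n,
                 intensity = intensity, bins = bins,
                 bf_strong = bf_strong, bf_weak = bf_weak, bgm = bgm,
                 resamplings = resamplings, seed = seed),
            class = "pipeline_config")
}

load_config_alignment <- function(config) {
  aln <- config$alignment
  if (is.character(aln)) aln <- codon_alignment(read_fasta(aln),
                                                reference = config$reference)
  if (!inherits(aln, "codon_alignment")) stop("config has no alignment")
  if (!is.null(config$mask)) {
    m <- config$mask
    if (is.character(m)) m <- read_region_mask(m)
    aln <- mask_regions(aln, m)
  }
  aln
}

load_config_tree <- function(config) {
  tr <- config$tree
  if (is.character(tr)) tr <- read_newick(tr)
  tr
}

stage_deps <- c(simulate = "", phylo = "", rates = "", rca = "rates",
                rel = "", bgm = "", family = "", usage = "")

#' Run one pipeline stage (or all)
#'
#' Executes a named analysis stage on the configured inputs, writing TSV
#' outputs and a JSON manifest (inputs, seed, parameter values, outputs)
#' into `outdir`. Deterministic stages rerun to byte-identical outputs;
#' stochastic stages reuse the configured seed.
#'
#' @param stage one of `"phylo"`, `"rates"`, `"rca"`, `"rel"`, `"bgm"`,
#'   `"family"`, `"usage"`, `"all"`.
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return A named list of stage results, invisibly; side effect: files
#'   under `outdir` and `manifest.json`.
#' @export
run_stage <- function(stage, config, outdir = tempfile("mek_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- if (identical(stage, "all"))
    c("phylo", "rates", "rca", "rel", "bgm", "usage",
      if (!is.null(config$family_counts)) "family")
  else stage
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  write_tsv <- function(d, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(d), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    path
  }
  manifest <- list(seed = config$seed, parameters = list(
    window_n = config$window_n, intensity = config$intensity,
    bins = config$bins, bf_strong = config$bf_strong,
    bf_weak = config$bf_weak, min_subs = config$bgm$min_subs,
    edge_threshold = config$bgm$edge_threshold,
    resamplings = config$resamplings), stages = list())
  needs_aln <- any(stages %in% c("phylo", "rates", "rca", "rel", "bgm", "usage"))
  aln <- if (needs_aln) load_config_alignment(config) else NULL
  tree <- load_config_tree(config)
  for (st in stages) {
    dep <- stage_deps[[st]]
    if (nzchar(dep) && !dep %in% names(results))
      stop("ordered-dependency error: stage '", st,
           "' requires stage '", dep, "' first")
    out <- switch(st,
      phylo = {
        aa <- translate_alignment(aln)
        tr <- bootstrap_support(aa, function(a) nj_tree(poisson_distance(a)),
                                n = 100, seed = config$seed)
        write_newick(tr, file.path(outdir, "tree.nwk"))
        list(tree = tr, files = "tree.nwk")
      },
      rates = {
        aa <- translate_alignment(aln)
        sr <- eb_site_rates(aa, tree = tree)
        list(rates = sr, files = write_tsv(sr, "site_rates"))
      },
      rca = {
        prof <- rca_profile(results$rates$rates, n = config$window_n,
                            I = config$intensity)
        f1 <- write_tsv(prof, "rca_profile")
        f2 <- write_tsv(rca_peaks(prof), "rca_peaks")
        list(profile = prof, files = c(f1, f2))
      },
      rel = {
        fit <- fit_rel(aln, tree = tree, spec = config$nuc_spec,
                       bins = config$bins, seed = config$seed)
        sel <- site_bayes_factor(fit, config$bf_strong, config$bf_weak)
        f1 <- write_tsv(sel, "site_selection")
        jsonlite::write_json(
          list(grid = fit$grid, logLik = fit$logLik,
               convergence = fit$convergence),
          file.path(outdir, "rel_fit.json"), auto_unbox = TRUE, digits = NA)
        list(fit = fit, selection = sel, files = c(f1, "rel_fit.json"))
      },
      bgm = {
        cfg <- config$bgm
        cfg$seed <- config$seed
        cv <- detect_coevolution(aln, tree = tree, spec = config$nuc_spec,
                                 config = cfg)
        f1 <- write_tsv(cv$edges, "bgm_edges")
        jsonlite::write_json(unclass(cv$groups),
                             file.path(outdir, "bgm_groups.json"))
        list(coevol = cv, files = c(f1, "bgm_groups.json"))
      },
      family = {
        fc <- config$family_counts
        if (is.character(fc)) fc <- as_tibble(utils::read.delim(fc))
        bt <- bd_family_test(fc, tree, M = config$resamplings,
                             seed = config$seed)
        f1 <- write_tsv(bt$families, "family_tests")
        jsonlite::write_json(
          list(lambda = bt$params$lam, logLik = bt$params$logLik,
               families = bt$families,
               branches = lapply(bt$branches, as.data.frame)),
          file.path(outdir, "family_results.json"),
          auto_unbox = TRUE, digits = NA)
        list(test = bt, files = c(f1, "family_results.json"))
      },
      usage = {
        cu <- codon_counts(as_tibble(aln))
        ca <- correspondence_analysis(cu)
        idt <- pairwise_identity(aln)
        f1 <- write_tsv(ca$coords, "ca_coordinates")
        f2 <- write_tsv(as.data.frame(idt$matrix), "identity_matrix")
        list(ca = ca, identity = idt, files = c(f1, f2))
      },
      stop("unknown stage: ", st)
    )
    results[[st]] <- out
    manifest$stages[[st]] <- list(outputs = basename(unlist(out$files)))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Run the full pipeline
#'
#' Convenience wrapper for `run_stage("all", ...)`.
#'
#' @inheritParams run_stage
#' @return See [run_stage()].
#' @export
run_pipeline <- function(config, outdir = tempfile("mek_run_")) {
  run_stage("all", config, outdir)
}
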