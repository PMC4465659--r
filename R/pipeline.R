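#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with the method's
#' canonical defaults: 100-bp windows sliding by 10 bp, folding at 3.5
#' degrees C, and a temperature sweep from 1.0 to 4.0 by 0.1 (31 folds per
#' haplotype).
#'
#' @param fasta,meta Input paths (alternatively pass an alignment directly
#'   to [run_pipeline()]).
#' @param frame_offset,ref_offset,code_table See [hap_alignment()].
#' @param central_method See [identify_central()].
#' @param window_width,window_step See [sliding_profile()].
#' @param fold_temperature Headline folding temperature (degrees C).
#' @param sweep Logical: run the temperature sweep and tree stages?
#' @param t_min,t_max,t_step Sweep grid.
#' @param metric Structure distance metric, see [sweep_distance_matrices()].
#' @param out_dir Output directory.
#' @param seed Seed recorded in the manifest (used by the `simulate`
#'   stage only; the analysis itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, meta = NULL, frame_offset = 0L,
                       ref_offset = 0L, code_table = "2",
                       central_method = "frequency",
                       window_width = 100L, window_step = 10L,
                       fold_temperature = 3.5, sweep = TRUE,
                       t_min = 1.0, t_max = 4.0, t_step = 0.1,
                       metric = "bp", out_dir = "tcsb_out", seed = 1L) {
  stopifnot(window_width >= 1, window_step >= 1, t_step > 0, t_max >= t_min,
            fold_temperature >= -10, fold_temperature <= 100)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis
#'
#' Classify > network > orient > spectra & Fisher tests > sliding windows >
#' fold group centrals > temperature sweep > Fitch-Margoliash trees >
#' majority-rule consensus, writing every stage's output plus a manifest
#' to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param alignment Optional [hap_alignment()]; when `NULL` the alignment
#'   is read from `config$fasta`/`config$meta`.
#' @return A list of class `tcsb_run` with the in-memory results:
#'   `alignment`, `network`, `central`, `oriented`, `spectrum`, `tests`,
#'   `profiles`, `structures`, `matrices`, `trees`, `consensus`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), alignment = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  aln <- alignment %||% stage("read", read_alignment(
    config$fasta, config$meta, config$frame_offset, config$ref_offset,
    config$code_table
  ))

  net <- stage("network", build_network(aln))
  write_network_tsv(net, file.path(out, "network_edges.tsv"))
  write_network_graphml(net, file.path(out, "network.graphml"))

  groups <- unique(aln$meta$group)
  centrals <- vapply(groups, identify_central, character(1),
                     net = net, method = config$central_method)
  # orient from the central of the most frequent (presumed ancestral) group
  grp_freq <- tapply(aln$meta$freq, aln$meta$group, sum)
  anc_group <- names(sort(grp_freq, decreasing = TRUE))[1]
  central <- centrals[[anc_group]]

  oriented <- stage("orient", orient_mutations(net, central))
  utils::write.table(as.data.frame(oriented[, setdiff(names(oriented), "columns")]),
                     file.path(out, "oriented_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  spectrum <- stage("tcsb", tally_spectrum(oriented))
  tests <- if (length(groups) >= 2) compare_all_groups(spectrum) else NULL
  write_tcsb_results(spectrum, tests, file.path(out, "spectra.tsv"),
                     file.path(out, "fisher_tests.json"))

  profiles <- stage("windows", dplyr::bind_rows(lapply(groups, function(g) {
    sliding_profile(aln, oriented, config$window_width, config$window_step,
                    group = g)
  })))
  write_profile_tsv(profiles, file.path(out, "window_profiles.tsv"))

  model <- model_at_temperature(energy_model(), config$fold_temperature)
  central_seqs <- stats::setNames(
    transcribe(gsub("-", "", aln$seqs[match(centrals, aln$ids)])),
    centrals
  )
  structures <- stage("fold", lapply(central_seqs, fold_mfe, model = model))
  write_vienna(structures, file.path(out, "central_structures.vienna"))

  matrices <- NULL; trees <- NULL; cons <- NULL
  if (isTRUE(config$sweep)) {
    all_seqs <- stats::setNames(transcribe(gsub("-", "", aln$seqs)), aln$ids)
    matrices <- stage("sweep", sweep_distance_matrices(
      all_seqs, t_min = config$t_min, t_max = config$t_max,
      t_step = config$t_step, metric = config$metric
    ))
    mdir <- file.path(out, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(matrices)) {
      write_phylip_dist(matrices[[nm]], file.path(mdir, paste0("dist_T", nm, ".phy")))
    }
    trees <- stage("trees", lapply(matrices, fitch_margoliash))
    write_newick_file(trees, file.path(out, "sweep_trees.nwk"))
    cons <- stage("consensus", majority_consensus(trees))
    writeLines(write_newick(cons), file.path(out, "consensus.nwk"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tcsb")),
    parameters = config[setdiff(names(config), c("fasta", "meta"))],
    inputs = list(fasta = config$fasta, meta = config$meta),
    n_haplotypes = length(aln$ids),
    n_columns = n_columns(aln),
    groups = as.list(centrals),
    oriented_central = central,
    n_oriented_mutations = nrow(oriented),
    n_excluded_nonsyn = sum(spectrum$n_excluded_nonsyn[!duplicated(spectrum$group)]),
    n_matrices = length(matrices),
    seed = config$seed
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(
    list(alignment = aln, network = net, central = central,
         centrals = centrals, oriented = oriented, spectrum = spectrum,
         tests = tests, profiles = profiles, structures = structures,
         matrices = matrices, trees = trees, consensus = cons,
         manifest = manifest),
    class = "tcsb_run"
  )
}

#' @export
print.tcsb_run <- function(x, ...) {
  cat("<tcsb_run> oriented from", x$central, "\n")
  print(x$spectrum)
  if (!is.null(x$tests)) print(x$tests)
  if (!is.null(x$matrices)) cat(" ", length(x$matrices), "distance matrices;",
                                "consensus with", x$consensus$Nnode, "internal nodes\n")
  invisible(x)
}
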