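`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score pipeline output against simulation ground truth
#'
#' Runs the orientation stages on a simulated dataset and reports how well
#' each was recovered: central-haplotype identification, per-mutation
#' orientation accuracy, the estimated versus true W>S bias per group, the
#' Fisher rejection indicator for every group pair, and (when hotspots
#' were planted) the localisation error of the top `pi_ws` maxima.
#'
#' @param sim A [simulate_haplotypes()] result.
#' @param central Node id to orient from; default is the estimated central
#'   of the ancestral group (`method = "frequency"`). Pass
#'   `sim$truth$centrals[[1]]` to score orientation under the true central.
#' @param alpha Significance level for the rejection indicator.
#' @param width,step Sliding-window parameters for hotspot localisation.
#' @return A list of class `recovery_report`: tibbles `centrals`, `groups`
#'   (beta_hat vs beta_true), `tests`, `orientation` (accuracy), and
#'   `hotspots` (NULL when none were planted).
#' @export
recovery_report <- function(sim, central = NULL, alpha = 0.05,
                            width = 100L, step = 10L) {
  stopifnot(inherits(sim, "hap_simulation"))
  aln <- sim$alignment
  truth <- sim$truth
  net <- build_network(aln)

  grp_names <- unique(aln$meta$group)
  if (!all(truth$centrals %in% net$nodes$id)) {
    stop("truth/alignment label mismatch: central haplotypes not in network")
  }
  centrals_tbl <- tibble::tibble(
    group = grp_names,
    true_central = unname(truth$centrals[grp_names]),
    est_central = vapply(grp_names, identify_central, character(1), net = net),
    correct = NA
  )
  centrals_tbl$correct <- centrals_tbl$true_central == centrals_tbl$est_central

  anc <- truth$centrals[[truth$ancestral_group]]
  oriented <- orient_mutations(net, central %||% anc)

  # orientation accuracy: every oriented mutation matched against truth by
  # (column, from, to); truth rows are per originating lineage
  truth_keys <- with(truth$mutations, paste(column, from_base, to_base))
  est_keys <- with(oriented, paste(column, from_base, to_base))
  orientation <- tibble::tibble(
    n_oriented = nrow(oriented),
    n_true = nrow(truth$mutations),
    n_matching = sum(est_keys %in% truth_keys),
    accuracy = if (nrow(oriented)) sum(est_keys %in% truth_keys) / nrow(oriented) else NA_real_
  )

  spectrum <- tally_spectrum(oriented)
  beta_true <- stats::setNames(truth$config$groups$beta, truth$config$groups$name)
  groups_tbl <- dplyr::summarise(
    dplyr::group_by(spectrum, .data$group),
    n_ws = sum(.data$n[.data$ws_class == "W>S"]),
    n_sw = sum(.data$n[.data$ws_class == "S>W"]),
    .groups = "drop"
  )
  groups_tbl$beta_hat <- with(groups_tbl, ifelse(n_ws + n_sw > 0, n_ws / (n_ws + n_sw), NA))
  groups_tbl$beta_true <- unname(beta_true[groups_tbl$group])

  tests <- if (length(grp_names) >= 2) {
    t <- compare_all_groups(spectrum)
    t$reject <- t$p_value < alpha
    t
  } else NULL

  hotspots <- NULL
  if (!is.null(truth$hotspots)) {
    hotspots <- purrr::map_dfr(names(truth$hotspots), function(g) {
      prof <- sliding_profile(aln, oriented, width = width, step = step, group = g)
      full <- prof[!prof$truncated, ]
      top <- full[order(-full$pi_ws, full$start), ]
      ranges <- truth$hotspots[[g]]
      k <- nrow(ranges)
      centers_true <- sort(rowMeans(ranges))
      # greedy peak picking: successive maxima at least one window apart
      centers_est <- numeric(0)
      for (r in seq_len(nrow(top))) {
        if (length(centers_est) == k) break
        if (!length(centers_est) ||
            all(abs(top$center[r] - centers_est) > width)) {
          centers_est <- c(centers_est, top$center[r])
        }
      }
      centers_est <- sort(centers_est)
      tibble::tibble(
        group = g,
        center_true = centers_true,
        center_est = centers_est,
        error_bp = abs(centers_est - centers_true)
      )
    })
  }

  structure(
    list(centrals = centrals_tbl, orientation = orientation,
         groups = groups_tbl, tests = tests, hotspots = hotspots),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n centrals:\n")
  print(x$centrals)
  cat(" orientation accuracy:", x$orientation$accuracy, "\n groups:\n")
  print(x$groups)
  if (!is.null(x$tests)) { cat(" tests:\n"); print(x$tests) }
  if (!is.null(x$hotspots)) { cat(" hotspot localisation:\n"); print(x$hotspots) }
  invisible(x)
}
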