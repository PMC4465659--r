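#' Configuration for the synthetic haplotype generator
#'
#' Describes a star-radiating haplotype system of the kind the analysis
#' assumes: one ancestral group whose central haplotype sits at the hub,
#' further groups derived from it by a small number of diagnostic
#' substitutions, and peripheral haplotypes radiating from each group's
#' central by private synonymous mutations with a group-specific
#' weak-to-strong direction bias.
#'
#' The defaults emulate the three-group mitochondrial Cytb system the
#' method was developed on: an ancestral group with a strong W>S excess, a
#' derived sister group two diagnostic T>C substitutions away (4
#' intervening nucleotides apart) with a weak bias, and a more distant
#' group with the opposite (S>W) bias.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param gene_length CDS length in bp, divisible by 3 (default 1140, a
#'   typical teleost Cytb).
#' @param groups Tibble with one row per group: `name`, `central_freq`,
#'   `n_peripheral`, `lambda` (Poisson mean mutations per peripheral
#'   lineage, at least one mutation is always applied), `beta` (probability
#'   a W<->S mutation is W>S).
#' @param p_ws_event Probability a peripheral mutation changes the W/S
#'   class at all (otherwise a W>W or S>S transversion is drawn).
#' @param diagnostics Named list (by derived group) of lists with `count`,
#'   optional `spacing` (intervening nucleotides between the first two
#'   sites), `from`, `to` (forced bases, e.g. "T" > "C"), `synonymous`
#'   (must currently be TRUE).
#' @param hotspots Named list (by group) of two-column matrices of 0-based
#'   column ranges with elevated mutation rate.
#' @param hotspot_weight Relative sampling weight of hotspot sites.
#' @param frame_offset,ref_offset,code_table Passed to [hap_alignment()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       gene_length = 1140L,
                       groups = tibble::tibble(
                         name = c("BGa", "BGp", "SG"),
                         central_freq = c(40L, 30L, 20L),
                         n_peripheral = c(12L, 10L, 15L),
                         lambda = c(2, 2, 2),
                         beta = c(0.8, 0.55, 0.2)
                       ),
                       p_ws_event = 0.9,
                       diagnostics = list(
                         BGp = list(count = 2L, spacing = 4L,
                                    from = "T", to = "C", synonymous = TRUE),
                         SG = list(count = 4L, synonymous = TRUE)
                       ),
                       hotspots = NULL,
                       hotspot_weight = 25,
                       frame_offset = 0L,
                       ref_offset = 15380L,
                       code_table = "2") {
  if (gene_length %% 3 != 0) stop("`gene_length` must be divisible by 3")
  if (any(groups$beta < 0 | groups$beta > 1)) stop("`beta` must be in [0,1]")
  if (!is.null(hotspots)) {
    for (h in hotspots) {
      if (any(h < 0) || any(h >= gene_length)) stop("hotspot ranges outside the gene")
    }
  }
  structure(
    list(seed = as.integer(seed), gene_length = as.integer(gene_length),
         groups = groups, p_ws_event = p_ws_event, diagnostics = diagnostics,
         hotspots = hotspots, hotspot_weight = hotspot_weight,
         frame_offset = as.integer(frame_offset),
         ref_offset = as.integer(ref_offset), code_table = code_table),
    class = "sim_config"
  )
}

# sample() that never falls into the length-1 integer trap
sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

#' Simulate a haplotype alignment with full ground truth
#'
#' Draws a random in-frame CDS without internal stops, derives each group's
#' central haplotype through the configured diagnostic substitutions,
#' radiates peripheral haplotypes from the group centrals along a star
#' genealogy (no nested structure), and applies only synonymous mutations
#' whose direction class follows the group's bias `beta`. Every mutated
#' codon is used at most once across the whole simulation, so there is no
#' homoplasy and every emitted change stays synonymous in its lineage.
#'
#' @param config A [sim_config()].
#' @return A `hap_simulation`: list with `alignment` (a [hap_alignment()]),
#'   `truth` (list: `centrals`, `mutations` tibble with per-mutation
#'   ancestral/derived alleles and class, `hotspots`, `config`).
#' @export
simulate_haplotypes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$gene_length
  n_codons <- L / 3L
  code <- genetic_code(config$code_table)
  safe_codons <- names(code)[code != "*"]

  ancestral <- sample(safe_codons, n_codons, replace = TRUE)
  groups <- config$groups
  anc_name <- groups$name[1]

  used_codons <- integer(0) # 1-based codon indices no further mutation may touch
  centrals <- list()
  mut_rows <- list()

  # --- diagnostic substitutions defining the derived group centrals -----
  # placement may rewrite ancestral codons (e.g. install a Leu TTA) before
  # any central is derived, so run all placements first
  site_sets <- list()
  for (g in intersect(groups$name, names(config$diagnostics))) {
    if (g == anc_name) next
    res <- place_diagnostics(ancestral, config$diagnostics[[g]], used_codons, code)
    ancestral <- res$seqc
    site_sets[[g]] <- res$sites
    used_codons <- c(used_codons, res$sites$column %/% 3L + 1L)
  }
  for (g in groups$name) {
    if (g == anc_name || is.null(site_sets[[g]])) {
      centrals[[g]] <- ancestral
      next
    }
    seqc <- ancestral
    sites <- site_sets[[g]]
    for (r in seq_len(nrow(sites))) {
      col <- sites$column[r]
      cdn <- col %/% 3L + 1L
      pos <- col %% 3L + 1L
      stopifnot(substr(seqc[cdn], pos, pos) == sites$from[r])
      new <- seqc[cdn]
      substr(new, pos, pos) <- sites$to[r]
      stopifnot(code[[new]] == code[[seqc[cdn]]], code[[new]] != "*")
      seqc[cdn] <- new
      mut_rows[[length(mut_rows) + 1L]] <- tibble::tibble(
        group = g, haplotype = paste0(g, "_c"), column = col,
        from_base = sites$from[r], to_base = sites$to[r],
        ws_class = ws_direction(sites$from[r], sites$to[r]),
        synonymous = TRUE, diagnostic = TRUE, hotspot = FALSE
      )
    }
    centrals[[g]] <- seqc
  }

  # --- peripheral haplotypes ------------------------------------------
  ids <- character(0); seqs <- character(0); grp <- character(0); freq <- integer(0)
  for (gi in seq_len(nrow(groups))) {
    g <- groups$name[gi]
    central <- centrals[[g]]
    ids <- c(ids, paste0(g, "_c"))
    seqs <- c(seqs, paste(central, collapse = ""))
    grp <- c(grp, g)
    freq <- c(freq, groups$central_freq[gi])
    np <- groups$n_peripheral[gi]
    if (np < 1) next
    cand <- candidate_changes(central, code, config$hotspots[[g]],
                              config$hotspot_weight)
    for (p in seq_len(np)) {
      hap <- central
      hap_id <- sprintf("%s_p%02d", g, p)
      n_mut <- max(1L, stats::rpois(1L, groups$lambda[gi]))
      for (m in seq_len(n_mut)) {
        is_ws <- stats::runif(1) < config$p_ws_event
        cls <- if (!is_ws) {
          sample1(c("W>W", "S>S"))
        } else if (stats::runif(1) < groups$beta[gi]) "W>S" else "S>W"
        avail <- which(cand$cls == cls & !(cand$codon %in% used_codons))
        if (!length(avail)) next # no admissible site left for this class
        i <- avail[sample.int(length(avail), 1L, prob = cand$weight[avail])]
        pick <- cand[i, ]
        cdn <- pick$codon
        new <- hap[cdn]
        substr(new, pick$column %% 3L + 1L, pick$column %% 3L + 1L) <- pick$to
        hap[cdn] <- new
        used_codons <- c(used_codons, cdn)
        mut_rows[[length(mut_rows) + 1L]] <- tibble::tibble(
          group = g, haplotype = hap_id, column = pick$column,
          from_base = pick$from, to_base = pick$to,
          ws_class = ws_direction(pick$from, pick$to),
          synonymous = TRUE, diagnostic = FALSE, hotspot = pick$hotspot
        )
      }
      ids <- c(ids, hap_id)
      seqs <- c(seqs, paste(hap, collapse = ""))
      grp <- c(grp, g)
      freq <- c(freq, 1L)
    }
  }

  aln <- hap_alignment(ids, seqs, grp, freq,
                       frame_offset = config$frame_offset,
                       ref_offset = config$ref_offset,
                       code_table = config$code_table)
  truth <- list(
    centrals = stats::setNames(paste0(groups$name, "_c"), groups$name),
    ancestral_group = anc_name,
    mutations = dplyr::bind_rows(mut_rows),
    hotspots = config$hotspots,
    config = config
  )
  structure(list(alignment = aln, truth = truth), class = "hap_simulation")
}

#' @export
print.hap_simulation <- function(x, ...) {
  cat("<hap_simulation> seed", x$truth$config$seed, "\n")
  print(x$alignment)
  cat("  ", nrow(x$truth$mutations), " true mutations\n", sep = "")
  invisible(x)
}

# Choose columns for the forced diagnostic substitutions. Returns
# list(seqc = possibly rewritten ancestral, sites = tibble(column, from,
# to)). A `spacing` request (intervening nt between the two sites) is
# honoured by combining third-position T sites with the Leu TTA/CTA
# first-position pair, whichever the reading-frame phase demands; the
# ancestral background is rewritten at the chosen codons so the forced
# T>C change is synonymous at both sites.
place_diagnostics <- function(seqc, dg, used_codons, code) {
  count <- dg$count
  n_codons <- length(seqc)
  free <- setdiff(seq(2L, n_codons - 1L), used_codons)

  if (!is.null(dg$spacing) && count >= 2L) {
    from <- dg$from %||% "T"
    to <- dg$to %||% "C"
    if (!identical(from, "T") || !identical(to, "C")) {
      stop("spaced diagnostics currently support only the T>C pair")
    }
    gap <- dg$spacing + 1L # column difference between the two sites
    phase <- gap %% 3L
    if (phase == 0L) {
      step <- gap %/% 3L
      kinds <- c("third", "third")
      codon2 <- function(k) k + step
    } else if (phase == 2L) {
      # pos1 of codon k (TTA) and pos3 of codon k + step
      step <- (gap - 2L) %/% 3L
      if (step < 1L) stop("spacing too small for a synonymous T>C pair in this frame")
      kinds <- c("tta", "third")
      codon2 <- function(k) k + step
    } else {
      step <- (gap - 1L) %/% 3L + 1L
      kinds <- c("third", "tta")
      codon2 <- function(k) k + step
    }
    cand <- free[codon2(free) %in% free]
    if (!length(cand)) stop("no admissible placement for spaced diagnostics")
    k <- sample1(cand)
    codons <- c(k, codon2(k))
    cols <- integer(2)
    for (i in 1:2) {
      if (kinds[i] == "tta") {
        seqc[codons[i]] <- "TTA"
        cols[i] <- (codons[i] - 1L) * 3L
      } else {
        seqc <- force_codon_third_T(seqc, codons[i], code)
        cols[i] <- (codons[i] - 1L) * 3L + 2L
      }
    }
    stopifnot(diff(sort(cols)) == gap)
    sites <- tibble::tibble(column = sort(cols), from = from, to = to)
    if (count > 2L) {
      extra <- place_diagnostics(
        seqc, list(count = count - 2L, from = dg$from, to = dg$to),
        c(used_codons, codons), code
      )
      seqc <- extra$seqc
      sites <- dplyr::bind_rows(sites, extra$sites)
    }
    return(list(seqc = seqc, sites = sites))
  }

  # unconstrained synonymous diagnostics at distinct codons
  cols <- integer(0); froms <- character(0); tos <- character(0)
  for (i in seq_len(count)) {
    pick <- NULL
    avail <- setdiff(free, cols %/% 3L + 1L)
    for (cdn in sample(avail)) {
      ch <- synonymous_changes(seqc[cdn], code, from = dg$from, to = dg$to)
      if (nrow(ch)) {
        r <- ch[sample.int(nrow(ch), 1L), ]
        pick <- list(column = (cdn - 1L) * 3L + r$pos - 1L,
                     from = r$from, to = r$to)
        break
      }
    }
    if (is.null(pick)) stop("no admissible site for diagnostic substitution")
    cols <- c(cols, pick$column)
    froms <- c(froms, pick$from)
    tos <- c(tos, pick$to)
  }
  list(seqc = seqc, sites = tibble::tibble(column = cols, from = froms, to = tos))
}

# all synonymous single-base changes within one codon
synonymous_changes <- function(codon, code, from = NULL, to = NULL) {
  aa <- code[[codon]]
  rows <- list()
  for (pos in 1:3) {
    b <- substr(codon, pos, pos)
    if (!is.null(from) && b != from) next
    for (nb in setdiff(c("A", "C", "G", "T"), b)) {
      if (!is.null(to) && nb != to) next
      alt <- codon
      substr(alt, pos, pos) <- nb
      if (code[[alt]] == aa && code[[alt]] != "*") {
        rows[[length(rows) + 1L]] <- tibble::tibble(pos = pos, from = b, to = nb)
      }
    }
  }
  if (!length(rows)) return(tibble::tibble(pos = integer(), from = character(), to = character()))
  dplyr::bind_rows(rows)
}

# table of every synonymous single-base change on `seqc`: codon index,
# 0-based column, from/to, W/S class, hotspot flag and sampling weight
candidate_changes <- function(seqc, code, hotspot_ranges = NULL,
                              hotspot_weight = 1) {
  cache <- syn_cache(code)
  per_codon <- cache[seqc]
  nch <- vapply(per_codon, nrow, integer(1))
  ch <- dplyr::bind_rows(per_codon)
  ch$codon <- rep(seq_along(seqc), nch)
  ch$column <- (ch$codon - 1L) * 3L + ch$pos - 1L
  ch$cls <- ws_direction(ch$from, ch$to)
  ch$hotspot <- FALSE
  ch$weight <- 1
  if (!is.null(hotspot_ranges)) {
    for (r in seq_len(nrow(hotspot_ranges))) {
      ch$hotspot <- ch$hotspot |
        (ch$column >= hotspot_ranges[r, 1] & ch$column <= hotspot_ranges[r, 2])
    }
    ch$weight[ch$hotspot] <- hotspot_weight
  }
  ch
}

# memoised per-codon synonymous change tables for a genetic code
.syn_cache_env <- new.env(parent = emptyenv())
syn_cache <- function(code) {
  key <- paste(code, collapse = "")
  if (is.null(.syn_cache_env[[key]])) {
    .syn_cache_env[[key]] <- lapply(
      stats::setNames(names(code), names(code)),
      function(cdn) synonymous_changes(cdn, code)
    )
  }
  .syn_cache_env[[key]]
}

# rewrite codon k so its third base is T (preserving the amino acid when
# possible, otherwise substituting a random ..T codon whose T>C change is
# synonymous); used when a spaced T>C diagnostic needs a third-position T
force_codon_third_T <- function(seqc, k, code) {
  cdn <- seqc[k]
  if (substr(cdn, 3, 3) == "T") return(seqc)
  alt <- cdn
  substr(alt, 3, 3) <- "T"
  if (code[[alt]] != "*" && code[[alt]] == code[[cdn]]) {
    seqc[k] <- alt
  } else {
    nnt <- names(code)[endsWith(names(code), "T") & code != "*"]
    seqc[k] <- sample1(nnt)
  }
  seqc
}

#' Write a simulation to the pipeline's input formats
#'
#' Emits the FASTA alignment, the TSV metadata and a JSON ground-truth
#' file.
#'
#' @param sim A [simulate_haplotypes()] result.
#' @param dir Output directory (created if needed).
#' @return The paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "haplotypes.fasta")
  meta <- file.path(dir, "haplotypes.tsv")
  truth <- file.path(dir, "truth.json")
  write_alignment(sim$alignment, fasta, meta)
  jsonlite::write_json(
    list(centrals = as.list(sim$truth$centrals),
         ancestral_group = sim$truth$ancestral_group,
         seed = sim$truth$config$seed,
         mutations = sim$truth$mutations),
    truth, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(c(fasta = fasta, meta = meta, truth = truth))
}
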