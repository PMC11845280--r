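# Seeded generators for fully synthetic benchmark scenarios: a random
# (Erdos-Renyi) reference PPIN, domain architectures with partial
# annotation coverage, a DDI library backing a controllable fraction of
# edges, and two-group transcript-level expression matrices with planted
# expression losses/gains and isoform switches plus background
# feature-level noise.

PLANT_MECHANISMS <- c("expression-loss", "expression-gain", "isoform-switch")

#' Specify a synthetic benchmark scenario
#'
#' Planted alterations are realized as dedicated degree-1 protein pairs
#' appended to the reference network, each driven by exactly one
#' transcriptomic mechanism, so the planted differential signal maps
#' one-to-one onto edges and reasons. Background noise switches whole
#' genes off per sample, propagating to the networks through
#' contextualization.
#'
#' @param n_proteins Number of background proteins (default 200).
#' @param edge_density Erdos-Renyi edge probability over background protein
#'   pairs (default 0.02).
#' @param backed_fraction Fraction of background edges given a documented
#'   DDI-library family pair (default 0.8); the rest fall back to dummy
#'   backing.
#' @param max_isoforms Isoforms per background protein are drawn uniformly
#'   from `1:max_isoforms` (default 3).
#' @param n_group_a,n_group_b Samples per group (default 3 and 3).
#' @param planted Either an integer (mechanisms cycled over
#'   expression-loss, expression-gain, isoform-switch) or a character
#'   vector of mechanisms, one planted edge each (default 0).
#' @param flip_rate Per-gene, per-sample probability of switching a
#'   background gene's expression off (default 0.02).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of
#'   baseline abundances (defaults `log(50)` and 0.5, comfortably above the
#'   default expression threshold of 1).
#' @param threshold Expression threshold the scenario is built against
#'   (default 1).
#' @param seed RNG seed; a fixed seed makes the scenario byte-identical.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_proteins = 200, edge_density = 0.02,
                          backed_fraction = 0.8, max_isoforms = 3,
                          n_group_a = 3, n_group_b = 3, planted = 0,
                          flip_rate = 0.02, expression_meanlog = log(50),
                          expression_sdlog = 0.5, threshold = 1, seed = 1) {
  if (is.numeric(planted) && length(planted) == 1L) {
    planted <- rep_len(PLANT_MECHANISMS, planted)
  }
  planted <- as.character(planted)
  if (!all(planted %in% PLANT_MECHANISMS)) {
    stop("planted mechanisms must be among: ",
         paste(PLANT_MECHANISMS, collapse = ", "), call. = FALSE)
  }
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must be in (0, 1]", call. = FALSE)
  }
  if (flip_rate < 0 || flip_rate >= 1) {
    stop("flip_rate must be in [0, 1)", call. = FALSE)
  }
  if (n_proteins < 2) stop("need at least 2 proteins", call. = FALSE)
  structure(
    list(n_proteins = n_proteins, edge_density = edge_density,
         backed_fraction = backed_fraction, max_isoforms = max_isoforms,
         n_group_a = n_group_a, n_group_b = n_group_b, planted = planted,
         flip_rate = flip_rate, expression_meanlog = expression_meanlog,
         expression_sdlog = expression_sdlog, threshold = threshold,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Generate a synthetic scenario
#'
#' Produces every input the workflow consumes, with ground truth: the
#' reference PPIN, the domain annotation, the DDI library, one
#' transcript-level expression table per sample (groups `A1..An`,
#' `B1..Bm`), and the planted alterations with their causing mechanism.
#'
#' @param spec A [scenario_spec].
#' @param outdir Optional directory; when given, all inputs are also
#'   written as tab-separated files (`reference_ppin.txt`,
#'   `annotation.txt`, `ddi_library.txt`, `<sample>_expr.txt`,
#'   `ground_truth.txt`).
#' @return A list of class `scenario`: `ppin`, `annotation`, `ddi`,
#'   `expression` (named list of [expression_table]s), `groups` (named
#'   list of sample-name vectors), `ground_truth` (data.frame `from`,
#'   `to`, `direction`, `mechanism`, `protein`), and `spec`.
#' @export
generate_scenario <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  n_planted <- length(spec$planted)
  if (n_planted > n) {
    stop("more planted edges than background proteins", call. = FALSE)
  }
  proteins <- sprintf("P%04d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(n))

  # Erdos-Renyi background edges.
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- stats::runif(nrow(idx)) < spec$edge_density
  ef <- proteins[idx[pick, 1L]]
  et <- proteins[idx[pick, 2L]]

  fam_of <- stats::setNames(vector("list", n), proteins)
  lib_a <- character()
  lib_b <- character()
  fam_counter <- 0L
  new_family <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("PF%05d", fam_counter)
  }
  backed <- stats::runif(length(ef)) < spec$backed_fraction
  for (i in which(backed)) {
    fu <- new_family()
    fv <- new_family()
    fam_of[[ef[i]]] <- c(fam_of[[ef[i]]], fu)
    fam_of[[et[i]]] <- c(fam_of[[et[i]]], fv)
    lib_a <- c(lib_a, fu)
    lib_b <- c(lib_b, fv)
  }
  # Decoy families (annotated but never interacting) for half the proteins
  # left without any library-backed family: partial annotation coverage.
  bare <- proteins[lengths(fam_of) == 0L]
  decoy <- bare[stats::runif(length(bare)) < 0.5]
  for (p in decoy) fam_of[[p]] <- new_family()

  # Planted degree-1 pairs, each backed by a dedicated family pair.
  plant <- data.frame(u = character(), v = character(),
                      mechanism = character(), fam_u = character(),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n_planted)) {
    u <- sprintf("U%03d", k)
    v <- sprintf("V%03d", k)
    fu <- new_family()
    fv <- new_family()
    fam_of[[u]] <- fu
    fam_of[[v]] <- fv
    lib_a <- c(lib_a, fu)
    lib_b <- c(lib_b, fv)
    ef <- c(ef, u)
    et <- c(et, v)
    plant <- rbind(plant, data.frame(u = u, v = v,
                                     mechanism = spec$planted[k],
                                     fam_u = fu, stringsAsFactors = FALSE))
  }
  all_proteins <- names(fam_of)
  gene_of <- stats::setNames(
    c(genes, sub("^U", "GU", plant$u), sub("^V", "GV", plant$v))[
      match(all_proteins, c(proteins, plant$u, plant$v))],
    all_proteins
  )
  ppin <- ppi_network(ef, et, level = "protein")

  # Isoform architectures: canonical isoform carries every family; extra
  # isoforms carry a random subset. Planted isoform-switch proteins get a
  # dedicated second isoform lacking the backing family.
  ann_rows <- list()
  tx_of <- stats::setNames(vector("list", length(all_proteins)), all_proteins)
  for (p in all_proteins) {
    fams <- as.character(fam_of[[p]])
    is_switch_u <- p %in% plant$u[plant$mechanism == "isoform-switch"]
    k_iso <- if (is_switch_u) 2L else sample.int(spec$max_isoforms, 1L)
    iso <- sprintf("%s.T%d", p, seq_len(k_iso))
    doms <- vector("list", k_iso)
    doms[[1L]] <- fams
    if (k_iso > 1L) {
      for (j in 2L:k_iso) {
        if (is_switch_u) {
          doms[[j]] <- setdiff(fams, plant$fam_u[plant$u == p])
        } else {
          doms[[j]] <- fams[stats::runif(length(fams)) < 0.5]
        }
      }
    }
    ann_rows[[p]] <- data.frame(protein = p, gene = gene_of[[p]],
                                isoform = iso,
                                canonical = seq_len(k_iso) == 1L,
                                stringsAsFactors = FALSE)
    ann_rows[[p]]$domains <- doms
    tx_of[[p]] <- iso
  }
  ann_df <- do.call(rbind, ann_rows)
  annotation <- domain_annotation(ann_df$protein, ann_df$gene,
                                  ann_df$isoform, ann_df$domains,
                                  ann_df$canonical)
  ddi <- ddi_library(lib_a, lib_b)

  # Baseline abundances: canonical isoform log-normal above threshold,
  # minor isoforms a sub-dominant multiple of it.
  base_ab <- stats::setNames(
    spec$threshold +
      stats::rlnorm(length(all_proteins), spec$expression_meanlog,
                    spec$expression_sdlog),
    all_proteins
  )
  minor_frac <- lapply(tx_of, function(iso) {
    if (length(iso) > 1L) stats::runif(length(iso) - 1L, 0.05, 0.5) else numeric()
  })
  tx_lengths <- stats::setNames(
    sample(500:5000, length(unlist(tx_of)), replace = TRUE),
    unlist(tx_of)
  )

  sampleA <- sprintf("A%d", seq_len(spec$n_group_a))
  sampleB <- sprintf("B%d", seq_len(spec$n_group_b))
  planted_set <- plant$u
  background <- setdiff(all_proteins, c(plant$u, plant$v))
  tx2gene <- stats::setNames(
    rep(gene_of[all_proteins], lengths(tx_of)), unlist(tx_of)
  )

  make_sample <- function(group) {
    on <- stats::setNames(rep(TRUE, length(all_proteins)), all_proteins)
    flips <- stats::runif(length(background)) < spec$flip_rate
    on[background[flips]] <- FALSE
    ab <- numeric()
    for (p in all_proteins) {
      iso <- tx_of[[p]]
      vals <- numeric(length(iso))
      mech <- plant$mechanism[match(p, plant$u)]
      if (!is.na(mech) && mech == "expression-loss" && group == "B") {
        # stays zero
      } else if (!is.na(mech) && mech == "expression-gain" && group == "A") {
        # stays zero
      } else if (!is.na(mech) && mech == "isoform-switch") {
        if (group == "A") {
          vals <- c(base_ab[[p]], 0.3 * base_ab[[p]])
        } else {
          vals <- c(0.3 * base_ab[[p]], base_ab[[p]])
        }
      } else if (on[[p]]) {
        vals[1L] <- base_ab[[p]]
        if (length(iso) > 1L) {
          vals[-1L] <- base_ab[[p]] * minor_frac[[p]]
        }
      }
      ab[iso] <- vals
    }
    expression_table("transcript", ab, tx2gene = tx2gene,
                     lengths = tx_lengths)
  }
  expression <- c(
    stats::setNames(lapply(sampleA, function(s) make_sample("A")), sampleA),
    stats::setNames(lapply(sampleB, function(s) make_sample("B")), sampleB)
  )

  gt <- data.frame(from = character(), to = character(),
                   direction = character(), mechanism = character(),
                   protein = character(), stringsAsFactors = FALSE)
  if (n_planted) {
    ce <- canonicalize_pairs(plant$u, plant$v)
    gt <- data.frame(
      from = ce$from, to = ce$to,
      direction = ifelse(plant$mechanism == "expression-gain",
                         "gained", "lost"),
      mechanism = plant$mechanism, protein = plant$u,
      stringsAsFactors = FALSE
    )
  }
  scen <- structure(
    list(ppin = ppin, annotation = annotation, ddi = ddi,
         expression = expression,
         groups = list(A = sampleA, B = sampleB),
         ground_truth = gt, spec = spec),
    class = "scenario"
  )
  if (!is.null(outdir)) write_scenario(scen, outdir)
  scen
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic scenario: %d proteins, %d PPIs, %d+%d samples, %d planted alterations>\n",
    length(x$ppin$nodes), n_edges(x$ppin), length(x$groups$A),
    length(x$groups$B), nrow(x$ground_truth)
  ))
  invisible(x)
}

#' Write a scenario's input files
#'
#' @param scen A `scenario` from [generate_scenario].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_scenario <- function(scen, outdir) {
  stopifnot(inherits(scen, "scenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_ppin(scen$ppin, file.path(outdir, "reference_ppin.txt"))
  write_domain_annotation(scen$annotation, file.path(outdir, "annotation.txt"))
  write_ddi_library(scen$ddi, file.path(outdir, "ddi_library.txt"))
  for (s in names(scen$expression)) {
    write_expression(scen$expression[[s]],
                     file.path(outdir, paste0(s, "_expr.txt")))
  }
  gt <- scen$ground_truth
  write_lines_to(
    paste(gt$from, gt$to, gt$direction, gt$mechanism, gt$protein, sep = "\t"),
    file.path(outdir, "ground_truth.txt")
  )
  invisible(outdir)
}

#' Run the full workflow on a scenario
#'
#' Builds the reference DDIN once, contextualizes every sample, computes
#' the differential network between the two groups, and attributes reasons.
#'
#' @param scen A `scenario`.
#' @param opts [context_options] (default: transcript-preferred mode at the
#'   scenario's threshold).
#' @param fdr FDR threshold for significant rewiring (default 0.05).
#' @param reasons Attribute reasons for the significant alterations
#'   (default `TRUE`).
#' @inheritParams pairwise_rewiring_probability
#' @return A list with `reference` (the reference DDIN), `contexts`,
#'   `groupA`, `groupB`, `diff` (a [differential_network]) and `reasons`
#'   (a `cover_solution` or `NULL`).
#' @export
run_scenario <- function(scen, opts = NULL, fdr = 0.05, reasons = TRUE,
                         denominator = c("pair", "global")) {
  stopifnot(inherits(scen, "scenario"))
  denominator <- match.arg(denominator)
  if (is.null(opts)) {
    opts <- context_options(threshold = scen$spec$threshold,
                            mode = "transcript")
  }
  ref <- build_reference_ddin(scen$ppin, scen$annotation, scen$ddi)
  contexts <- lapply(scen$expression, function(expr) {
    contextualize_sample(scen$ppin, ref, scen$annotation, expr, opts)
  })
  mk_group <- function(label, samples) {
    sample_group(label,
                 networks = lapply(contexts[samples], `[[`, "ppin"),
                 majors = lapply(contexts[samples], `[[`, "major"))
  }
  groupA <- mk_group("A", scen$groups$A)
  groupB <- mk_group("B", scen$groups$B)
  diff <- differential_network(groupA, groupB, fdr = fdr,
                               denominator = denominator)
  sol <- if (reasons && nrow(diff$significant)) {
    attribute_reasons(diff, groupA, groupB)
  } else NULL
  list(reference = ref, contexts = contexts, groupA = groupA,
       groupB = groupB, diff = diff, reasons = sol)
}

#' Compare a differential network against planted ground truth
#'
#' @param diff A [differential_network].
#' @param scen The `scenario` whose ground truth to compare against.
#' @param reasons Optional `cover_solution` for reason-level recovery.
#' @return A list with edge-level `precision` and `recall` (direction must
#'   match too) and, when `reasons` is given, `reason_recall` (fraction of
#'   planted mechanisms among the selected reasons).
#' @export
evaluate_recovery <- function(diff, scen, reasons = NULL) {
  stopifnot(inherits(diff, "differential_network"),
            inherits(scen, "scenario"))
  gt <- scen$ground_truth
  truth <- paste(gt$from, gt$to, gt$direction)
  found <- paste(diff$significant$from, diff$significant$to,
                 diff$significant$direction)
  tp <- sum(found %in% truth)
  out <- list(
    precision = if (length(found)) tp / length(found) else 1,
    recall = if (length(truth)) tp / length(truth) else 1,
    n_found = length(found), n_truth = length(truth)
  )
  if (!is.null(reasons)) {
    planted_reasons <- reason_id(gt$protein, gt$mechanism)
    out$reason_recall <- if (length(planted_reasons)) {
      mean(planted_reasons %in% reasons$selected$id)
    } else 1
  }
  out
}
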