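# File-level pipeline runners: contextualize expression files against a
# reference network (writing the per-sample *_ppin/*_ddin/
# *_major_transcripts triplets), and compare two groups of contextualized
# samples (writing the differential network, reasons and attribute table).

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(...)))
}

sample_name_from_path <- function(path) {
  base <- basename(path)
  base <- sub("\\.gz$", "", base)
  base <- sub("\\.(txt|tsv)$", "", base)
  sub("_expr$", "", base)
}

#' Contextualize expression files against a reference network
#'
#' For each expression file, selects major features, prunes the reference
#' DDIN and writes the sample triplet `<sample>_ppin.txt[.gz]`,
#' `<sample>_ddin.txt[.gz]`, `<sample>_major_transcripts.txt[.gz]` into
#' `outdir` (sample names derive from the file names).
#'
#' @param ppin_path Reference PPIN edge list.
#' @param annotation_path Protein domain annotation table.
#' @param ddi_path DDI library table.
#' @param expr_paths Character vector of expression files (one per sample).
#' @param level Expression table level, `"transcript"` or `"gene"`.
#' @param threshold Expression threshold (default 1).
#' @param mode Contextualization mode, see [context_options]; defaults to
#'   `level`.
#' @param normalize_length Length-normalize transcript abundances first.
#' @param outdir Output directory (created if absent).
#' @param gz Gzip the outputs (default `TRUE`).
#' @return Invisibly, a data.frame of per-sample output paths and
#'   before/after network sizes.
#' @export
run_ppixpress <- function(ppin_path, annotation_path, ddi_path, expr_paths,
                          level = c("transcript", "gene"), threshold = 1,
                          mode = NULL, normalize_length = FALSE,
                          outdir = ".", gz = TRUE) {
  level <- match.arg(level)
  if (is.null(mode)) mode <- level
  opts <- context_options(threshold = threshold, mode = mode,
                          normalize_length = normalize_length)
  ppin <- read_ppin(ppin_path)
  annotation <- read_domain_annotation(annotation_path)
  ddi <- read_ddi_library(ddi_path)
  log_msg("ppixpress", "reference PPIN: %d nodes, %d edges",
          length(ppin$nodes), n_edges(ppin))
  ref <- build_reference_ddin(ppin, annotation, ddi)
  log_msg("ppixpress", "reference DDIN: %d nodes, %d edges",
          length(ref$ddin$nodes), n_edges(ref$ddin))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  suffix <- if (gz) ".txt.gz" else ".txt"
  rows <- lapply(expr_paths, function(path) {
    s <- sample_name_from_path(path)
    expr <- read_expression(path, level = level)
    ctx <- contextualize_sample(ppin, ref, annotation, expr, opts)
    ppin_out <- file.path(outdir, paste0(s, "_ppin", suffix))
    ddin_out <- file.path(outdir, paste0(s, "_ddin", suffix))
    major_out <- file.path(outdir, paste0(s, "_major_transcripts", suffix))
    write_ppin(ctx$ppin, ppin_out)
    write_ddin(ctx$ddin, ddin_out)
    write_major_transcripts(ctx$major, major_out)
    log_msg("ppixpress",
            "sample %s: %d/%d PPIs, %d/%d DDIs retained (threshold %g, %s mode)",
            s, n_edges(ctx$ppin), n_edges(ppin), n_edges(ctx$ddin),
            n_edges(ref$ddin), opts$threshold, opts$mode)
    data.frame(sample = s, ppin = ppin_out, ddin = ddin_out,
               major_transcripts = major_out,
               edges_reference = n_edges(ppin),
               edges_retained = n_edges(ctx$ppin),
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}

#' Load a group of contextualized samples from files
#'
#' Accepts either a directory containing per-sample triplets or an explicit
#' vector of `*_ppin.txt(.gz)` paths; the matching
#' `*_major_transcripts.txt(.gz)` files are picked up alongside when
#' present.
#'
#' @param paths A directory or a character vector of PPIN file paths.
#' @param label Group label.
#' @return A [sample_group].
#' @export
load_sample_group <- function(paths, label) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "_ppin\\.txt(\\.gz)?$",
                             full.names = TRUE))
  }
  if (!length(paths)) {
    stop("no *_ppin.txt(.gz) files found for group '", label, "'",
         call. = FALSE)
  }
  samples <- sub("_ppin\\.txt(\\.gz)?$", "", basename(paths))
  networks <- stats::setNames(lapply(paths, read_ppin), samples)
  major_paths <- sub("_ppin\\.txt", "_major_transcripts.txt", paths)
  majors <- NULL
  if (all(file.exists(major_paths))) {
    majors <- stats::setNames(lapply(major_paths, read_major_transcripts),
                              samples)
  }
  sample_group(label, networks, majors)
}

#' Compare two groups of contextualized networks
#'
#' Runs the rewiring statistics between two sample groups and writes
#' `differential_network.txt` (edge, direction, support, p, q); optionally
#' `reasons.txt` (the greedy set-cover attribution) and
#' `attribute_table.txt` (per-protein alteration summary).
#'
#' @param group1,group2 Directory or PPIN file paths per group (see
#'   [load_sample_group]).
#' @param fdr FDR threshold (default 0.05).
#' @param outdir Output directory.
#' @param reasons Write the reason attribution (default `TRUE`; needs
#'   major-transcript files).
#' @param attribute_table Also write the per-protein summary (default
#'   `FALSE`).
#' @inheritParams pairwise_rewiring_probability
#' @return Invisibly, a list with the [differential_network] and the
#'   `cover_solution` (or `NULL`).
#' @export
run_ppicompare <- function(group1, group2, fdr = 0.05, outdir = ".",
                           reasons = TRUE, attribute_table = FALSE,
                           denominator = c("pair", "global")) {
  denominator <- match.arg(denominator)
  groupA <- load_sample_group(group1, "group1")
  groupB <- load_sample_group(group2, "group2")
  log_msg("ppicompare", "groups: %d vs %d samples",
          length(groupA$networks), length(groupB$networks))
  diff <- differential_network(groupA, groupB, fdr = fdr,
                               denominator = denominator)
  log_msg("ppicompare",
          "P_rewired = %.4g over N = %d pairs; %d/%d alterations significant at FDR %g",
          diff$null$p_rewired, diff$null$n_pairs, nrow(diff$significant),
          nrow(diff$alterations), fdr)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  alt <- diff$alterations
  write_lines_to(
    c("protein1\tprotein2\tdirection\tsupport\tp_value\tq_value\tsignificant",
      paste(alt$from, alt$to, alt$direction, alt$support,
            fmt_num(alt$p), fmt_num(alt$q),
            as.integer(alt$significant), sep = "\t")),
    file.path(outdir, "differential_network.txt")
  )
  sol <- NULL
  if (reasons) {
    if (is.null(groupA$majors) || is.null(groupB$majors)) {
      stop("reason attribution needs *_major_transcripts files next to ",
           "every *_ppin file (or pass reasons = FALSE)", call. = FALSE)
    }
    sol <- attribute_reasons(diff, groupA, groupB)
    sel <- sol$selected
    write_lines_to(
      c("reason\tkind\tr_w\tp_w\ts\tw\trank\tcovered_edges",
        if (nrow(sel)) {
          paste(sel$protein, sel$kind, sel$r_w, sel$p_w,
                fmt_num(sel$s), fmt_num(sel$w), sel$rank,
                vapply(sel$covered_edges, paste, "", collapse = ","),
                sep = "\t")
        }),
      file.path(outdir, "reasons.txt")
    )
    log_msg("ppicompare", "%d reasons cover %.1f%% of alteration instances",
            nrow(sel), 100 * sol$covered_fraction)
  }
  if (attribute_table) {
    prot <- sort(unique(c(alt$from, alt$to)))
    sig <- diff$significant
    n_lost <- vapply(prot, function(p) {
      sum((sig$from == p | sig$to == p) & sig$direction == "lost")
    }, 0L)
    n_gained <- vapply(prot, function(p) {
      sum((sig$from == p | sig$to == p) & sig$direction == "gained")
    }, 0L)
    keep <- n_lost + n_gained > 0
    write_lines_to(
      c("protein\tn_lost\tn_gained",
        paste(prot[keep], n_lost[keep], n_gained[keep], sep = "\t")),
      file.path(outdir, "attribute_table.txt")
    )
  }
  invisible(list(diff = diff, reasons = sol))
}

#' Generate a synthetic scenario from the command line
#'
#' @param spec_json Optional path to a JSON file of [scenario_spec]
#'   arguments.
#' @param seed RNG seed (overrides the spec file's seed).
#' @param outdir Output directory.
#' @return Invisibly, the generated `scenario`.
#' @export
run_simulate <- function(spec_json = NULL, seed = 1, outdir = ".") {
  args <- list()
  if (!is.null(spec_json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading a JSON spec requires the jsonlite package", call. = FALSE)
    }
    args <- jsonlite::fromJSON(spec_json, simplifyVector = TRUE)
  }
  args$seed <- seed
  spec <- do.call(scenario_spec, args)
  scen <- generate_scenario(spec, outdir = outdir)
  log_msg("simulate",
          "wrote %d-protein scenario (%d PPIs, %d planted) to %s",
          length(scen$ppin$nodes), n_edges(scen$ppin),
          nrow(scen$ground_truth), outdir)
  invisible(scen)
}
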