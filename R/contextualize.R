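# Network contextualization: translate the reference PPIN into a reference
# domain-domain interaction network (DDIN) using domain annotations and a
# DDI library, then prune it per sample to the interactions supported by
# each protein's major (most abundant) feature, and map back to a
# condition-specific PPIN. A PPI survives iff at least one of its backing
# domain edges survives.

domain_id <- function(protein, family, occurrence) {
  paste(protein, family, occurrence, sep = "|")
}

#' Contextualization options
#'
#' @param threshold Expression threshold: a gene or transcript is considered
#'   expressed when its abundance is strictly greater than this value
#'   (default 1, TPM/FPKM scale).
#' @param mode `"transcript"` (transcript-preferred: the most abundant
#'   annotated isoform decides the domain architecture) or `"gene"`
#'   (gene-level only: gene abundance decides expression and the canonical
#'   isoform's architecture is used).
#' @param normalize_length If `TRUE`, transcript-level abundances are
#'   divided by transcript length and rescaled to sum to 1e6 before major
#'   features are selected (FPKM-to-TPM-style normalization).
#' @return A list of class `context_options`.
#' @export
context_options <- function(threshold = 1, mode = c("transcript", "gene"),
                            normalize_length = FALSE) {
  mode <- match.arg(mode)
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0) {
    stop("threshold must be a finite non-negative number", call. = FALSE)
  }
  structure(
    list(threshold = threshold, mode = mode,
         normalize_length = isTRUE(normalize_length)),
    class = "context_options"
  )
}

#' Length-normalize transcript abundances
#'
#' Divides each transcript's abundance by its length (nucleotides) and
#' rescales so the normalized values sum to 1e6, converting
#' per-kilobase-style counts into TPM-like relative abundances. If every
#' abundance is zero the table is returned unchanged (all zeros).
#'
#' @param expr A transcript-level [expression_table] with lengths for every
#'   transcript of nonzero abundance.
#' @return A normalized [expression_table].
#' @export
length_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_table"))
  if (!identical(expr$level, "transcript")) {
    stop("length normalization applies to transcript-level tables",
         call. = FALSE)
  }
  ab <- expr$abundance
  len <- expr$lengths[names(ab)]
  need <- ab > 0
  if (any(need & (is.na(len) | is.null(len)))) {
    missing <- names(ab)[which(need & is.na(len))[1L]]
    stop("missing length for expressed transcript '", missing, "'",
         call. = FALSE)
  }
  rate <- ifelse(ab > 0, ab / len, 0)
  total <- sum(rate)
  out <- if (total > 0) rate / total * 1e6 else rate
  expression_table("transcript", stats::setNames(out, names(ab)),
                   tx2gene = expr$tx2gene, lengths = expr$lengths)
}

# Gene-level abundance vector regardless of table level.
gene_abundance <- function(expr) {
  if (expr$level == "gene") return(expr$abundance)
  tapply_sum(expr$abundance, expr$tx2gene[names(expr$abundance)])
}

# Per-protein major feature selection, vectorised over all proteins in the
# annotation. Returns a data.frame(protein, gene, feature, abundance) for
# expressed proteins only, plus a list-column `domains` with the chosen
# feature's domain families.
major_feature_map <- function(annotation, expr, opts) {
  mode <- opts$mode
  if (mode == "transcript" && expr$level == "gene") {
    # No transcript resolution available; gene abundance is all there is.
    mode <- "gene"
  }
  can <- annotation[annotation$canonical, , drop = FALSE]
  if (mode == "gene") {
    gab <- gene_abundance(expr)
    ab <- gab[can$gene]
    ab[is.na(ab)] <- 0
    keep <- ab > opts$threshold
    out <- data.frame(protein = can$protein[keep], gene = can$gene[keep],
                      feature = can$gene[keep],
                      abundance = as.numeric(ab[keep]),
                      stringsAsFactors = FALSE)
    out$domains <- can$domains[keep]
  } else {
    ab <- expr$abundance[annotation$isoform]
    ab[is.na(ab)] <- 0
    ord <- order(annotation$protein, -ab, annotation$isoform)
    first <- ord[!duplicated(annotation$protein[ord])]
    keep <- first[ab[first] > opts$threshold]
    out <- data.frame(protein = annotation$protein[keep],
                      gene = annotation$gene[keep],
                      feature = annotation$isoform[keep],
                      abundance = as.numeric(ab[keep]),
                      stringsAsFactors = FALSE)
    out$domains <- annotation$domains[keep]
  }
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the major feature of one protein
#'
#' In gene-level mode the protein's gene is chosen if its abundance exceeds
#' the threshold, paired with the canonical isoform's domain architecture;
#' in transcript-preferred mode the annotated isoform with maximal abundance
#' is chosen (ties broken lexicographically by transcript id), provided it
#' exceeds the threshold. Missing expression records count as abundance 0.
#'
#' @param expr An [expression_table].
#' @param protein Protein identifier present in `annotation`.
#' @param annotation A [domain_annotation].
#' @param opts [context_options].
#' @return A list with `feature`, `abundance`, `domains`, or `NULL` if the
#'   protein is not expressed above threshold.
#' @export
select_major_feature <- function(expr, protein, annotation,
                                 opts = context_options()) {
  stopifnot(inherits(annotation, "domain_annotation"))
  sub <- annotation[annotation$protein == protein, , drop = FALSE]
  if (!nrow(sub)) {
    stop("protein '", protein, "' absent from annotation", call. = FALSE)
  }
  m <- major_feature_map(sub, expr, opts)
  if (!nrow(m)) return(NULL)
  list(feature = m$feature[1L], abundance = m$abundance[1L],
       domains = m$domains[[1L]])
}

# Max copy number of each domain family per protein, over all isoforms.
protein_family_counts <- function(annotation) {
  lapply(split(annotation$domains, annotation$protein), function(dl) {
    counts <- integer()
    for (d in dl) {
      if (!length(d)) next
      tb <- table(d)
      fam <- names(tb)
      cur <- counts[fam]
      cur[is.na(cur)] <- 0L
      counts[fam] <- pmax(cur, as.integer(tb))
    }
    counts
  })
}

#' Build the reference domain-domain interaction network
#'
#' Maps every protein interaction of the reference PPIN onto domain-level
#' edges: for each pair of domain families (one from each endpoint, over all
#' isoforms) documented in the DDI library, edges are added between all
#' occurrence instances (`protein|family|occurrence` nodes). A PPI with no
#' documented family pair gets a single artificial edge between dummy
#' domains of its endpoints, so every reference interaction remains
#' representable at domain level.
#'
#' @param ppin Protein-level reference [ppi_network]; every node must be in
#'   the annotation.
#' @param annotation A [domain_annotation].
#' @param ddi A [ddi_library].
#' @return A list of class `reference_ddin` with `ddin` (a domain-level
#'   [ppi_network]) and `backing` (a data.frame mapping each PPI to its
#'   supporting domain edges, with columns `ppi_key`, `u`, `v`, `fam_u`,
#'   `fam_v`, `d_u`, `d_v`).
#' @export
build_reference_ddin <- function(ppin, annotation, ddi) {
  stopifnot(inherits(ppin, "ppi_network"), identical(ppin$level, "protein"),
            inherits(annotation, "domain_annotation"),
            inherits(ddi, "ddi_library"))
  missing <- setdiff(ppin$nodes, annotation$protein)
  if (length(missing)) {
    stop("PPIN nodes absent from annotation: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "", call. = FALSE)
  }
  fam_counts <- protein_family_counts(annotation)
  lib_keys <- ddi_keys(ddi)
  e <- ppin$edges
  rows <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    u <- e$from[i]
    v <- e$to[i]
    fu <- names(fam_counts[[u]])
    fv <- names(fam_counts[[v]])
    hits <- NULL
    if (length(fu) && length(fv)) {
      cand <- expand.grid(fu = fu, fv = fv, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      key <- ifelse(cand$fu <= cand$fv,
                    paste(cand$fu, cand$fv, sep = "|"),
                    paste(cand$fv, cand$fu, sep = "|"))
      hits <- cand[key %in% lib_keys, , drop = FALSE]
    }
    if (is.null(hits) || !nrow(hits)) {
      rows[[i]] <- data.frame(
        ppi_key = edge_key(u, v), u = u, v = v,
        fam_u = DUMMY_FAMILY, fam_v = DUMMY_FAMILY,
        d_u = domain_id(u, DUMMY_FAMILY, 1L),
        d_v = domain_id(v, DUMMY_FAMILY, 1L),
        stringsAsFactors = FALSE
      )
    } else {
      sub <- vector("list", nrow(hits))
      for (h in seq_len(nrow(hits))) {
        f <- hits$fu[h]
        g <- hits$fv[h]
        occ <- expand.grid(oi = seq_len(fam_counts[[u]][[f]]),
                           oj = seq_len(fam_counts[[v]][[g]]),
                           KEEP.OUT.ATTRS = FALSE)
        sub[[h]] <- data.frame(
          ppi_key = edge_key(u, v), u = u, v = v, fam_u = f, fam_v = g,
          d_u = domain_id(u, f, occ$oi), d_v = domain_id(v, g, occ$oj),
          stringsAsFactors = FALSE
        )
      }
      rows[[i]] <- do.call(rbind, sub)
    }
  }
  backing <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ppi_key = character(), u = character(), v = character(),
               fam_u = character(), fam_v = character(),
               d_u = character(), d_v = character(), stringsAsFactors = FALSE)
  ddin <- ppi_network(backing$d_u, backing$d_v, level = "domain")
  structure(list(ddin = ddin, backing = backing), class = "reference_ddin")
}

#' @export
print.reference_ddin <- function(x, ...) {
  cat(sprintf("<reference DDIN: %d domain edges backing %d PPIs>\n",
              n_edges(x$ddin), length(unique(x$backing$ppi_key))))
  invisible(x)
}

#' Contextualize one sample
#'
#' Prunes the reference DDIN to the domain interactions supported by the
#' sample's expression: a domain edge survives iff both owner proteins have
#' a major feature above the expression threshold and both domain families
#' occur in the chosen feature's architecture (dummy domains occur in every
#' feature of their owner). The set of PPIs explained by at least one
#' surviving domain edge is the condition-specific PPIN.
#'
#' @param ppin Reference protein-level [ppi_network].
#' @param ref A `reference_ddin` from [build_reference_ddin].
#' @param annotation A [domain_annotation].
#' @param expr An [expression_table] for the sample.
#' @param opts [context_options].
#' @return A list of class `context_result`: `ppin` and `ddin` (the
#'   condition-specific networks), `major` (data.frame `protein`, `gene`,
#'   `feature`, `abundance`), and `options`.
#' @export
contextualize_sample <- function(ppin, ref, annotation, expr,
                                 opts = context_options()) {
  stopifnot(inherits(ref, "reference_ddin"),
            inherits(expr, "expression_table"))
  if (opts$normalize_length && expr$level == "transcript") {
    expr <- length_normalize(expr)
  }
  major <- major_feature_map(annotation, expr, opts)
  # Families present in each expressed protein's chosen feature, keyed
  # "protein|family"; dummies are present for every expressed protein.
  fam_present <- c(
    paste(rep.int(major$protein, lengths(major$domains)),
          unlist(major$domains), sep = "|"),
    paste(major$protein, DUMMY_FAMILY, sep = "|")
  )
  b <- ref$backing
  alive <- paste(b$u, b$fam_u, sep = "|") %in% fam_present &
    paste(b$v, b$fam_v, sep = "|") %in% fam_present
  cond_keys <- unique(b$ppi_key[alive])
  cond_ppin <- subset_network(ppin, cond_keys)
  cond_ddin <- ppi_network(b$d_u[alive], b$d_v[alive], level = "domain")
  major_out <- major[, c("protein", "gene", "feature", "abundance")]
  structure(
    list(ppin = cond_ppin, ddin = cond_ddin, major = major_out,
         options = opts),
    class = "context_result"
  )
}

#' @export
print.context_result <- function(x, ...) {
  cat(sprintf(
    "<contextualized sample: %d proteins expressed, %d PPIs, %d DDIs>\n",
    nrow(x$major), n_edges(x$ppin), n_edges(x$ddin)
  ))
  invisible(x)
}
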