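# Differential rewiring statistics: the null rewiring probability averaged
# over all inter-group sample pairs, a one-tailed binomial test per edge
# alteration, Benjamini-Hochberg correction, and assembly of the
# significant differential network.

#' A group of condition-specific networks
#'
#' @param label Group label.
#' @param networks Named list of protein-level [ppi_network]s (one per
#'   sample).
#' @param majors Optional named list (same names) of major-feature
#'   data.frames as produced by [contextualize_sample] or read by
#'   [read_major_transcripts]; required for reason attribution.
#' @return A list of class `sample_group`.
#' @export
sample_group <- function(label, networks, majors = NULL) {
  if (!length(networks)) stop("a group needs at least one sample", call. = FALSE)
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("networks must be a named list (one name per sample)", call. = FALSE)
  }
  ok <- vapply(networks, function(n) {
    inherits(n, "ppi_network") && identical(n$level, "protein")
  }, TRUE)
  if (!all(ok)) stop("all group networks must be protein-level", call. = FALSE)
  if (!is.null(majors)) {
    if (!all(names(networks) %in% names(majors))) {
      stop("majors must cover every sample in the group", call. = FALSE)
    }
    majors <- majors[names(networks)]
  }
  structure(list(label = label, networks = networks, majors = majors),
            class = "sample_group")
}

#' @export
print.sample_group <- function(x, ...) {
  cat(sprintf("<sample group '%s': %d samples>\n", x$label,
              length(x$networks)))
  invisible(x)
}

#' Pairwise rewiring probability
#'
#' The fraction of rewired edges (vanishing plus appearing) between two
#' condition-specific networks. With `denominator = "pair"` (default) the
#' fraction is over the union of the pair's edges; `"global"` divides by the
#' size of a caller-supplied global edge union instead (the alternative
#' reading of "all edges present in all samples").
#'
#' @param netA,netB Protein-level [ppi_network]s.
#' @param denominator `"pair"` or `"global"`.
#' @param global_union Character vector of edge keys of the global union
#'   (required for `denominator = "global"`).
#' @return A number in `[0, 1]`; 0 for two empty networks.
#' @export
pairwise_rewiring_probability <- function(netA, netB,
                                          denominator = c("pair", "global"),
                                          global_union = NULL) {
  denominator <- match.arg(denominator)
  ka <- edge_keys(netA)
  kb <- edge_keys(netB)
  sym <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  den <- if (denominator == "pair") {
    length(union(ka, kb))
  } else {
    if (is.null(global_union)) {
      stop("global denominator needs the global edge union", call. = FALSE)
    }
    length(global_union)
  }
  if (den == 0L) return(0)
  sym / den
}

inter_group_pairs <- function(groupA, groupB) {
  expand.grid(a = names(groupA$networks), b = names(groupB$networks),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Build the rewiring null
#'
#' Averages the pairwise rewiring probabilities over all `N = |A| * |B|`
#' inter-group sample pairs into the success probability of the binomial
#' null.
#'
#' @param groupA,groupB [sample_group]s.
#' @inheritParams pairwise_rewiring_probability
#' @return A list of class `rewiring_null` with `n_pairs`, `pairs` (the
#'   sample-name pairs, in row order matching `p_pair`), `p_pair` and the
#'   aggregate `p_rewired`.
#' @export
build_null <- function(groupA, groupB, denominator = c("pair", "global")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(groupA, "sample_group"), inherits(groupB, "sample_group"))
  pairs <- inter_group_pairs(groupA, groupB)
  global_union <- NULL
  if (denominator == "global") {
    global_union <- unique(unlist(c(lapply(groupA$networks, edge_keys),
                                    lapply(groupB$networks, edge_keys))))
  }
  p_pair <- vapply(seq_len(nrow(pairs)), function(k) {
    pairwise_rewiring_probability(groupA$networks[[pairs$a[k]]],
                                  groupB$networks[[pairs$b[k]]],
                                  denominator, global_union)
  }, numeric(1))
  structure(
    list(n_pairs = nrow(pairs), pairs = pairs, p_pair = p_pair,
         p_rewired = mean(p_pair), denominator = denominator),
    class = "rewiring_null"
  )
}

#' @export
print.rewiring_null <- function(x, ...) {
  cat(sprintf("<rewiring null: P_rewired = %.4g over %d inter-group pairs>\n",
              x$p_rewired, x$n_pairs))
  invisible(x)
}

#' Count edge alterations across all inter-group pairs
#'
#' For every edge in the union over all samples, counts the inter-group
#' pairs where it vanishes (present in the A-sample, absent from the
#' B-sample: "lost") or appears ("gained"). Each altered edge yields one
#' record in its majority direction with support equal to that direction's
#' count; ties break toward "lost" with a warning. Edges identical across
#' all pairs are omitted.
#'
#' @param groupA,groupB [sample_group]s (alterations are oriented A to B).
#' @return A data.frame with columns `from`, `to`, `direction`, `support`,
#'   `n_lost`, `n_gained`, and an attribute `instances`: a list, per row,
#'   of the pair indices (rows of `inter_group_pairs`) exhibiting the
#'   majority-direction event.
#' @export
count_alterations <- function(groupA, groupB) {
  stopifnot(inherits(groupA, "sample_group"), inherits(groupB, "sample_group"))
  pairs <- inter_group_pairs(groupA, groupB)
  keysA <- lapply(groupA$networks, edge_keys)
  keysB <- lapply(groupB$networks, edge_keys)
  recs <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ka <- keysA[[pairs$a[k]]]
    kb <- keysB[[pairs$b[k]]]
    lost <- setdiff(ka, kb)
    gained <- setdiff(kb, ka)
    recs[[k]] <- data.frame(
      key = c(lost, gained),
      direction = rep(c("lost", "gained"), c(length(lost), length(gained))),
      pair = rep.int(k, length(lost) + length(gained)),
      stringsAsFactors = FALSE
    )
  }
  ev <- do.call(rbind, recs)
  empty <- data.frame(from = character(), to = character(),
                      direction = character(), support = integer(),
                      n_lost = integer(), n_gained = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(ev) || !nrow(ev)) {
    attr(empty, "instances") <- list()
    attr(empty, "pairs") <- pairs
    return(empty)
  }
  keys <- sort(unique(ev$key))
  n_lost <- integer(length(keys))
  n_gained <- integer(length(keys))
  tl <- table(factor(ev$key[ev$direction == "lost"], levels = keys))
  tg <- table(factor(ev$key[ev$direction == "gained"], levels = keys))
  n_lost <- as.integer(tl)
  n_gained <- as.integer(tg)
  tie <- n_lost == n_gained
  if (any(tie)) {
    warning(sum(tie), " edge(s) with equally many lost and gained events; ",
            "direction tie broken toward 'lost'", call. = FALSE)
  }
  direction <- ifelse(n_gained > n_lost, "gained", "lost")
  support <- pmax(n_lost, n_gained)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    direction = direction, support = support,
    n_lost = n_lost, n_gained = n_gained,
    stringsAsFactors = FALSE
  )
  ev_major <- ev[ev$direction == direction[match(ev$key, keys)], , drop = FALSE]
  inst <- split(ev_major$pair, factor(ev_major$key, levels = keys))
  attr(out, "instances") <- unname(inst)
  attr(out, "pairs") <- pairs
  out
}

#' One-tailed binomial p-value for an edge alteration
#'
#' Probability, under the rewiring null, of observing at least `support`
#' rewiring events of one edge over `n_pairs` pairwise comparisons, i.e.
#' the upper tail `P[X >= support]` for `X ~ Binomial(n_pairs, p_rewired)`,
#' computed with a numerically stable survival function.
#'
#' @param support Observed number of rewiring events (1..`n_pairs`);
#'   vectorised.
#' @param n_pairs Number of inter-group sample pairs `N`.
#' @param p_rewired Null rewiring probability in `[0, 1]`, or a
#'   `rewiring_null` object (in which case `n_pairs` is taken from it).
#' @return The p-value(s) in `[0, 1]`.
#' @export
edge_pvalue <- function(support, n_pairs = NULL, p_rewired) {
  if (inherits(p_rewired, "rewiring_null")) {
    if (is.null(n_pairs)) n_pairs <- p_rewired$n_pairs
    p_rewired <- p_rewired$p_rewired
  }
  support <- as.numeric(support)
  if (any(support < 1 | support != round(support))) {
    stop("support must be a positive integer count", call. = FALSE)
  }
  if (any(support > n_pairs)) {
    stop("support cannot exceed the number of pairwise comparisons",
         call. = FALSE)
  }
  if (p_rewired < 0 || p_rewired > 1) {
    stop("p_rewired must be in [0, 1]", call. = FALSE)
  }
  stats::pbinom(support - 1, size = n_pairs, prob = p_rewired,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, returned in input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential network between two sample groups
#'
#' Full rewiring pipeline: build the binomial null from all inter-group
#' pairwise comparisons, count per-edge alterations, test each with the
#' one-tailed binomial test, adjust with Benjamini-Hochberg, and retain
#' the alterations with `q <= fdr`.
#'
#' @param groupA,groupB [sample_group]s (direction is oriented A to B).
#' @param fdr False discovery rate threshold (default 0.05).
#' @inheritParams pairwise_rewiring_probability
#' @return A list of class `differential_network`: `alterations` (all
#'   tested alterations with `p`, `q` and `significant`, ordered by `q`
#'   then edge), `significant` (the retained subset), `null`, `fdr`,
#'   `pairs`, and `instances` (majority-direction pair indices per
#'   alteration row).
#' @export
differential_network <- function(groupA, groupB, fdr = 0.05,
                                 denominator = c("pair", "global")) {
  denominator <- match.arg(denominator)
  if (fdr < 0 || fdr > 1) stop("fdr must be in [0, 1]", call. = FALSE)
  null <- build_null(groupA, groupB, denominator)
  alt <- count_alterations(groupA, groupB)
  inst <- attr(alt, "instances")
  pairs <- attr(alt, "pairs")
  if (nrow(alt)) {
    alt$p <- edge_pvalue(alt$support, null$n_pairs, null$p_rewired)
    alt$q <- bh_adjust(alt$p)
    alt$significant <- alt$q <= fdr
    ord <- order(alt$q, edge_key(alt$from, alt$to))
    alt <- alt[ord, , drop = FALSE]
    inst <- inst[ord]
    rownames(alt) <- NULL
  } else {
    alt$p <- numeric()
    alt$q <- numeric()
    alt$significant <- logical()
  }
  structure(
    list(alterations = alt,
         significant = alt[alt$significant, , drop = FALSE],
         null = null, fdr = fdr, pairs = pairs, instances = inst),
    class = "differential_network"
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf(
    "<differential network: %d/%d alterations significant at FDR %.3g (P_rewired = %.4g, N = %d)>\n",
    nrow(x$significant), nrow(x$alterations), x$fdr,
    x$null$p_rewired, x$null$n_pairs
  ))
  invisible(x)
}
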