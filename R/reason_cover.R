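# Attribution of significant rewiring to transcriptomic changes: candidate
# "reasons" (expression gains/losses and isoform switches at the endpoints
# of each altered edge), the score/weight scheme s_i = p_w * r_w,
# w_i = s_max - s_i, and a greedy weighted set cover over the (alteration,
# sample-pair) instances.

reason_id <- function(protein, kind) paste(protein, kind, sep = "|")

instance_id <- function(edge_key, pair) paste(edge_key, pair, sep = "@")

instance_pair <- function(instance) {
  sub("^.*@", "", instance)
}

instance_edge <- function(instance) {
  sub("@[0-9]+$", "", instance)
}

majors_feature_lookup <- function(majors) {
  lapply(majors, function(m) stats::setNames(m$feature, m$protein))
}

#' Enumerate candidate reasons for significant alterations
#'
#' The universe to explain is the set of (significant alteration, inter-group
#' sample pair) instances in the alteration's majority direction. For each
#' instance of edge `(u, v)` in pair `(a, b)`, each endpoint protein
#' contributes a candidate when its major feature changed consistently with
#' the alteration: an expression loss (feature in `a`, none in `b`) for a
#' lost edge, an expression gain (the reverse) for a gained edge, or an
#' isoform switch (different major features, both present) for either
#' direction. Instances with no candidate are reported as uncoverable.
#'
#' @param diff A [differential_network].
#' @param groupA,groupB [sample_group]s with major-feature maps for every
#'   sample.
#' @return A list of class `reason_candidates`: `reasons` (named list; each
#'   element has `id`, `protein`, `kind` and the covered `instances`) and
#'   `universe` (all instance ids).
#' @export
enumerate_reasons <- function(diff, groupA, groupB) {
  stopifnot(inherits(diff, "differential_network"))
  if (is.null(groupA$majors) || is.null(groupB$majors)) {
    stop("reason attribution needs major-feature maps for every sample",
         call. = FALSE)
  }
  featA <- majors_feature_lookup(groupA$majors)
  featB <- majors_feature_lookup(groupB$majors)
  alt <- diff$alterations
  sig_rows <- which(alt$significant)
  pairs <- diff$pairs
  universe <- character()
  cover <- list()   # reason id -> character vector of instances
  meta <- list()    # reason id -> c(protein, kind)
  add <- function(protein, kind, inst) {
    id <- reason_id(protein, kind)
    cover[[id]] <<- c(cover[[id]], inst)
    meta[[id]] <<- c(protein = protein, kind = kind)
  }
  for (r in sig_rows) {
    ekey <- edge_key(alt$from[r], alt$to[r])
    dir <- alt$direction[r]
    for (k in diff$instances[[r]]) {
      inst <- instance_id(ekey, k)
      universe <- c(universe, inst)
      fa_map <- featA[[pairs$a[k]]]
      fb_map <- featB[[pairs$b[k]]]
      for (w in c(alt$from[r], alt$to[r])) {
        fa <- fa_map[w]
        fb <- fb_map[w]
        has_a <- !is.na(fa)
        has_b <- !is.na(fb)
        if (dir == "lost" && has_a && !has_b) {
          add(w, "expression-loss", inst)
        } else if (dir == "gained" && !has_a && has_b) {
          add(w, "expression-gain", inst)
        } else if (has_a && has_b && fa != fb) {
          add(w, "isoform-switch", inst)
        }
      }
    }
  }
  ids <- sort(names(cover))
  reasons <- lapply(ids, function(id) {
    list(id = id, protein = unname(meta[[id]]["protein"]),
         kind = unname(meta[[id]]["kind"]),
         instances = sort(unique(cover[[id]])))
  })
  names(reasons) <- ids
  structure(list(reasons = reasons, universe = sort(unique(universe))),
            class = "reason_candidates")
}

#' Score candidate reasons
#'
#' Computes, per reason, `r_w` (number of covered alteration instances),
#' `p_w` (number of distinct pairwise comparisons among them), the score
#' `s = p_w * r_w` and the weight `w = s_max - s`, where `s_max` is the
#' maximum score over the candidate pool.
#'
#' @param candidates A `reason_candidates` from [enumerate_reasons].
#' @return A data.frame of class `scored_reasons` with columns `id`,
#'   `protein`, `kind`, `r_w`, `p_w`, `s`, `w` and a list-column
#'   `instances`; attribute `universe` is carried through.
#' @export
score_reasons <- function(candidates) {
  stopifnot(inherits(candidates, "reason_candidates"))
  rs <- candidates$reasons
  if (!length(rs)) {
    out <- data.frame(id = character(), protein = character(),
                      kind = character(), r_w = integer(), p_w = integer(),
                      s = numeric(), w = numeric(), stringsAsFactors = FALSE)
    out$instances <- list()
  } else {
    out <- data.frame(
      id = vapply(rs, `[[`, "", "id"),
      protein = vapply(rs, `[[`, "", "protein"),
      kind = vapply(rs, `[[`, "", "kind"),
      r_w = vapply(rs, function(r) length(r$instances), 0L),
      p_w = vapply(rs, function(r) {
        length(unique(instance_pair(r$instances)))
      }, 0L),
      stringsAsFactors = FALSE
    )
    out$s <- out$p_w * out$r_w
    out$w <- max(out$s) - out$s
    out$instances <- lapply(rs, `[[`, "instances")
    rownames(out) <- NULL
  }
  attr(out, "universe") <- candidates$universe
  class(out) <- c("scored_reasons", "data.frame")
  out
}

#' Greedy weighted set cover over alteration instances
#'
#' Chvatal's greedy heuristic: repeatedly select the reason with the
#' smallest weight-per-newly-covered-instance ratio (ties: lower weight,
#' then larger new coverage, then lexicographic id) until no candidate adds
#' coverage. Instances no reason covers are reported separately.
#'
#' @param scored A `scored_reasons` data.frame from [score_reasons].
#' @param universe Character vector of instance ids to cover; defaults to
#'   the universe recorded on `scored`.
#' @return A list of class `cover_solution`: `selected` (the chosen reasons
#'   in selection order, with `rank` and `new_covered`), `covered`,
#'   `uncovered`, `total_weight` and `covered_fraction`.
#' @export
greedy_cover <- function(scored, universe = attr(scored, "universe")) {
  stopifnot(inherits(scored, "scored_reasons"))
  universe <- unique(universe)
  covered <- character()
  remaining <- seq_len(nrow(scored))
  picked <- integer()
  new_counts <- integer()
  while (length(remaining)) {
    new <- vapply(remaining, function(i) {
      length(setdiff(intersect(scored$instances[[i]], universe), covered))
    }, 0L)
    useful <- new > 0L
    if (!any(useful)) break
    cand <- remaining[useful]
    nc <- new[useful]
    ratio <- scored$w[cand] / nc
    ord <- order(ratio, scored$w[cand], -nc, scored$id[cand])
    best <- ord[1L]
    picked <- c(picked, cand[best])
    new_counts <- c(new_counts, nc[best])
    covered <- union(covered, intersect(scored$instances[[cand[best]]], universe))
    remaining <- setdiff(remaining, cand[best])
  }
  selected <- scored[picked, , drop = FALSE]
  selected$rank <- seq_along(picked)
  selected$new_covered <- new_counts
  rownames(selected) <- NULL
  structure(
    list(selected = selected, covered = sort(covered),
         uncovered = sort(setdiff(universe, covered)),
         total_weight = sum(selected$w),
         covered_fraction = if (length(universe)) {
           length(covered) / length(universe)
         } else 1),
    class = "cover_solution"
  )
}

#' @export
print.cover_solution <- function(x, ...) {
  cat(sprintf(
    "<set cover: %d reasons, %.1f%% of %d instances covered, total weight %g>\n",
    nrow(x$selected), 100 * x$covered_fraction,
    length(x$covered) + length(x$uncovered), x$total_weight
  ))
  invisible(x)
}

#' Attribute significant rewiring to a minimal set of transcriptomic changes
#'
#' Convenience pipeline: [enumerate_reasons], [score_reasons],
#' [greedy_cover]. The selected reasons jointly explain every coverable
#' (alteration, pair) instance of the significant differential network.
#'
#' @inheritParams enumerate_reasons
#' @return A `cover_solution`; `selected` additionally carries a
#'   `covered_edges` list-column with the altered edges each reason
#'   explains.
#' @export
attribute_reasons <- function(diff, groupA, groupB) {
  scored <- score_reasons(enumerate_reasons(diff, groupA, groupB))
  sol <- greedy_cover(scored)
  sol$selected$covered_edges <- lapply(sol$selected$instances, function(inst) {
    sort(unique(gsub("\t", ":", instance_edge(inst), fixed = TRUE)))
  })
  sol
}
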