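# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary data.

# Random protein-level network over `n` nodes.
random_network <- function(n = 10, p = 0.3, weighted = FALSE) {
  nodes <- sprintf("P%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- runif(nrow(idx)) < p
  w <- if (weighted) round(runif(sum(pick)), 3) else NULL
  ppi_network(nodes[idx[pick, 1L]], nodes[idx[pick, 2L]], weight = w,
              nodes = nodes)
}

# Independent oracle: literal term-by-term summation of the one-tailed
# binomial formula p = 1 - sum_{j=0}^{support-1} C(N,j) p^j (1-p)^(N-j).
binom_tail_literal <- function(support, n, p) {
  j <- 0:(support - 1)
  1 - sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Independent oracle: brute-force Benjamini-Hochberg step-up adjustment.
bh_brute_force <- function(p) {
  m <- length(p)
  ps <- sort(p)
  qs <- numeric(m)
  # q for the k-th smallest p: min over j >= k of min(1, p_(j) * m / j)
  for (k in seq_len(m)) {
    qs[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  qs[rank(p, ties.method = "first")]
}

# Independent oracle: exhaustive weighted set cover (max coverage with
# minimum total weight among covers of the coverable universe).
exhaustive_cover <- function(sets, weights, universe) {
  coverable <- unique(unlist(sets))
  target <- intersect(universe, coverable)
  n <- length(sets)
  best_w <- Inf
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    cov <- unique(unlist(sets[sel]))
    if (all(target %in% cov)) {
      w <- sum(weights[sel])
      if (w < best_w) best_w <- w
    }
  }
  best_w
}

# Minimal two-protein fixture demonstrating isoform-resolved pruning: the
# interaction's only documented backing is PF_A-PF_B; protein PB has a
# second isoform lacking PF_B.
isoform_switch_fixture <- function() {
  ann <- domain_annotation(
    protein = c("PA", "PB", "PB"),
    gene = c("GA", "GB", "GB"),
    isoform = c("TA1", "TB1", "TB2"),
    domains = list("PF_A", "PF_B", character()),
    canonical = c(TRUE, TRUE, FALSE)
  )
  list(
    ppin = ppi_network("PA", "PB"),
    annotation = ann,
    ddi = ddi_library("PF_A", "PF_B")
  )
}

# Expression table for the two-protein fixture; `major_b` picks which PB
# isoform dominates.
isoform_switch_expression <- function(major_b = c("TB1", "TB2")) {
  major_b <- match.arg(major_b)
  ab <- c(TA1 = 50, TB1 = 5, TB2 = 5)
  ab[major_b] <- 50
  expression_table("transcript", ab,
                   tx2gene = c(TA1 = "GA", TB1 = "GB", TB2 = "GB"))
}

# Random contextualization fixture: network + annotation + library +
# expression, with a controllable backed fraction.
random_context_fixture <- function(n = 12, p_edge = 0.3, backed = 0.7,
                                   p_expressed = 0.8) {
  net <- random_network(n, p_edge)
  proteins <- net$nodes
  fam <- character(0)
  lib_a <- character(0)
  lib_b <- character(0)
  fams_of <- setNames(replicate(n, character(), simplify = FALSE), proteins)
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    if (runif(1) < backed) {
      fu <- sprintf("PFU%03d", i)
      fv <- sprintf("PFV%03d", i)
      fams_of[[e$from[i]]] <- c(fams_of[[e$from[i]]], fu)
      fams_of[[e$to[i]]] <- c(fams_of[[e$to[i]]], fv)
      lib_a <- c(lib_a, fu)
      lib_b <- c(lib_b, fv)
    }
  }
  ann <- domain_annotation(
    protein = proteins, gene = paste0("G", proteins),
    isoform = paste0(proteins, ".T1"),
    domains = unname(fams_of[proteins]),
    canonical = rep(TRUE, n)
  )
  ab <- ifelse(runif(n) < p_expressed, 10 + runif(n, 0, 50), 0)
  expr <- expression_table("gene", setNames(ab, paste0("G", proteins)))
  list(ppin = net, annotation = ann,
       ddi = ddi_library(lib_a, lib_b), expr = expr)
}
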