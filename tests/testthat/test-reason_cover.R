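# Build a small two-group setting by hand: networks plus major-feature maps
# per sample, so candidate enumeration is fully controlled.
mk_major <- function(...) {
  rows <- list(...)
  data.frame(
    protein = vapply(rows, `[[`, "", 1),
    gene = paste0("G", vapply(rows, `[[`, "", 1)),
    feature = vapply(rows, `[[`, "", 2),
    abundance = 10,
    stringsAsFactors = FALSE
  )
}

loss_setting <- function() {
  # four stable background edges keep the rewiring null low
  stable_f <- sprintf("s%d", c(1, 3, 5, 7))
  stable_t <- sprintf("s%d", c(2, 4, 6, 8))
  with_ab <- ppi_network(c(stable_f, "a"), c(stable_t, "b"))
  without <- ppi_network(stable_f, stable_t, nodes = c("a", "b"))
  on <- mk_major(c("a", "Ta1"), c("b", "Tb1"))
  b_off <- mk_major(c("b", "Tb1"))  # a unexpressed
  gA <- sample_group("A", list(A1 = with_ab, A2 = with_ab),
                     majors = list(A1 = on, A2 = on))
  gB <- sample_group("B", list(B1 = without, B2 = without),
                     majors = list(B1 = b_off, B2 = b_off))
  list(diff = differential_network(gA, gB, fdr = 0.05), gA = gA, gB = gB)
}

test_that("an expression loss covering every pair is the single reason", {
  s <- loss_setting()
  expect_equal(nrow(s$diff$significant), 1)
  cand <- enumerate_reasons(s$diff, s$gA, s$gB)
  expect_length(cand$universe, 4)  # one alteration x 4 pairs
  expect_identical(names(cand$reasons), "a|expression-loss")
  expect_length(cand$reasons[["a|expression-loss"]]$instances, 4)

  sol <- attribute_reasons(s$diff, s$gA, s$gB)
  expect_equal(nrow(sol$selected), 1)
  expect_identical(sol$selected$protein, "a")
  expect_identical(sol$selected$kind, "expression-loss")
  expect_equal(sol$covered_fraction, 1)
  expect_length(sol$uncovered, 0)
})

test_that("an isoform switch that removes the backing domain is attributed", {
  fx <- isoform_switch_fixture()
  ref <- build_reference_ddin(fx$ppin, fx$annotation, fx$ddi)
  opts <- context_options(mode = "transcript")
  ctxA <- contextualize_sample(fx$ppin, ref, fx$annotation,
                               isoform_switch_expression("TB1"), opts)
  ctxB <- contextualize_sample(fx$ppin, ref, fx$annotation,
                               isoform_switch_expression("TB2"), opts)
  gA <- sample_group("A", list(A1 = ctxA$ppin, A2 = ctxA$ppin),
                     majors = list(A1 = ctxA$major, A2 = ctxA$major))
  gB <- sample_group("B", list(B1 = ctxB$ppin, B2 = ctxB$ppin),
                     majors = list(B1 = ctxB$major, B2 = ctxB$major))
  # the two-protein fixture has no stable background, so the rewiring null
  # is saturated; retain all alterations to exercise the attribution itself
  diff <- differential_network(gA, gB, fdr = 1)
  expect_equal(nrow(diff$significant), 1)
  sol <- attribute_reasons(diff, gA, gB)
  expect_identical(sol$selected$protein, "PB")
  expect_identical(sol$selected$kind, "isoform-switch")
})

test_that("alterations with no endpoint change are reported uncoverable", {
  ab <- ppi_network("a", "b")
  none <- ppi_network(nodes = c("a", "b"))
  on <- mk_major(c("a", "Ta1"), c("b", "Tb1"))
  # both endpoints expressed with identical features everywhere
  gA <- sample_group("A", list(A1 = ab), majors = list(A1 = on))
  gB <- sample_group("B", list(B1 = none), majors = list(B1 = on))
  diff <- differential_network(gA, gB, fdr = 1)  # force retention (N = 1)
  expect_equal(nrow(diff$significant), 1)
  cand <- enumerate_reasons(diff, gA, gB)
  expect_length(cand$reasons, 0)
  sol <- greedy_cover(score_reasons(cand))
  expect_equal(nrow(sol$selected), 0)
  expect_length(sol$uncovered, 1)
  expect_equal(sol$covered_fraction, 0)
})

test_that("scores follow s = p_w * r_w and w = s_max - s", {
  s <- loss_setting()
  # add a second, weaker reason by differing b's isoform in one B sample
  s$gB$majors$B1 <- mk_major(c("b", "Tb2"))
  cand <- enumerate_reasons(s$diff, s$gA, s$gB)
  scored <- score_reasons(cand)
  a_row <- scored[scored$protein == "a", ]
  b_row <- scored[scored$protein == "b", ]
  expect_equal(a_row$r_w, 4)
  expect_equal(a_row$p_w, 4)
  expect_equal(a_row$s, 16)
  expect_equal(a_row$w, 0)        # the arg-max reason
  expect_identical(b_row$kind, "isoform-switch")
  expect_equal(b_row$r_w, 2)      # pairs (A1,B1), (A2,B1)
  expect_equal(b_row$p_w, 2)
  expect_equal(b_row$s, 4)
  expect_equal(b_row$w, 16 - 4)
})

test_that("greedy cover follows the cost-effectiveness ratio", {
  mk_scored <- function(ids, sets, w) {
    out <- data.frame(id = ids, protein = ids, kind = "expression-loss",
                      r_w = lengths(sets), p_w = 1L, stringsAsFactors = FALSE)
    out$s <- 0
    out$w <- w
    out$instances <- sets
    attr(out, "universe") <- sort(unique(unlist(sets)))
    class(out) <- c("scored_reasons", "data.frame")
    out
  }
  # R1 covers {1,2} w=1 (ratio 1/2); R2 covers {3} w=1; R3 covers all w=5
  scored <- mk_scored(c("R1", "R2", "R3"),
                      list(c("i1", "i2"), "i3", c("i1", "i2", "i3")),
                      c(1, 1, 5))
  sol <- greedy_cover(scored)
  expect_identical(sol$selected$id, c("R1", "R2"))
  expect_equal(sol$total_weight, 2)
  expect_length(sol$uncovered, 0)
  # a single reason covering everything is the whole solution
  solo <- greedy_cover(mk_scored("R", list(c("i1", "i2")), 0))
  expect_identical(solo$selected$id, "R")
  # zero-new-coverage reasons are never selected
  dup <- mk_scored(c("R1", "R2"), list(c("i1", "i2"), c("i1", "i2")), c(0, 0))
  expect_equal(nrow(greedy_cover(dup)$selected), 1)
})

test_that("greedy respects the Chvatal bound against exhaustive search", {
  set.seed(71)
  h <- function(d) sum(1 / seq_len(max(d, 1)))
  for (i in 1:50) {
    n_r <- sample(2:8, 1)
    n_u <- sample(3:12, 1)
    universe <- sprintf("i%02d", seq_len(n_u))
    sets <- lapply(seq_len(n_r), function(j) {
      sample(universe, sample(1:n_u, 1))
    })
    w <- sample(0:10, n_r, replace = TRUE)
    out <- data.frame(id = sprintf("R%d", seq_len(n_r)),
                      protein = sprintf("R%d", seq_len(n_r)),
                      kind = "expression-loss", r_w = lengths(sets),
                      p_w = 1L, stringsAsFactors = FALSE)
    out$s <- 0
    out$w <- w
    out$instances <- sets
    attr(out, "universe") <- universe
    class(out) <- c("scored_reasons", "data.frame")
    sol <- greedy_cover(out)
    # completeness over the coverable part
    expect_setequal(sol$covered, intersect(universe, unique(unlist(sets))))
    opt <- exhaustive_cover(sets, w, universe)
    d <- max(lengths(sets))
    expect_lte(sol$total_weight, h(d) * opt + 1e-9)
  }
})

test_that("greedy tie-breaking is deterministic", {
  out <- data.frame(id = c("Rb", "Ra"), protein = c("Rb", "Ra"),
                    kind = "expression-loss", r_w = c(1L, 1L), p_w = 1L,
                    stringsAsFactors = FALSE)
  out$s <- 0
  out$w <- c(2, 2)
  out$instances <- list("i1", "i1")
  attr(out, "universe") <- "i1"
  class(out) <- c("scored_reasons", "data.frame")
  expect_identical(greedy_cover(out)$selected$id, "Ra")
})
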