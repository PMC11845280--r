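test_that("length normalization rescales by transcript length to 1e6", {
  expr <- expression_table(
    "transcript", c(T1 = 10, T2 = 10),
    tx2gene = c(T1 = "G1", T2 = "G1"),
    lengths = c(T1 = 1000, T2 = 2000)
  )
  norm <- length_normalize(expr)
  # (10/1000) / (10/1000 + 10/2000) * 1e6 = 2/3 * 1e6
  expect_equal(unname(norm$abundance["T1"]), 2 / 3 * 1e6)
  expect_equal(unname(norm$abundance["T2"]), 1 / 3 * 1e6)
  expect_equal(sum(norm$abundance), 1e6)

  single <- expression_table("transcript", c(T1 = 7),
                             tx2gene = c(T1 = "G1"), lengths = c(T1 = 500))
  expect_equal(unname(length_normalize(single)$abundance), 1e6)

  zero <- expression_table("transcript", c(T1 = 0, T2 = 0),
                           tx2gene = c(T1 = "G1", T2 = "G1"),
                           lengths = c(T1 = 500, T2 = 600))
  expect_equal(unname(length_normalize(zero)$abundance), c(0, 0))

  nolen <- expression_table("transcript", c(T1 = 5),
                            tx2gene = c(T1 = "G1"), lengths = c(T9 = 100))
  expect_error(length_normalize(nolen), "missing length")
})

test_that("major feature selection follows mode, threshold and ties", {
  ann <- domain_annotation(
    protein = c("P1", "P1"), gene = c("G1", "G1"),
    isoform = c("T1", "T2"), domains = list("PFa", "PFb"),
    canonical = c(TRUE, FALSE)
  )
  tx <- expression_table("transcript", c(T1 = 3, T2 = 4),
                         tx2gene = c(T1 = "G1", T2 = "G1"))
  # transcript-preferred: argmax isoform
  m <- select_major_feature(tx, "P1", ann, context_options(mode = "transcript"))
  expect_identical(m$feature, "T2")
  expect_identical(m$domains, "PFb")
  # gene-only: gene abundance (sum of isoforms), canonical architecture
  g <- select_major_feature(tx, "P1", ann, context_options(mode = "gene"))
  expect_identical(g$feature, "G1")
  expect_equal(g$abundance, 7)
  expect_identical(g$domains, "PFa")
  # threshold is strict: abundance exactly at the threshold is unexpressed
  at <- expression_table("transcript", c(T1 = 1, T2 = 1),
                         tx2gene = c(T1 = "G1", T2 = "G1"))
  expect_null(select_major_feature(at, "P1", ann,
                                   context_options(threshold = 1,
                                                   mode = "transcript")))
  # ties break lexicographically by transcript id
  tie <- expression_table("transcript", c(T2 = 5, T1 = 5),
                          tx2gene = c(T1 = "G1", T2 = "G1"))
  expect_identical(
    select_major_feature(tie, "P1", ann,
                         context_options(mode = "transcript"))$feature, "T1")
  # zero abundance everywhere -> none
  off <- expression_table("transcript", c(T1 = 0, T2 = 0),
                          tx2gene = c(T1 = "G1", T2 = "G1"))
  expect_null(select_major_feature(off, "P1", ann))
  expect_error(select_major_feature(tx, "P9", ann), "absent")
})

test_that("reference DDIN backs PPIs by documented pairs or dummy edges", {
  ann <- domain_annotation(
    protein = c("U", "V", "W"), gene = c("GU", "GV", "GW"),
    isoform = c("TU", "TV", "TW"),
    domains = list(c("PF1", "PF1"), "PF2", "PF9"),
    canonical = rep(TRUE, 3)
  )
  ppin <- ppi_network(c("U", "U"), c("V", "W"))
  ref <- build_reference_ddin(ppin, ann, ddi_library("PF1", "PF2"))
  b <- ref$backing
  # two copies of PF1 in U -> two domain edges back (U,V)
  uv <- b[b$ppi_key == "U\tV", ]
  expect_equal(nrow(uv), 2)
  expect_setequal(uv$d_u, c("U|PF1|1", "U|PF1|2"))
  expect_identical(unique(uv$d_v), "V|PF2|1")
  # U-W has no documented pair -> one dummy-dummy edge
  uw <- b[b$ppi_key == "U\tW", ]
  expect_equal(nrow(uw), 1)
  expect_identical(uw$fam_u, "DUMMY")
  expect_identical(uw$d_v, "W|DUMMY|1")

  expect_error(build_reference_ddin(ppi_network("U", "X"), ann,
                                    ddi_library()), "absent from annotation")
})

test_that("an isoform switch removes an edge that expression alone keeps", {
  fx <- isoform_switch_fixture()
  ref <- build_reference_ddin(fx$ppin, fx$annotation, fx$ddi)

  keep <- contextualize_sample(fx$ppin, ref, fx$annotation,
                               isoform_switch_expression("TB1"),
                               context_options(mode = "transcript"))
  expect_equal(n_edges(keep$ppin), 1)

  # both proteins well expressed, but PB's major isoform loses PF_B
  drop <- contextualize_sample(fx$ppin, ref, fx$annotation,
                               isoform_switch_expression("TB2"),
                               context_options(mode = "transcript"))
  expect_equal(n_edges(drop$ppin), 0)
  expect_equal(nrow(drop$major), 2)  # both proteins still expressed

  # gene-level mode cannot see the switch and keeps the edge
  gene_mode <- contextualize_sample(fx$ppin, ref, fx$annotation,
                                    isoform_switch_expression("TB2"),
                                    context_options(mode = "gene"))
  expect_equal(n_edges(gene_mode$ppin), 1)
})

test_that("unexpressed endpoints drop all their interactions", {
  fx <- isoform_switch_fixture()
  ref <- build_reference_ddin(fx$ppin, fx$annotation, fx$ddi)
  off <- expression_table("transcript", c(TA1 = 50, TB1 = 0, TB2 = 0),
                          tx2gene = c(TA1 = "GA", TB1 = "GB", TB2 = "GB"))
  ctx <- contextualize_sample(fx$ppin, ref, fx$annotation, off)
  expect_equal(n_edges(ctx$ppin), 0)
  expect_identical(ctx$major$protein, "PA")
})

test_that("contextualization invariants hold on random fixtures", {
  set.seed(51)
  for (i in 1:30) {
    fx <- random_context_fixture()
    ref <- build_reference_ddin(fx$ppin, fx$annotation, fx$ddi)
    opts <- context_options(threshold = 1, mode = "gene")
    ctx <- contextualize_sample(fx$ppin, ref, fx$annotation, fx$expr, opts)
    ref_keys <- paste(fx$ppin$edges$from, fx$ppin$edges$to)
    ctx_keys <- paste(ctx$ppin$edges$from, ctx$ppin$edges$to)
    # subset of the reference
    expect_true(all(ctx_keys %in% ref_keys))
    # every retained PPI explained by >= 1 retained domain edge
    ddin_prots <- unique(sub("\\|.*$", "", c(ctx$ddin$edges$from,
                                             ctx$ddin$edges$to)))
    for (k in seq_len(nrow(ctx$ppin$edges))) {
      expect_true(ctx$ppin$edges$from[k] %in% ddin_prots &&
                    ctx$ppin$edges$to[k] %in% ddin_prots)
    }
    # threshold monotonicity
    ctx_hi <- contextualize_sample(fx$ppin, ref, fx$annotation, fx$expr,
                                   context_options(threshold = 10,
                                                   mode = "gene"))
    expect_true(all(paste(ctx_hi$ppin$edges$from, ctx_hi$ppin$edges$to)
                    %in% ctx_keys))
  }
})

test_that("dummy-backed pairs depend only on expression of both endpoints", {
  ann <- domain_annotation(
    protein = c("A", "B"), gene = c("GA", "GB"), isoform = c("TA", "TB"),
    domains = list(character(), character()), canonical = c(TRUE, TRUE)
  )
  ppin <- ppi_network("A", "B")
  ref <- build_reference_ddin(ppin, ann, ddi_library())
  on <- expression_table("gene", c(GA = 5, GB = 5))
  half <- expression_table("gene", c(GA = 5, GB = 0))
  expect_equal(n_edges(contextualize_sample(ppin, ref, ann, on,
                                            context_options(mode = "gene"))$ppin), 1)
  expect_equal(n_edges(contextualize_sample(ppin, ref, ann, half,
                                            context_options(mode = "gene"))$ppin), 0)
})

test_that("all-expressed dummy-backed gene mode reproduces the reference", {
  set.seed(52)
  net <- random_network(10, 0.4)
  ann <- domain_annotation(
    protein = net$nodes, gene = paste0("G", net$nodes),
    isoform = paste0(net$nodes, ".T1"),
    domains = replicate(length(net$nodes), character(), simplify = FALSE),
    canonical = rep(TRUE, length(net$nodes))
  )
  ref <- build_reference_ddin(net, ann, ddi_library())
  expr <- expression_table("gene", setNames(rep(10, length(net$nodes)),
                                            paste0("G", net$nodes)))
  ctx <- contextualize_sample(net, ref, ann, expr,
                              context_options(mode = "gene"))
  expect_identical(ctx$ppin$edges[c("from", "to")],
                   net$edges[c("from", "to")])
})
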