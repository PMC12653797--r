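test_that("GMT parsing normalizes symbols and rejects malformed input", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\ttnf\tIL6", "S2\tother\tAKT1\tTP53\tEGFR"), p)
  col <- read_gmt(p)
  expect_equal(col$S1, c("TNF", "IL6"))
  expect_equal(length(col$S2), 3)
  expect_equal(attr(col, "description")[["S2"]], "other")

  writeLines(c("S1\tdesc\tTNF", "S1\tdesc\tIL6"), p)
  expect_error(read_gmt(p), "duplicate")
  writeLines("S1\tdesc-only", p)
  expect_error(read_gmt(p), "line 1")
})

test_that("hypergeometric ORA reproduces the enumeration oracle", {
  bg <- paste0("g", 1:10)
  col <- list(S = paste0("g", 1:4))
  r <- ora(paste0("g", c(1, 2, 3, 5, 6)), bg, col)
  expect_equal(r$p_raw, 66 / 252, tolerance = 1e-12)
  expect_equal(r$overlap_k, 3L)

  # zero overlap is the certain event
  r0 <- ora(paste0("g", 8:10), bg, list(S = paste0("g", 1:4)))
  expect_equal(r0$p_raw, 1)

  # spot-check the oracle on a handful of random configurations
  set.seed(21)
  for (i in 1:15) {
    N <- sample(5:12, 1); K <- sample(3:N, 1); n <- sample(1:N, 1)
    bgx <- paste0("x", 1:N)
    q <- paste0("x", sample(N, n))
    rr <- ora(q, bgx, list(S = paste0("x", 1:K)), min_size = 1)
    k <- sum(q %in% paste0("x", 1:K))
    expect_equal(rr$p_raw, ora_enum_oracle(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("sets below min_size are excluded before testing", {
  bg <- paste0("g", 1:20)
  col <- list(BIG = paste0("g", 1:5), TINY = paste0("g", 1:2))
  r <- ora(paste0("g", 1:4), bg, col)
  expect_equal(r$set_name, "BIG")
  expect_warning(ora(paste0("g", 1:4), bg, list(TINY = paste0("g", 1:2))),
                 "min_size")
})

test_that("ORA demands the query be inside the background", {
  expect_error(ora(c("A", "ZZZ"), c("A", "B"), list(S = c("A", "B", "C"))),
               "missing from background")
})

test_that("p-value adjustment: BH step-up and Bonferroni", {
  expect_equal(adjust_pvalues(c(0.005, 0.01, 0.03, 0.04), "BH"),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.5, 0.9), "bonferroni")[1], 0.03)
  expect_equal(adjust_pvalues(numeric(0)), numeric(0))
  # permutation invariance up to re-indexing; monotone in sorted order
  set.seed(13)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_pvalues(p, "BH")[perm], adjust_pvalues(p[perm], "BH"))
  expect_false(is.unsorted(adjust_pvalues(sort(p), "BH")))
  expect_true(all(adjust_pvalues(p, "BH") >= p))
  expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
})

test_that("GSEA enrichment score matches the running-sum oracle", {
  rk <- setNames(c(5, 4, 3, 2, 1), paste0("G", 1:5))
  r <- gsea_preranked(rk, list(S = c("G1", "G3")), n_perm = 50, min_size = 2,
                      seed = 1)
  expect_equal(r$es, 2 / 3, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- paste0("G", seq_len(n))
    set_genes <- paste0("G", sample(n, sample(4:8, 1)))
    r <- gsea_preranked(scores, list(S = set_genes), n_perm = 10, seed = i)
    expect_equal(r$es, gsea_walk_oracle(scores, set_genes), tolerance = 1e-12)
  }
})

test_that("GSEA ES agrees with an external reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- paste0("G", 1:50)
  for (i in 1:5) {
    set_genes <- paste0("G", sample(50, 8))
    ours <- gsea_preranked(scores, list(S = set_genes), n_perm = 10,
                           seed = i)$es
    ref <- fgsea::calcGseaStat(scores, which(names(scores) %in% set_genes))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("GSEA p-values, NES signs and floors behave as constructed", {
  set.seed(5)
  scores <- sort(rnorm(100), decreasing = TRUE)
  names(scores) <- paste0("G", 1:100)
  col <- c(list(TOP = paste0("G", 1:10)),
           setNames(lapply(1:10, function(i) paste0("G", sample(100, 8))),
                    paste0("R", 1:10)))
  r <- gsea_preranked(scores, col, n_perm = 200, seed = 3)
  expect_true(all(r$p_raw >= 1 / 201))
  expect_true(all(r$p_raw <= 1))
  expect_true(all(abs(r$es) <= 1))
  expect_true(all(sign(r$nes) == sign(r$es) | r$es == 0))
  expect_true(all(r$direction == sign(r$es)))
  # the deliberately top-loaded set is the strongest hit
  expect_equal(r$set_name[1], "TOP")
})

test_that("GSEA handles degenerate rankings and skips tiny overlaps", {
  flat <- setNames(rep(0, 20), paste0("G", 1:20))
  r <- gsea_preranked(flat, list(S = paste0("G", 1:5)), n_perm = 20, seed = 1)
  expect_equal(nrow(r), 1)
  expect_true(is.finite(r$es))
  expect_warning(
    gsea_preranked(setNames(5:1, paste0("G", 1:5)),
                   list(S = c("G1", "G2")), n_perm = 10),
    "min_size")
  expect_error(gsea_preranked(setNames(c(1, 2), c("A", "A")), list(S = "A")),
               "duplicate")
})

test_that("compound-connectivity ranking is deterministic with lexicographic ties", {
  tbl <- clean_relationships(read_relationships(write_rel_csv(
    c("gene,compound,plant",
      "B,C1,P1", "B,C2,P1", "A,C1,P1", "A,C2,P1", "Z,C1,P1", "ORPH,,"))))
  rk <- gene_ranking(tbl)
  expect_equal(names(rk), c("A", "B", "Z", "ORPH"))
  expect_equal(unname(rk), c(2, 2, 1, 0))
})

test_that("GSVA matches its independently coded direct-formula oracle", {
  set.seed(8)
  x <- matrix(rnorm(80), 20, 4,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:4)))
  sets <- list(A = paste0("G", 1:16), B = paste0("G", 3:18))
  ours <- gsva_scores(x, sets, min_size = 15)
  oracle <- gsva_direct_oracle(x, sets)
  expect_equal(ours, oracle, tolerance = 1e-10)
  expect_true(all(ours >= -1 & ours <= 1))
})

test_that("GSVA is invariant to positive affine transforms of one gene", {
  set.seed(9)
  x <- matrix(rnorm(100), 20, 5,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:5)))
  sets <- list(A = paste0("G", 2:17))
  base <- gsva_scores(x, sets, min_size = 10)
  x2 <- x
  x2["G5", ] <- 3.7 * x2["G5", ] + 11
  expect_equal(gsva_scores(x2, sets, min_size = 10), base, tolerance = 1e-12)
})

test_that("GSVA degenerate genes get the flat-density fallback", {
  set.seed(10)
  x <- matrix(rnorm(60), 15, 4,
              dimnames = list(paste0("G", 1:15), paste0("S", 1:4)))
  x["G1", ] <- 2.5  # zero variance
  z <- phytonet:::.gsva_kcdf(x)
  expect_equal(unname(z["G1", ]), rep(0.5, 4))
  sc <- gsva_scores(x, list(A = paste0("G", 1:12)), min_size = 10)
  expect_true(all(is.finite(sc)))
})

test_that("GSVA size filter and sample-permutation equivariance", {
  set.seed(11)
  x <- matrix(rnorm(200), 40, 5,
              dimnames = list(paste0("G", 1:40), paste0("S", 1:5)))
  expect_warning(gsva_scores(x, list(TINY = paste0("G", 1:5))), "min_size")
  sc <- gsva_scores(x, list(A = paste0("G", 1:20)), min_size = 15)
  perm <- c(3, 1, 5, 2, 4)
  sc_perm <- gsva_scores(x[, perm], list(A = paste0("G", 1:20)), min_size = 15)
  expect_equal(sc_perm, sc[, perm, drop = FALSE])  # order carries no signal
})

test_that("entity bundles cover global, compounds and plants independently", {
  rows <- c("G1,C1,P1", "G2,C1,P1", "G3,C2,P1", "G3,C2,P2",
            "G4,C3,P2", "G5,C3,P2", "ORPH,,")
  tbl <- clean_relationships(read_relationships(
    write_rel_csv(c("gene,compound,plant", rows))))
  p <- tempfile(fileext = ".gmt")
  writeLines(paste(c("S1", "d", paste0("G", 1:5)), collapse = "\t"), p)
  col <- read_gmt(p)
  bundles <- entity_enrichment(tbl, col, min_genes = 1, min_size = 1)
  expect_setequal(names(bundles), c("global", "C1", "C2", "C3", "P1", "P2"))
  expect_true("ORPH" %in% bundles$global$genes)
  for (b in bundles) if (b$type == "compound")
    expect_false("ORPH" %in% b$genes)
  # plant gene list is the union of its compounds' targets
  expect_setequal(bundles$P1$genes, c("G1", "G2", "G3"))
  expect_setequal(bundles$P2$genes, c("G3", "G4", "G5"))
  # a compound shared by two plants contributes genes to both
  expect_true(all(c("G3") %in% bundles$P1$genes) &&
                all(c("G3") %in% bundles$P2$genes))
  # each bundle is its own multiple-testing family
  expect_equal(bundles$C1$records$p_adj, bundles$C1$records$p_raw)
})

test_that("undersized entity gene lists are flagged skipped, not dropped", {
  rows <- c("G1,C1,P1", "G2,C2,P1", "G3,C2,P1", "G4,C2,P1")
  tbl <- clean_relationships(read_relationships(
    write_rel_csv(c("gene,compound,plant", rows))))
  p <- tempfile(fileext = ".gmt")
  writeLines(paste(c("S1", "d", paste0("G", 1:4)), collapse = "\t"), p)
  bundles <- entity_enrichment(tbl, read_gmt(p), min_genes = 3)
  expect_true(bundles$C1$skipped)
  expect_null(bundles$C1$records)
  expect_false(bundles$C2$skipped)
})

test_that("shared-target algebra: intersections, uniques, pairwise", {
  rows <- c("A,C1,P1", "B,C1,P1", "C,C1,P1",
            "B,C2,P2", "C,C2,P2", "D,C2,P2",
            "C,C3,P3", "E,C3,P3")
  tbl <- clean_relationships(read_relationships(
    write_rel_csv(c("gene,compound,plant", rows))))
  st <- shared_target_analysis(tbl)
  expect_equal(st$all_plants, "C")
  expect_setequal(st$unique_per_plant$P1, "A")
  expect_setequal(st$unique_per_plant$P2, "D")
  expect_setequal(st$unique_per_plant$P3, "E")
  expect_equal(st$pairwise["P1", "P2"], 2L)

  # disjoint target sets
  rows2 <- c("A,C1,P1", "B,C2,P2")
  tbl2 <- clean_relationships(read_relationships(
    write_rel_csv(c("gene,compound,plant", rows2))))
  st2 <- shared_target_analysis(tbl2)
  expect_equal(length(st2$all_plants), 0)
  expect_equal(st2$unique_per_plant$P1, "A")

  rows3 <- c("A,C1,P1")
  tbl3 <- clean_relationships(read_relationships(
    write_rel_csv(c("gene,compound,plant", rows3))))
  expect_error(shared_target_analysis(tbl3), "at least 2 plants")
})
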