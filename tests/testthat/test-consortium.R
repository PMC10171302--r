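test_that("union profiles OR the selected rows", {
  pm <- toy_matrix()
  up <- union_profile(pm, c("g1", "g2"))
  expect_equal(up$union_gene_count, 4L)
  expect_setequal(up$categories, c("A", "B"))
  # singleton subset is the genome's own profile
  up1 <- union_profile(pm, "g3")
  expect_equal(up1$union_gene_count, 2L)
  # all genomes = nonzero columns
  expect_equal(union_profile(pm, rownames(pm$cells))$union_gene_count, 4L)
  expect_error(union_profile(pm, "gX"), "unknown genome")
  expect_error(union_profile(pm, character()), "non-empty")
  # idempotent and order-independent
  expect_equal(union_profile(pm, c("g2", "g1", "g2")),
               union_profile(pm, c("g1", "g2")))
})

test_that("exhaustive selection on the toy matrix finds union 4 at k=2", {
  pm <- toy_matrix()
  sol <- select_exhaustive(pm, 2, "genes")
  expect_true(sol$is_optimal)
  expect_equal(sol$union_gene_count, 4L)
  # brute force over all 6 pairs: optimum 4, attained by {g1,g2} and {g2,g4}
  oracle <- oracle_best_subsets(pm$cells, 2, "genes")
  expect_equal(oracle$best, 4L)
  all_opt <- c(list(sol$genome_ids), sol$ties)
  expect_setequal(vapply(all_opt, paste, character(1), collapse = "+"),
                  vapply(oracle$argmax, paste, character(1), collapse = "+"))
  expect_true("g2+g4" %in% vapply(all_opt, paste, character(1), collapse = "+"))
  # returned set is the lexicographically smallest tie
  expect_equal(sol$genome_ids, c("g1", "g2"))
})

test_that("k = n selects everything; identical genomes tie completely", {
  pm <- toy_matrix()
  sol <- select_exhaustive(pm, 4, "genes")
  expect_equal(sol$genome_ids, c("g1", "g2", "g3", "g4"))
  same <- presence_matrix(
    matrix(1L, 3, 2, dimnames = list(c("b", "a", "c"), c("f1", "f2"))),
    tibble::tibble(feature_id = c("f1", "f2"), category_id = "A"), "enzyme")
  sol1 <- select_exhaustive(same, 1, "genes")
  expect_equal(sol1$genome_ids, "a")
  expect_equal(length(sol1$ties), 2L)
  expect_error(select_exhaustive(pm, 2, "genes", enumeration_cap = 3),
               "select_greedy")
})

test_that("greedy traces marginal gains and matches exhaustive at k=1", {
  pm <- toy_matrix()
  sol <- select_greedy(pm, 2, "genes")
  expect_false(sol$is_optimal)
  # step 1: g4 alone has 3 genes (max); step 2: g2 adds 1 -> union 4
  expect_equal(sol$genome_ids, c("g4", "g2"))
  expect_equal(sol$union_gene_count, 4L)
  expect_equal(select_greedy(pm, 1, "genes")$union_gene_count,
               select_exhaustive(pm, 1, "genes")$union_gene_count)
  td <- tidy(sol, pm)
  expect_equal(td$cumulative_genes, c(3L, 4L))
  expect_equal(td$marginal_genes, c(3L, 1L))
  gl <- glance(sol)
  expect_equal(gl$union_gene_count, 4L)
  expect_false(gl$is_optimal)
})

test_that("greedy stops early when no genome adds anything", {
  pm <- presence_matrix(
    matrix(c(1L, 1L, 0L, 0L), 2, byrow = TRUE,
           dimnames = list(c("g1", "g2"), c("f1", "f2"))),
    tibble::tibble(feature_id = c("f1", "f2"), category_id = "A"), "enzyme")
  expect_message(sol <- select_greedy(pm, 2, "genes"), "no remaining marginal gain")
  expect_equal(sol$genome_ids, "g1")
})

test_that("greedy on a max-coverage counterexample still meets the 1-1/e bound", {
  # classic trap: greedy takes the big middle set and cannot reach the optimum
  cells <- rbind(
    gA = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    gB = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
    gC = c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L))
  colnames(cells) <- paste0("f", 1:8)
  pm <- presence_matrix(cells, tibble::tibble(feature_id = paste0("f", 1:8),
                                              category_id = "A"), "enzyme")
  greedy <- select_greedy(pm, 2, "genes")
  exact <- select_exhaustive(pm, 2, "genes")
  expect_equal(exact$union_gene_count, 8L)
  expect_lt(greedy$union_gene_count, exact$union_gene_count)
  expect_gte(greedy$union_gene_count, (1 - exp(-1)) * exact$union_gene_count)
})

test_that("exhaustive matches brute force and dominates greedy on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(6:12, 1); m <- sample(10:30, 1); k <- sample(1:3, 1)
    pm <- random_matrix(n, m, n_categories = sample(2:4, 1), seed = seed + 1000)
    exact <- select_exhaustive(pm, k, "genes")
    oracle <- oracle_best_subsets(pm$cells, k, "genes")
    expect_equal(exact$union_gene_count, oracle$best)
    expect_true(paste(exact$genome_ids, collapse = "+") %in%
                  vapply(oracle$argmax, paste, character(1), collapse = "+"))
    greedy <- select_greedy(pm, k, "genes")
    expect_lte(greedy$union_gene_count, exact$union_gene_count)
    expect_gte(greedy$union_gene_count,
               (1 - exp(-1)) * exact$union_gene_count - 1e-9)
    # lex maximises categories first, so it covers at least as many as any
    # other size-k subset, including the genes-only optimum
    lex <- select_exhaustive(pm, k, "lex")
    expect_gte(lex$categories_covered, exact$categories_covered)
  }
})

test_that("the exhaustive optimum is non-decreasing in k", {
  pm <- random_matrix(7, 15, seed = 123)
  vals <- vapply(1:4, function(k) select_exhaustive(pm, k, "genes")$union_gene_count,
                 integer(1))
  expect_true(all(diff(vals) >= 0))
})
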