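hits_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(genome_id = r[[1]], protein_id = r[[2]], enzyme_id = r[[3]],
                   category_id = r[[4]], evidence = "keyword",
                   identity = NA_real_, query_coverage = NA_real_,
                   subject_coverage = NA_real_, score = NA_real_)
  }))
}

test_that("enzyme-mode cells flag genomes with at least one hit", {
  hits <- hits_tbl(list("g1", "p1", "phy", "phytate_degradation"),
                   list("g1", "p2", "tan", "tannin_degradation"),
                   list("g2", "p9", "phy", "phytate_degradation"))
  pm <- build_matrix(hits, c("g1", "g2"), "enzyme")
  expect_equal(pm$cells, matrix(c(1L, 1L, 1L, 0L), 2, byrow = TRUE,
                                dimnames = list(c("g1", "g2"), c("phy", "tan"))))
  expect_error(build_matrix(hits, "g1", "enzyme"), "unknown genome id")
  # empty hit list over 3 genomes -> 3 x 0 matrix
  pm0 <- build_matrix(hits[0, ], c("a", "b", "c"), "enzyme")
  expect_equal(dim(pm0), c(3L, 0L))
})

test_that("cluster-mode features are hit-bearing clusters", {
  hits <- hits_tbl(list("g1", "p1", "phy", "phytate_degradation"),
                   list("g2", "q1", "phy", "phytate_degradation"))
  clusters <- tibble::tibble(cluster_id = c("OC00001", "OC00001", "OC00002"),
                             genome_id = c("g1", "g2", "g2"),
                             protein_id = c("p1", "q1", "q9"))
  pm <- build_matrix(hits, c("g1", "g2"), "cluster", clusters)
  expect_equal(colnames(pm$cells), "OC00001")
  expect_equal(unname(pm$cells[, 1]), c(1L, 1L))
  expect_equal(pm$feature_category$category_id, "phytate_degradation")
  expect_error(build_matrix(hits, c("g1", "g2"), "cluster"),
               "requires a clusters table")
})

test_that("profiles count distinct features per category and coverage", {
  hits <- hits_tbl(list("g1", "p1", "phy", "phytate_degradation"),
                   list("g1", "p2", "tan", "tannin_degradation"),
                   list("g2", "p9", "phy", "phytate_degradation"))
  pm <- build_matrix(hits, c("g1", "g2", "g3"), "enzyme")
  prof <- profiles(pm)
  g1 <- prof[prof$genome_id == "g1", ]
  expect_equal(g1$total_genes, 2L)
  expect_equal(g1$categories_covered, 2L)
  # all-zero row
  g3 <- prof[prof$genome_id == "g3", ]
  expect_equal(g3$total_genes, 0L)
  expect_equal(g3$categories_covered, 0L)
  # total is always the row sum over categories
  expect_equal(prof$total_genes,
               prof$phytate_degradation + prof$tannin_degradation)
})

test_that("a genome with several same-category features counts them all", {
  cells <- matrix(c(1L, 1L, 1L), 1, dimnames = list("g1", c("c1", "c2", "c3")))
  pm <- presence_matrix(cells, tibble::tibble(
    feature_id = c("c1", "c2", "c3"),
    category_id = rep("phytate_degradation", 3)), "cluster")
  prof <- profiles(pm)
  expect_equal(prof$phytate_degradation, 3L)
  expect_equal(prof$categories_covered, 1L)
})

test_that("tally_category equals a brute-force row scan", {
  hits <- hits_tbl(list("g1", "p1", "phy", "phytate_degradation"),
                   list("g1", "p2", "tan", "tannin_degradation"),
                   list("g2", "p9", "phy", "phytate_degradation"))
  pm <- build_matrix(hits, c("g1", "g2"), "enzyme")
  expect_equal(tally_category(pm, "phytate_degradation", 1), 2)
  expect_equal(tally_category(pm, "tannin_degradation", 1), 1)
  expect_error(tally_category(pm, "nope"), "unknown category")
  # random matrix vs direct enumeration
  pm5 <- random_matrix(5, 8, n_categories = 2, seed = 44)
  for (cc in unique(pm5$feature_category$category_id)) {
    cols <- pm5$feature_category$feature_id[pm5$feature_category$category_id == cc]
    for (m in 1:3) {
      manual <- sum(apply(pm5$cells[, cols, drop = FALSE], 1,
                          function(r) sum(r) >= m))
      expect_equal(tally_category(pm5, cc, m), manual)
    }
  }
})

test_that("partition counts clusters by distinct genome span", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c1", "c2", "c3", "c3"),
    genome_id = c("g1", "g2", "g3", "g1", "g1", "g2"),
    protein_id = paste0("p", 1:6))
  part <- partition(clusters, 3)
  expect_equal(part$core_count, 1L)
  expect_equal(part$singleton_count, 1L)
  expect_equal(part$dispensable_count, 1L)
  expect_equal(part$total_clusters, 3L)
  expect_equal(part$core_count + part$singleton_count + part$dispensable_count,
               part$total_clusters)
  # two paralogs from one genome span one genome
  para <- tibble::tibble(cluster_id = "c1", genome_id = c("g1", "g1"),
                         protein_id = c("p1", "p2"))
  expect_equal(partition(para, 2)$singleton_count, 1L)
  expect_error(partition(clusters, 2), "more distinct genomes")
})

test_that("partition conservation holds on random collections", {
  for (seed in c(61, 62, 63)) {
    set.seed(seed)
    n_cl <- sample(5:15, 1)
    clusters <- dplyr::bind_rows(lapply(seq_len(n_cl), function(i) {
      gs <- sample(paste0("g", 1:4), sample(1:4, 1))
      tibble::tibble(cluster_id = sprintf("c%02d", i), genome_id = gs,
                     protein_id = sprintf("c%02d_%s", i, gs))
    }))
    part <- partition(clusters, 4)
    expect_equal(part$core_count + part$singleton_count + part$dispensable_count,
                 part$total_clusters)
    # independent per-cluster span tally
    spans <- tapply(clusters$genome_id, clusters$cluster_id,
                    function(g) length(unique(g)))
    expect_equal(part$core_count, sum(spans == 4))
    expect_equal(part$singleton_count, sum(spans == 1))
  }
})

test_that("gene tables load into cluster-mode matrices for tallying", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    genome_id = c("gA", "gA", "gB"),
    feature_id = c("acc1", "acc2", "acc1"),
    category_id = c("phytate_degradation", "phytate_degradation",
                    "phytate_degradation")), path)
  pm <- read_gene_table(path)
  expect_equal(tally_category(pm, "phytate_degradation", 1), 2)
  expect_equal(tally_category(pm, "phytate_degradation", 2), 1)
  expect_equal(profiles(pm)$total_genes, c(2L, 1L))
})

test_that("tidy() returns the long form of a presence matrix", {
  long <- tidy(toy_matrix())
  expect_equal(nrow(long), 16L)
  expect_equal(sum(long$present), sum(toy_matrix()$cells))
  expect_setequal(names(long), c("genome_id", "feature_id", "category_id",
                                 "present"))
})
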