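test_that("protein FASTA headers split into id and product; stops stripped", {
  path <- tempfile(fileext = ".faa")
  writeLines(c(">p1 3-phytase", "MKT", ">p2", "MQR*"), path)
  g <- read_protein_fasta(path, genome_id = "g1", taxon_group = "X")
  expect_equal(g$protein_id, c("p1", "p2"))
  expect_equal(g$product, c("3-phytase", ""))
  expect_equal(g$sequence, c("MKT", "MQR"))
  expect_equal(unique(g$taxon_group), "X")
})

test_that("FASTA reading rejects duplicates, empties and bad residues", {
  path <- tempfile(fileext = ".faa")
  writeLines(c(">p1 a", "MKT", ">p1 b", "MQR"), path)
  expect_error(read_protein_fasta(path), "duplicate protein id 'p1'")
  writeLines(character(), path)
  expect_error(read_protein_fasta(path), "no FASTA records")
  writeLines(c(">p1 a", "MK2T"), path)
  expect_error(read_protein_fasta(path), "position 3")
})

test_that("FASTA write -> read is idempotent on the internal model", {
  g <- make_genome("gx", c("a", "b"), c(random_aa(30, 1), random_aa(40, 2)),
                   products = c("phytase homolog", ""))
  path <- tempfile(fileext = ".faa")
  write_protein_fasta(g, path)
  back <- read_protein_fasta(path, genome_id = "gx")
  expect_equal(back$protein_id, g$protein_id)
  expect_equal(back$product, g$product)
  expect_equal(back$sequence, g$sequence)
})

gb_fixture <- function() {
  c("LOCUS       TESTCTG              5000 bp    DNA     linear BCT 01-JAN-2020",
    "DEFINITION  Test organism strain T1.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "                     /organism=\"Test organism\"",
    "     CDS             10..48",
    "                     /locus_tag=\"T1_0001\"",
    "                     /protein_id=\"AAA00001.1\"",
    "                     /product=\"tannase\"",
    "                     /translation=\"MKTLLVVAAAQQQ\"",
    "     CDS             complement(100..138)",
    "                     /locus_tag=\"T1_0002\"",
    "                     /translation=\"MNPQRSTVWYAAA\"",
    "//")
}

test_that("GenBank CDS features become protein records with coordinates", {
  path <- tempfile(fileext = ".gbk")
  writeLines(gb_fixture(), path)
  g <- read_genbank(path, taxon_group = "X")
  expect_equal(nrow(g), 2L)
  expect_equal(g$genome_id, rep("TESTCTG", 2))
  expect_equal(g$protein_id, c("AAA00001.1", "T1_0002"))
  expect_equal(g$product, c("tannase", ""))
  expect_equal(g$start, c(10L, 100L))
  expect_equal(g$end, c(48L, 138L))
  expect_equal(g$strand, c("+", "-"))
})

test_that("GenBank without CDS or without ids errors", {
  path <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X 100 bp", "FEATURES             Location/Qualifiers",
               "     source          1..100", "//"), path)
  expect_error(read_genbank(path), "no CDS")
  writeLines(c("LOCUS       X 100 bp", "FEATURES             Location/Qualifiers",
               "     CDS             1..9",
               "                     /translation=\"MKT\"", "//"), path)
  expect_error(read_genbank(path), "lacks both protein_id and locus_tag")
})

write_gff_fixture <- function(gff_lines, fasta_seq) {
  gff <- tempfile(fileext = ".gff3")
  fas <- tempfile(fileext = ".fna")
  writeLines(c("##gff-version 3", gff_lines), gff)
  writeLines(c(">ctg1", fasta_seq), fas)
  list(gff = gff, fasta = fas)
}

test_that("GFF3 CDS translate identically on either strand", {
  fwd <- write_gff_fixture(
    "ctg1\ttest\tCDS\t1\t9\t.\t+\t0\tID=cds1;product=phytase",
    "ATGAAAACC")
  g1 <- read_gff3_with_fasta(fwd$gff, fwd$fasta, genome_id = "g")
  expect_equal(g1$sequence, "MKT")
  expect_equal(g1$product, "phytase")
  # same CDS annotated on the minus strand of the reverse complement
  rev <- write_gff_fixture(
    "ctg1\ttest\tCDS\t1\t9\t.\t-\t0\tID=cds1",
    "GGTTTTCAT")
  g2 <- read_gff3_with_fasta(rev$gff, rev$fasta, genome_id = "g")
  expect_equal(g2$sequence, "MKT")
  expect_equal(g2$strand, "-")
})

test_that("multi-segment CDS concatenate in coordinate order", {
  fx <- write_gff_fixture(
    c("ctg1\ttest\tCDS\t1\t3\t.\t+\t0\tID=cds1",
      "ctg1\ttest\tCDS\t7\t9\t.\t+\t0\tID=cds1"),
    "ATGGGGAAACCC")
  g <- read_gff3_with_fasta(fx$gff, fx$fasta, genome_id = "g")
  # ATG + AAA -> MK, derived by hand
  expect_equal(g$sequence, "MK")
  expect_equal(g$start, 1L)
  expect_equal(g$end, 9L)
})

test_that("GFF3 errors on missing contigs and warns on frame overhang", {
  fx <- write_gff_fixture(
    "ctg2\ttest\tCDS\t1\t6\t.\t+\t0\tID=cds1", "ATGAAA")
  expect_error(read_gff3_with_fasta(fx$gff, fx$fasta), "missing from")
  fx2 <- write_gff_fixture(
    "ctg1\ttest\tCDS\t1\t8\t.\t+\t0\tID=cds1", "ATGAAACCC")
  expect_warning(g <- read_gff3_with_fasta(fx2$gff, fx2$fasta), "truncating")
  expect_equal(g$sequence, "MK")
})

test_that("matrix TSV round-trips cells, categories and mode", {
  pm <- toy_matrix()
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(pm, path)
  back <- read_matrix_tsv(path)
  expect_equal(back$cells, pm$cells)
  expect_equal(back$feature_category, pm$feature_category)
  expect_equal(back$mode, pm$mode)
  # degenerate: zero features still writes a one-column table
  pm0 <- build_matrix(screen_collection(make_genome("g1", "p", random_aa(50, 3)),
                                        tiny_catalog()),
                      c("g1", "g2", "g3"), "enzyme")
  expect_equal(dim(pm0), c(3L, 0L))
  write_matrix_tsv(pm0, path)
  expect_equal(readLines(path), c("genome_id", "g1", "g2", "g3"))
})

test_that("newick output reproduces ultrametric heights when re-parsed", {
  skip_if_not_installed("ape")
  D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- upgma(D)
  expect_equal(write_newick(tree), "((a:0.1,b:0.1):0.2,c:0.3);")
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  ph <- ape::read.tree(path)
  patristic <- cophenetic(ph)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(patristic, cophenetic_distances(tree), tolerance = 1e-10)
})

test_that("two leaves joined at a height serialise with equal branch lengths", {
  D <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(upgma(D)), "(A:0.2,B:0.2);")
  # degenerate single-leaf tree
  leaf <- structure(list(root = list(label = "A", height = 0), labels = "A"),
                    class = "anf_tree")
  expect_equal(write_newick(leaf), "A;")
  # reserved characters are quoted
  leaf$root$label <- "A (x)"
  expect_equal(write_newick(leaf), "'A (x)';")
})
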