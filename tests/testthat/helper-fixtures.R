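# Fixtures are built in code at test time; no binary files.

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# two-category, two-enzyme catalog with deterministic synthetic baits,
# loaded through the public YAML reader so the schema is exercised too
tiny_catalog <- function() {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    version = "test",
    categories = list(
      list(category_id = "phytate_degradation",
           display_name = "Phytate degradation",
           enzymes = list(list(
             enzyme_id = "phy", name = "3-phytase",
             ec_numbers = list("3.1.3.8"),
             product_keywords = list("phytase"),
             reference_proteins = list(list(
               ref_id = "phy_ref", sequence = random_aa(120, seed = 101)))))),
      list(category_id = "tannin_degradation",
           display_name = "Tannin degradation",
           enzymes = list(list(
             enzyme_id = "tan", name = "tannase",
             ec_numbers = list("3.1.1.20"),
             product_keywords = list("tannase"),
             reference_proteins = list(list(
               ref_id = "tan_ref", sequence = random_aa(150, seed = 102)))))))),
    path)
  load_catalog(path)
}

# genome tibble built directly (no file round trip)
make_genome <- function(genome_id, ids, seqs, products = NULL,
                        taxon_group = NA_character_) {
  if (is.null(products)) products <- rep("", length(ids))
  tibble::tibble(genome_id = genome_id, label = genome_id,
                 taxon_group = taxon_group, protein_id = ids,
                 product = products, sequence = seqs,
                 contig = NA_character_, start = NA_integer_,
                 end = NA_integer_, strand = NA_character_)
}

# the 4-genome / 4-feature worked example (features f1,f2 category A; f3,f4 B)
toy_matrix <- function() {
  cells <- rbind(g1 = c(1L, 1L, 0L, 0L), g2 = c(0L, 0L, 1L, 1L),
                 g3 = c(1L, 0L, 1L, 0L), g4 = c(1L, 1L, 1L, 0L))
  colnames(cells) <- c("f1", "f2", "f3", "f4")
  presence_matrix(cells,
                  tibble::tibble(feature_id = c("f1", "f2", "f3", "f4"),
                                 category_id = c("A", "A", "B", "B")),
                  "cluster")
}

random_matrix <- function(n_genomes, n_features, n_categories = 2L,
                          p = 0.4, seed = 1L) {
  set.seed(seed)
  cells <- matrix(rbinom(n_genomes * n_features, 1L, p),
                  n_genomes, n_features,
                  dimnames = list(sprintf("g%02d", seq_len(n_genomes)),
                                  sprintf("f%02d", seq_len(n_features))))
  storage.mode(cells) <- "integer"
  fc <- tibble::tibble(
    feature_id = colnames(cells),
    category_id = sprintf("cat%d", 1L + (seq_len(n_features) %% n_categories)))
  presence_matrix(cells, fc, "cluster")
}
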