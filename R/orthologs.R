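#' Bidirectional best hits between two genomes
#'
#' All-vs-all global alignment between the proteomes of two genomes; a pair
#' (x, y) is reported when y is x's best-scoring partner in B and x is y's
#' best-scoring partner in A, with identity and both coverages at or above the
#' thresholds. Ties are broken by higher identity, then lexicographic protein
#' id, so the best partner is always unique. This reciprocal-best-hit rule is
#' the pipeline's ortholog proxy, standing in for a full ortholog-inference
#' suite.
#'
#' @param genome_a,genome_b genome tibbles, each a single non-empty genome.
#' @param min_identity,min_coverage thresholds applied to candidate pairs.
#' @return tibble: `protein_id_a`, `protein_id_b`, `score`, `identity`.
#' @export
bbh_pairs <- function(genome_a, genome_b, min_identity = 0.40,
                      min_coverage = 0.70) {
  if (!nrow(genome_a) || !nrow(genome_b)) {
    rlang::abort("bbh_pairs requires two non-empty genomes")
  }
  pairs <- all_pairs_scores(genome_a, genome_b) |>
    dplyr::filter(.data$identity >= min_identity,
                  .data$query_coverage >= min_coverage,
                  .data$subject_coverage >= min_coverage)
  if (!nrow(pairs)) {
    return(tibble::tibble(protein_id_a = character(), protein_id_b = character(),
                          score = double(), identity = double()))
  }
  best_ab <- pairs |>
    dplyr::arrange(.data$protein_id_a, dplyr::desc(.data$score),
                   dplyr::desc(.data$identity), .data$protein_id_b) |>
    dplyr::distinct(.data$protein_id_a, .keep_all = TRUE)
  best_ba <- pairs |>
    dplyr::arrange(.data$protein_id_b, dplyr::desc(.data$score),
                   dplyr::desc(.data$identity), .data$protein_id_a) |>
    dplyr::distinct(.data$protein_id_b, .keep_all = TRUE)
  dplyr::inner_join(
    best_ab, best_ba[, c("protein_id_a", "protein_id_b")],
    by = c("protein_id_a", "protein_id_b")) |>
    dplyr::select("protein_id_a", "protein_id_b", "score", "identity") |>
    dplyr::arrange(.data$protein_id_a)
}

all_pairs_scores <- function(genome_a, genome_b) {
  per_b <- lapply(seq_len(nrow(genome_b)), function(j) {
    res <- align_set_to_subject(genome_a$sequence, genome_b$sequence[j])
    res$protein_id_a <- genome_a$protein_id
    res$protein_id_b <- genome_b$protein_id[j]
    res
  })
  dplyr::bind_rows(per_b)
}

#' Ortholog clusters across a genome collection
#'
#' Computes BBH pairs for every genome pair and takes connected components of
#' the union graph (single-linkage clustering); proteins without any BBH edge
#' become singleton clusters. Every protein appears in exactly one cluster.
#' Cluster ids are assigned deterministically (`OC00001`, ... ordered by each
#' component's smallest `genome_id|protein_id` member).
#'
#' @param genomes a genome tibble holding >= 1 genome.
#' @param min_identity,min_coverage BBH thresholds.
#' @return tibble: `cluster_id`, `genome_id`, `protein_id`.
#' @export
cluster_orthologs <- function(genomes, min_identity = 0.40, min_coverage = 0.70) {
  if (!nrow(genomes)) rlang::abort("cluster_orthologs requires >= 1 genome")
  gids <- unique(genomes$genome_id)
  vertex <- paste(genomes$genome_id, genomes$protein_id, sep = "|")
  if (anyDuplicated(vertex)) {
    rlang::abort("duplicate (genome_id, protein_id) in collection")
  }
  edges <- list()
  if (length(gids) > 1L) {
    for (i in seq_len(length(gids) - 1L)) {
      ga <- genomes[genomes$genome_id == gids[i], ]
      for (j in seq((i + 1L), length(gids))) {
        gb <- genomes[genomes$genome_id == gids[j], ]
        bb <- bbh_pairs(ga, gb, min_identity, min_coverage)
        if (nrow(bb)) {
          edges[[length(edges) + 1L]] <- tibble::tibble(
            from = paste(gids[i], bb$protein_id_a, sep = "|"),
            to = paste(gids[j], bb$protein_id_b, sep = "|"))
        }
      }
    }
  }
  edge_df <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(from = character(), to = character())
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = data.frame(name = vertex))
  comp <- igraph::components(g)$membership
  members <- tibble::tibble(
    vertex = names(comp), component = unname(comp),
    genome_id = sub("\\|.*$", "", names(comp)),
    protein_id = sub("^[^|]*\\|", "", names(comp)))
  # deterministic ids: order components by their smallest member vertex
  rank <- members |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(key = min(.data$vertex), .groups = "drop") |>
    dplyr::arrange(.data$key)
  rank$cluster_id <- sprintf("OC%05d", seq_len(nrow(rank)))
  members |>
    dplyr::left_join(rank[, c("component", "cluster_id")], by = "component") |>
    dplyr::select("cluster_id", "genome_id", "protein_id") |>
    dplyr::arrange(.data$cluster_id, .data$genome_id, .data$protein_id)
}
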