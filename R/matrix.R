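#' Binary gene presence/absence matrices
#'
#' A `presence_matrix` is a light S3 wrapper around a binary integer matrix
#' (genomes x features) plus a `feature_category` tibble mapping each feature
#' to its ANF category, and a `mode` flag: `"enzyme"` (features are catalog
#' enzymes; paralogs collapse to one cell) or `"cluster"` (features are
#' ortholog clusters, so paralog copies split by BBH appear as separate
#' features — the representation matching per-gene heatmaps).
#'
#' @name presence_matrix_class
NULL

#' Construct a presence matrix
#'
#' @param cells binary integer matrix with genome ids as rownames and feature
#'   ids as colnames.
#' @param feature_category tibble with `feature_id`, `category_id`.
#' @param mode `"enzyme"` or `"cluster"`.
#' @return a `presence_matrix`.
#' @export
presence_matrix <- function(cells, feature_category, mode) {
  mode <- match.arg(mode, c("enzyme", "cluster"))
  stopifnot(is.matrix(cells), all(cells %in% c(0L, 1L)))
  if (ncol(cells) != nrow(feature_category) ||
      (ncol(cells) && !identical(colnames(cells), feature_category$feature_id))) {
    rlang::abort("feature_category must match matrix columns one-to-one, in order")
  }
  structure(list(cells = cells, feature_category = feature_category, mode = mode),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix [%s-mode]: %d genomes x %d features, %d categories>\n",
              x$mode, nrow(x$cells), ncol(x$cells),
              length(unique(x$feature_category$category_id))))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$cells)

#' Build the binary presence/absence matrix from screen hits
#'
#' In enzyme-mode, `cell(g, e) = 1` iff genome g has at least one hit for
#' enzyme e; features are the enzymes observed in `hits` (sorted). In
#' cluster-mode, features are the ortholog clusters containing at least one
#' hit protein, and `cell(g, c) = 1` iff genome g contributes any member to
#' cluster c. A cluster inherits the category of its member hits; if members
#' disagree (promiscuous keywords), the highest-scoring hit wins and a warning
#' is logged. Genomes with no hits appear as all-zero rows.
#'
#' @param hits hit tibble from [screen_collection()].
#' @param genome_ids ordered character vector of all genome ids (rows).
#' @param mode `"enzyme"` or `"cluster"`.
#' @param clusters cluster tibble from [cluster_orthologs()]; required in
#'   cluster-mode, and every hit protein must belong to some cluster.
#' @return a [presence_matrix].
#' @export
build_matrix <- function(hits, genome_ids, mode = c("enzyme", "cluster"),
                         clusters = NULL) {
  mode <- match.arg(mode)
  unknown <- setdiff(hits$genome_id, genome_ids)
  if (length(unknown)) {
    rlang::abort(sprintf("hit references unknown genome id: %s",
                         paste(unknown, collapse = ", ")))
  }
  if (mode == "enzyme") {
    feats <- sort(unique(hits$enzyme_id))
    fc <- hits |>
      dplyr::distinct(feature_id = .data$enzyme_id, .data$category_id) |>
      dplyr::arrange(.data$feature_id)
    present <- dplyr::distinct(hits, .data$genome_id, feature_id = .data$enzyme_id)
  } else {
    if (is.null(clusters)) rlang::abort("cluster-mode requires a clusters table")
    joined <- dplyr::inner_join(hits, clusters, by = c("genome_id", "protein_id"))
    if (nrow(joined) < nrow(hits)) {
      rlang::abort("some hit proteins belong to no ortholog cluster")
    }
    feats <- sort(unique(joined$cluster_id))
    fc <- joined |>
      dplyr::group_by(feature_id = .data$cluster_id) |>
      dplyr::group_map(function(d, key) {
        cats <- unique(d$category_id)
        if (length(cats) > 1L) {
          rlang::warn(sprintf(
            "cluster %s spans categories (%s); keeping the highest-scoring hit's",
            key$feature_id, paste(cats, collapse = ", ")))
          sc <- ifelse(is.na(d$score), -Inf, d$score)
          ord <- order(-sc, d$category_id)
          cats <- d$category_id[ord[1]]
        }
        tibble::tibble(feature_id = key$feature_id, category_id = cats)
      }) |>
      dplyr::bind_rows() |>
      dplyr::arrange(.data$feature_id)
    present <- clusters |>
      dplyr::filter(.data$cluster_id %in% feats,
                    .data$genome_id %in% genome_ids) |>
      dplyr::distinct(.data$genome_id, feature_id = .data$cluster_id)
  }
  cells <- matrix(0L, nrow = length(genome_ids), ncol = length(feats),
                  dimnames = list(genome_ids, feats))
  if (nrow(present)) {
    cells[cbind(match(present$genome_id, genome_ids),
                match(present$feature_id, feats))] <- 1L
  }
  if (!length(feats)) {
    fc <- tibble::tibble(feature_id = character(), category_id = character())
  }
  presence_matrix(cells, fc, mode)
}

#' Per-genome ANF profiles
#'
#' Counts, for each genome, the distinct features present per ANF category
#' (under the matrix's mode), the total feature count, and the number of
#' categories covered ("the total ANFs the strain can metabolise").
#'
#' @param matrix a [presence_matrix].
#' @return wide tibble: `genome_id`, one count column per category (sorted),
#'   `total_genes`, `categories_covered`.
#' @export
profiles <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  cats <- sort(unique(matrix$feature_category$category_id))
  out <- tibble::tibble(genome_id = rownames(matrix$cells))
  for (cc in cats) {
    cols <- matrix$feature_category$feature_id[
      matrix$feature_category$category_id == cc]
    out[[cc]] <- as.integer(rowSums(
      matrix$cells[, cols, drop = FALSE]))
  }
  counts <- as.matrix(out[, cats, drop = FALSE])
  out$total_genes <- as.integer(if (length(cats)) rowSums(counts) else
    rep(0L, nrow(out)))
  out$categories_covered <- as.integer(if (length(cats)) rowSums(counts > 0) else
    rep(0L, nrow(out)))
  out
}

#' Count genomes carrying a category
#'
#' Number of genomes with at least `min_features` features of the given ANF
#' category — the "n out of N genomes harbor gene(s)" tally.
#'
#' @param matrix a [presence_matrix].
#' @param category_id a category present in the matrix's feature map.
#' @param min_features minimum feature count per genome (default 1, matching
#'   "at least one gene").
#' @return integer count of genomes.
#' @export
tally_category <- function(matrix, category_id, min_features = 1L) {
  stopifnot(inherits(matrix, "presence_matrix"), min_features >= 1L)
  if (!category_id %in% matrix$feature_category$category_id) {
    rlang::abort(sprintf("unknown category '%s' in matrix", category_id))
  }
  cols <- matrix$feature_category$feature_id[
    matrix$feature_category$category_id == category_id]
  sum(rowSums(matrix$cells[, cols, drop = FALSE]) >= min_features)
}

#' Core / dispensable / singleton pan-genome partition
#'
#' Each ortholog cluster is counted by the number of *distinct* genomes it
#' spans: all `n_genomes` makes it core, exactly one makes it a singleton
#' (strain-specific), anything else dispensable. Paralogs from one genome do
#' not inflate the span.
#'
#' @param clusters cluster tibble from [cluster_orthologs()].
#' @param n_genomes number of genomes in the collection.
#' @return one-row tibble: `n_genomes`, `core_count`, `dispensable_count`,
#'   `singleton_count`, `total_clusters`.
#' @export
partition <- function(clusters, n_genomes) {
  if (!nrow(clusters)) {
    return(tibble::tibble(n_genomes = n_genomes, core_count = 0L,
                          dispensable_count = 0L, singleton_count = 0L,
                          total_clusters = 0L))
  }
  span <- clusters |>
    dplyr::distinct(.data$cluster_id, .data$genome_id) |>
    dplyr::count(.data$cluster_id, name = "span")
  if (any(span$span > n_genomes)) {
    rlang::abort("cluster spans more distinct genomes than n_genomes")
  }
  tibble::tibble(
    n_genomes = n_genomes,
    core_count = sum(span$span == n_genomes),
    dispensable_count = sum(span$span > 1L & span$span < n_genomes),
    singleton_count = sum(span$span == 1L),
    total_clusters = nrow(span))
}

#' Build a presence matrix from a plain genome-by-gene table
#'
#' Reads a TSV listing one detected gene per row (`genome_id`, `feature_id`,
#' `category_id`) — the shape of curated supplementary gene tables — and turns
#' it into a cluster-mode [presence_matrix] so [tally_category()] and
#' [profiles()] apply to externally curated screens as well.
#'
#' @param path TSV with columns `genome_id`, `feature_id`, `category_id`.
#' @param genome_ids optional ordered genome universe (defaults to the genomes
#'   in the file, sorted).
#' @return a [presence_matrix].
#' @export
read_gene_table <- function(path, genome_ids = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("genome_id", "feature_id", "category_id")
  if (!all(need %in% names(tab))) {
    rlang::abort(sprintf("gene table %s must have columns: %s", path,
                         paste(need, collapse = ", ")))
  }
  if (is.null(genome_ids)) genome_ids <- sort(unique(tab$genome_id))
  feats <- sort(unique(tab$feature_id))
  fc <- tab |>
    dplyr::distinct(.data$feature_id, .data$category_id) |>
    dplyr::arrange(.data$feature_id)
  if (anyDuplicated(fc$feature_id)) {
    rlang::abort("a feature_id maps to more than one category in the gene table")
  }
  cells <- matrix(0L, length(genome_ids), length(feats),
                  dimnames = list(genome_ids, feats))
  cells[cbind(match(tab$genome_id, genome_ids),
              match(tab$feature_id, feats))] <- 1L
  presence_matrix(cells, fc, "cluster")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a presence matrix into long format
#'
#' @param x a [presence_matrix].
#' @param ... unused.
#' @return long tibble: `genome_id`, `feature_id`, `category_id`, `present`.
#' @method tidy presence_matrix
#' @export
tidy.presence_matrix <- function(x, ...) {
  tibble::as_tibble(x$cells, rownames = "genome_id") |>
    tidyr::pivot_longer(-"genome_id", names_to = "feature_id",
                        values_to = "present") |>
    dplyr::left_join(x$feature_category, by = "feature_id") |>
    dplyr::select("genome_id", "feature_id", "category_id", "present")
}
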