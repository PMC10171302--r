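#' Pipeline orchestration
#'
#' `run_screen()`, `run_cluster()` and `run_select()` chain the package's
#' modules into the three analysis stages — detection + matrix building,
#' gene-content clustering, and consortium selection — writing plain-text
#' artifacts (TSV / Newick / JSON) that the package's own readers re-read.
#' A thin command-line wrapper over these functions ships in
#' `inst/scripts/anfscreen`.
#'
#' @name pipeline
NULL

#' Validate a pipeline run configuration
#'
#' Checks option names and value ranges before any compute; unknown keys are
#' rejected.
#'
#' @param ... configuration entries (`min_identity`, `min_coverage`,
#'   `full_scan`, `mode`, `metric`, `categories`, `k`, `objective`,
#'   `select_mode`, `seed`, `outdir`).
#' @return a validated named list with defaults filled in.
#' @export
run_config <- function(...) {
  defaults <- list(
    min_identity = 0.40, min_coverage = 0.70, full_scan = FALSE,
    mode = "enzyme", metric = "jaccard", categories = NULL,
    k = 3L, objective = "lex", select_mode = "exhaustive",
    seed = 1L, outdir = ".")
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    rlang::abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  stopifnot(cfg$min_identity >= 0, cfg$min_identity <= 1,
            cfg$min_coverage >= 0, cfg$min_coverage <= 1, cfg$k >= 1)
  cfg$mode <- match.arg(cfg$mode, c("enzyme", "cluster"))
  cfg$metric <- match.arg(cfg$metric, c("jaccard", "simple_matching"))
  cfg$objective <- match.arg(cfg$objective, c("lex", "genes"))
  cfg$select_mode <- match.arg(cfg$select_mode, c("exhaustive", "greedy"))
  cfg
}

#' Screen a collection and write all stage-one artifacts
#'
#' Screens every genome against the catalog, builds the presence/absence
#' matrix (and, when requested, the BBH ortholog clusters and the
#' core/dispensable/singleton partition), computes per-genome ANF profiles,
#' and writes `hits.tsv`, `matrix.tsv` (+ feature map), `profiles.tsv`,
#' `partition.json` and `run_report.json` to `outdir`.
#'
#' @param genomes a genome tibble (see [genome_io]). Genomes whose proteins
#'   all have empty sequences are skipped with a warning.
#' @param outdir output directory, created if needed; `NULL` skips writing.
#' @param catalog an [anf_catalog].
#' @param config a [run_config()] list.
#' @param compute_partition also compute ortholog clusters over the full
#'   proteomes and the pan-genome partition (quadratic in collection size;
#'   forced on in cluster-mode).
#' @return list: `hits`, `matrix`, `profiles`, `partition` (or `NULL`),
#'   `clusters` (or `NULL`), invisibly when writing.
#' @export
run_screen <- function(genomes, outdir = NULL, catalog = default_catalog(),
                       config = run_config(), compute_partition = TRUE) {
  if (!nrow(genomes)) rlang::abort("no genomes supplied")
  empty <- !nzchar(genomes$sequence)
  if (any(empty)) {
    bad <- unique(genomes$genome_id[empty])
    rlang::warn(sprintf("skipping empty protein record(s) in genome(s): %s",
                        paste(bad, collapse = ", ")))
    genomes <- genomes[!empty, ]
  }
  gids <- unique(genomes$genome_id)
  hits <- screen_collection(genomes, catalog,
                            min_identity = config$min_identity,
                            min_coverage = config$min_coverage,
                            full_scan = config$full_scan)
  clusters <- NULL; part <- NULL
  if (config$mode == "cluster" || compute_partition) {
    clusters <- cluster_orthologs(genomes, config$min_identity,
                                  config$min_coverage)
    part <- partition(clusters, length(gids))
  }
  pm <- build_matrix(hits, gids, mode = config$mode, clusters = clusters)
  prof <- profiles(pm)
  out <- list(hits = hits, matrix = pm, profiles = prof, partition = part,
              clusters = clusters)
  if (is.null(outdir)) return(out)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_hits_tsv(hits, file.path(outdir, "hits.tsv"))
  write_matrix_tsv(pm, file.path(outdir, "matrix.tsv"))
  readr::write_tsv(prof, file.path(outdir, "profiles.tsv"))
  if (!is.null(part)) {
    jsonlite::write_json(as.list(part), file.path(outdir, "partition.json"),
                         auto_unbox = TRUE)
  }
  report <- list(
    catalog_version = catalog$version,
    config_hash = rlang::hash(config),
    n_genomes = length(gids), n_proteins = nrow(genomes),
    n_hits = nrow(hits), n_features = ncol(pm$cells),
    mode = config$mode)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

#' Cluster genomes by gene content and write tree artifacts
#'
#' UPGMA over binary gene-content distances; writes `tree.nwk` and
#' `heatmap_table.tsv` (matrix rows reordered to leaf order) when `outdir`
#' is given.
#'
#' @param matrix a [presence_matrix] with >= 2 genomes.
#' @param outdir output directory or `NULL`.
#' @param config a [run_config()] list (`metric`, `categories`).
#' @return list: `tree` (an `anf_tree`), `order` (leaf order), invisibly when
#'   writing.
#' @export
run_cluster <- function(matrix, outdir = NULL, config = run_config()) {
  if (nrow(matrix$cells) < 2L) rlang::abort("clustering needs >= 2 genomes")
  D <- distance_matrix(matrix, metric = config$metric,
                       categories = config$categories)
  tree <- upgma(D)
  ord <- leaf_order(tree)
  out <- list(tree = tree, order = ord)
  if (is.null(outdir)) return(out)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_newick(tree, file.path(outdir, "tree.nwk"))
  tab <- tibble::as_tibble(matrix$cells[ord, , drop = FALSE],
                           rownames = "genome_id")
  readr::write_tsv(tab, file.path(outdir, "heatmap_table.tsv"))
  invisible(out)
}

#' Select a consortium and write the JSON report
#'
#' @param matrix a [presence_matrix].
#' @param outdir output directory or `NULL`.
#' @param config a [run_config()] list (`k`, `objective`, `select_mode`).
#' @return the `consortium_solution`, invisibly when writing.
#' @export
run_select <- function(matrix, outdir = NULL, config = run_config()) {
  sol <- if (config$select_mode == "exhaustive") {
    select_exhaustive(matrix, config$k, config$objective)
  } else {
    select_greedy(matrix, config$k, config$objective)
  }
  if (is.null(outdir)) return(sol)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    genome_ids = sol$genome_ids, k = sol$k,
    categories = sol$categories, categories_covered = sol$categories_covered,
    union_gene_count = sol$union_gene_count,
    objective = sol$objective, mode = sol$mode, is_optimal = sol$is_optimal,
    ties = sol$ties)
  jsonlite::write_json(report, file.path(outdir, "consortium.json"),
                       auto_unbox = TRUE)
  invisible(sol)
}
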