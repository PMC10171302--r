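#' Strain-consortium selection
#'
#' Selects k genomes whose combined gene content maximises ANF-elimination
#' capacity: either the lexicographic objective (categories covered first,
#' then distinct genes — covering both the "eight antinutrient factors" and
#' "highest number of genes" readings) or a genes-only objective. Exhaustive
#' mode enumerates every size-k subset (global optimum, ties reported);
#' greedy mode adds the genome with the largest marginal gain and carries the
#' classic (1 - 1/e) max-coverage guarantee.
#'
#' @name consortium
NULL

#' Union gene profile of a genome subset
#'
#' Elementwise OR of the selected rows: the distinct features present in at
#' least one selected genome and the ANF categories they cover.
#'
#' @param matrix a [presence_matrix].
#' @param subset non-empty character vector of genome ids in the matrix.
#' @return list: `categories` (sorted character vector), `n_categories`,
#'   `union_gene_count`.
#' @export
union_profile <- function(matrix, subset) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!length(subset)) rlang::abort("subset must be non-empty")
  unknown <- setdiff(subset, rownames(matrix$cells))
  if (length(unknown)) {
    rlang::abort(sprintf("unknown genome id(s): %s", paste(unknown, collapse = ", ")))
  }
  u <- as.integer(colSums(matrix$cells[unique(subset), , drop = FALSE]) > 0)
  cats <- sort(unique(matrix$feature_category$category_id[u == 1L]))
  list(categories = cats, n_categories = length(cats),
       union_gene_count = sum(u))
}

objective_of <- function(matrix, subset, objective) {
  up <- union_profile(matrix, subset)
  if (objective == "genes") c(up$union_gene_count) else
    c(up$n_categories, up$union_gene_count)
}

obj_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

new_consortium_solution <- function(genome_ids, matrix, objective, mode,
                                    is_optimal, ties = list()) {
  up <- union_profile(matrix, genome_ids)
  structure(list(
    genome_ids = genome_ids,
    k = length(genome_ids),
    categories = up$categories,
    categories_covered = up$n_categories,
    union_gene_count = up$union_gene_count,
    objective = objective,
    objective_value = objective_of(matrix, genome_ids, objective),
    mode = mode, is_optimal = is_optimal, ties = ties),
    class = "consortium_solution")
}

#' @export
print.consortium_solution <- function(x, ...) {
  cat(sprintf("<consortium_solution [%s, %s]: {%s}>\n", x$mode, x$objective,
              paste(x$genome_ids, collapse = ", ")))
  cat(sprintf("  categories covered: %d (%s)\n", x$categories_covered,
              paste(x$categories, collapse = ", ")))
  cat(sprintf("  union gene count:   %d\n", x$union_gene_count))
  cat(sprintf("  optimal: %s; tied alternatives: %d\n", x$is_optimal,
              length(x$ties)))
  invisible(x)
}

#' Exhaustive consortium selection
#'
#' Enumerates all size-k genome subsets and returns the global optimum under
#' the chosen objective. Ties are fully enumerated; the returned set is the
#' lexicographically smallest among them.
#'
#' @param matrix a [presence_matrix].
#' @param k consortium size, `1 <= k <=` number of genomes.
#' @param objective `"lex"` (categories covered, then union genes) or
#'   `"genes"` (union genes only).
#' @param enumeration_cap refuse to enumerate more than this many subsets
#'   (default 2e6); the error directs to [select_greedy()].
#' @return a `consortium_solution` with `is_optimal = TRUE`.
#' @export
select_exhaustive <- function(matrix, k, objective = c("lex", "genes"),
                              enumeration_cap = 2e6) {
  objective <- match.arg(objective)
  ids <- sort(rownames(matrix$cells))
  if (k < 1L || k > length(ids)) rlang::abort("k out of range")
  if (choose(length(ids), k) > enumeration_cap) {
    rlang::abort(sprintf(
      "%.0f subsets exceed the enumeration cap (%g); use select_greedy()",
      choose(length(ids), k), enumeration_cap))
  }
  subsets <- utils::combn(ids, k, simplify = FALSE)
  best_obj <- NULL; ties <- list()
  for (s in subsets) {
    ob <- objective_of(matrix, s, objective)
    if (is.null(best_obj) || obj_gt(ob, best_obj)) {
      best_obj <- ob; ties <- list(s)
    } else if (identical(ob, best_obj)) {
      ties <- c(ties, list(s))
    }
  }
  # combn over sorted ids emits subsets in lexicographic order already
  new_consortium_solution(ties[[1]], matrix, objective, "exhaustive",
                          is_optimal = TRUE, ties = ties[-1])
}

#' Greedy consortium selection
#'
#' Iteratively adds the genome with the largest marginal gain (new categories
#' first, then new genes under `"lex"`; new genes under `"genes"`), breaking
#' ties by lexicographic genome id. Stops early with a message if every
#' remaining genome adds nothing. The result carries the standard greedy
#' max-coverage guarantee of at least (1 - 1/e) of the optimal coverage.
#'
#' @inheritParams select_exhaustive
#' @return a `consortium_solution` with `is_optimal = FALSE`.
#' @export
select_greedy <- function(matrix, k, objective = c("lex", "genes")) {
  objective <- match.arg(objective)
  ids <- sort(rownames(matrix$cells))
  if (k < 1L || k > length(ids)) rlang::abort("k out of range")
  chosen <- character()
  for (step in seq_len(k)) {
    gains <- lapply(setdiff(ids, chosen), function(g) {
      list(g = g, obj = objective_of(matrix, c(chosen, g), objective))
    })
    base <- if (length(chosen)) objective_of(matrix, chosen, objective) else
      rep(0L, if (objective == "genes") 1L else 2L)
    best <- gains[[1]]
    for (cand in gains[-1]) if (obj_gt(cand$obj, best$obj)) best <- cand
    if (!obj_gt(best$obj, base)) {
      rlang::inform(sprintf(
        "greedy selection stopped after %d genome(s): no remaining marginal gain",
        length(chosen)))
      break
    }
    chosen <- c(chosen, best$g)
  }
  new_consortium_solution(chosen, matrix, objective, "greedy",
                          is_optimal = FALSE)
}

#' Tidy a consortium solution
#'
#' One row per selected genome with its marginal contribution in selection
#' order.
#'
#' @param x a `consortium_solution`.
#' @param matrix the [presence_matrix] the solution was computed on.
#' @param ... unused.
#' @return tibble: `genome_id`, `order`, `cumulative_genes`,
#'   `cumulative_categories`, `marginal_genes`.
#' @export
tidy.consortium_solution <- function(x, matrix, ...) {
  rows <- list()
  prev_genes <- 0L
  for (i in seq_along(x$genome_ids)) {
    up <- union_profile(matrix, x$genome_ids[seq_len(i)])
    rows[[i]] <- tibble::tibble(
      genome_id = x$genome_ids[i], order = i,
      cumulative_genes = up$union_gene_count,
      cumulative_categories = up$n_categories,
      marginal_genes = up$union_gene_count - prev_genes)
    prev_genes <- up$union_gene_count
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a consortium solution
#'
#' @param x a `consortium_solution`.
#' @param ... unused.
#' @return one-row tibble: `k`, `mode`, `objective`, `categories_covered`,
#'   `union_gene_count`, `is_optimal`, `n_ties`.
#' @export
glance.consortium_solution <- function(x, ...) {
  tibble::tibble(k = x$k, mode = x$mode, objective = x$objective,
                 categories_covered = x$categories_covered,
                 union_gene_count = x$union_gene_count,
                 is_optimal = x$is_optimal, n_ties = length(x$ties))
}
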