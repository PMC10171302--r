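#' Keyword matching against product annotations
#'
#' A product matches when any keyword is a case-insensitive substring of the
#' whitespace-normalised product description.
#'
#' @param product character vector of product descriptions (may be empty
#'   strings).
#' @param keywords character vector of annotation keywords.
#' @return logical vector, one element per product.
#' @export
#' @examples
#' keyword_match("3-phytase precursor", "phytase")
keyword_match <- function(product, keywords) {
  if (!length(keywords)) return(rep(FALSE, length(product)))
  norm <- tolower(stringr::str_squish(product))
  out <- rep(FALSE, length(norm))
  for (kw in tolower(stringr::str_squish(keywords))) {
    out <- out | stringr::str_detect(norm, stringr::fixed(kw))
  }
  out
}

default_thresholds <- function() list(min_identity = 0.40, min_coverage = 0.70)

#' Screen a genome collection for catalog enzymes
#'
#' For every protein x enzyme pair, keyword evidence is tested first
#' (enzyme keywords against the product annotation); alignment evidence is
#' then tested against the enzyme's reference proteins — keeping the best
#' reference by score, then identity, then `ref_id` — for proteins passing the
#' keyword prefilter (product matches *any* catalog keyword, or is empty), or
#' for all proteins when `full_scan = TRUE`. A hit is emitted when either
#' evidence passes; at most one hit per (protein, enzyme).
#'
#' Homology evidence requires `identity >= min_identity` and both coverages
#' `>= min_coverage`. Keyword-only hits carry `NA` alignment fields.
#'
#' @param genomes a genome tibble (one or many genomes; see [genome_io]).
#' @param catalog an [anf_catalog].
#' @param min_identity,min_coverage homology-evidence thresholds.
#' @param full_scan align every protein against every reference instead of
#'   only keyword-prefiltered ones.
#' @return hit tibble: `genome_id`, `protein_id`, `enzyme_id`, `category_id`,
#'   `evidence` (`"keyword"`, `"homology"` or `"both"`), `identity`,
#'   `query_coverage`, `subject_coverage`, `score`.
#' @export
screen_collection <- function(genomes, catalog,
                              min_identity = 0.40, min_coverage = 0.70,
                              full_scan = FALSE) {
  stopifnot(inherits(catalog, "anf_catalog"))
  empty <- tibble::tibble(
    genome_id = character(), protein_id = character(), enzyme_id = character(),
    category_id = character(), evidence = character(), identity = double(),
    query_coverage = double(), subject_coverage = double(), score = double())
  if (!nrow(genomes)) return(empty)

  enz <- catalog$enzymes
  all_keywords <- unique(unlist(enz$product_keywords))
  kw_any <- keyword_match(genomes$product, all_keywords)
  candidates <- if (full_scan) rep(TRUE, nrow(genomes)) else kw_any | !nzchar(genomes$product)

  hits <- list()
  for (j in seq_len(nrow(enz))) {
    eid <- enz$enzyme_id[j]
    kw_hit <- keyword_match(genomes$product, enz$product_keywords[[j]])
    refs <- catalog$references[catalog$references$enzyme_id == eid, ]
    idx <- which(candidates)
    best <- NULL
    if (nrow(refs) && length(idx)) {
      per_ref <- lapply(seq_len(nrow(refs)), function(k) {
        res <- align_set_to_subject(genomes$sequence[idx], refs$sequence[k])
        res$ref_id <- refs$ref_id[k]
        res$row <- idx
        res
      })
      best <- dplyr::bind_rows(per_ref) |>
        dplyr::arrange(.data$row, dplyr::desc(.data$score),
                       dplyr::desc(.data$identity), .data$ref_id) |>
        dplyr::distinct(.data$row, .keep_all = TRUE)
      best$pass <- best$identity >= min_identity &
        best$query_coverage >= min_coverage &
        best$subject_coverage >= min_coverage
    }
    hom_pass <- rep(FALSE, nrow(genomes))
    if (!is.null(best)) hom_pass[best$row] <- best$pass
    take <- kw_hit | hom_pass
    if (!any(take)) next
    h <- tibble::tibble(
      genome_id = genomes$genome_id[take],
      protein_id = genomes$protein_id[take],
      enzyme_id = eid,
      category_id = enz$category_id[j],
      evidence = dplyr::case_when(
        kw_hit[take] & hom_pass[take] ~ "both",
        hom_pass[take] ~ "homology",
        TRUE ~ "keyword"),
      identity = NA_real_, query_coverage = NA_real_,
      subject_coverage = NA_real_, score = NA_real_)
    if (!is.null(best)) {
      m <- match(which(take), best$row)
      ok <- !is.na(m) & h$evidence != "keyword"
      h$identity[ok] <- best$identity[m[ok]]
      h$query_coverage[ok] <- best$query_coverage[m[ok]]
      h$subject_coverage[ok] <- best$subject_coverage[m[ok]]
      h$score[ok] <- best$score[m[ok]]
    }
    hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) return(empty)
  dplyr::bind_rows(hits) |>
    dplyr::arrange(.data$genome_id, .data$protein_id, .data$enzyme_id)
}

#' Screen a single genome
#'
#' Convenience wrapper around [screen_collection()] for one genome tibble.
#'
#' @inheritParams screen_collection
#' @param genome a genome tibble holding a single `genome_id`.
#' @return a hit tibble (see [screen_collection()]).
#' @export
screen_genome <- function(genome, catalog, min_identity = 0.40,
                          min_coverage = 0.70, full_scan = FALSE) {
  if (length(unique(genome$genome_id)) > 1L) {
    rlang::abort("screen_genome expects a single genome; use screen_collection")
  }
  screen_collection(genome, catalog, min_identity, min_coverage, full_scan)
}

#' Write a hit table as TSV
#'
#' @param hits hit tibble from [screen_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}
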