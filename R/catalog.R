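#' ANF enzyme catalogs
#'
#' An `anf_catalog` describes the antinutritional-factor (ANF) categories the
#' pipeline screens for and, within each category, the enzymes whose genes are
#' sought. Each enzyme carries annotation keywords (matched case-insensitively
#' against product descriptions), optional EC numbers (metadata only — matching
#' never depends on them), and optional reference protein sequences used as
#' alignment baits.
#'
#' The object is a list of three tibbles plus a version string:
#' `$categories` (`category_id`, `display_name`), `$enzymes` (`enzyme_id`,
#' `category_id`, `name`, list-columns `ec_numbers` and `product_keywords`),
#' and `$references` (`enzyme_id`, `ref_id`, `sequence`).
#'
#' @name anf_catalog
NULL

AA_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 20 standard residues plus X (unknown)
aa_valid <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", x)

new_anf_catalog <- function(categories, enzymes, references, version) {
  structure(
    list(categories = categories, enzymes = enzymes,
         references = references, version = version),
    class = "anf_catalog"
  )
}

#' @export
print.anf_catalog <- function(x, ...) {
  cat(sprintf("<anf_catalog v%s: %d categories, %d enzymes, %d reference proteins>\n",
              x$version, nrow(x$categories), nrow(x$enzymes), nrow(x$references)))
  invisible(x)
}

validate_catalog <- function(cat) {
  if (anyDuplicated(cat$categories$category_id)) {
    dup <- cat$categories$category_id[duplicated(cat$categories$category_id)]
    rlang::abort(sprintf("duplicate category_id in catalog: %s",
                         paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(cat$enzymes$enzyme_id)) {
    dup <- cat$enzymes$enzyme_id[duplicated(cat$enzymes$enzyme_id)]
    rlang::abort(sprintf("duplicate enzyme_id in catalog: %s",
                         paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(cat$enzymes$category_id, cat$categories$category_id)
  if (length(bad)) {
    rlang::abort(sprintf("enzyme references unknown category: %s",
                         paste(bad, collapse = ", ")))
  }
  n_kw <- vapply(cat$enzymes$product_keywords, length, integer(1))
  has_ref <- cat$enzymes$enzyme_id %in% cat$references$enzyme_id
  orphan <- cat$enzymes$enzyme_id[n_kw == 0 & !has_ref]
  if (length(orphan)) {
    rlang::abort(sprintf(
      "enzyme(s) with neither product keywords nor reference proteins: %s",
      paste(orphan, collapse = ", ")))
  }
  if (nrow(cat$references)) {
    bad_enz <- setdiff(cat$references$enzyme_id, cat$enzymes$enzyme_id)
    if (length(bad_enz)) {
      rlang::abort(sprintf("reference protein for unknown enzyme: %s",
                           paste(bad_enz, collapse = ", ")))
    }
    bad_seq <- !aa_valid(cat$references$sequence)
    if (any(bad_seq)) {
      rlang::abort(sprintf(
        "reference sequence %s contains letters outside the 20 standard residues + X",
        cat$references$ref_id[bad_seq][1]))
    }
  }
  invisible(cat)
}

catalog_from_list <- function(obj) {
  if (!is.list(obj) || is.null(obj$categories)) {
    rlang::abort("catalog file must contain a top-level 'categories' list")
  }
  version <- as.character(obj$version %||% "unversioned")
  cats <- list(); enzs <- list(); refs <- list()
  for (cc in obj$categories) {
    if (is.null(cc$category_id)) rlang::abort("category without category_id")
    cats[[length(cats) + 1L]] <- tibble::tibble(
      category_id = as.character(cc$category_id),
      display_name = as.character(cc$display_name %||% cc$category_id))
    for (ee in cc$enzymes %||% list()) {
      if (is.null(ee$enzyme_id)) {
        rlang::abort(sprintf("enzyme without enzyme_id in category '%s'",
                             cc$category_id))
      }
      enzs[[length(enzs) + 1L]] <- tibble::tibble(
        enzyme_id = as.character(ee$enzyme_id),
        category_id = as.character(cc$category_id),
        name = as.character(ee$name %||% ee$enzyme_id),
        ec_numbers = list(as.character(unlist(ee$ec_numbers))),
        product_keywords = list(tolower(as.character(unlist(ee$product_keywords)))))
      for (rr in ee$reference_proteins %||% list()) {
        refs[[length(refs) + 1L]] <- tibble::tibble(
          enzyme_id = as.character(ee$enzyme_id),
          ref_id = as.character(rr$ref_id),
          sequence = toupper(gsub("\\s", "", as.character(rr$sequence))))
      }
    }
  }
  empty_refs <- tibble::tibble(enzyme_id = character(), ref_id = character(),
                               sequence = character())
  cat <- new_anf_catalog(
    categories = dplyr::bind_rows(cats),
    enzymes = dplyr::bind_rows(enzs),
    references = if (length(refs)) dplyr::bind_rows(refs) else empty_refs,
    version = version)
  validate_catalog(cat)
  cat
}

#' Load an ANF enzyme catalog from a YAML file
#'
#' The schema is documented in the package README: a top-level `version` and a
#' `categories` list, each category holding `category_id`, `display_name` and
#' an `enzymes` list with `enzyme_id`, `name`, `ec_numbers`,
#' `product_keywords` and optional `reference_proteins`
#' (`ref_id`/`sequence` pairs). Keywords are lower-cased on load; all ids must
#' be unique and every enzyme needs at least one keyword or reference protein.
#'
#' @param path path to a catalog YAML file.
#' @return a validated [anf_catalog] object.
#' @export
#' @examples
#' cat <- load_catalog(system.file("extdata", "anf_catalog_default.yaml",
#'                                 package = "anfscreen"))
#' cat$categories
load_catalog <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("catalog file not found: %s", path))
  obj <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) rlang::abort(
      sprintf("failed to parse catalog '%s': %s", path, conditionMessage(e))))
  catalog_from_list(obj)
}

#' Write a catalog back to YAML
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(cat, f))` compares
#' equal to `cat` field by field.
#'
#' @param catalog an [anf_catalog].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "anf_catalog"))
  cats <- lapply(seq_len(nrow(catalog$categories)), function(i) {
    cid <- catalog$categories$category_id[i]
    enz_rows <- which(catalog$enzymes$category_id == cid)
    enzymes <- lapply(enz_rows, function(j) {
      eid <- catalog$enzymes$enzyme_id[j]
      ref_rows <- which(catalog$references$enzyme_id == eid)
      ee <- list(
        enzyme_id = eid,
        name = catalog$enzymes$name[j],
        ec_numbers = as.list(catalog$enzymes$ec_numbers[[j]]),
        product_keywords = as.list(catalog$enzymes$product_keywords[[j]]))
      if (length(ref_rows)) {
        ee$reference_proteins <- lapply(ref_rows, function(k) {
          list(ref_id = catalog$references$ref_id[k],
               sequence = catalog$references$sequence[k])
        })
      }
      ee
    })
    list(category_id = cid,
         display_name = catalog$categories$display_name[i],
         enzymes = enzymes)
  })
  yaml::write_yaml(list(version = catalog$version, categories = cats), path)
  invisible(path)
}

#' The packaged default ANF catalog
#'
#' Eight ANF categories: phytate degradation (phytase, EC 3.1.3.8 / 3.1.3.26 /
#' 3.1.3.72), myo-inositol metabolism, tannin degradation (tannase), phenolic
#' compound metabolism (phenolic acid decarboxylase and UbiX), lectin,
#' trypsin / trypsin-like protease (EC 3.4.21.4), saponin degradation
#' (beta-glucuronidase) and alpha-galactooligosaccharide degradation
#' (alpha-galactosidase). Reference protein sequences bundled with the catalog
#' are synthetic representative baits (see the file header in
#' `inst/extdata/anf_catalog_default.yaml`).
#'
#' @return an [anf_catalog] with 8 categories.
#' @export
#' @examples
#' default_catalog()
default_catalog <- function() {
  load_catalog(system.file("extdata", "anf_catalog_default.yaml",
                           package = "anfscreen"))
}
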