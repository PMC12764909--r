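#' Normalize an entity identifier
#'
#' Applies the canonical identifier normalization used throughout the
#' package: trim surrounding whitespace, case-fold to lower case, collapse
#' internal whitespace runs to a single space, and drop tokens consisting
#' only of punctuation. Display names keep their original casing; normalized
#' forms are the identity used for matching across source databases.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @examples
#' normalize_id("  E. coli  ")   # "e. coli"
#' normalize_id("Bacteroides")   # "bacteroides"
#' @export
normalize_id <- function(x) {
  x <- trimws(as.character(x))
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    keep <- tok[!grepl("^[[:punct:]]+$", tok) | nchar(tok) == 0]
    paste(keep, collapse = " ")
  }, character(1))
}

#' Construct an entity registry
#'
#' A registry is an ordered set of unique normalized identifiers of one kind
#' (microbe, disease, drug, symptom, gene_family or genome) together with
#' optional display names. Every matrix in the pipeline inherits its row and
#' column order from a registry, which makes all outputs deterministic.
#'
#' @param ids character vector of identifiers (already normalized, or raw if
#'   `normalize = TRUE`); must be unique after normalization.
#' @param kind one of `"microbe"`, `"disease"`, `"drug"`, `"symptom"`,
#'   `"gene_family"`, `"genome"`.
#' @param names optional display names, same length as `ids`.
#' @param normalize normalize `ids` first (default `FALSE`).
#' @param sort order lexicographically instead of keeping insertion order.
#' @return an object of class `entity_registry`.
#' @export
entity_registry <- function(ids, kind, names = NULL, normalize = FALSE,
                            sort = FALSE) {
  kind <- match.arg(kind, c("microbe", "disease", "drug", "symptom",
                            "gene_family", "genome"))
  ids <- as.character(ids)
  if (is.null(names)) names <- ids
  if (length(names) != length(ids)) {
    stop("`names` must have the same length as `ids`")
  }
  if (normalize) ids <- normalize_id(ids)
  if (any(!nzchar(ids))) stop("registry ids must be nonempty after normalization")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate ids in ", kind, " registry: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (sort) {
    o <- order(ids, method = "radix")
    ids <- ids[o]
    names <- names[o]
  }
  structure(list(kind = kind, ids = ids, names = stats::setNames(names, ids)),
            class = "entity_registry")
}

#' Build a registry from raw names seen in edge records
#'
#' First occurrence fixes the display name; order is first-seen (or
#' lexicographic when `sort = TRUE`).
#'
#' @param raw character vector of raw entity names (repeats allowed).
#' @param kind registry kind, see [entity_registry()].
#' @param sort lexicographic ordering flag.
#' @return an `entity_registry`.
#' @export
registry_from_names <- function(raw, kind, sort = FALSE) {
  ids <- normalize_id(raw)
  first <- !duplicated(ids)
  entity_registry(ids[first], kind, names = trimws(raw)[first], sort = sort)
}

#' @export
print.entity_registry <- function(x, ...) {
  cat(sprintf("<entity_registry> kind=%s n=%d\n", x$kind, length(x$ids)))
  cat("  ", paste(utils::head(x$ids, 6), collapse = ", "),
      if (length(x$ids) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.entity_registry <- function(x) length(x$ids)

#' Position of ids in a registry
#'
#' @param reg an `entity_registry`.
#' @param ids identifiers to look up (normalized form).
#' @return integer positions; errors on any unknown id.
#' @export
registry_index <- function(reg, ids) {
  idx <- match(ids, reg$ids)
  if (anyNA(idx)) {
    stop("unknown ", reg$kind, " id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

# internal: check two dimnamed square matrices share a registry ordering
check_same_entities <- function(a, b, what = "similarity matrices") {
  ia <- rownames(a)
  ib <- rownames(b)
  if (is.null(ia) || is.null(ib) || !identical(ia, ib)) {
    extra_a <- setdiff(ia, ib)
    extra_b <- setdiff(ib, ia)
    stop(what, " do not share a registry; only in first: [",
         paste(utils::head(extra_a, 5), collapse = ", "),
         "]; only in second: [",
         paste(utils::head(extra_b, 5), collapse = ", "),
         "]; order must also match")
  }
  invisible(TRUE)
}
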