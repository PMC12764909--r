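# Association edge lists, deduplication, binary incidence matrices, and the
# network writers (SIF / GraphML / TSV) shared by the whole pipeline.

# column dialects of the supported source-database exports; names are the
# canonical roles, values the expected (case-insensitive) header names
.dialects <- list(
  generic       = c(source = "source",   target = "target"),
  hmdad_like    = c(source = "microbe",  target = "disease"),
  disbiome_like = c(source = "organism", target = "disease"),
  mdad_like     = c(source = "microbe",  target = "drug")
)

#' Read an association edge list
#'
#' Parses a tab-separated association export with a header row into edge
#' records. Four header dialects are accepted: `generic` (columns
#' `source`/`target`), `hmdad_like` (`microbe`/`disease`), `disbiome_like`
#' (`organism`/`disease`) and `mdad_like` (`microbe`/`drug`). Optional
#' columns `direction` (`elevated`/`reduced`), `evidence` and `origin` are
#' carried through when present. Identifiers are trimmed; the normalized
#' form (case-folded, whitespace-collapsed, see [normalize_id()]) becomes
#' the id while the original casing is kept as the display name. Windows
#' line endings and trailing blank lines are tolerated.
#'
#' @param path file to read.
#' @param dialect one of `"generic"`, `"hmdad_like"`, `"disbiome_like"`,
#'   `"mdad_like"`.
#' @return a data.frame of class `edge_records` with columns `source_id`,
#'   `target_id`, `source_name`, `target_name`, `direction`, `evidence`,
#'   `origin`.
#' @export
read_association_edges <- function(path, dialect = "generic") {
  dialect <- match.arg(dialect, names(.dialects))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  names(df) <- trimws(names(df))
  lower <- tolower(names(df))
  want <- .dialects[[dialect]]
  for (role in c("source", "target")) {
    if (!(want[[role]] %in% lower)) {
      stop(sprintf("dialect '%s' requires a '%s' column (for the %s role); found: %s",
                   dialect, want[[role]], role, paste(names(df), collapse = ", ")))
    }
  }
  if (nrow(df) == 0) {
    warning("no data rows in ", path)
    return(empty_edge_records())
  }
  col <- function(name, default = NA_character_) {
    i <- match(name, lower)
    if (is.na(i)) rep(default, nrow(df)) else df[[i]]
  }
  src <- trimws(col(want[["source"]]))
  tgt <- trimws(col(want[["target"]]))
  keep <- nzchar(src) & nzchar(tgt)
  src <- src[keep]; tgt <- tgt[keep]
  dir <- tolower(trimws(col("direction")[keep]))
  dir[!dir %in% c("elevated", "reduced")] <- "unknown"
  out <- data.frame(
    source_id = normalize_id(src), target_id = normalize_id(tgt),
    source_name = src, target_name = tgt,
    direction = dir,
    evidence = col("evidence")[keep],
    origin = col("origin", default = dialect)[keep],
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$source_id) | !nzchar(out$target_id))) {
    stop("identifier empty after normalization in ", path)
  }
  class(out) <- c("edge_records", "data.frame")
  out
}

empty_edge_records <- function() {
  out <- data.frame(source_id = character(), target_id = character(),
                    source_name = character(), target_name = character(),
                    direction = character(), evidence = character(),
                    origin = character(), stringsAsFactors = FALSE)
  class(out) <- c("edge_records", "data.frame")
  out
}

#' Make an edge-record table in code
#'
#' @param source,target raw entity names.
#' @param direction,evidence,origin optional annotations (recycled).
#' @return an `edge_records` data.frame.
#' @export
edge_records <- function(source, target, direction = "unknown",
                         evidence = NA_character_, origin = "manual") {
  n <- length(source)
  stopifnot(length(target) == n)
  src <- trimws(source); tgt <- trimws(target)
  out <- data.frame(
    source_id = normalize_id(src), target_id = normalize_id(tgt),
    source_name = src, target_name = tgt,
    direction = rep_len(direction, n),
    evidence = rep_len(evidence, n), origin = rep_len(origin, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("edge_records", "data.frame")
  out
}

#' Remove redundant association records
#'
#' One record per unique (normalized source, normalized target) pair; the
#' first occurrence wins for display names and annotations, and output
#' order is first-seen, so deduplication is deterministic and idempotent.
#'
#' @param edges an `edge_records` data.frame.
#' @return deduplicated `edge_records`.
#' @export
deduplicate <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  key <- paste(edges$source_id, edges$target_id, sep = "\r")
  out <- edges[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write edge records back to TSV
#'
#' @param edges `edge_records`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  df <- data.frame(source = edges$source_name, target = edges$target_name,
                   direction = edges$direction, evidence = edges$evidence,
                   origin = edges$origin, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    df[is.na(df)] <- ""
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Build a binary association matrix
#'
#' Constructs the bipartite incidence matrix Y whose rows are one entity
#' kind (typically microbes) and columns the partner kind (diseases or
#' drugs). Row i of Y is the interaction profile IP of entity i: the binary
#' vector of its known partners. Registries are auto-built from the edges
#' in first-seen order when not supplied.
#'
#' @param edges deduplicated `edge_records`.
#' @param rows,cols optional `entity_registry` objects fixing the axes.
#' @param row_kind,col_kind registry kinds used when auto-building.
#' @param drop_unknown when registries are supplied: drop (with a warning)
#'   edges whose ids are absent instead of erroring (default `FALSE`).
#' @param sort lexicographic registry order for auto-built registries.
#' @return an object of class `assoc_matrix`: list with elements `Y`
#'   (binary matrix with id dimnames), `rows`, `cols` (registries) and
#'   `annotations` (the edge records retained).
#' @export
build_association_matrix <- function(edges, rows = NULL, cols = NULL,
                                     row_kind = "microbe", col_kind = "disease",
                                     drop_unknown = FALSE, sort = FALSE) {
  edges <- deduplicate(edges)
  if (is.null(rows)) {
    rows <- registry_from_names(edges$source_name, row_kind, sort = sort)
  }
  if (is.null(cols)) {
    cols <- registry_from_names(edges$target_name, col_kind, sort = sort)
  }
  known <- edges$source_id %in% rows$ids & edges$target_id %in% cols$ids
  if (!all(known)) {
    bad <- edges[!known, , drop = FALSE]
    ids <- unique(c(setdiff(bad$source_id, rows$ids),
                    setdiff(bad$target_id, cols$ids)))
    if (!drop_unknown) {
      stop("edge id(s) absent from the supplied registries: ",
           paste(utils::head(ids, 10), collapse = ", "))
    }
    warning("dropping ", sum(!known), " edge(s) with unregistered id(s): ",
            paste(utils::head(ids, 5), collapse = ", "))
    edges <- edges[known, , drop = FALSE]
  }
  Y <- matrix(0L, length(rows$ids), length(cols$ids),
              dimnames = list(rows$ids, cols$ids))
  if (nrow(edges)) {
    Y[cbind(match(edges$source_id, rows$ids),
            match(edges$target_id, cols$ids))] <- 1L
  }
  structure(list(Y = Y, rows = rows, cols = cols, annotations = edges),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d %s x %d %s, %d associations\n",
              nrow(x$Y), x$rows$kind, ncol(x$Y), x$cols$kind, sum(x$Y)))
  invisible(x)
}

#' Row and column association counts
#'
#' @param assoc an `assoc_matrix`.
#' @return list with `rows` and `cols` named integer vectors.
#' @export
assoc_marginals <- function(assoc) {
  list(rows = rowSums(assoc$Y), cols = colSums(assoc$Y))
}

# relation name for a (partner kind, status) pair
.relation_name <- function(kind, status) {
  base <- if (kind == "drug") "treats" else "associates"
  if (identical(status, "predicted")) paste0("predicted_", base) else base
}

# internal: flatten an assoc_matrix or triple table into a node/edge list
network_tables <- function(x) {
  if (inherits(x, "assoc_matrix")) {
    idx <- which(x$Y == 1L, arr.ind = TRUE)
    rel <- .relation_name(x$cols$kind, "known")
    if (x$cols$kind == "drug") {
      # drugs act on microbes: drug is the SIF source
      edges <- data.frame(source = colnames(x$Y)[idx[, 2]],
                          relation = rel,
                          target = rownames(x$Y)[idx[, 1]],
                          provenance = "known", stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(source = rownames(x$Y)[idx[, 1]],
                          relation = rel,
                          target = colnames(x$Y)[idx[, 2]],
                          provenance = "known", stringsAsFactors = FALSE)
    }
    o <- order(edges$source, edges$target, method = "radix")
    edges <- edges[o, , drop = FALSE]
    nodes <- data.frame(
      id = c(x$rows$ids, x$cols$ids),
      kind = c(rep(x$rows$kind, length(x$rows$ids)),
               rep(x$cols$kind, length(x$cols$ids))),
      stringsAsFactors = FALSE)
  } else if (inherits(x, "triple_table")) {
    t <- x
    dis <- data.frame(source = t$microbe_id,
                      relation = vapply(t$disease_edge_status,
                                        function(s) .relation_name("disease", s),
                                        character(1)),
                      target = t$disease_id,
                      provenance = t$disease_edge_status,
                      stringsAsFactors = FALSE)
    drg <- data.frame(source = t$drug_id,
                      relation = vapply(t$drug_edge_status,
                                        function(s) .relation_name("drug", s),
                                        character(1)),
                      target = t$microbe_id,
                      provenance = t$drug_edge_status,
                      stringsAsFactors = FALSE)
    edges <- rbind(dis, drg)
    edges <- edges[!duplicated(edges[c("source", "relation", "target")]), ]
    o <- order(edges$source, edges$target, method = "radix")
    edges <- edges[o, , drop = FALSE]
    nodes <- unique(data.frame(
      id = c(t$microbe_id, t$disease_id, t$drug_id),
      kind = rep(c("microbe", "disease", "drug"),
                 each = nrow(t)), stringsAsFactors = FALSE))
    nodes <- nodes[order(nodes$id, method = "radix"), , drop = FALSE]
  } else {
    stop("export_network() accepts an assoc_matrix or a triple_table")
  }
  rownames(edges) <- rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a network file Cytoscape can open
#'
#' Writes an association matrix or a triple table as SIF
#' (`source<TAB>relation<TAB>target`), GraphML (node `kind` and edge
#' `relation`/`provenance` attributes) or a plain TSV edge table whose
#' re-import reproduces the edge set. Relations are `associates` /
#' `treats` for known edges and `predicted_associates` /
#' `predicted_treats` for predicted ones; drugs are written as the source
#' of `treats` edges.
#'
#' @param x an `assoc_matrix` or `triple_table`.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, format = c("sif", "graphml", "tsv"), path) {
  if (is.character(format) && length(format) == 1 &&
      !format %in% c("sif", "graphml", "tsv")) {
    stop("unknown format '", format, "'; supported formats: sif, graphml, tsv")
  }
  format <- match.arg(format)
  nt <- network_tables(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "sif") {
    writeLines(paste(nt$edges$source, nt$edges$relation, nt$edges$target,
                     sep = "\t"), con, sep = "\n")
  } else if (format == "tsv") {
    writeLines(c(
      "source\trelation\ttarget\tprovenance",
      paste(nt$edges$source, nt$edges$relation, nt$edges$target,
            nt$edges$provenance, sep = "\t")), con, sep = "\n")
  } else {
    n <- nt$nodes
    e <- nt$edges
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
      '  <key id="relation" for="edge" attr.name="relation" attr.type="string"/>',
      '  <key id="provenance" for="edge" attr.name="provenance" attr.type="string"/>',
      '  <graph id="G" edgedefault="undirected">',
      sprintf('    <node id="%s"><data key="kind">%s</data></node>',
              xml_escape(n$id), xml_escape(n$kind)),
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="relation">%s</data>',
                     '<data key="provenance">%s</data></edge>'),
              xml_escape(e$source), xml_escape(e$target),
              xml_escape(e$relation), xml_escape(e$provenance)),
      "  </graph>",
      "</graphml>")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read back a TSV network export
#'
#' @param path file written by [export_network()] with `format = "tsv"`.
#' @return data.frame with `source`, `relation`, `target`, `provenance`.
#' @export
read_network_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
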