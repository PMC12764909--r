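# Biological similarity layers: microbe functional similarity from genome
# gene-family content and connectivity, symptom-profile disease similarity
# (TF-IDF weighted cosine), and drug structural similarity (thresholded
# Tanimoto over fingerprint bit vectors).

#' Gene-family data for functional microbe similarity
#'
#' Bundles a genome x gene-family presence/absence table with a weighted
#' functional-association network over the families (STRING-style: edge
#' weight = association confidence in [0, 1]).
#'
#' @param presence binary matrix, genomes as rows, gene families as
#'   columns, with dimnames.
#' @param network data.frame with columns `family_a`, `family_b`, `weight`;
#'   undirected, no self-edges, families must appear in `presence` columns.
#' @return object of class `gene_family_data`.
#' @export
gene_family_data <- function(presence,
                             network = data.frame(family_a = character(),
                                                  family_b = character(),
                                                  weight = numeric())) {
  presence <- as.matrix(presence)
  stopifnot(!is.null(rownames(presence)), !is.null(colnames(presence)))
  if (!all(presence %in% c(0, 1))) stop("presence table must be binary")
  storage.mode(presence) <- "integer"
  req <- c("family_a", "family_b", "weight")
  if (!all(req %in% names(network))) {
    stop("network needs columns family_a, family_b, weight")
  }
  fam <- colnames(presence)
  unknown <- setdiff(c(network$family_a, network$family_b), fam)
  if (length(unknown)) {
    stop("network references unregistered families: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(network$family_a == network$family_b)) stop("self-edges not allowed")
  if (any(network$weight < 0 | network$weight > 1)) {
    stop("network weights must lie in [0, 1]")
  }
  structure(list(
    genomes = entity_registry(rownames(presence), "genome"),
    families = entity_registry(fam, "gene_family"),
    presence = presence,
    network = network[c("family_a", "family_b", "weight")]
  ), class = "gene_family_data")
}

#' Classify gene families for a genome pair
#'
#' Partitions the family registry by presence status in genomes A and B:
#' `shared` (present in both), `A_only`, `B_only`, `absent_both`.
#'
#' @param gfd a `gene_family_data`.
#' @param genome_a,genome_b genome ids.
#' @return named character vector over families with the four class labels.
#' @export
classify_families <- function(gfd, genome_a, genome_b) {
  ia <- registry_index(gfd$genomes, genome_a)
  ib <- registry_index(gfd$genomes, genome_b)
  a <- gfd$presence[ia, ]
  b <- gfd$presence[ib, ]
  cls <- ifelse(a == 1 & b == 1, "shared",
         ifelse(a == 1, "A_only",
         ifelse(b == 1, "B_only", "absent_both")))
  stats::setNames(cls, gfd$families$ids)
}

#' Genome-content similarity index
#'
#' Scores how much of a gene set two genomes agree on. Under the default
#' `"shared_presence"` scoring each family present in both genomes
#' contributes one point; under `"half_weight"` every matched family
#' (present in both or absent from both) contributes half a point. The
#' index is the raw score divided by the number of families in the set, so
#' it lies in [0, 1].
#'
#' @param gfd a `gene_family_data`.
#' @param genome_a,genome_b genome ids.
#' @param scoring `"shared_presence"` (default) or `"half_weight"`.
#' @return list with `raw` (the agreement score) and `index` (raw / number
#'   of families).
#' @export
genome_content_index <- function(gfd, genome_a, genome_b,
                                 scoring = c("shared_presence", "half_weight")) {
  scoring <- match.arg(scoring)
  nfam <- length(gfd$families$ids)
  if (nfam == 0) stop("empty family registry")
  cls <- classify_families(gfd, genome_a, genome_b)
  raw <- if (scoring == "shared_presence") {
    sum(cls == "shared")
  } else {
    0.5 * sum(cls %in% c("shared", "absent_both"))
  }
  list(raw = raw, index = raw / nfam)
}

#' Functional connectivity index
#'
#' The proportion of realized cross-genomic edges — functional-association
#' network edges (weight >= `weight_cutoff`) joining a family exclusive to
#' genome A to one exclusive to genome B — among all |A_only| x |B_only|
#' possible cross pairs. Returns 0 when either exclusive set is empty.
#'
#' @param gfd a `gene_family_data`.
#' @param genome_a,genome_b genome ids.
#' @param weight_cutoff minimum edge confidence for an edge to qualify
#'   (default 0.4, a conventional medium-confidence cutoff).
#' @param denominator `"cross_pairs"` (default, |A_only| x |B_only|) or
#'   `"all_exclusive_pairs"` (all pairs within the union of exclusives).
#' @return numeric in [0, 1].
#' @export
functional_connectivity_index <- function(gfd, genome_a, genome_b,
                                          weight_cutoff = 0.4,
                                          denominator = c("cross_pairs",
                                                          "all_exclusive_pairs")) {
  denominator <- match.arg(denominator)
  stopifnot(weight_cutoff >= 0, weight_cutoff <= 1)
  cls <- classify_families(gfd, genome_a, genome_b)
  a_only <- names(cls)[cls == "A_only"]
  b_only <- names(cls)[cls == "B_only"]
  denom <- if (denominator == "cross_pairs") {
    length(a_only) * length(b_only)
  } else {
    k <- length(a_only) + length(b_only)
    k * (k - 1) / 2
  }
  if (denom == 0) return(0)
  net <- gfd$network
  net <- net[net$weight >= weight_cutoff, , drop = FALSE]
  cross <- (net$family_a %in% a_only & net$family_b %in% b_only) |
           (net$family_a %in% b_only & net$family_b %in% a_only)
  # undirected: count each unordered qualifying pair once
  pairs <- unique(t(apply(net[cross, c("family_a", "family_b"), drop = FALSE],
                          1, sort)))
  num <- if (is.matrix(pairs)) nrow(pairs) else as.integer(length(pairs) > 0)
  num / denom
}

#' Microbe functional similarity matrix (FM)
#'
#' Pairwise functional similarity for a microbe registry whose members map
#' to genomes in the gene-family data. Modes: `"content"` (genome-content
#' index), `"connectivity"` (functional connectivity index) or `"mean"`
#' (their arithmetic mean, the default). The diagonal is set to 1.
#'
#' @param gfd a `gene_family_data`.
#' @param microbes `entity_registry` of microbes, or character ids.
#' @param mode `"mean"`, `"content"` or `"connectivity"`.
#' @param weight_cutoff passed to [functional_connectivity_index()].
#' @param genome_map optional named character vector microbe id -> genome
#'   id; by default microbe ids are used as genome ids directly.
#' @param scoring content-index scoring, see [genome_content_index()].
#' @return symmetric similarity matrix in [0, 1] with microbe-id dimnames
#'   and attribute `mode`.
#' @export
functional_similarity <- function(gfd, microbes,
                                  mode = c("mean", "content", "connectivity"),
                                  weight_cutoff = 0.4, genome_map = NULL,
                                  scoring = "shared_presence") {
  mode <- match.arg(mode)
  ids <- if (inherits(microbes, "entity_registry")) microbes$ids else microbes
  genomes <- if (is.null(genome_map)) stats::setNames(ids, ids) else genome_map
  missing_map <- setdiff(ids, names(genomes))
  if (length(missing_map)) {
    stop("microbe(s) with no genome mapping: ",
         paste(utils::head(missing_map, 5), collapse = ", "))
  }
  unknown <- setdiff(genomes[ids], gfd$genomes$ids)
  if (length(unknown)) {
    stop("microbe genome(s) absent from gene-family data: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  n <- length(ids)
  FM <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) { FM[i, i] <- 1; next }
      ga <- genomes[[ids[i]]]; gb <- genomes[[ids[j]]]
      val <- switch(mode,
        content = genome_content_index(gfd, ga, gb, scoring = scoring)$index,
        connectivity = functional_connectivity_index(gfd, ga, gb, weight_cutoff),
        mean = (genome_content_index(gfd, ga, gb, scoring = scoring)$index +
                functional_connectivity_index(gfd, ga, gb, weight_cutoff)) / 2)
      FM[i, j] <- FM[j, i] <- val
    }
  }
  attr(FM, "mode") <- mode
  FM
}

#' TF-IDF weighting of a disease x symptom table
#'
#' Re-weights raw symptom co-occurrence strengths by the inverse document
#' frequency: out[j, i] = W[j, i] * log(N / n_i) (natural log), where N is
#' the number of diseases and n_i the number of diseases with symptom i.
#' Symptoms present in every disease get weight 0; symptoms present in no
#' disease stay 0 (no log of infinity is taken).
#'
#' @param W nonnegative matrix, diseases as rows, symptoms as columns.
#' @return matrix of the same shape.
#' @export
tfidf_weights <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("symptom weights must be nonnegative")
  N <- nrow(W)
  if (N < 1) stop("need at least one disease")
  n_i <- colSums(W > 0)
  idf <- ifelse(n_i > 0, log(N / n_i), 0)
  sweep(W, 2, idf, "*")
}

#' Symptom-profile disease similarity (SDM)
#'
#' Cosine similarity between the TF-IDF weighted symptom vectors of each
#' disease pair. Diseases whose weighted vector is all-zero get similarity
#' 0 to every other disease and 1 to themselves.
#'
#' @param W nonnegative disease x symptom matrix with disease row names.
#' @return symmetric similarity matrix in [0, 1] with disease dimnames.
#' @export
symptom_similarity <- function(W) {
  W <- as.matrix(W)
  D <- tfidf_weights(W)
  nrm <- sqrt(rowSums(D^2))
  S <- tcrossprod(D)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, S / denom, 0)
  S[S > 1] <- 1; S[S < 0] <- 0
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(W), rownames(W))
  S
}

#' Tanimoto coefficient between fingerprint bit vectors
#'
#' |a AND b| / |a OR b|; defined as 0 when both vectors are all-zero.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return numeric in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  if (length(a) < 1) stop("fingerprints must have length >= 1")
  a <- as.integer(a != 0); b <- as.integer(b != 0)
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Drug structural similarity matrix (DS)
#'
#' Pairwise Tanimoto coefficients over fingerprint bit vectors, with
#' sub-threshold entries set to 0 (default threshold 0.8) so the nonzero
#' entries mark accepted structural matches for downstream conditional
#' fusion. The diagonal is 1 for drugs with a fingerprint; drugs absent
#' from the fingerprint table get an all-zero row and column.
#'
#' @param fingerprints named list or 0/1 matrix (drugs as rows) of equal
#'   length bit vectors.
#' @param threshold minimum Tanimoto similarity retained (default 0.8).
#' @param drugs optional `entity_registry` (or id vector) fixing the axis;
#'   defaults to the fingerprinted drugs.
#' @return symmetric matrix with drug-id dimnames and attribute `threshold`.
#' @export
structural_similarity <- function(fingerprints, threshold = 0.8, drugs = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.matrix(fingerprints)) {
    FP <- fingerprints
  } else {
    lens <- lengths(fingerprints)
    if (length(unique(lens)) > 1) {
      stop("mixed fingerprint lengths: ",
           paste(sort(unique(lens)), collapse = ", "))
    }
    FP <- do.call(rbind, fingerprints)
    rownames(FP) <- names(fingerprints)
  }
  storage.mode(FP) <- "integer"
  ids <- if (is.null(drugs)) rownames(FP)
         else if (inherits(drugs, "entity_registry")) drugs$ids else drugs
  n <- length(ids)
  DS <- matrix(0, n, n, dimnames = list(ids, ids))
  have <- intersect(ids, rownames(FP))
  if (length(have)) {
    P <- FP[have, , drop = FALSE]
    inter <- tcrossprod(P)
    cnt <- rowSums(P)
    un <- outer(cnt, cnt, "+") - inter
    Tm <- ifelse(un > 0, inter / un, 0)
    Tm[Tm < threshold] <- 0
    DS[have, have] <- Tm
    diag(DS)[match(have, ids)] <- 1
  }
  DS <- (DS + t(DS)) / 2
  attr(DS, "threshold") <- threshold
  DS
}

#' Read a fingerprint table
#'
#' TSV with columns `drug` and `bits` (a string of 0/1 characters).
#'
#' @param path input file.
#' @return named list of integer bit vectors.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("drug", "bits") %in% names(df))) {
    stop("fingerprint table needs columns 'drug' and 'bits'")
  }
  fps <- lapply(df$bits, function(s) {
    v <- as.integer(strsplit(s, "")[[1]])
    if (anyNA(v) || any(!v %in% c(0L, 1L))) stop("bits must be 0/1 characters")
    v
  })
  stats::setNames(fps, normalize_id(df$drug))
}

#' Write a fingerprint table
#'
#' @param fingerprints named list of 0/1 vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("drug\tbits",
               paste(names(fingerprints),
                     vapply(fingerprints, paste, character(1), collapse = ""),
                     sep = "\t")), con, sep = "\n")
  invisible(path)
}
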