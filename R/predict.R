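# Neighbor-vote link prediction and disease-microbe-drug triple extraction.
# The inference rule: if microbe X is similar to microbes X_1..X_n and X is
# linked to a disease or drug L, then X_1..X_n are candidate partners of L,
# each vote weighted by similarity.

# internal: dense score matrix over all (microbe, partner) cells.
# Sf = similarity with the diagonal removed and sub-floor entries zeroed.
score_matrix <- function(S, Y, mode = c("weighted_sum", "weighted_mean", "max"),
                         similarity_floor = 0) {
  mode <- match.arg(mode)
  stopifnot(similarity_floor >= 0, similarity_floor <= 1)
  Sf <- as.matrix(S)
  diag(Sf) <- 0
  Sf[Sf < similarity_floor] <- 0
  if (mode == "weighted_sum") {
    SC <- Sf %*% Y
  } else if (mode == "weighted_mean") {
    rs <- rowSums(Sf)
    SC <- Sf %*% Y
    pos <- rs > 0
    SC[pos, ] <- SC[pos, , drop = FALSE] / rs[pos]
    SC[!pos, ] <- 0
  } else {
    SC <- matrix(0, nrow(Y), ncol(Y))
    for (l in seq_len(ncol(Y))) {
      assoc <- Y[, l] == 1
      if (any(assoc)) {
        SC[, l] <- apply(Sf[, assoc, drop = FALSE], 1, max)
      }
    }
  }
  dimnames(SC) <- list(rownames(Y), colnames(Y))
  SC
}

#' Similarity-weighted neighbor score of one (microbe, partner) pair
#'
#' Scores the association of microbe i with partner l from the known
#' associations of i's similar neighbors (self always excluded):
#' `weighted_sum` = sum over j != i of S[i,j] * Y[j,l]; `weighted_mean`
#' divides that by sum over j != i of S[i,j]; `max` is the largest
#' similarity to an associated neighbor (0 if none). Known pairs
#' (Y[i,l] = 1) are scored the same way but flagged.
#'
#' @param S integrated microbe similarity matrix.
#' @param Y `assoc_matrix` (microbes x partners) or a binary matrix sharing
#'   the microbe registry with `S`.
#' @param microbe,partner entity ids (or indices).
#' @param mode scoring mode (default `"weighted_sum"`).
#' @param similarity_floor neighbors below this similarity contribute
#'   nothing (default 0).
#' @return list with `score` and `known` (logical).
#' @export
neighbor_score <- function(S, Y, microbe, partner,
                           mode = "weighted_sum", similarity_floor = 0) {
  Ym <- if (inherits(Y, "assoc_matrix")) Y$Y else as.matrix(Y)
  check_same_entities(S, Ym, "microbe similarity and association matrix")
  i <- if (is.character(microbe)) match(microbe, rownames(Ym)) else microbe
  l <- if (is.character(partner)) match(partner, colnames(Ym)) else partner
  if (is.na(i) || is.na(l)) stop("unknown microbe or partner id")
  SC <- score_matrix(S, Ym, mode, similarity_floor)
  list(score = SC[i, l], known = Ym[i, l] == 1)
}

#' Rank unobserved association candidates
#'
#' Scores every (microbe, partner) cell with Y = 0 by neighbor voting and
#' returns the top candidates in deterministic order: score descending,
#' then partner id, then microbe id. Each returned candidate lists its
#' supporting neighbors (associated microbes at or above the similarity
#' floor) as `id=similarity` pairs.
#'
#' @param S integrated microbe similarity matrix.
#' @param Y `assoc_matrix`, microbes x partners.
#' @param top_k number of candidates returned (default all).
#' @param similarity_floor minimum neighbor similarity in [0, 1].
#' @param mode scoring mode, see [neighbor_score()].
#' @return data.frame of class `candidate_table` with columns `microbe_id`,
#'   `partner_id`, `partner_kind`, `score`, `rank`,
#'   `supporting_neighbors`.
#' @export
rank_candidates <- function(S, Y, top_k = Inf, similarity_floor = 0,
                            mode = "weighted_sum") {
  partner_kind <- if (inherits(Y, "assoc_matrix")) Y$cols$kind else "disease"
  Ym <- if (inherits(Y, "assoc_matrix")) Y$Y else as.matrix(Y)
  check_same_entities(S, Ym, "microbe similarity and association matrix")
  SC <- score_matrix(S, Ym, mode, similarity_floor)
  cand <- which(Ym == 0, arr.ind = TRUE)
  df <- data.frame(
    microbe_id = rownames(Ym)[cand[, 1]],
    partner_id = colnames(Ym)[cand[, 2]],
    partner_kind = partner_kind,
    score = SC[cand],
    stringsAsFactors = FALSE
  )
  o <- order(-df$score, df$partner_id, df$microbe_id, method = "radix")
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (is.finite(top_k)) df <- df[seq_len(min(top_k, nrow(df))), , drop = FALSE]
  Sf <- as.matrix(S); diag(Sf) <- 0; Sf[Sf < similarity_floor] <- 0
  df$supporting_neighbors <- vapply(seq_len(nrow(df)), function(r) {
    i <- df$microbe_id[r]; l <- df$partner_id[r]
    j <- which(Ym[, l] == 1 & Sf[i, ] > 0)
    if (!length(j)) return("")
    nb <- rownames(Ym)[j]
    ordn <- order(-Sf[i, j], nb, method = "radix")
    paste(sprintf("%s=%.6g", nb[ordn], Sf[i, j][ordn]), collapse = ";")
  }, character(1))
  rownames(df) <- NULL
  class(df) <- c("candidate_table", "data.frame")
  df
}

#' Extract disease-microbe-drug triples through shared microbes
#'
#' For every microbe, crosses its disease partners (known associations
#' plus predicted candidates scoring at or above `threshold`) with its
#' drug partners (same rule), yielding one triple per (disease, microbe,
#' drug) combination with the status of each edge. Ordering is
#' deterministic: microbe, then disease, then drug id.
#'
#' @param md `assoc_matrix` microbes x diseases.
#' @param mr `assoc_matrix` microbes x drugs (same microbe registry).
#' @param predicted_md,predicted_mr optional `candidate_table`s of
#'   predicted links (from [rank_candidates()]).
#' @param threshold minimum predicted score for an edge to enter a triple.
#' @return data.frame of class `triple_table` with columns `disease_id`,
#'   `microbe_id`, `drug_id`, `disease_edge_status`, `drug_edge_status`,
#'   `disease_score`, `drug_score` (NA for known edges).
#' @export
extract_triples <- function(md, mr, predicted_md = NULL, predicted_mr = NULL,
                            threshold = 0) {
  if (!identical(rownames(md$Y), rownames(mr$Y))) {
    stop("association matrices do not share the microbe registry")
  }
  partner_set <- function(assoc, pred, m) {
    known <- colnames(assoc$Y)[assoc$Y[m, ] == 1]
    out <- data.frame(id = known,
                      status = rep("known", length(known)),
                      score = rep(NA_real_, length(known)),
                      stringsAsFactors = FALSE)
    if (!is.null(pred)) {
      p <- pred[pred$microbe_id == m & pred$score >= threshold &
                  pred$score > 0, , drop = FALSE]
      p <- p[!p$partner_id %in% known, , drop = FALSE]
      if (nrow(p)) {
        out <- rbind(out, data.frame(id = p$partner_id, status = "predicted",
                                     score = p$score, stringsAsFactors = FALSE))
      }
    }
    out
  }
  res <- list()
  for (m in rownames(md$Y)) {
    dis <- partner_set(md, predicted_md, m)
    drg <- partner_set(mr, predicted_mr, m)
    if (!nrow(dis) || !nrow(drg)) next
    grid <- expand.grid(di = seq_len(nrow(dis)), dr = seq_len(nrow(drg)))
    res[[m]] <- data.frame(
      disease_id = dis$id[grid$di], microbe_id = m, drug_id = drg$id[grid$dr],
      disease_edge_status = dis$status[grid$di],
      drug_edge_status = drg$status[grid$dr],
      disease_score = dis$score[grid$di], drug_score = drg$score[grid$dr],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    disease_id = character(), microbe_id = character(), drug_id = character(),
    disease_edge_status = character(), drug_edge_status = character(),
    disease_score = numeric(), drug_score = numeric(),
    stringsAsFactors = FALSE)
  o <- order(out$microbe_id, out$disease_id, out$drug_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triple_table", "data.frame")
  out
}

#' Write a candidate or triple table to TSV
#'
#' @param x `candidate_table` or `triple_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", formatC(v, format = "g", digits = 10)))
  df[is.na(df)] <- ""
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) writeLines(do.call(paste, c(unname(df), sep = "\t")), con,
                           sep = "\n")
  invisible(path)
}
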