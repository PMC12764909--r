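mk_sim <- function(vals, ids) matrix(vals, length(ids), length(ids),
                                     dimnames = list(ids, ids))

test_that("neighbor scores match hand-evaluated single-neighbor cases", {
  ids <- c("m1", "m2", "m3")
  S <- mk_sim(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), ids)
  Y <- matrix(c(0, 1, 0), 3, 1, dimnames = list(ids, "d1"))
  # one associated neighbor at similarity 0.9
  expect_equal(neighbor_score(S, Y, "m1", "d1")$score, 0.9)
  expect_false(neighbor_score(S, Y, "m1", "d1")$known)
  expect_true(neighbor_score(S, Y, "m2", "d1")$known)
  # no associated neighbors -> 0 under every mode
  for (mode in c("weighted_sum", "weighted_mean", "max")) {
    expect_equal(neighbor_score(S, Y, "m3", "d1", mode = mode)$score, 0)
  }
  # uniform similarity over two neighbors, one associated: weighted_mean 0.5
  S2 <- mk_sim(c(1, 0.4, 0.4, 0.4, 1, 0, 0.4, 0, 1), ids)
  expect_equal(neighbor_score(S2, Y, "m1", "d1", mode = "weighted_mean")$score,
               0.5)
})

test_that("scores match the brute-force oracle across modes and floors", {
  set.seed(55)
  for (rep in 1:4) {
    n <- 8; m <- 5
    ids <- paste0("m", 1:n)
    S <- matrix(runif(n * n), n, n); S <- (S + t(S)) / 2; diag(S) <- 1
    dimnames(S) <- list(ids, ids)
    Y <- random_assoc(n, m)
    rownames(Y) <- ids
    for (mode in c("weighted_sum", "weighted_mean", "max")) {
      for (floor in c(0, 0.5)) {
        got <- neighbor_score(S, Y, 3, 2, mode = mode,
                              similarity_floor = floor)$score
        expect_equal(got, brute_neighbor_score(S, Y, 3, 2, mode, floor))
      }
    }
  }
})

test_that("score monotonicity, bounds, and isolated-microbe invariance", {
  set.seed(65)
  n <- 6
  ids <- paste0("m", 1:n)
  S <- matrix(runif(n * n, 0.1, 0.9), n, n); S <- (S + t(S)) / 2; diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  Y <- random_assoc(n, 4)
  rownames(Y) <- ids
  Y[2, 1] <- 1L
  l <- 1
  base <- neighbor_score(S, Y, 1, l)$score
  S_up <- S; S_up[1, 2] <- S_up[2, 1] <- min(1, S[1, 2] + 0.3)
  expect_gte(neighbor_score(S_up, Y, 1, l)$score, base)
  # bounds
  for (i in 1:n) for (ll in 1:4) {
    expect_lte(neighbor_score(S, Y, i, ll, mode = "weighted_mean")$score, 1)
    expect_lte(neighbor_score(S, Y, i, ll, mode = "max")$score, 1)
    expect_lte(neighbor_score(S, Y, i, ll)$score, sum(S[i, -i]) + 1e-12)
  }
  # appending an isolated microbe changes nothing
  S_big <- rbind(cbind(S, 0), 0); diag(S_big) <- 1
  dimnames(S_big) <- list(c(ids, "m_iso"), c(ids, "m_iso"))
  Y_big <- rbind(Y, m_iso = 0)
  cand <- rank_candidates(S, Y)
  cand_big <- rank_candidates(S_big, Y_big)
  keep <- cand_big$microbe_id != "m_iso"
  expect_equal(cand_big$score[keep][order(cand_big$microbe_id[keep],
                                          cand_big$partner_id[keep])],
               cand$score[order(cand$microbe_id, cand$partner_id)])
})

test_that("candidate ranking excludes known pairs and is deterministically ordered", {
  set.seed(85)
  ids <- paste0("m", 1:6)
  S <- matrix(runif(36, 0.1, 0.95), 6, 6); S <- (S + t(S)) / 2; diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  Y <- random_assoc(6, 4)
  rownames(Y) <- ids
  cand <- rank_candidates(S, Y)
  expect_equal(nrow(cand), sum(Y == 0))
  expect_equal(cand$rank, seq_len(nrow(cand)))
  known <- paste(rep(rownames(Y), ncol(Y)), rep(colnames(Y), each = nrow(Y)))
  expect_false(any(paste(cand$microbe_id, cand$partner_id) %in%
                     known[as.vector(Y) == 1]))
  # deterministic order: score desc then partner then microbe
  o <- order(-cand$score, cand$partner_id, cand$microbe_id, method = "radix")
  expect_equal(o, seq_len(nrow(cand)))
  # ranking equals brute-force re-scoring
  brute <- vapply(seq_len(nrow(cand)), function(r) {
    brute_neighbor_score(S, Y, match(cand$microbe_id[r], ids),
                         match(cand$partner_id[r], colnames(Y)))
  }, numeric(1))
  expect_equal(cand$score, brute)
  # top_k larger than the candidate count returns everything
  expect_equal(nrow(rank_candidates(S, Y, top_k = 10000)), sum(Y == 0))
  # a floor above every off-diagonal similarity empties the table of support
  cand_f <- rank_candidates(S, Y, similarity_floor = 1)
  expect_true(all(cand_f$score == 0))
  expect_true(all(cand_f$supporting_neighbors == ""))
})

test_that("a held-out within-block edge ranks first on a planted two-clique network", {
  ids <- paste0("m", 1:6)
  S <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  S[1:3, 1:3] <- 0.95; S[4:6, 4:6] <- 0.95; diag(S) <- 1
  Y <- matrix(0L, 6, 2, dimnames = list(ids, c("d1", "d2")))
  Y[1:3, "d1"] <- 1L; Y[4:6, "d2"] <- 1L
  Y[1, "d1"] <- 0L  # hold out one within-block edge
  cand <- rank_candidates(S, Y)
  expect_equal(cand$microbe_id[1], "m1")
  expect_equal(cand$partner_id[1], "d1")
  expect_match(cand$supporting_neighbors[1], "m2=0.95")
})

test_that("triples are the cross product of qualifying disease and drug partners", {
  ids <- c("m1", "m2")
  mkA <- function(Y, kind) structure(
    list(Y = Y, rows = entity_registry(rownames(Y), "microbe"),
         cols = entity_registry(colnames(Y), kind),
         annotations = empty_edge_records()), class = "assoc_matrix")
  Ymd <- matrix(c(1, 0, 1, 0), 2, 2, dimnames = list(ids, c("d1", "d2")))
  Ymr <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3,
                dimnames = list(ids, c("r1", "r2", "r3")))
  md <- mkA(Ymd, "disease"); mr <- mkA(Ymr, "drug")
  t0 <- extract_triples(md, mr)
  # m1 has 2 diseases x 3 drugs; m2 none
  expect_equal(nrow(t0), 6)
  expect_true(all(t0$microbe_id == "m1"))
  expect_true(all(t0$disease_edge_status == "known"))
  # single known-known pair
  md1 <- mkA(Ymd[, 1, drop = FALSE], "disease")
  mr1 <- mkA(Ymr[, 1, drop = FALSE], "drug")
  t1 <- extract_triples(md1, mr1)
  expect_equal(nrow(t1), 1)
  # predicted edges enter only at or above the threshold
  pred <- data.frame(microbe_id = "m2", partner_id = "d2",
                     partner_kind = "disease", score = 0.4, rank = 1,
                     supporting_neighbors = "", stringsAsFactors = FALSE)
  class(pred) <- c("candidate_table", "data.frame")
  predr <- data.frame(microbe_id = "m2", partner_id = "r2",
                      partner_kind = "drug", score = 0.9, rank = 1,
                      supporting_neighbors = "", stringsAsFactors = FALSE)
  class(predr) <- c("candidate_table", "data.frame")
  t2 <- extract_triples(md, mr, pred, predr, threshold = 0.3)
  m2_rows <- t2[t2$microbe_id == "m2", ]
  expect_equal(nrow(m2_rows), 1)
  expect_equal(m2_rows$disease_edge_status, "predicted")
  expect_equal(m2_rows$drug_edge_status, "predicted")
  # threshold above all predicted scores leaves only known-known triples
  t3 <- extract_triples(md, mr, pred, predr, threshold = 0.95)
  expect_true(all(t3$disease_edge_status == "known" &
                    t3$drug_edge_status == "known"))
  expect_equal(nrow(t3), 6)
  # registry mismatch errors
  bad <- mkA(matrix(0L, 1, 1, dimnames = list("mX", "r1")), "drug")
  expect_error(extract_triples(md, bad), "microbe registry")
})

test_that("candidate and triple tables serialize to TSV and read back", {
  ids <- paste0("m", 1:4)
  S <- mk_sim(rep(0.5, 16), ids); diag(S) <- 1
  Y <- random_assoc(4, 3)
  rownames(Y) <- ids
  cand <- rank_candidates(S, Y, top_k = 5)
  f <- tempfile(fileext = ".tsv")
  write_table_tsv(cand, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(cand))
  expect_equal(back$score, cand$score, tolerance = 1e-9)
})
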