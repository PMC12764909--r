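test_that("family classification reads off the presence table", {
  pres <- rbind(A = c(1, 1, 0), B = c(1, 0, 1))
  colnames(pres) <- c("f1", "f2", "f3")
  gfd <- gene_family_data(pres)
  cls <- classify_families(gfd, "A", "B")
  expect_equal(unname(cls), c("shared", "A_only", "B_only"))
  # identical genomes: nothing exclusive
  cls2 <- classify_families(gfd, "A", "A")
  expect_false(any(cls2 %in% c("A_only", "B_only")))
  expect_error(classify_families(gfd, "A", "Z"), "unknown genome")
})

test_that("worked-example toy gene set scores 2 raw, index 0.33", {
  gfd <- toy_gene_set()
  cls <- classify_families(gfd, "A", "B")
  expect_equal(sum(cls == "shared"), 2)
  expect_equal(sum(cls == "absent_both"), 2)
  expect_equal(sum(cls == "A_only"), 1)
  expect_equal(sum(cls == "B_only"), 1)
  gc <- genome_content_index(gfd, "A", "B")
  expect_equal(gc$raw, 2)
  expect_equal(round(gc$index, 2), 0.33)
  # half-weight matched scoring reproduces the same numbers on this toy
  gh <- genome_content_index(gfd, "A", "B", scoring = "half_weight")
  expect_equal(gh$raw, 2)
  expect_equal(round(gh$index, 2), 0.33)
})

test_that("content index identity and zero cases", {
  pres <- rbind(A = c(1, 1, 1), B = c(1, 1, 1), C = c(0, 0, 0))
  colnames(pres) <- paste0("f", 1:3)
  gfd <- gene_family_data(pres)
  expect_equal(genome_content_index(gfd, "A", "B")$index, 1)
  z <- genome_content_index(gfd, "A", "C")
  expect_equal(z$raw, 0)
  expect_equal(z$index, 0)
})

test_that("connectivity index counts qualifying cross edges over cross pairs", {
  pres <- rbind(A = c(1, 1, 1, 1, 0, 0, 1),
                B = c(1, 0, 0, 0, 1, 1, 1))
  colnames(pres) <- paste0("f", 1:7)
  # A_only = f2,f3,f4 (3); B_only = f5,f6 (2)
  net <- data.frame(family_a = c("f2", "f3", "f2", "f1"),
                    family_b = c("f5", "f6", "f6", "f5"),
                    weight = c(0.9, 0.8, 0.2, 0.9))
  gfd <- gene_family_data(pres, net)
  # f2-f5 and f3-f6 qualify; f2-f6 below cutoff; f1-f5 not cross-exclusive
  expect_equal(functional_connectivity_index(gfd, "A", "B", 0.4), 2 / 6)
  # no cross edges
  gfd0 <- gene_family_data(pres)
  expect_equal(functional_connectivity_index(gfd0, "A", "B", 0.4), 0)
  # single saturating pair
  pres1 <- rbind(A = c(1, 0), B = c(0, 1))
  colnames(pres1) <- c("a1", "b1")
  gfd1 <- gene_family_data(pres1, data.frame(family_a = "a1", family_b = "b1",
                                             weight = 0.9))
  expect_equal(functional_connectivity_index(gfd1, "A", "B", 0.4), 1)
})

test_that("connectivity index matches brute-force enumeration on random data", {
  set.seed(21)
  for (rep in 1:8) {
    nf <- sample(4:12, 1)
    fam <- paste0("f", seq_len(nf))
    pres <- matrix(as.integer(runif(2 * nf) < 0.5), 2, nf,
                   dimnames = list(c("A", "B"), fam))
    pairs <- t(combn(fam, 2))
    keep <- runif(nrow(pairs)) < 0.5
    net <- data.frame(family_a = pairs[keep, 1], family_b = pairs[keep, 2],
                      weight = round(runif(sum(keep)), 2),
                      stringsAsFactors = FALSE)
    gfd <- gene_family_data(pres, net)
    expect_equal(functional_connectivity_index(gfd, "A", "B", 0.4),
                 brute_connectivity(pres, net, "A", "B", 0.4))
  }
})

test_that("functional similarity combines modes and is permutation-equivariant", {
  set.seed(5)
  nf <- 10
  fam <- paste0("f", 1:nf)
  ids <- paste0("m", 1:4)
  pres <- matrix(as.integer(runif(4 * nf) < 0.5), 4, nf,
                 dimnames = list(ids, fam))
  pairs <- t(combn(fam, 2))
  net <- data.frame(family_a = pairs[, 1], family_b = pairs[, 2],
                    weight = round(runif(nrow(pairs)), 2),
                    stringsAsFactors = FALSE)
  gfd <- gene_family_data(pres, net)
  Fc <- functional_similarity(gfd, ids, mode = "content")
  Fk <- functional_similarity(gfd, ids, mode = "connectivity")
  Fm <- functional_similarity(gfd, ids, mode = "mean")
  off <- upper.tri(Fm)
  expect_equal(Fm[off], (Fc[off] + Fk[off]) / 2)
  expect_equal(diag(Fm), setNames(rep(1, 4), ids))
  expect_true(all(Fm >= 0 & Fm <= 1))
  perm <- c(3, 1, 4, 2)
  Fp <- functional_similarity(gfd, ids[perm], mode = "mean")
  expect_equal(bare(Fp), bare(Fm[perm, perm]))
  expect_error(functional_similarity(gfd, c(ids, "mX")), "mX")
})

test_that("TF-IDF zeroes ubiquitous symptoms and scales by log(N/n_i)", {
  W <- rbind(d1 = c(2, 3, 0), d2 = c(1, 0, 0))
  colnames(W) <- c("s1", "s2", "s3")
  out <- tfidf_weights(W)
  expect_equal(unname(out[, "s1"]), c(0, 0))          # present in all N diseases
  expect_equal(out["d1", "s2"], 3 * log(2))           # N=2, n_i=1
  expect_equal(unname(out[, "s3"]), c(0, 0))          # absent everywhere, no log(Inf)
  expect_equal(tfidf_weights(matrix(0, 2, 2)), matrix(0, 2, 2))
})

test_that("symptom similarity is a TF-IDF cosine with safe zero handling", {
  # engineered so TF-IDF weights are nonzero and hand-checkable:
  # 4 diseases, symptoms below are each in 2 of 4 diseases (idf = log 2)
  W <- rbind(d1 = c(1, 1, 0), d2 = c(1, 0, 1), d3 = c(0, 1, 1),
             d4 = c(0, 0, 0))
  colnames(W) <- paste0("s", 1:3)
  S <- symptom_similarity(W)
  expect_equal(S["d1", "d2"], 0.5)  # (1,1,0)x(1,0,1) cosine, idf cancels
  expect_equal(S["d4", "d1"], 0)    # all-zero profile: 0 to everything
  expect_equal(S["d4", "d4"], 1)    # ...and 1 to itself
  expect_equal(S, t(S))
})

test_that("symptom similarity matches the brute-force cosine oracle and is scale-invariant", {
  set.seed(13)
  for (rep in 1:5) {
    W <- matrix(rpois(6 * 8, 1), 6, 8,
                dimnames = list(paste0("d", 1:6), paste0("s", 1:8)))
    S <- symptom_similarity(W)
    expect_lt(max(abs(unname(S) - brute_cosine(tfidf_weights(W)))), 1e-12)
    # scaling one disease's raw row leaves its similarities unchanged
    W2 <- W
    W2[3, ] <- 7 * W2[3, ]
    expect_equal(symptom_similarity(W2), S, tolerance = 1e-12)
  }
})

test_that("tanimoto coefficient matches popcount oracle and its invariances", {
  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
  set.seed(3)
  for (rep in 1:10) {
    a <- rbinom(16, 1, 0.4); b <- rbinom(16, 1, 0.4)
    expect_equal(tanimoto(a, b), brute_tanimoto(a, b))
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(c(a, 0, 0), c(b, 0, 0)), tanimoto(a, b))
  }
})

test_that("structural similarity thresholds at 0.8 and handles missing drugs", {
  # Tanimoto 0.79 < 0.8 is zeroed: 79 shared bits, 100 in the union
  a <- c(rep(1, 79), rep(1, 21), rep(0, 0))
  b <- c(rep(1, 79), rep(0, 21), rep(0, 0))
  fp <- list(r1 = a, r2 = b)
  expect_equal(tanimoto(a, b), 0.79)
  DS <- structural_similarity(fp, threshold = 0.8)
  expect_equal(DS["r1", "r2"], 0)
  expect_equal(diag(DS), c(r1 = 1, r2 = 1))
  # above-threshold values pass through
  c1 <- c(rep(1, 9), 1); c2 <- c(rep(1, 9), 0)
  DS2 <- structural_similarity(list(r1 = c1, r2 = c2), threshold = 0.8)
  expect_equal(DS2["r1", "r2"], 0.9)
  # threshold 0 reproduces the raw Tanimoto matrix
  set.seed(9)
  fps <- lapply(1:4, function(i) rbinom(12, 1, 0.5))
  names(fps) <- paste0("r", 1:4)
  DS0 <- structural_similarity(fps, threshold = 0)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) expect_equal(DS0[i, j], brute_tanimoto(fps[[i]], fps[[j]]))
  }
  # a drug with no fingerprint gets an all-zero row/column
  DS3 <- structural_similarity(fp, threshold = 0.8, drugs = c("r1", "r2", "r9"))
  expect_true(all(DS3["r9", ] == 0) && all(DS3[, "r9"] == 0))
  expect_error(structural_similarity(list(r1 = c(1, 0), r2 = c(1, 0, 1))),
               "mixed fingerprint lengths")
})

test_that("fingerprint table round-trips through TSV", {
  fps <- list(aspirin = c(1L, 0L, 1L, 1L), ibuprofen = c(0L, 1L, 1L, 0L))
  f <- tempfile(fileext = ".tsv")
  write_fingerprints(fps, f)
  expect_equal(read_fingerprints(f), fps)
})

test_that("all biological similarity outputs are symmetric in [0,1]", {
  set.seed(77)
  W <- matrix(rpois(5 * 6, 2), 5, 6,
              dimnames = list(paste0("d", 1:5), paste0("s", 1:6)))
  fps <- setNames(lapply(1:5, function(i) rbinom(16, 1, 0.5)), paste0("r", 1:5))
  for (S in list(symptom_similarity(W), structural_similarity(fps, 0.3))) {
    expect_equal(S, t(S))
    expect_true(all(S >= 0 & S <= 1))
  }
})
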