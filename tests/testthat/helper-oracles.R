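# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. All deliberately naive: double loops and explicit
# enumeration, no shared code with the package internals.

# strip every attribute except dim (for exact matrix-value comparisons)
bare <- function(M) array(as.vector(M), dim(M))

brute_gip <- function(P, eta) {
  n <- nrow(P)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp(-eta * sum((P[i, ] - P[j, ])^2))
  }
  K
}

brute_cosine <- function(D) {
  n <- nrow(D)
  S <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    na <- sqrt(sum(D[i, ]^2)); nb <- sqrt(sum(D[j, ]^2))
    S[i, j] <- if (na > 0 && nb > 0) sum(D[i, ] * D[j, ]) / (na * nb) else 0
  }
  S
}

brute_tanimoto <- function(a, b) {
  inter <- 0; un <- 0
  for (k in seq_along(a)) {
    if (a[k] == 1 && b[k] == 1) inter <- inter + 1
    if (a[k] == 1 || b[k] == 1) un <- un + 1
  }
  if (un == 0) 0 else inter / un
}

# enumerate all A_only x B_only pairs and check each against the edge list
brute_connectivity <- function(presence, network, a, b, cutoff) {
  pa <- presence[a, ]; pb <- presence[b, ]
  fam <- colnames(presence)
  a_only <- fam[pa == 1 & pb == 0]
  b_only <- fam[pb == 1 & pa == 0]
  if (!length(a_only) || !length(b_only)) return(0)
  has_edge <- function(x, y) {
    sel <- ((network$family_a == x & network$family_b == y) |
            (network$family_a == y & network$family_b == x)) &
           network$weight >= cutoff
    any(sel)
  }
  hits <- 0
  for (x in a_only) for (y in b_only) if (has_edge(x, y)) hits <- hits + 1
  hits / (length(a_only) * length(b_only))
}

brute_neighbor_score <- function(S, Y, i, l, mode = "weighted_sum", floor = 0) {
  acc <- 0; wsum <- 0; mx <- 0
  for (j in seq_len(nrow(Y))) {
    if (j == i) next
    s <- S[i, j]
    if (s < floor) s <- 0
    wsum <- wsum + s
    if (Y[j, l] == 1) {
      acc <- acc + s
      if (s > mx) mx <- s
    }
  }
  switch(mode,
         weighted_sum = acc,
         weighted_mean = if (wsum > 0) acc / wsum else 0,
         max = mx)
}

# the six-family toy gene set: two families present in both genomes, two
# absent from both, one exclusive to each genome
toy_gene_set <- function() {
  pres <- rbind(A = c(1, 1, 0, 0, 1, 0),
                B = c(1, 1, 0, 0, 0, 1))
  colnames(pres) <- paste0("f", 1:6)
  gene_family_data(pres)
}

random_assoc <- function(n, m, p = 0.4, prefix = c("m", "d")) {
  Y <- matrix(as.integer(stats::runif(n * m) < p), n, m,
              dimnames = list(sprintf("%s%02d", prefix[1], seq_len(n)),
                              sprintf("%s%02d", prefix[2], seq_len(m))))
  if (all(Y == 0)) Y[1, 1] <- 1L
  Y
}

write_tsv_lines <- function(lines, path, eol = "\n") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = eol)
  invisible(path)
}
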