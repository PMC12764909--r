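# Deterministic synthetic-data generator. Microbes, diseases and drugs are
# partitioned into matched blocks; associations are dense within matched
# blocks (p_in) and sparse across (p_out); all side-data modalities (gene
# families, symptoms, fingerprints) inherit the same block structure up to
# per-modality noise, so fused similarity is informative by construction.

#' Synthetic-data configuration
#'
#' Defaults are the study conditions used throughout the package's tests:
#' 60 microbes, 20 diseases, 20 drugs in 3 matched blocks, within-block
#' association probability 0.6 vs 0.05 across, 5% feature noise and a 10%
#' holdout of positive edges.
#'
#' @param n_microbes,n_diseases,n_drugs entity counts.
#' @param n_blocks number of planted blocks.
#' @param p_in,p_out within-/between-block association probabilities;
#'   `p_in > p_out` is required (otherwise there is no recoverable signal).
#' @param holdout_fraction fraction of positive edges withheld, in [0, 1).
#' @param n_families,n_symptoms,fingerprint_len side-data dimensions.
#' @param noise per-feature flip probability in [0, 0.5).
#' @param seed integer seed driving every random draw.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_microbes = 60, n_diseases = 20, n_drugs = 20,
                         n_blocks = 3, p_in = 0.6, p_out = 0.05,
                         holdout_fraction = 0.1, n_families = 40,
                         n_symptoms = 30, fingerprint_len = 64,
                         noise = 0.05, seed = 42) {
  stopifnot(n_microbes >= 1, n_diseases >= 1, n_drugs >= 1, n_blocks >= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            holdout_fraction >= 0, holdout_fraction < 1,
            n_families >= 1, n_symptoms >= 1, fingerprint_len >= 1,
            noise >= 0, noise < 0.5)
  if (p_in <= p_out) {
    stop("p_in must exceed p_out: no recoverable block signal otherwise")
  }
  structure(as.list(environment()), class = "synth_config")
}

# fixed sub-stream offsets: one per modality, so changing one modality's
# draw count never perturbs the others
.synth_offsets <- c(md = 101L, mr = 211L, families = 307L, network = 401L,
                    symptoms = 503L, fingerprints = 601L, holdout = 701L,
                    negatives = 809L)

sub_seed <- function(seed, stream) {
  (as.integer(seed) + .synth_offsets[[stream]]) %% .Machine$integer.max
}

block_of <- function(n, n_blocks) ((seq_len(n) - 1L) %% n_blocks) + 1L

bernoulli_matrix <- function(n, m, p) {
  matrix(as.integer(stats::runif(n * m) < p), n, m)
}

#' Generate a synthetic input bundle
#'
#' Returns every input kind the pipeline consumes: microbe-disease and
#' microbe-drug association matrices with planted block structure, gene
#' family data whose presence profiles follow the microbe blocks, a
#' disease x symptom weight table following the disease blocks, drug
#' fingerprints following the drug blocks, the held-out positive edges,
#' and the planted block labels. Identical configs produce identical
#' bundles.
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_bundle` with elements `md`, `mr`
#'   (`assoc_matrix`), `gene_families`, `symptoms` (weight matrix),
#'   `fingerprints`, `held_out` (data.frame `kind`/`microbe_id`/
#'   `partner_id`), `blocks`, `config`.
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  microbes <- sprintf("m%03d", seq_len(cfg$n_microbes))
  diseases <- sprintf("d%03d", seq_len(cfg$n_diseases))
  drugs    <- sprintf("r%03d", seq_len(cfg$n_drugs))
  families <- sprintf("f%03d", seq_len(cfg$n_families))
  symptoms <- sprintf("s%03d", seq_len(cfg$n_symptoms))
  bl <- list(microbe = block_of(cfg$n_microbes, cfg$n_blocks),
             disease = block_of(cfg$n_diseases, cfg$n_blocks),
             drug    = block_of(cfg$n_drugs, cfg$n_blocks))

  planted_assoc <- function(stream, partners, pb) {
    set.seed(sub_seed(cfg$seed, stream))
    P <- ifelse(outer(bl$microbe, pb, "=="), cfg$p_in, cfg$p_out)
    Y <- matrix(as.integer(stats::runif(length(P)) < P),
                nrow(P), ncol(P), dimnames = list(microbes, partners))
    Y
  }
  Ymd <- planted_assoc("md", diseases, bl$disease)
  Ymr <- planted_assoc("mr", drugs, bl$drug)

  flip <- function(proto, noise) {
    if (noise == 0) return(proto)
    f <- bernoulli_matrix(nrow(proto), ncol(proto), noise)
    abs(proto - f)
  }

  # gene families: block prototypes, flipped per microbe with `noise`
  set.seed(sub_seed(cfg$seed, "families"))
  fam_proto <- bernoulli_matrix(cfg$n_blocks, cfg$n_families, 0.5)
  presence <- flip(fam_proto[bl$microbe, , drop = FALSE], cfg$noise)
  dimnames(presence) <- list(microbes, families)

  # family functional-association network: random edges, uniform weights
  set.seed(sub_seed(cfg$seed, "network"))
  pairs <- which(upper.tri(matrix(0, cfg$n_families, cfg$n_families)),
                 arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < 0.25
  network <- data.frame(family_a = families[pairs[keep, 1]],
                        family_b = families[pairs[keep, 2]],
                        weight = round(stats::runif(sum(keep)), 3),
                        stringsAsFactors = FALSE)
  gfd <- gene_family_data(presence, network)

  # symptoms: block prototypes (which symptoms occur) with integer strengths
  set.seed(sub_seed(cfg$seed, "symptoms"))
  sym_proto <- bernoulli_matrix(cfg$n_blocks, cfg$n_symptoms, 0.4)
  sym_occ <- flip(sym_proto[bl$disease, , drop = FALSE], cfg$noise)
  W <- sym_occ * matrix(stats::rpois(length(sym_occ), 3) + 1,
                        nrow(sym_occ), ncol(sym_occ))
  dimnames(W) <- list(diseases, symptoms)

  # fingerprints: block prototypes flipped per drug
  set.seed(sub_seed(cfg$seed, "fingerprints"))
  fp_proto <- bernoulli_matrix(cfg$n_blocks, cfg$fingerprint_len, 0.5)
  FP <- flip(fp_proto[bl$drug, , drop = FALSE], cfg$noise)
  rownames(FP) <- drugs
  fingerprints <- stats::setNames(lapply(seq_len(nrow(FP)),
                                         function(i) FP[i, ]), drugs)

  # holdout: remove a fraction of positives from each association matrix
  set.seed(sub_seed(cfg$seed, "holdout"))
  hold <- list()
  for (nm in c("md", "mr")) {
    Y <- if (nm == "md") Ymd else Ymr
    pos <- which(Y == 1L)
    n_hold <- floor(cfg$holdout_fraction * length(pos))
    h <- if (n_hold > 0) sort(sample(pos, n_hold)) else integer()
    if (length(h)) {
      idx <- arrayInd(h, dim(Y))
      hold[[nm]] <- data.frame(kind = if (nm == "md") "disease" else "drug",
                               microbe_id = rownames(Y)[idx[, 1]],
                               partner_id = colnames(Y)[idx[, 2]],
                               stringsAsFactors = FALSE)
      Y[h] <- 0L
    } else {
      hold[[nm]] <- data.frame(kind = character(), microbe_id = character(),
                               partner_id = character(),
                               stringsAsFactors = FALSE)
    }
    if (nm == "md") Ymd <- Y else Ymr <- Y
  }
  held_out <- rbind(hold$md, hold$mr)
  rownames(held_out) <- NULL

  as_assoc <- function(Y, col_kind) {
    structure(list(Y = Y,
                   rows = entity_registry(rownames(Y), "microbe"),
                   cols = entity_registry(colnames(Y), col_kind),
                   annotations = empty_edge_records()),
              class = "assoc_matrix")
  }
  structure(list(md = as_assoc(Ymd, "disease"), mr = as_assoc(Ymr, "drug"),
                 gene_families = gfd, symptoms = W,
                 fingerprints = fingerprints, held_out = held_out,
                 blocks = bl, config = cfg),
            class = "synth_bundle")
}

#' Labeled evaluation pairs from a synthetic bundle
#'
#' Positives are the held-out edges of the requested kind; negatives are
#' sampled uniformly from the zero cells of the corresponding association
#' matrix, disjoint from both the current positives and the held-out set,
#' matched in count, and driven by a seed independent of the bundle's
#' generation streams.
#'
#' @param bundle a `synth_bundle`.
#' @param kind `"disease"` or `"drug"`.
#' @param seed negative-sampling seed; defaults to a fixed sub-stream of
#'   the bundle's seed.
#' @return data.frame with `microbe_id`, `partner_id`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
truth_table <- function(bundle, kind = c("disease", "drug"), seed = NULL) {
  kind <- match.arg(kind)
  assoc <- if (kind == "disease") bundle$md else bundle$mr
  pos <- bundle$held_out[bundle$held_out$kind == kind, , drop = FALSE]
  Y <- assoc$Y
  zero <- which(Y == 0L)
  held_lin <- (match(pos$partner_id, colnames(Y)) - 1L) * nrow(Y) +
    match(pos$microbe_id, rownames(Y))
  candidates <- setdiff(zero, held_lin)
  n_neg <- nrow(pos)
  if (length(candidates) < n_neg) {
    stop("not enough zero cells to sample ", n_neg, " negatives")
  }
  if (is.null(seed)) seed <- sub_seed(bundle$config$seed, "negatives")
  set.seed(seed)
  neg <- sort(sample(candidates, n_neg))
  idx <- arrayInd(neg, dim(Y))
  rbind(
    data.frame(microbe_id = pos$microbe_id, partner_id = pos$partner_id,
               label = "positive", stringsAsFactors = FALSE),
    data.frame(microbe_id = rownames(Y)[idx[, 1]],
               partner_id = colnames(Y)[idx[, 2]],
               label = "negative", stringsAsFactors = FALSE)
  )
}

#' Write a synthetic bundle as the pipeline's input files
#'
#' Emits the exact TSV dialects the readers consume: two generic edge
#' lists, the presence/absence table, the family network, the symptom
#' table and the fingerprint table.
#'
#' @param bundle a `synth_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(md = file.path(dir, "microbe_disease.tsv"),
         mr = file.path(dir, "microbe_drug.tsv"),
         presence = file.path(dir, "gene_family_presence.tsv"),
         network = file.path(dir, "gene_family_network.tsv"),
         symptoms = file.path(dir, "disease_symptoms.tsv"),
         fingerprints = file.path(dir, "drug_fingerprints.tsv"))
  edges_of <- function(assoc) {
    idx <- which(assoc$Y == 1L, arr.ind = TRUE)
    o <- order(idx[, 1], idx[, 2])
    edge_records(rownames(assoc$Y)[idx[o, 1]], colnames(assoc$Y)[idx[o, 2]],
                 origin = "synthetic")
  }
  write_edges(edges_of(bundle$md), f[["md"]])
  write_edges(edges_of(bundle$mr), f[["mr"]])
  write_matrix_tsv(bundle$gene_families$presence, f[["presence"]])
  net <- bundle$gene_families$network
  con <- file(f[["network"]], open = "wb")
  writeLines(c("family_a\tfamily_b\tweight",
               paste(net$family_a, net$family_b,
                     formatC(net$weight, format = "g", digits = 10),
                     sep = "\t")), con, sep = "\n")
  close(con)
  write_matrix_tsv(bundle$symptoms, f[["symptoms"]])
  write_fingerprints(bundle$fingerprints, f[["fingerprints"]])
  f
}
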