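# End-to-end pipeline: similarity construction, fusion, RWR featurization,
# candidate ranking, triple extraction, network export, run manifest.

#' Pipeline run configuration
#'
#' Collects every stage parameter. Defaults carry the framework's printed
#' constants (eta' = 1, restart phi = 0.9, Tanimoto threshold 0.8) and the
#' package's documented choices for the rest.
#'
#' @param eta_prime GIP reference bandwidth.
#' @param fm_mode functional-similarity mode (`"mean"`, `"content"`,
#'   `"connectivity"`).
#' @param weight_cutoff family-network confidence cutoff.
#' @param tanimoto_threshold structural-similarity threshold.
#' @param disease_fusion `"unconditional"` (default) or `"conditional"`
#'   rule for combining the disease kernel with symptom similarity.
#' @param restart,tol,max_iter,solver RWR parameters, see [rwr_config()].
#' @param score_mode neighbor-vote mode, see [neighbor_score()].
#' @param similarity_floor minimum neighbor similarity.
#' @param top_k candidates kept per association kind.
#' @param triple_threshold minimum predicted score entering a triple.
#' @param seed seed for `--simulate` runs.
#' @param simulate generate inputs with [synth_generate()] instead of
#'   reading files.
#' @param inputs named list of input paths (`md`, `mr`, `presence`,
#'   `network`, `symptoms`, `fingerprints`) when `simulate = FALSE`.
#' @return list of class `run_config`.
#' @export
run_config <- function(eta_prime = 1, fm_mode = "mean", weight_cutoff = 0.4,
                       tanimoto_threshold = 0.8,
                       disease_fusion = c("unconditional", "conditional"),
                       restart = 0.9, tol = 1e-10, max_iter = 1000,
                       solver = "direct", score_mode = "weighted_sum",
                       similarity_floor = 0, top_k = 100,
                       triple_threshold = 0.5, seed = 42, simulate = TRUE,
                       inputs = NULL) {
  disease_fusion <- match.arg(disease_fusion)
  cfg <- as.list(environment())
  cfg$rwr <- rwr_config(restart, tol, max_iter, solver)
  if (!simulate) {
    need <- c("md", "mr", "presence", "network", "symptoms", "fingerprints")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

load_inputs <- function(cfg) {
  if (cfg$simulate) {
    bundle <- synth_generate(synth_config(seed = cfg$seed))
    return(list(md = bundle$md, mr = bundle$mr,
                gfd = bundle$gene_families, symptoms = bundle$symptoms,
                fingerprints = bundle$fingerprints))
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", what, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  md0 <- stage("read microbe-disease associations",
               deduplicate(read_association_edges(cfg$inputs$md)))
  mr0 <- stage("read microbe-drug associations",
               deduplicate(read_association_edges(cfg$inputs$mr)))
  # both association matrices must share one microbe registry (union, in
  # first-seen order across the two edge lists)
  mic <- registry_from_names(c(md0$source_name, mr0$source_name), "microbe")
  md <- build_association_matrix(md0, rows = mic, col_kind = "disease")
  mr <- build_association_matrix(mr0, rows = mic, col_kind = "drug")
  gfd <- stage("read gene-family data", gene_family_data(
    read_matrix_tsv(cfg$inputs$presence),
    utils::read.delim(cfg$inputs$network, stringsAsFactors = FALSE)))
  symptoms <- stage("read symptom table", read_matrix_tsv(cfg$inputs$symptoms))
  fingerprints <- stage("read fingerprints", read_fingerprints(cfg$inputs$fingerprints))
  list(md = md, mr = mr, gfd = gfd, symptoms = symptoms,
       fingerprints = fingerprints)
}

#' Run the full prediction pipeline
#'
#' Executes every stage in order — GIP kernels for microbes, diseases and
#' drugs; functional, symptom and structural similarities; conditional /
#' unconditional fusion; RWR feature matrices and the block matrix X;
#' candidate ranking for both association kinds; triple extraction; SIF
#' export — and writes each product plus a run manifest to `out_dir`.
#' Reruns with identical inputs and config are byte-identical.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory products.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_inputs(cfg)
  md <- inp$md; mr <- inp$mr

  message("similarity: GIP kernels")
  GM <- gip_kernel(md, "rows", cfg$eta_prime)          # microbes from diseases
  GD <- gip_kernel(md, "cols", cfg$eta_prime)          # diseases
  Gdrug <- gip_kernel(mr, "cols", cfg$eta_prime)       # drugs

  message("similarity: biological layers")
  FM <- functional_similarity(inp$gfd, md$rows, mode = cfg$fm_mode,
                              weight_cutoff = cfg$weight_cutoff)
  SDM <- symptom_similarity(inp$symptoms[md$cols$ids, , drop = FALSE])
  DS <- structural_similarity(inp$fingerprints, cfg$tanimoto_threshold,
                              drugs = mr$cols)

  message("fusion")
  Sm <- fuse_conditional(GM, FM)
  Sdrug <- fuse_conditional(Gdrug, DS)
  Sdis <- if (cfg$disease_fusion == "conditional") {
    fuse_conditional(GD, SDM)
  } else {
    fuse_unconditional(GD, SDM)
  }

  message("random walk with restart")
  Fd <- feature_matrix(Sdrug, cfg$rwr)
  Fm <- feature_matrix(Sm, cfg$rwr)
  X <- assemble_block(Fd, Fm)

  message("candidate ranking")
  cand_md <- rank_candidates(Sm, md, top_k = cfg$top_k,
                             similarity_floor = cfg$similarity_floor,
                             mode = cfg$score_mode)
  cand_mr <- rank_candidates(Sm, mr, top_k = cfg$top_k,
                             similarity_floor = cfg$similarity_floor,
                             mode = cfg$score_mode)

  message("triple extraction")
  triples <- extract_triples(md, mr, cand_md, cand_mr,
                             threshold = cfg$triple_threshold)

  mats <- list(kernel_microbe = GM, kernel_disease = GD, kernel_drug = Gdrug,
               functional_microbe = FM, symptom_disease = SDM,
               structural_drug = DS, fused_microbe = Sm, fused_drug = Sdrug,
               fused_disease = Sdis, features_drug = Fd,
               features_microbe = Fm, features_block = X)
  for (nm in names(mats)) {
    write_matrix_tsv(mats[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  write_table_tsv(cand_md, file.path(out_dir, "candidates_disease.tsv"))
  write_table_tsv(cand_mr, file.path(out_dir, "candidates_drug.tsv"))
  write_table_tsv(triples, file.path(out_dir, "triples.tsv"))
  if (nrow(triples)) {
    export_network(triples, "sif", file.path(out_dir, "triples.sif"))
    export_network(triples, "graphml", file.path(out_dir, "triples.graphml"))
  }
  export_network(md, "sif", file.path(out_dir, "known_microbe_disease.sif"))
  export_network(mr, "sif", file.path(out_dir, "known_microbe_drug.sif"))

  manifest <- c(
    sprintf("eta_prime: %g", cfg$eta_prime),
    sprintf("fm_mode: %s", cfg$fm_mode),
    sprintf("weight_cutoff: %g", cfg$weight_cutoff),
    sprintf("tanimoto_threshold: %g", cfg$tanimoto_threshold),
    sprintf("disease_fusion: %s", cfg$disease_fusion),
    sprintf("restart: %g", cfg$restart),
    sprintf("tol: %g", cfg$tol),
    sprintf("max_iter: %d", as.integer(cfg$max_iter)),
    sprintf("solver: %s", cfg$solver),
    sprintf("score_mode: %s", cfg$score_mode),
    sprintf("similarity_floor: %g", cfg$similarity_floor),
    sprintf("top_k: %g", cfg$top_k),
    sprintf("triple_threshold: %g", cfg$triple_threshold),
    sprintf("simulate: %s", cfg$simulate),
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("n_microbes: %d", nrow(md$Y)),
    sprintf("n_diseases: %d", ncol(md$Y)),
    sprintf("n_drugs: %d", ncol(mr$Y))
  )
  if (!cfg$simulate) {
    sums <- tools::md5sum(unlist(cfg$inputs))
    manifest <- c(manifest,
                  sprintf("input_%s: %s %s", names(cfg$inputs),
                          unlist(cfg$inputs), sums))
  }
  con <- file(file.path(out_dir, "manifest.txt"), open = "wb")
  writeLines(manifest, con, sep = "\n")
  close(con)

  invisible(list(md = md, mr = mr, matrices = mats,
                 candidates_disease = cand_md, candidates_drug = cand_mr,
                 triples = triples))
}
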