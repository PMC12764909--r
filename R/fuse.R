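# Fusion of Gaussian-kernel and biological similarity matrices.

#' Conditional similarity fusion
#'
#' Integrates a topology-derived kernel similarity with a biological
#' similarity by conditional averaging: where the biological similarity is
#' nonzero the fused value is the arithmetic mean of the two, elsewhere the
#' kernel value passes through unchanged. This is the rule used for the
#' integrated microbe similarity (kernel + functional similarity) and the
#' integrated drug similarity (kernel + structural similarity).
#'
#' @param kernel square similarity matrix with id dimnames.
#' @param bio square similarity matrix on the same registry and order.
#' @return fused matrix with attribute `recipe` (rule and gating mask).
#' @export
fuse_conditional <- function(kernel, bio) {
  check_same_entities(kernel, bio)
  mask <- bio != 0
  S <- kernel
  S[mask] <- (kernel[mask] + bio[mask]) / 2
  attr(S, "recipe") <- list(rule = "conditional_average", gated = mask)
  attr(S, "bandwidth") <- NULL
  S
}

#' Unconditional similarity fusion
#'
#' Elementwise arithmetic mean of two similarity matrices on the same
#' registry; the rule used to combine the disease kernel similarity with
#' the symptom-profile disease similarity.
#'
#' @param a,b square similarity matrices with identical id dimnames.
#' @return `(a + b) / 2` with attribute `recipe`.
#' @export
fuse_unconditional <- function(a, b) {
  check_same_entities(a, b)
  S <- (a + b) / 2
  attr(S, "recipe") <- list(rule = "unconditional_average")
  S
}
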