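# Gaussian interaction-profile (GIP) kernel similarity. The same
# construction is instantiated four times in the pipeline: microbes and
# diseases from the microbe-disease matrix, drugs and microbes from the
# microbe-drug matrix.

#' GIP kernel bandwidth
#'
#' The bandwidth eta is the reference bandwidth eta' divided by the mean
#' squared Euclidean norm of the interaction profiles, i.e. normalized by
#' the average number of associations per entity (for binary profiles the
#' squared norm of a profile equals its association count).
#'
#' @param profiles binary matrix, one interaction profile per row.
#' @param eta_prime reference bandwidth eta' > 0 (default 1).
#' @return positive bandwidth.
#' @examples
#' gip_bandwidth(diag(2))            # 1
#' gip_bandwidth(matrix(1, 2, 2))    # 0.5
#' @export
gip_bandwidth <- function(profiles, eta_prime = 1) {
  stopifnot(is.numeric(eta_prime), length(eta_prime) == 1, eta_prime > 0)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1) stop("need at least one profile")
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) {
    stop("degenerate bandwidth: every interaction profile is all-zero ",
         "(division by zero); filter isolated entities or supply eta explicitly")
  }
  eta_prime / mean_sq
}

#' Gaussian interaction-profile kernel similarity matrix
#'
#' Computes K[i, j] = exp(-eta * ||IP_i - IP_j||^2) over the row or column
#' interaction profiles of an association matrix, with the bandwidth eta
#' from [gip_bandwidth()] over the same profiles (or supplied explicitly).
#' The result is symmetric with unit diagonal and entries in (0, 1].
#' Entities with all-zero profiles are allowed inside a non-degenerate
#' matrix and follow the same formula.
#'
#' @param assoc an `assoc_matrix`, or a plain binary matrix with dimnames.
#' @param axis `"rows"` or `"cols"`: which profiles to compare.
#' @param eta_prime reference bandwidth (default 1).
#' @param eta optional explicit bandwidth overriding the normalized one.
#' @return square similarity matrix with entity-id dimnames and attributes
#'   `bandwidth`, `eta_prime`, `source_axis`.
#' @export
gip_kernel <- function(assoc, axis = c("rows", "cols"), eta_prime = 1,
                       eta = NULL) {
  axis <- match.arg(axis)
  Y <- if (inherits(assoc, "assoc_matrix")) assoc$Y else as.matrix(assoc)
  P <- if (axis == "rows") Y else t(Y)
  if (is.null(rownames(P))) rownames(P) <- paste0("e", seq_len(nrow(P)))
  if (is.null(eta)) eta <- gip_bandwidth(P, eta_prime)
  stopifnot(eta > 0)
  sq <- rowSums(P^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0  # numerical guard
  K <- exp(-eta * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  attr(K, "bandwidth") <- eta
  attr(K, "eta_prime") <- eta_prime
  attr(K, "source_axis") <- axis
  K
}
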