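# Random walk with restart on fused similarity networks: the iteration
# p <- (1 - phi) M p + phi e, whose fixed point summarizes network
# proximity to a seed node and serves as its feature profile.

#' RWR solver configuration
#'
#' @param restart restart probability phi in (0, 1] (default 0.9).
#' @param tol L1 convergence tolerance of the iterative solver.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param solver `"iterative"` (power iteration) or `"direct"` (matrix
#'   inverse, exact fixed point).
#' @return list of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.9, tol = 1e-10, max_iter = 1000,
                       solver = c("iterative", "direct")) {
  solver <- match.arg(solver)
  stopifnot(restart > 0, restart <= 1, tol > 0, max_iter >= 1)
  structure(list(restart = restart, tol = tol, max_iter = max_iter,
                 solver = solver), class = "rwr_config")
}

#' Column-stochastic transition matrix from a similarity matrix
#'
#' Divides each column by its sum; all-zero columns (entities with no
#' similarity to anything) become the uniform column 1/n, the standard
#' dangling-node teleport.
#'
#' @param S nonnegative square matrix.
#' @param zero_diagonal drop self-similarity before normalization
#'   (default `FALSE`: the diagonal is kept).
#' @return column-stochastic matrix, same dimnames.
#' @export
to_transition <- function(S, zero_diagonal = FALSE) {
  S <- as.matrix(S)
  if (any(S < 0)) stop("similarity matrix has negative entries")
  if (zero_diagonal) diag(S) <- 0
  cs <- colSums(S)
  M <- S
  pos <- cs > 0
  if (any(pos)) {
    M[, pos] <- sweep(S[, pos, drop = FALSE], 2, cs[pos], "/")
  }
  if (any(!pos)) M[, !pos] <- 1 / nrow(S)
  M
}

#' Steady-state RWR profile of one node
#'
#' Solves the fixed point of p = (1 - phi) M p + phi e_i. The iterative
#' solver stops at the first iterate whose L1 change is below `tol`
#' (geometric convergence with ratio at most 1 - phi); the direct solver
#' returns phi * (I - (1 - phi) M)^-1 e_i. Both are renormalized to sum
#' exactly 1.
#'
#' @param M column-stochastic transition matrix.
#' @param node_index seed node index (or id).
#' @param cfg an [rwr_config()].
#' @return probability vector over nodes (named when M has dimnames).
#' @export
rwr_profile <- function(M, node_index, cfg = rwr_config()) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (is.character(node_index)) node_index <- match(node_index, rownames(M))
  stopifnot(!is.na(node_index), node_index >= 1, node_index <= n)
  phi <- cfg$restart
  e <- numeric(n); e[node_index] <- 1
  if (cfg$solver == "direct") {
    p <- phi * solve(diag(n) - (1 - phi) * M, e)
  } else {
    p <- e
    converged <- FALSE
    for (it in seq_len(cfg$max_iter)) {
      p_new <- (1 - phi) * (M %*% p) + phi * e
      delta <- sum(abs(p_new - p))
      p <- as.vector(p_new)
      if (delta < cfg$tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
                   cfg$max_iter, delta))
    }
  }
  p[p < 0] <- 0  # numerical guard
  p <- p / sum(p)
  stats::setNames(as.vector(p), rownames(M))
}

#' RWR feature matrix over all nodes of a similarity network
#'
#' Column i is the steady-state RWR profile seeded at node i, each column
#' renormalized to sum 1. The similarity matrix is converted to a
#' transition matrix with [to_transition()] first.
#'
#' @param S nonnegative similarity matrix with dimnames.
#' @param cfg an [rwr_config()].
#' @param zero_diagonal passed to [to_transition()].
#' @return square feature matrix, columns summing to 1.
#' @export
feature_matrix <- function(S, cfg = rwr_config(), zero_diagonal = FALSE) {
  M <- to_transition(S, zero_diagonal = zero_diagonal)
  n <- nrow(M)
  phi <- cfg$restart
  if (cfg$solver == "direct") {
    FF <- phi * solve(diag(n) - (1 - phi) * M)
    FF[FF < 0] <- 0
    FF <- sweep(FF, 2, colSums(FF), "/")
  } else {
    FF <- vapply(seq_len(n), function(i) rwr_profile(M, i, cfg), numeric(n))
  }
  dimnames(FF) <- dimnames(M)
  FF
}

#' Assemble the block feature matrix X
#'
#' X = [[0, F_d], [F_m, 0]]: zero top-left and bottom-right blocks, the
#' partner-entity feature matrix F_d top-right and the microbe feature
#' matrix F_m bottom-left. Rows and columns carry the composite registry
#' (partner ids first, then microbe ids / vice versa on columns).
#'
#' @param Fd feature matrix of the partner entities (e.g. drugs), nd x nd.
#' @param Fm feature matrix of the microbes, nm x nm.
#' @return (nd + nm) x (nm + nd) matrix.
#' @export
assemble_block <- function(Fd, Fm) {
  nd <- nrow(Fd); nm <- nrow(Fm)
  X <- rbind(cbind(matrix(0, nd, nm), Fd),
             cbind(Fm, matrix(0, nm, nd)))
  rownames(X) <- c(rownames(Fd), rownames(Fm))
  colnames(X) <- c(colnames(Fm), colnames(Fd))
  X
}

#' Extract the blocks of an assembled feature matrix
#'
#' @param X matrix from [assemble_block()].
#' @param nd number of partner entities (top-right block size).
#' @return list with `Fd` and `Fm`.
#' @export
split_block <- function(X, nd) {
  nm <- nrow(X) - nd
  list(Fd = X[seq_len(nd), nm + seq_len(nd), drop = FALSE],
       Fm = X[nd + seq_len(nm), seq_len(nm), drop = FALSE])
}
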