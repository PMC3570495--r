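#' Markov Cluster Algorithm on a weighted similarity graph
#'
#' Dense implementation of MCL: the symmetric non-negative adjacency matrix
#' gets self-loops (weight = the node's maximum incident edge weight, 1 for
#' isolated nodes), is column-normalised to a stochastic matrix, and is then
#' iterated by \emph{expansion} (matrix squaring) and \emph{inflation}
#' (entry-wise power followed by column renormalisation) until the largest
#' entry change drops below \code{tol} or \code{maxIter} is reached.
#' Entries below \code{prune} are zeroed between iterations for numerical
#' stability.  Clusters are read off as connected components of the
#' non-zero structure of the limit matrix; by default singleton clusters
#' are dropped (a paralog cluster needs at least two members).
#'
#' @param adjacency square numeric matrix of non-negative similarities with
#'   dimnames naming the nodes; asymmetric input is symmetrised with
#'   \code{pmax}.
#' @param inflation inflation exponent, > 1 (default 2).
#' @param maxIter iteration cap (default 100); non-convergence raises a
#'   warning and the current state is still interpreted.
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @param prune zero-threshold between iterations (default 1e-9).
#' @param dropSingletons drop clusters of size 1 (default TRUE).
#' @return A list of character vectors (cluster memberships), each sorted,
#'   clusters ordered by first member.
#' @examples
#' adj <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' adj["a", "b"] <- adj["b", "a"] <- 10
#' adj["b", "c"] <- adj["c", "b"] <- 1
#' adj["c", "d"] <- adj["d", "c"] <- 10
#' mclCluster(adj)  # list(c("a","b"), c("c","d"))
#' @export
mclCluster <- function(adjacency, inflation = 2, maxIter = 100L,
                       tol = 1e-6, prune = 1e-9, dropSingletons = TRUE) {
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == ncol(A), inflation > 1)
  if (any(A < 0)) stop("negative similarity weight", call. = FALSE)
  n <- nrow(A)
  if (n == 0L) return(list())
  if (is.null(rownames(A)))
    dimnames(A) <- list(paste0("V", seq_len(n)), paste0("V", seq_len(n)))
  A <- pmax(A, t(A))
  diag(A) <- 0
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    Mnew <- M %*% M
    Mnew <- Mnew^inflation
    Mnew[Mnew < prune] <- 0
    cs <- colSums(Mnew)
    cs[cs == 0] <- 1
    Mnew <- sweep(Mnew, 2, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", maxIter, " iterations",
            call. = FALSE)
  link <- (M > tol) | t(M > tol)
  g <- igraph::graph_from_adjacency_matrix(link, mode = "undirected",
                                           diag = FALSE)
  membership <- igraph::components(g)$membership
  clusters <- split(names(membership), membership)
  clusters <- lapply(clusters, sort)
  if (dropSingletons)
    clusters <- clusters[vapply(clusters, length, integer(1)) >= 2L]
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  unname(clusters)
}
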