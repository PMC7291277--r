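#' Restart-based network diffusion (personalized PageRank style)
#'
#' Propagates seed "heat" over the directed multilayer network to the fixed
#' point of
#' \deqn{h = r s + (1 - r) (P^T h + d s)}
#' where `s` is the seed distribution (weights normalized to sum 1), `P` is
#' the row-stochastic transition matrix spreading each node's heat uniformly
#' over its out-edges, and `d` is the mass sitting on dangling nodes (no
#' out-edges), which is returned to the seed distribution so that total heat
#' is conserved. For `direction = "reverse"` all edges are reversed first
#' (used to diffuse backwards from target genes). Parallel edges between the
#' same node pair in both layers count as a single transition channel.
#'
#' Diffusion (rather than e.g. shortest paths) avoids prioritization biases
#' from network topology such as degree: a hub gains no heat unless it is
#' actually reachable from the seeds.
#'
#' @param network An `mhl_network`.
#' @param seeds Weighted node set (data frame with `node`, `weight`) or a
#'   named numeric vector. Seeds absent from the network are dropped with a
#'   warning; if none remain, this is an error.
#' @param restart Restart probability in (0, 1); default 0.15.
#' @param direction `"forward"` (along edges) or `"reverse"` (against
#'   edges).
#' @param tol L1 convergence tolerance on successive iterates; default
#'   1e-9.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return Named numeric heat vector over all network nodes; entries are
#'   nonnegative and sum to 1 (within 1e-6).
#' @examples
#' net <- multilayer_network(data.frame(
#'   source = "A", target = "B", layer = "PPI", sign = 0L
#' ))
#' h <- diffuse(net, c(A = 1), restart = 0.15)
#' abs(h[["A"]] - 0.15 / (1 - 0.85^2)) < 1e-8
#' @export
diffuse <- function(network, seeds, restart = 0.15,
                    direction = c("forward", "reverse"),
                    tol = 1e-9, max_iter = 10000L) {
  direction <- match.arg(direction)
  if (length(restart) != 1 || is.na(restart) || restart <= 0 ||
      restart >= 1) {
    mhl_stop("restart must lie strictly between 0 and 1", "mhl_param_error")
  }
  if (is.data.frame(seeds)) {
    seeds <- stats::setNames(seeds$weight, seeds$node)
  }
  if (is.null(names(seeds)) || any(seeds < 0)) {
    mhl_stop("seeds must be a named nonnegative weight vector",
             "mhl_param_error")
  }
  nodes <- network_nodes(network)
  absent <- setdiff(names(seeds)[seeds > 0], nodes)
  if (length(absent) > 0) {
    warning(
      sprintf(
        "dropping %d seed(s) absent from the network: %s",
        length(absent), paste(absent, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  seeds <- seeds[names(seeds) %in% nodes & seeds > 0]
  if (length(seeds) == 0 || sum(seeds) == 0) {
    mhl_stop("no seed node present in the network", "mhl_seed_error")
  }
  n <- length(nodes)
  s <- numeric(n)
  names(s) <- nodes
  s[names(seeds)] <- s[names(seeds)] + seeds
  s <- s / sum(s)

  src <- network$source
  tgt <- network$target
  if (direction == "reverse") {
    tmp <- src
    src <- tgt
    tgt <- tmp
  }
  pair <- unique(data.frame(src = src, tgt = tgt, stringsAsFactors = FALSE))
  i <- match(pair$src, nodes)
  j <- match(pair$tgt, nodes)
  outdeg <- tabulate(i, nbins = n)
  # P^T as a sparse matrix: column i holds 1/outdeg(i) at each out-neighbour
  Pt <- Matrix::sparseMatrix(
    i = j, j = i, x = 1 / outdeg[i], dims = c(n, n)
  )
  dangling <- outdeg == 0

  h <- s
  for (iter in seq_len(max_iter)) {
    d <- sum(h[dangling])
    h_new <- restart * s + (1 - restart) * (as.numeric(Pt %*% h) + d * s)
    delta <- sum(abs(h_new - h))
    h <- h_new
    if (delta < tol) {
      names(h) <- nodes
      return(h)
    }
  }
  mhl_stop(
    sprintf(
      "diffusion did not converge in %d iterations (L1 residual %.3g)",
      max_iter, delta
    ),
    "mhl_convergence_error"
  )
}

#' Min-heat linker scores
#'
#' A linker is a node carrying heat both from the receptors (forward
#' diffusion) and from the target genes (reverse diffusion); its score is
#' the smaller of the two heats, `L(v) = min(h_source(v), h_target(v))`.
#' Nodes absent from either vector score 0.
#'
#' @param h_source Forward heat vector (named numeric).
#' @param h_target Reverse heat vector (named numeric).
#' @return Named numeric vector over the union of nodes, sorted by node id.
#' @export
linker_scores <- function(h_source, h_target) {
  nodes <- sort(union(names(h_source), names(h_target)))
  a <- stats::setNames(numeric(length(nodes)), nodes)
  b <- a
  a[names(h_source)] <- h_source
  b[names(h_target)] <- h_target
  pmin(a, b)
}

#' Select the linker subnetwork
#'
#' Keeps the sources, the targets and the `k = ceiling(size_factor *
#' (|sources| + |targets|))` top-scoring linker candidates (nodes that are
#' neither sources nor targets), ranked by min-heat score with ties broken
#' lexicographically by node id for determinism. Nodes with a zero linker
#' score are never selected, even if the budget `k` is not filled. The edge
#' set is the induced typed edge set over the retained nodes.
#'
#' @param network An `mhl_network`.
#' @param L Linker scores from [linker_scores()].
#' @param sources,targets Nonempty character vectors of node ids.
#' @param size_factor Positive linker budget multiplier (default 1).
#' @return A `mhl_subnetwork`: list with `nodes` (sorted), `edges` (induced
#'   `mhl_network`), `roles` (data frame: `node`, `is_source`, `is_target`,
#'   `is_linker`, `linker_score`), `k` and `size_factor`.
#' @export
select_subnetwork <- function(network, L, sources, targets,
                              size_factor = 1.0) {
  if (length(sources) == 0 || length(targets) == 0) {
    mhl_stop("sources and targets must be nonempty", "mhl_param_error")
  }
  if (length(size_factor) != 1 || is.na(size_factor) || size_factor <= 0) {
    mhl_stop("size_factor must be a positive real", "mhl_param_error")
  }
  sources <- sort(unique(sources))
  targets <- sort(unique(targets))
  k <- as.integer(ceiling(size_factor * (length(sources) + length(targets))))
  cand <- setdiff(names(L)[L > 0], union(sources, targets))
  cand <- cand[order(-L[cand], cand)]
  linkers <- utils::head(cand, k)
  nodes <- sort(unique(c(sources, targets, linkers)))
  keep <- network$source %in% nodes & network$target %in% nodes
  edges <- multilayer_network(as.data.frame(network)[keep, , drop = FALSE])
  roles <- data.frame(
    node = nodes,
    is_source = nodes %in% sources,
    is_target = nodes %in% targets,
    is_linker = nodes %in% linkers,
    linker_score = ifelse(nodes %in% names(L), L[nodes], 0),
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes, edges = edges, roles = roles, k = k,
         size_factor = size_factor),
    class = "mhl_subnetwork"
  )
}

#' @export
print.mhl_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<mhl_subnetwork> %d nodes (%d sources, %d targets, %d linkers of budget %d), %d edges\n",
    length(x$nodes), sum(x$roles$is_source), sum(x$roles$is_target),
    sum(x$roles$is_linker), x$k, nrow(x$edges)
  ))
  invisible(x)
}
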