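# Constructor for the chain table: list-columns for microbial_ids, nodes
# and edge_layers; one row per chain, in deterministic order.
chain_table <- function(microbial_ids = list(), condition = character(0),
                        nodes = list(), edge_layers = list()) {
  df <- data.frame(
    condition = as.character(condition), stringsAsFactors = FALSE
  )
  df$microbial_ids <- microbial_ids
  df$nodes <- nodes
  df$edge_layers <- edge_layers
  df <- df[, c("microbial_ids", "condition", "nodes", "edge_layers"),
           drop = FALSE]
  sort_chains(df)
}

sort_chains <- function(chains) {
  if (nrow(chains) == 0) {
    rownames(chains) <- NULL
    return(chains)
  }
  node_key <- vapply(chains$nodes, paste, character(1), collapse = "|")
  layer_key <- vapply(chains$edge_layers, paste, character(1),
                      collapse = "|")
  chains <- chains[order(node_key, layer_key, chains$condition), ,
                   drop = FALSE]
  rownames(chains) <- NULL
  chains
}

#' Enumerate receptor-to-target signalling chains
#'
#' Finds all simple directed paths (no repeated node) from any receptor to
#' any target with at most `max_len` edges, by depth-first search over the
#' typed edges of the subnetwork. When an edge exists in both the PPI and
#' the TRI layer, one chain per layer assignment is produced, since the
#' layer of the final step decides the chain's fate downstream. Each chain
#' is annotated with the microbial proteins bound to its receptor. Output
#' order is deterministic (lexicographic by node sequence, then layers).
#'
#' @param sub An `mhl_subnetwork` from [select_subnetwork()], or an
#'   `mhl_network`.
#' @param receptors,targets Character vectors of node ids; must be subsets
#'   of the (sub)network's nodes.
#' @param max_len Maximum number of edges per chain (>= 1); default 4,
#'   enough for receptor -> intermediates -> transcription factor -> target.
#' @param receptor_microbes Optional named list mapping receptor id to the
#'   microbial proteins predicted to bind it (see
#'   [merge_predictions()]).
#' @return A chain table: data frame with list-columns `microbial_ids`,
#'   `nodes`, `edge_layers` and a character column `condition`
#'   (`"unassigned"` until [filter_condition_specific()]).
#' @export
enumerate_chains <- function(sub, receptors, targets, max_len = 4L,
                             receptor_microbes = NULL) {
  if (length(max_len) != 1 || is.na(max_len) || max_len < 1) {
    mhl_stop("max_len must be an integer >= 1", "mhl_param_error")
  }
  edges <- if (inherits(sub, "mhl_subnetwork")) sub$edges else sub
  nodes <- if (inherits(sub, "mhl_subnetwork")) {
    sub$nodes
  } else {
    network_nodes(edges)
  }
  outside <- setdiff(c(receptors, targets), nodes)
  if (length(outside) > 0) {
    mhl_stop(
      sprintf(
        "receptor/target node(s) not in subnetwork: %s",
        paste(sort(unique(outside)), collapse = ", ")
      ),
      "mhl_param_error"
    )
  }
  # adjacency over typed edges, neighbours pre-sorted for determinism
  adj <- split(
    data.frame(to = edges$target, layer = edges$layer,
               stringsAsFactors = FALSE),
    factor(edges$source, levels = nodes)
  )
  adj <- lapply(adj, function(df) {
    df[order(df$to, df$layer), , drop = FALSE]
  })
  target_set <- unique(targets)
  found_nodes <- list()
  found_layers <- list()

  walk <- function(path, layers, on_path) {
    head <- path[length(path)]
    if (length(layers) > 0 && head %in% target_set) {
      found_nodes[[length(found_nodes) + 1L]] <<- path
      found_layers[[length(found_layers) + 1L]] <<- layers
    }
    if (length(layers) >= max_len) {
      return(invisible(NULL))
    }
    nb <- adj[[head]]
    if (is.null(nb) || nrow(nb) == 0) {
      return(invisible(NULL))
    }
    for (e in seq_len(nrow(nb))) {
      nxt <- nb$to[e]
      if (nxt %in% on_path) next # simple-path (on-path cycle) check
      walk(c(path, nxt), c(layers, nb$layer[e]), c(on_path, nxt))
    }
    invisible(NULL)
  }
  for (r in sort(unique(receptors))) {
    walk(r, character(0), r)
  }
  micro_for <- function(r) {
    if (is.null(receptor_microbes)) {
      character(0)
    } else {
      sort(unique(receptor_microbes[[r]] %||% character(0)))
    }
  }
  chain_table(
    microbial_ids = lapply(found_nodes, function(p) micro_for(p[1])),
    condition = rep("unassigned", length(found_nodes)),
    nodes = found_nodes,
    edge_layers = found_layers
  )
}

#' Keep condition-specific chains
#'
#' Restricts the chain set to chains initiated by microbial proteins
#' detected in exactly one study condition, to retain condition
#' specificity:
#' \itemize{
#'   \item Initiating microbial proteins detected in more than one
#'     condition are removed from a chain's initiator set.
#'   \item A chain survives only if at least one single-condition initiator
#'     remains; when its remaining initiators span several single
#'     conditions, the chain is split into one copy per condition.
#'   \item A node shared by surviving chains of different conditions would
#'     blur the separation between the condition-specific models, so chains
#'     routing through such a shared node are dropped -- except when the
#'     shared node directly regulates a target, i.e. occupies the
#'     penultimate position of the chain. Receptors (first position) and
#'     targets (last position) are exempt from the sharing rule.
#' }
#' The operation is idempotent.
#'
#' @param chains A chain table.
#' @param cmap Condition map: named list microbial id -> character vector
#'   of condition labels (see [read_conditions()]). Every initiator must be
#'   present.
#' @return The filtered chain table with `condition` set to the single
#'   label of each surviving copy.
#' @export
filter_condition_specific <- function(chains, cmap) {
  if (nrow(chains) == 0) {
    return(chains)
  }
  all_micro <- unique(unlist(chains$microbial_ids))
  missing <- setdiff(all_micro, names(cmap))
  if (length(missing) > 0) {
    mhl_stop(
      sprintf(
        "microbial protein(s) absent from condition map: %s",
        paste(missing, collapse = ", ")
      ),
      "mhl_param_error"
    )
  }
  rows <- list()
  for (i in seq_len(nrow(chains))) {
    inits <- chains$microbial_ids[[i]]
    nconds <- vapply(cmap[inits], length, integer(1))
    single <- inits[nconds == 1]
    if (length(single) == 0) next
    labels <- vapply(cmap[single], identity, character(1))
    for (cond in sort(unique(labels))) {
      rows[[length(rows) + 1L]] <- list(
        microbial_ids = sort(single[labels == cond]),
        condition = cond,
        nodes = chains$nodes[[i]],
        edge_layers = chains$edge_layers[[i]]
      )
    }
  }
  if (length(rows) == 0) {
    return(chains[0, , drop = FALSE])
  }
  out <- chain_table(
    microbial_ids = lapply(rows, `[[`, "microbial_ids"),
    condition = vapply(rows, `[[`, character(1), "condition"),
    nodes = lapply(rows, `[[`, "nodes"),
    edge_layers = lapply(rows, `[[`, "edge_layers")
  )
  drop_shared_intermediates(out)
}

# Second pass of the condition filter: intermediate nodes (neither first
# nor last) occurring in chains of >= 2 distinct conditions kill every
# chain in which they occupy a non-penultimate intermediate position.
drop_shared_intermediates <- function(chains) {
  if (nrow(chains) == 0) {
    return(chains)
  }
  inter <- function(p) if (length(p) > 2) p[2:(length(p) - 1)] else character(0)
  node_conds <- list()
  for (i in seq_len(nrow(chains))) {
    for (v in inter(chains$nodes[[i]])) {
      node_conds[[v]] <- union(node_conds[[v]], chains$condition[i])
    }
  }
  shared <- names(node_conds)[
    vapply(node_conds, length, integer(1)) >= 2
  ]
  if (length(shared) == 0) {
    return(chains)
  }
  keep <- vapply(seq_len(nrow(chains)), function(i) {
    p <- chains$nodes[[i]]
    mid <- inter(p)
    bad <- intersect(mid, shared)
    # allowed only at the penultimate position (direct regulator of target)
    all(match(bad, p) == length(p) - 1L)
  }, logical(1))
  out <- chains[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep chains whose final edge is a transcriptional regulatory interaction
#'
#' Confines the step immediately upstream of the target to the
#' transcriptional regulatory layer, so that surviving chains capture the
#' regulatory biology behind the target genes' expression change.
#'
#' @param chains A chain table.
#' @return The chains whose last `edge_layers` entry is `"TRI"`.
#' @export
filter_tri_last <- function(chains) {
  if (nrow(chains) == 0) {
    return(chains)
  }
  keep <- vapply(chains$edge_layers, function(l) {
    length(l) >= 1 && l[length(l)] == "TRI"
  }, logical(1))
  out <- chains[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive the node/edge model implied by a set of chains
#'
#' The filtering unit throughout is the chain; network views are derived as
#' the union of surviving chains. This collects every edge actually used by
#' a chain (with its layer, and the sign looked up in the full network when
#' supplied).
#'
#' @param chains A chain table.
#' @param network Optional `mhl_network` used to recover edge signs.
#' @return An `mhl_network` of the union of chain edges (zero rows when no
#'   chains survive).
#' @export
chains_to_network <- function(chains, network = NULL) {
  rows <- list()
  for (i in seq_len(nrow(chains))) {
    p <- chains$nodes[[i]]
    l <- chains$edge_layers[[i]]
    for (e in seq_along(l)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = p[e], target = p[e + 1], layer = l[e], sign = 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(multilayer_network(data.frame(
      source = character(0), target = character(0), layer = character(0),
      sign = integer(0), stringsAsFactors = FALSE
    )))
  }
  edges <- unique(do.call(rbind, rows))
  if (!is.null(network)) {
    key <- function(df) paste(df$source, df$target, df$layer, sep = "\r")
    idx <- match(key(edges), key(network))
    hit <- !is.na(idx)
    edges$sign[hit] <- network$sign[idx[hit]]
  }
  multilayer_network(edges)
}
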