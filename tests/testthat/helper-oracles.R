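# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Exhaustive triple loop over (microbial annotation, host annotation, gold
# pair), unordered pair matching.
brute_force_dd <- function(micro_annots, host_annots, gold) {
  rows <- list()
  for (i in seq_len(nrow(micro_annots))) {
    for (j in seq_len(nrow(host_annots))) {
      for (g in seq_len(nrow(gold))) {
        a <- gold$domain_a[g]
        b <- gold$domain_b[g]
        md <- micro_annots$domain_acc[i]
        hd <- host_annots$domain_acc[j]
        if ((md == a && hd == b) || (md == b && hd == a)) {
          rows[[length(rows) + 1]] <- sprintf(
            "%s|%s|%s|%s|%d|%d|%d|%d",
            micro_annots$protein_id[i], host_annots$protein_id[j],
            md, hd,
            micro_annots$start[i], micro_annots$end[i],
            host_annots$start[j], host_annots$end[j]
          )
        }
      }
    }
  }
  sort(unique(unlist(rows, use.names = FALSE))) %||% character(0)
}

dd_to_keys <- function(pred) {
  sort(unique(sprintf(
    "%s|%s|%s|%s|%d|%d|%d|%d",
    pred$microbial_id, pred$host_id, pred$microbial_domain,
    pred$host_domain, pred$m_start, pred$m_end, pred$h_start, pred$h_end
  )))
}

# Exhaustive loop over (microbial annotation, passing instance).
brute_force_dm <- function(micro_annots, instances, classes) {
  inst <- instances[instances$passes_qc, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(micro_annots))) {
    for (j in seq_len(nrow(inst))) {
      cls <- which(classes$class_id == inst$class_id[j])
      if (micro_annots$domain_acc[i] %in% classes$binding_domains[[cls]]) {
        rows[[length(rows) + 1]] <- sprintf(
          "%s|%s|%s|%s|%d|%d",
          micro_annots$protein_id[i], inst$protein_id[j],
          micro_annots$domain_acc[i], inst$class_id[j],
          inst$start[j], inst$end[j]
        )
      }
    }
  }
  sort(unique(unlist(rows, use.names = FALSE))) %||% character(0)
}

dm_to_keys <- function(pred) {
  sort(unique(sprintf(
    "%s|%s|%s|%s|%d|%d",
    pred$microbial_id, pred$host_id, pred$microbial_domain, pred$class_id,
    pred$motif_start, pred$motif_end
  )))
}

# Per-position anchored regex matching: a match starts at s iff the
# pattern, anchored, matches the suffix starting at s.
motif_scan_oracle <- function(seq, pattern) {
  n <- nchar(seq)
  out <- list()
  for (s in seq_len(n)) {
    m <- regexpr(paste0("^(?:", pattern, ")"), substr(seq, s, n),
                 perl = TRUE)
    if (m == 1L && attr(m, "match.length") >= 1L) {
      out[[length(out) + 1]] <- c(s, s + attr(m, "match.length") - 1L)
    }
  }
  out
}

# All simple paths receptor -> target with <= max_len edges, via igraph,
# expanded over every per-step layer assignment.
chain_oracle <- function(edges, receptors, targets, max_len) {
  g <- igraph::graph_from_data_frame(
    unique(edges[, c("source", "target")]),
    directed = TRUE,
    vertices = sort(unique(c(edges$source, edges$target)))
  )
  layer_of <- split(edges$layer, paste(edges$source, edges$target))
  keys <- character(0)
  for (r in intersect(receptors, igraph::V(g)$name)) {
    paths <- igraph::all_simple_paths(
      g, from = r, to = intersect(targets, igraph::V(g)$name),
      mode = "out", cutoff = max_len
    )
    for (p in paths) {
      nodes <- igraph::V(g)$name[p]
      steps <- lapply(seq_len(length(nodes) - 1), function(e) {
        sort(unique(layer_of[[paste(nodes[e], nodes[e + 1])]]))
      })
      combos <- expand.grid(steps, stringsAsFactors = FALSE)
      for (ci in seq_len(nrow(combos))) {
        keys <- c(keys, paste(
          paste(nodes, collapse = "|"),
          paste(unlist(combos[ci, ]), collapse = "|"),
          sep = "#"
        ))
      }
    }
  }
  sort(unique(keys))
}

chains_to_keys <- function(chains) {
  sort(unique(vapply(seq_len(nrow(chains)), function(i) {
    paste(
      paste(chains$nodes[[i]], collapse = "|"),
      paste(chains$edge_layers[[i]], collapse = "|"),
      sep = "#"
    )
  }, character(1))))
}

# Exact hypergeometric upper tail by binomial-coefficient enumeration
# (exact in double precision for N <= 25).
hyper_tail_oracle <- function(k, n, K, N) {
  i <- seq(k, min(n, K))
  if (length(i) == 0 || k > min(n, K)) {
    if (k == 0) return(1)
  }
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random small annotation/gold instance for the prediction oracles.
random_dd_instance <- function() {
  n_m <- sample(1:10, 1)
  n_h <- sample(1:10, 1)
  doms <- sprintf("PF%05d", 1:8)
  micro <- do.call(rbind, lapply(seq_len(n_m), function(i) {
    k <- sample(1:5, 1)
    data.frame(
      protein_id = sprintf("m%02d", i),
      domain_acc = sample(doms, k, replace = TRUE),
      start = sample(1:50, k, replace = TRUE), end = 60L,
      globular = TRUE, stringsAsFactors = FALSE
    )
  }))
  host <- do.call(rbind, lapply(seq_len(n_h), function(i) {
    k <- sample(1:5, 1)
    data.frame(
      protein_id = sprintf("h%02d", i),
      domain_acc = sample(doms, k, replace = TRUE),
      start = sample(1:50, k, replace = TRUE), end = 60L,
      globular = TRUE, stringsAsFactors = FALSE
    )
  }))
  ng <- sample(0:6, 1)
  gold <- if (ng == 0) {
    data.frame(domain_a = character(0), domain_b = character(0),
               stringsAsFactors = FALSE)
  } else {
    a <- sample(doms, ng, replace = TRUE)
    b <- sample(doms, ng, replace = TRUE)
    unique(data.frame(domain_a = pmin(a, b), domain_b = pmax(a, b),
                      stringsAsFactors = FALSE))
  }
  list(micro = micro, host = host, gold = gold)
}

random_graph_edges <- function(n_nodes = NULL, p = 0.12) {
  if (is.null(n_nodes)) n_nodes <- sample(5:30, 1)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- stats::runif(nrow(pairs)) < p
  edges <- pairs[pick, , drop = FALSE]
  if (nrow(edges) == 0) {
    edges <- pairs[sample(nrow(pairs), 2), , drop = FALSE]
  }
  edges$layer <- sample(c("PPI", "TRI"), nrow(edges), replace = TRUE)
  edges$sign <- 0L
  rownames(edges) <- NULL
  edges
}

make_net <- function(df) {
  multilayer_network(data.frame(
    source = df$source, target = df$target, layer = df$layer,
    sign = df$sign %||% 0L, stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
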