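#' Write a multilayer network edge list
#'
#' Inverse of [read_edge_list()]: writing then reading reproduces the
#' network exactly.
#'
#' @param network An `mhl_network`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(network, path) {
  write_tsv_table(as.data.frame(network)[, c("source", "target", "layer", "sign")], path)
  invisible(path)
}

#' Write signalling chains
#'
#' One chain per row: the initiating microbial proteins (comma-joined), the
#' condition label, the node path joined by `|` and the edge layers joined
#' by `|`.
#'
#' @param chains A chain table (see [enumerate_chains()]).
#' @param path Output TSV path.
#' @export
write_chains <- function(chains, path) {
  df <- data.frame(
    microbial_ids = vapply(chains$microbial_ids, function(x) {
      paste(sort(x), collapse = ",")
    }, character(1)),
    condition = chains$condition,
    nodes = vapply(chains$nodes, paste, character(1), collapse = "|"),
    edge_layers = vapply(chains$edge_layers, paste, character(1),
                         collapse = "|"),
    stringsAsFactors = FALSE
  )
  write_tsv_table(df, path)
  invisible(path)
}

#' Write the final model (SIF, edge list, chains)
#'
#' Emits three files under a common prefix: `<prefix>.sif` with
#' `source <tab> relation <tab> target` rows where the relation is
#' `layer:sign`; `<prefix>_edges.tsv` in the exact schema read by
#' [read_edge_list()] (the round trip is the identity on the network); and
#' `<prefix>_chains.tsv` via [write_chains()].
#'
#' @param network Nonempty `mhl_network`.
#' @param chains Chain table (may have zero rows).
#' @param path_prefix Path prefix for the three output files.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_model <- function(network, chains, path_prefix) {
  if (nrow(network) == 0) {
    mhl_stop("cannot write an empty network model", "mhl_io_error")
  }
  sif_path <- paste0(path_prefix, ".sif")
  edges_path <- paste0(path_prefix, "_edges.tsv")
  chains_path <- paste0(path_prefix, "_chains.tsv")
  sif <- sprintf(
    "%s\t%s:%+d\t%s", network$source, network$layer, network$sign,
    network$target
  )
  writeLines(sif, sif_path)
  write_edge_list(network, edges_path)
  write_chains(chains, chains_path)
  invisible(c(sif = sif_path, edges = edges_path, chains = chains_path))
}

#' Write a heat vector as a two-column TSV
#'
#' @param heat Named numeric vector (node id to heat).
#' @param path Output TSV path.
#' @export
write_heat <- function(heat, path) {
  df <- data.frame(
    node = names(heat), heat = sprintf("%.12g", unname(heat)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$node), , drop = FALSE]
  write_tsv_table(df, path)
  invisible(path)
}

# FASTA writer used by the fixture generator (60-column wrapping).
write_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    seq <- proteins$sequence[i]
    starts <- seq(1, nchar(seq), by = 60)
    writeLines(substring(seq, starts, pmin(starts + 59, nchar(seq))), con)
  }
  invisible(path)
}
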