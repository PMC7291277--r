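#' Read a protein FASTA file
#'
#' Parses a protein FASTA file into a protein table. The header token up to
#' the first whitespace becomes the protein id; sequences are uppercased and
#' the ambiguity codes U, B, Z and J are collapsed to X (metaproteomic
#' contigs routinely contain ambiguous translations, so these are accepted
#' rather than rejected).
#'
#' @param path Path to a FASTA file.
#' @param side Which side of the interface the proteins belong to, either
#'   `"microbial"` or `"host"`.
#' @return A data frame with columns `id`, `sequence`, `side` and a
#'   list-column `localizations` (empty until [attach_localizations()] is
#'   called). One row per FASTA entry; zero rows for an empty file.
#' @details Duplicate ids, empty sequences and characters outside the
#'   20-letter amino-acid alphabet plus X (after ambiguity mapping) are hard
#'   errors.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 desc", "MKV", ">p2", "ACD"), fa)
#' read_protein_fasta(fa, side = "host")
#' @export
read_protein_fasta <- function(path, side = c("microbial", "host")) {
  side <- match.arg(side)
  if (!file.exists(path)) {
    mhl_stop(sprintf("file not found: %s", path), "mhl_io_error")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(
    strsplit(names(aa), "[ \t]"), function(x) x[1], character(1)
  )
  if (length(ids) == 0) {
    return(protein_table(character(0), character(0), side))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    mhl_stop(
      sprintf("duplicate protein id(s): %s", paste(unique(dup), collapse = ", ")),
      "mhl_io_error"
    )
  }
  seqs <- toupper(as.character(aa))
  names(seqs) <- NULL
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    mhl_stop(
      sprintf("empty sequence for protein '%s'", ids[empty[1]]),
      "mhl_io_error"
    )
  }
  seqs <- chartr("UBZJ", "XXXX", seqs)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    mhl_stop(
      sprintf(
        "invalid amino-acid character '%s' at position %d of protein '%s'",
        substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]
      ),
      "mhl_io_error"
    )
  }
  protein_table(ids, seqs, side)
}

protein_table <- function(ids, seqs, side) {
  df <- data.frame(
    id = ids, sequence = seqs, side = rep(side, length(ids)),
    stringsAsFactors = FALSE
  )
  df$localizations <- rep(list(character(0)), nrow(df))
  df
}

#' Read protein localization annotations
#'
#' @param path Tab-separated file with header columns `protein_id` and
#'   `localization` (one row per protein/compartment pair).
#' @return A data frame with columns `protein_id` and `localization`.
#' @seealso [attach_localizations()]
#' @export
read_localizations <- function(path) {
  df <- read_tsv_table(path, c("protein_id", "localization"))
  bad <- which(df$protein_id == "" | df$localization == "")
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("%s: blank field at row %d", path, bad[1]), "mhl_row_error"
    )
  }
  df[order(df$protein_id, df$localization), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Attach localization tags to a protein table
#'
#' @param proteins A protein table from [read_protein_fasta()].
#' @param locs A localization table from [read_localizations()]. Rows for
#'   proteins absent from `proteins` are ignored.
#' @return `proteins` with its `localizations` list-column filled.
#' @export
attach_localizations <- function(proteins, locs) {
  by_prot <- split(locs$localization, locs$protein_id)
  proteins$localizations <- lapply(proteins$id, function(id) {
    sort(unique(by_prot[[id]] %||% character(0)))
  })
  proteins
}

#' Read protein domain annotations
#'
#' Reads Pfam-style domain annotations with 1-based inclusive residue
#' coordinates. The optional `globular` column marks folded domains; it
#' defaults to `TRUE` for every row, a conservative choice because motif
#' matches inside folded domains are sterically implausible and should be
#' rejected unless a curated non-globular flag says otherwise.
#'
#' @param path Tab-separated file with header columns `protein_id`,
#'   `domain_acc`, `start`, `end` and optionally `globular`.
#' @param proteins Optional protein table; when given, annotation
#'   coordinates are checked against sequence lengths.
#' @return A data frame with columns `protein_id`, `domain_acc`, `start`,
#'   `end` (integer, 1-based inclusive) and `globular` (logical).
#' @export
read_domain_annotations <- function(path, proteins = NULL) {
  df <- read_tsv_table(path, c("protein_id", "domain_acc", "start", "end"))
  if (nrow(df) == 0) {
    return(data.frame(
      protein_id = character(0), domain_acc = character(0),
      start = integer(0), end = integer(0), globular = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  bad <- which(df$protein_id == "" | df$domain_acc == "")
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("%s: blank protein or domain accession at row %d", path, bad[1]),
      "mhl_row_error"
    )
  }
  start <- parse_int(df$start)
  end <- parse_int(df$end)
  validate_coords(start, end, path)
  globular <- if ("globular" %in% names(df)) {
    tolower(df$globular) %in% c("true", "t", "1", "yes")
  } else {
    rep(TRUE, nrow(df))
  }
  out <- data.frame(
    protein_id = df$protein_id, domain_acc = df$domain_acc,
    start = start, end = end, globular = globular,
    stringsAsFactors = FALSE
  )
  if (!is.null(proteins)) {
    len <- stats::setNames(nchar(proteins$sequence), proteins$id)
    known <- out$protein_id %in% names(len)
    over <- which(known & out$end > len[out$protein_id])
    if (length(over) > 0) {
      i <- over[1]
      mhl_stop(
        sprintf(
          "%s: annotation end %d exceeds length of protein '%s'",
          path, out$end[i], out$protein_id[i]
        ),
        "mhl_row_error"
      )
    }
  }
  out <- out[order(out$protein_id, out$domain_acc, out$start, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gold-standard table of interacting domain pairs
#'
#' Pairs are unordered: `(A, B)` and `(B, A)` denote the same interacting
#' pair and are stored order-normalized (lexicographically smaller accession
#' first) with duplicates collapsed. A self pair `(A, A)` is a valid
#' self-interacting domain family and is retained.
#'
#' @param path Tab-separated file with header columns `domain_a`, `domain_b`.
#' @return A data frame with columns `domain_a`, `domain_b`
#'   (`domain_a <= domain_b` in every row), one row per distinct pair.
#' @export
read_domain_pairs <- function(path) {
  df <- read_tsv_table(path, c("domain_a", "domain_b"))
  bad <- which(df$domain_a == "" | df$domain_b == "")
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("%s: blank domain accession at row %d", path, bad[1]),
      "mhl_row_error"
    )
  }
  normalize_domain_pairs(df$domain_a, df$domain_b)
}

normalize_domain_pairs <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- unique(data.frame(
    domain_a = lo, domain_b = hi, stringsAsFactors = FALSE
  ))
  out <- out[order(out$domain_a, out$domain_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a motif class table
#'
#' Each motif class carries a regular expression over amino-acid letters and
#' the set of partner domain accessions known to bind instances of the
#' class, in the style of linear-motif resources.
#'
#' @param path Tab-separated file with header columns `class_id`, `pattern`
#'   and `binding_domains` (comma-separated accessions).
#' @return A data frame with columns `class_id`, `pattern` and a list-column
#'   `binding_domains` (character vectors, split on commas and trimmed).
#' @details A pattern that does not compile as a (Perl-compatible) regular
#'   expression, or an empty binding-domain set, is a row error naming the
#'   class.
#' @export
read_motif_classes <- function(path) {
  df <- read_tsv_table(path, c("class_id", "pattern", "binding_domains"))
  if (nrow(df) == 0) {
    return(data.frame(
      class_id = character(0), pattern = character(0),
      binding_domains = I(list()), stringsAsFactors = FALSE
    ))
  }
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch(
      {
        grepl(df$pattern[i], "", perl = TRUE)
        TRUE
      },
      error = function(e) FALSE,
      warning = function(w) FALSE
    )
    if (!ok) {
      mhl_stop(
        sprintf(
          "%s: invalid regular expression for class '%s'", path, df$class_id[i]
        ),
        "mhl_row_error"
      )
    }
  }
  doms <- lapply(strsplit(df$binding_domains, ","), function(x) {
    x <- trimws(x)
    sort(unique(x[x != ""]))
  })
  empty <- which(vapply(doms, length, integer(1)) == 0)
  if (length(empty) > 0) {
    mhl_stop(
      sprintf(
        "%s: empty binding_domains for class '%s'", path, df$class_id[empty[1]]
      ),
      "mhl_row_error"
    )
  }
  out <- data.frame(
    class_id = df$class_id, pattern = df$pattern, stringsAsFactors = FALSE
  )
  out$binding_domains <- doms
  out <- out[order(out$class_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a directed multilayer network edge list
#'
#' Edges are typed by layer: `PPI` (protein-protein interaction) or `TRI`
#' (transcriptional regulatory interaction, a directed TF-to-gene edge). An
#' optional `sign` column records activation (+1), inhibition (-1) or
#' unknown (0, the default). Duplicate `(source, target, layer)` rows are
#' collapsed, keeping a known sign over an unknown one; conflicting known
#' signs (+1 and -1 for the same typed edge) are a hard error because
#' contradictory curation must be surfaced, not silently resolved.
#'
#' @param path Tab-separated file with header columns `source`, `target`,
#'   `layer` and optionally `sign`.
#' @return A multilayer network: a data frame with columns `source`,
#'   `target`, `layer`, `sign` (integer), sorted for deterministic
#'   downstream behaviour, with class `mhl_network`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_table(path, c("source", "target", "layer"))
  if (nrow(df) == 0) {
    return(multilayer_network(data.frame(
      source = character(0), target = character(0),
      layer = character(0), sign = integer(0), stringsAsFactors = FALSE
    )))
  }
  bad <- which(df$source == "" | df$target == "")
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("%s: blank node id at row %d", path, bad[1]), "mhl_row_error"
    )
  }
  bad <- which(!df$layer %in% c("PPI", "TRI"))
  if (length(bad) > 0) {
    mhl_stop(
      sprintf(
        "%s: unknown layer '%s' at row %d (expected PPI or TRI)",
        path, df$layer[bad[1]], bad[1]
      ),
      "mhl_row_error"
    )
  }
  sign <- if ("sign" %in% names(df)) {
    s <- suppressWarnings(as.integer(df$sign))
    if (any(is.na(s) | !s %in% c(-1L, 0L, 1L))) {
      i <- which(is.na(s) | !s %in% c(-1L, 0L, 1L))[1]
      mhl_stop(
        sprintf("%s: invalid sign '%s' at row %d", path, df$sign[i], i),
        "mhl_row_error"
      )
    }
    s
  } else {
    rep(0L, nrow(df))
  }
  edges <- data.frame(
    source = df$source, target = df$target, layer = df$layer, sign = sign,
    stringsAsFactors = FALSE
  )
  key <- paste(edges$source, edges$target, edges$layer, sep = "\r")
  collapsed <- lapply(split(seq_len(nrow(edges)), key), function(idx) {
    signs <- unique(edges$sign[idx])
    known <- setdiff(signs, 0L)
    if (length(known) > 1) {
      mhl_stop(
        sprintf(
          "sign conflict for edge %s -> %s (%s): both +1 and -1 present",
          edges$source[idx[1]], edges$target[idx[1]], edges$layer[idx[1]]
        ),
        "mhl_io_error"
      )
    }
    i <- idx[1]
    data.frame(
      source = edges$source[i], target = edges$target[i],
      layer = edges$layer[i],
      sign = if (length(known) == 1) known else 0L,
      stringsAsFactors = FALSE
    )
  })
  multilayer_network(do.call(rbind, collapsed))
}

#' Construct a multilayer network from an edge data frame
#'
#' @param edges Data frame with columns `source`, `target`, `layer`, `sign`.
#' @return The edge data frame, sorted by (source, target, layer), with
#'   class `mhl_network`.
#' @export
multilayer_network <- function(edges) {
  stopifnot(all(c("source", "target", "layer", "sign") %in% names(edges)))
  key <- paste(edges$source, edges$target, edges$layer, sep = "\r")
  if (anyDuplicated(key)) {
    mhl_stop("duplicate (source, target, layer) edges", "mhl_io_error")
  }
  edges <- edges[order(edges$source, edges$target, edges$layer), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("mhl_network", "data.frame")
  edges
}

#' Nodes of a multilayer network
#'
#' @param network An `mhl_network` (or any edge data frame with `source` and
#'   `target` columns).
#' @return Sorted character vector of node ids.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$source, network$target)))
}

#' Read a weighted node set
#'
#' Used both for diffusion seeds and for target genes: each node carries a
#' nonnegative weight (e.g. an absolute log-fold-change, or a count of bound
#' microbial proteins) and an optional direction of change.
#'
#' @param path Tab-separated file with header column `node`, and optionally
#'   `weight` (default 1) and `direction` (-1, 0 or +1; default 0).
#' @return A data frame with columns `node`, `weight` (numeric, >= 0) and
#'   `direction` (integer in -1/0/+1).
#' @export
read_weighted_nodes <- function(path) {
  df <- read_tsv_table(path, "node")
  if (nrow(df) == 0) {
    mhl_stop(sprintf("%s: empty node set", path), "mhl_io_error")
  }
  w <- if ("weight" %in% names(df)) {
    suppressWarnings(as.numeric(df$weight))
  } else {
    rep(1, nrow(df))
  }
  if (any(is.na(w) | w < 0)) {
    mhl_stop(
      sprintf("%s: weights must be nonnegative numbers", path), "mhl_row_error"
    )
  }
  if (all(w == 0)) {
    mhl_stop(
      sprintf("%s: at least one weight must be positive", path), "mhl_io_error"
    )
  }
  d <- if ("direction" %in% names(df)) {
    s <- suppressWarnings(as.integer(df$direction))
    if (any(is.na(s) | !s %in% c(-1L, 0L, 1L))) {
      mhl_stop(
        sprintf("%s: direction must be -1, 0 or +1", path), "mhl_row_error"
      )
    }
    s
  } else {
    rep(0L, nrow(df))
  }
  out <- data.frame(
    node = df$node, weight = w, direction = d, stringsAsFactors = FALSE
  )
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a microbial-protein condition map
#'
#' @param path Tab-separated file with header columns `microbial_id` and
#'   `condition`; a protein detected in several conditions occupies several
#'   rows.
#' @return A named list mapping microbial protein id to a sorted character
#'   vector of condition labels.
#' @export
read_conditions <- function(path) {
  df <- read_tsv_table(path, c("microbial_id", "condition"))
  bad <- which(df$microbial_id == "" | df$condition == "")
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("%s: blank field at row %d", path, bad[1]), "mhl_row_error"
    )
  }
  lapply(split(df$condition, df$microbial_id), function(x) sort(unique(x)))
}

#' Read term annotations for over-representation analysis
#'
#' @param path Tab-separated file with header columns `term_id` and
#'   `protein_id` (GAF-like, one association per row).
#' @param names_path Optional tab-separated file with header columns
#'   `term_id`, `term_name`.
#' @return A data frame with columns `term_id`, `term_name` and a
#'   list-column `proteins` (sorted unique protein ids); terms with no
#'   annotated protein cannot arise (each input row names one).
#' @export
read_term_annotations <- function(path, names_path = NULL) {
  df <- read_tsv_table(path, c("term_id", "protein_id"))
  bad <- which(df$term_id == "" | df$protein_id == "")
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("%s: blank field at row %d", path, bad[1]), "mhl_row_error"
    )
  }
  by_term <- lapply(split(df$protein_id, df$term_id), function(x) {
    sort(unique(x))
  })
  term_ids <- sort(names(by_term))
  nm <- stats::setNames(term_ids, term_ids)
  if (!is.null(names_path)) {
    nmap <- read_tsv_table(names_path, c("term_id", "term_name"))
    hit <- term_ids %in% nmap$term_id
    nm[hit] <- nmap$term_name[match(term_ids[hit], nmap$term_id)]
  }
  out <- data.frame(
    term_id = term_ids, term_name = unname(nm), stringsAsFactors = FALSE
  )
  out$proteins <- unname(by_term[term_ids])
  out
}

#' Read a per-residue disorder score file
#'
#' @param path Two-column tab-separated file with header columns `position`
#'   (1-based residue index) and `score` (in `[0, 1]`).
#' @return Numeric vector of scores ordered by position (positions must be
#'   the contiguous range 1..n).
#' @export
read_disorder_profile <- function(path) {
  df <- read_tsv_table(path, c("position", "score"))
  pos <- parse_int(df$position)
  score <- suppressWarnings(as.numeric(df$score))
  if (any(is.na(pos)) || any(is.na(score))) {
    mhl_stop(sprintf("%s: malformed disorder row", path), "mhl_row_error")
  }
  if (any(score < 0 | score > 1)) {
    mhl_stop(
      sprintf("%s: disorder scores must lie in [0, 1]", path), "mhl_row_error"
    )
  }
  o <- order(pos)
  pos <- pos[o]
  if (!identical(pos, seq_along(pos))) {
    mhl_stop(
      sprintf("%s: positions must be the contiguous range 1..n", path),
      "mhl_row_error"
    )
  }
  score[o]
}

#' Read signalling chains written by [write_model()]
#'
#' @param path Chains file (`<prefix>_chains.tsv`).
#' @return A chain table as produced by [enumerate_chains()].
#' @export
read_chains <- function(path) {
  df <- read_tsv_table(
    path, c("microbial_ids", "condition", "nodes", "edge_layers")
  )
  chain_table(
    microbial_ids = lapply(strsplit(df$microbial_ids, ","), function(x) {
      sort(x[x != ""])
    }),
    condition = df$condition,
    nodes = strsplit(df$nodes, "|", fixed = TRUE),
    edge_layers = lapply(strsplit(df$edge_layers, "|", fixed = TRUE),
                         function(x) x[x != ""])
  )
}
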