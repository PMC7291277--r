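#' Filter proteins by subcellular localization
#'
#' Keeps proteins whose localization tags intersect the allowed set.
#' Proteins with no localization evidence are excluded: for an interaction
#' at the microbe-host interface the protein must be demonstrably in a
#' compartment physically accessible to the partner (for extracellular
#' microbes, the extracellular matrix or plasma membrane).
#'
#' @param proteins Protein table with a `localizations` list-column (see
#'   [attach_localizations()]).
#' @param allowed Nonempty character vector of allowed localization tags.
#' @return The filtered protein table.
#' @export
filter_by_localization <- function(proteins, allowed) {
  if (length(allowed) == 0) {
    mhl_stop("allowed localization set must be nonempty", "mhl_param_error")
  }
  keep <- vapply(proteins$localizations, function(tags) {
    length(intersect(tags, allowed)) > 0
  }, logical(1))
  out <- proteins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict interactions by the domain-domain method
#'
#' A microbial and a host protein are predicted to interact when they carry
#' a pair of domains with gold-standard evidence of interaction. Matching is
#' unordered: the gold pair (A, B) fires whether A sits on the microbial and
#' B on the host protein or vice versa. One prediction is emitted per
#' (microbial protein, host protein, gold pair, microbial annotation, host
#' annotation) combination.
#'
#' @param microbial_annots,host_annots Domain annotation tables (see
#'   [read_domain_annotations()]) for the two sides.
#' @param gold Gold-standard domain pair table (see [read_domain_pairs()]).
#' @return A data frame of predictions with columns `microbial_id`,
#'   `host_id`, `evidence` (`"domain_domain"`), `microbial_domain`,
#'   `host_domain`, `m_start`, `m_end`, `h_start`, `h_end`.
#' @export
predict_domain_domain <- function(microbial_annots, host_annots, gold) {
  empty <- data.frame(
    microbial_id = character(0), host_id = character(0),
    evidence = character(0), microbial_domain = character(0),
    host_domain = character(0), m_start = integer(0), m_end = integer(0),
    h_start = integer(0), h_end = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(gold) == 0 || nrow(microbial_annots) == 0 ||
      nrow(host_annots) == 0) {
    return(empty)
  }
  # Both orientations of each unordered pair; a self pair fires once.
  ori <- rbind(
    data.frame(md = gold$domain_a, hd = gold$domain_b,
               stringsAsFactors = FALSE),
    data.frame(md = gold$domain_b, hd = gold$domain_a,
               stringsAsFactors = FALSE)
  )
  ori <- unique(ori)
  m <- merge(microbial_annots, ori, by.x = "domain_acc", by.y = "md")
  if (nrow(m) == 0) {
    return(empty)
  }
  hit <- merge(
    m, host_annots,
    by.x = "hd", by.y = "domain_acc", suffixes = c(".m", ".h")
  )
  if (nrow(hit) == 0) {
    return(empty)
  }
  out <- data.frame(
    microbial_id = hit$protein_id.m, host_id = hit$protein_id.h,
    evidence = "domain_domain",
    microbial_domain = hit$domain_acc, host_domain = hit$hd,
    m_start = hit$start.m, m_end = hit$end.m,
    h_start = hit$start.h, h_end = hit$end.h,
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan host proteins for motif class matches
#'
#' Matches each motif-class regular expression against each protein
#' sequence, reporting every position-distinct match including overlapping
#' ones (after a match at position s, scanning restarts at s + 1; linear
#' motif semantics permit overlapping instances). Matches are unanchored.
#' QC fields are initialized to passing and are overwritten by
#' [apply_steric_qc()].
#'
#' @param proteins Protein table (one or more host-side rows).
#' @param classes Motif class table (see [read_motif_classes()]).
#' @return A motif instance table with columns `protein_id`, `class_id`,
#'   `start`, `end` (1-based inclusive), `matched_subsequence`,
#'   `disordered_fraction`, `overlaps_globular`, `passes_qc`.
#' @export
scan_motifs <- function(proteins, classes) {
  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    n <- nchar(seq)
    for (j in seq_len(nrow(classes))) {
      pat <- classes$pattern[j]
      from <- 1L
      while (from <= n) {
        m <- regexpr(pat, substr(seq, from, n), perl = TRUE)
        if (m == -1L) break
        len <- attr(m, "match.length")
        s <- from + as.integer(m) - 1L
        if (len < 1L) { # zero-width match: advance without reporting
          from <- s + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = proteins$id[i], class_id = classes$class_id[j],
          start = s, end = s + len - 1L,
          matched_subsequence = substr(seq, s, s + len - 1L),
          stringsAsFactors = FALSE
        )
        from <- s + 1L
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(
      protein_id = character(0), class_id = character(0),
      start = integer(0), end = integer(0),
      matched_subsequence = character(0), stringsAsFactors = FALSE
    )
  } else {
    do.call(rbind, rows)
  }
  out$disordered_fraction <- rep(1, nrow(out))
  out$overlaps_globular <- rep(FALSE, nrow(out))
  out$passes_qc <- rep(TRUE, nrow(out))
  out <- out[order(out$protein_id, out$class_id, out$start, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Steric quality control of motif instances
#'
#' Linear motifs are functional only when sterically accessible: the match
#' must lie within an intrinsically disordered region and outside folded
#' (globular) domains. For each instance this computes the fraction of its
#' residues with disorder score >= 0.5, flags overlap (by at least one
#' residue) with any globular-flagged domain annotation on the same
#' protein, and sets `passes_qc` to
#' `disordered_fraction >= theta && !overlaps_globular`.
#'
#' All instances are returned with their flags; downstream prediction uses
#' only the passing ones.
#'
#' @param instances Motif instance table from [scan_motifs()].
#' @param profiles Named list mapping protein id to a per-residue disorder
#'   score vector ([compute_disorder()] or [read_disorder_profile()]).
#' @param annots Host domain annotation table.
#' @param theta Minimum disordered fraction in `[0, 1]`; default 1.0, the
#'   strict reading that the whole motif must sit inside a disordered
#'   region.
#' @return The instance table with `disordered_fraction`,
#'   `overlaps_globular` and `passes_qc` recomputed.
#' @export
apply_steric_qc <- function(instances, profiles, annots, theta = 1.0) {
  if (length(theta) != 1 || is.na(theta) || theta < 0 || theta > 1) {
    mhl_stop("theta must be a single value in [0, 1]", "mhl_param_error")
  }
  if (nrow(instances) == 0) {
    return(instances)
  }
  missing <- setdiff(unique(instances$protein_id), names(profiles))
  if (length(missing) > 0) {
    mhl_stop(
      sprintf(
        "no disorder profile for protein(s): %s",
        paste(missing, collapse = ", ")
      ),
      "mhl_param_error"
    )
  }
  glob <- annots[annots$globular, , drop = FALSE]
  for (i in seq_len(nrow(instances))) {
    pid <- instances$protein_id[i]
    s <- instances$start[i]
    e <- instances$end[i]
    scores <- profiles[[pid]]
    if (e > length(scores)) {
      mhl_stop(
        sprintf(
          "disorder profile for '%s' shorter than motif end %d", pid, e
        ),
        "mhl_param_error"
      )
    }
    instances$disordered_fraction[i] <- mean(scores[s:e] >= 0.5)
    g <- glob[glob$protein_id == pid, , drop = FALSE]
    instances$overlaps_globular[i] <-
      nrow(g) > 0 && any(g$start <= e & g$end >= s)
  }
  instances$passes_qc <- instances$disordered_fraction >= theta &
    !instances$overlaps_globular
  instances
}

#' Predict interactions by the domain-motif method
#'
#' A microbial and a host protein are predicted to interact when the
#' microbial protein carries a domain known to bind a motif class and the
#' host protein carries a QC-passing instance of that class. One prediction
#' per (microbial domain annotation, motif instance) combination.
#'
#' @param microbial_annots Microbial domain annotation table.
#' @param instances Motif instance table; only rows with `passes_qc == TRUE`
#'   are used.
#' @param classes Motif class table; every instance's `class_id` must be
#'   present.
#' @return A data frame of predictions with columns `microbial_id`,
#'   `host_id`, `evidence` (`"domain_motif"`), `microbial_domain`,
#'   `class_id`, `motif_start`, `motif_end`, `matched_subsequence`.
#' @export
predict_domain_motif <- function(microbial_annots, instances, classes) {
  empty <- data.frame(
    microbial_id = character(0), host_id = character(0),
    evidence = character(0), microbial_domain = character(0),
    class_id = character(0), motif_start = integer(0),
    motif_end = integer(0), matched_subsequence = character(0),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(instances$class_id), classes$class_id)
  if (length(unknown) > 0) {
    mhl_stop(
      sprintf(
        "motif instance(s) reference unknown class(es): %s",
        paste(unknown, collapse = ", ")
      ),
      "mhl_param_error"
    )
  }
  if ("passes_qc" %in% names(instances)) {
    instances <- instances[instances$passes_qc, , drop = FALSE]
  }
  if (nrow(instances) == 0 || nrow(microbial_annots) == 0) {
    return(empty)
  }
  # class -> binding domain long table, joined against microbial domains
  link <- do.call(rbind, lapply(seq_len(nrow(classes)), function(j) {
    data.frame(
      class_id = classes$class_id[j],
      domain_acc = classes$binding_domains[[j]],
      stringsAsFactors = FALSE
    )
  }))
  md <- merge(microbial_annots, link, by = "domain_acc")
  if (nrow(md) == 0) {
    return(empty)
  }
  hit <- merge(instances, md, by = "class_id",
               suffixes = c(".inst", ".annot"))
  if (nrow(hit) == 0) {
    return(empty)
  }
  out <- data.frame(
    microbial_id = hit$protein_id.annot, host_id = hit$protein_id.inst,
    evidence = "domain_motif", microbial_domain = hit$domain_acc,
    class_id = hit$class_id, motif_start = hit$start.inst %||% hit$start,
    motif_end = hit$end.inst %||% hit$end,
    matched_subsequence = hit$matched_subsequence,
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge predictions and derive receptor weights
#'
#' Takes the union of domain-domain and domain-motif predictions (the two
#' evidence types are kept as separate records; duplicates within an
#' evidence type are collapsed) and weights each host receptor by the
#' number of distinct microbial proteins predicted to bind it. These
#' weights later seed the forward diffusion.
#'
#' @param dd Domain-domain prediction table.
#' @param dm Domain-motif prediction table.
#' @return A list with `interactions` (merged prediction table) and
#'   `receptor_weights` (weighted node set: `node`, `weight`, `direction`).
#' @export
merge_predictions <- function(dd, dm) {
  all_cols <- union(names(dd), names(dm))
  pad <- function(df) {
    for (col in setdiff(all_cols, names(df))) {
      df[[col]] <- rep(NA, nrow(df))
    }
    df[, all_cols, drop = FALSE]
  }
  merged <- unique(rbind(pad(dd), pad(dm)))
  if (nrow(merged) > 0) {
    merged <- merged[do.call(order, merged), , drop = FALSE]
  }
  rownames(merged) <- NULL
  if (nrow(merged) == 0) {
    weights <- data.frame(
      node = character(0), weight = numeric(0), direction = integer(0),
      stringsAsFactors = FALSE
    )
  } else {
    counts <- tapply(
      merged$microbial_id, merged$host_id,
      function(x) length(unique(x))
    )
    weights <- data.frame(
      node = names(counts), weight = as.numeric(counts),
      direction = 0L, stringsAsFactors = FALSE
    )
    weights <- weights[order(weights$node), , drop = FALSE]
    rownames(weights) <- NULL
  }
  list(interactions = merged, receptor_weights = weights)
}

#' Map receptors to the microbial proteins predicted to bind them
#'
#' @param interactions A prediction table (see [merge_predictions()]).
#' @return Named list: host receptor id to sorted distinct microbial ids;
#'   suitable for the `receptor_microbes` argument of
#'   [enumerate_chains()].
#' @export
receptor_microbe_map <- function(interactions) {
  if (nrow(interactions) == 0) {
    return(list())
  }
  lapply(
    split(interactions$microbial_id, interactions$host_id),
    function(x) sort(unique(x))
  )
}
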