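# Synthetic fixture generation with planted, provable ground truth.
#
# Design notes on alphabets: background sequence uses only residues that
# appear neither in any motif pattern nor in the charged disorder tracts,
# motif patterns are literal words over {W, C, M, F}, and disordered
# stretches are runs over {K, E, D, R}. Consequences, provable rather than
# probabilistic: (a) a pattern matches exactly at planted and decoy sites
# and nowhere else; (b) inside a charged run flanked by at least one window
# half-width of charged residues, the windowed fold index is analytically
# negative (mean rescaled hydropathy <= 0.17 and the charge/offset terms
# dominate), so every planted motif residue scores disordered.
BG_ALPHABET <- c("A", "G", "S", "T", "L", "V", "I", "P", "N", "Q")
MOTIF_ALPHABET <- c("W", "C", "M", "F")
CHARGED_ALPHABET <- c("K", "E", "D", "R")

#' Specification of a synthetic fixture
#'
#' Bundles all shape parameters of the generated study: proteome sizes,
#' planted interaction counts, decoy count, network shape and condition
#' labels. The single seed fixes every random draw, so a spec generates
#' byte-identical files on every run.
#'
#' @param seed Integer RNG seed.
#' @param n_microbial,n_host Proteome sizes.
#' @param n_planted_dm Planted domain-motif interactions (each gets its own
#'   motif class, binding domain, microbial protein and host protein).
#' @param n_planted_dd Planted domain-domain interactions (each gets its
#'   own gold domain pair).
#' @param n_decoy_ordered Decoy motif matches placed strictly inside
#'   globular-flagged domains (must fail steric QC).
#' @param n_targets Number of target genes.
#' @param n_planted_paths Planted receptor-to-target signalling paths
#'   (must not exceed `n_planted_dm`).
#' @param path_length Edges per planted path (>= 2); all steps are PPI
#'   except the final TF-to-target TRI step.
#' @param n_distractor_nodes,n_distractor_edges Distractor subgraph size;
#'   distractor edges are drawn only within the distractor partition so
#'   they can never join the receptor-reachable set to the
#'   target-co-reachable set.
#' @param conditions Two condition labels (e.g. disease and healthy).
#' @param p_both Probability that a non-path microbial protein is detected
#'   in both conditions.
#' @param window Disorder window the fixture guarantees against.
#' @return A validated `mhl_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_microbial = 12L, n_host = 20L,
                         n_planted_dm = 5L, n_planted_dd = 3L,
                         n_decoy_ordered = 5L, n_targets = 5L,
                         n_planted_paths = 3L, path_length = 3L,
                         n_distractor_nodes = 12L,
                         n_distractor_edges = 20L,
                         conditions = c("CD", "healthy"), p_both = 0.25,
                         window = 51L) {
  spec <- list(
    seed = as.integer(seed), n_microbial = as.integer(n_microbial),
    n_host = as.integer(n_host), n_planted_dm = as.integer(n_planted_dm),
    n_planted_dd = as.integer(n_planted_dd),
    n_decoy_ordered = as.integer(n_decoy_ordered),
    n_targets = as.integer(n_targets),
    n_planted_paths = as.integer(n_planted_paths),
    path_length = as.integer(path_length),
    n_distractor_nodes = as.integer(n_distractor_nodes),
    n_distractor_edges = as.integer(n_distractor_edges),
    conditions = as.character(conditions), p_both = p_both,
    window = as.integer(window)
  )
  counts <- unlist(spec[c(
    "n_microbial", "n_host", "n_planted_dm", "n_planted_dd",
    "n_decoy_ordered", "n_targets", "n_planted_paths",
    "n_distractor_nodes", "n_distractor_edges"
  )])
  if (any(counts < 0)) {
    mhl_stop("all fixture counts must be >= 0", "mhl_generation_error")
  }
  if (spec$n_host < spec$n_planted_dm + spec$n_planted_dd +
      spec$n_decoy_ordered) {
    mhl_stop(
      "n_host too small for planted hosts plus decoy hosts",
      "mhl_generation_error"
    )
  }
  if (spec$n_microbial < spec$n_planted_dm + spec$n_planted_dd) {
    mhl_stop("n_microbial too small for planted microbes",
             "mhl_generation_error")
  }
  if (spec$n_planted_paths > spec$n_planted_dm) {
    mhl_stop("n_planted_paths must not exceed n_planted_dm",
             "mhl_generation_error")
  }
  if (spec$path_length < 2) {
    mhl_stop("path_length must be >= 2 (need a terminal TRI step)",
             "mhl_generation_error")
  }
  if (spec$n_targets < 1 || length(spec$conditions) != 2) {
    mhl_stop("need >= 1 target and exactly 2 condition labels",
             "mhl_generation_error")
  }
  # linker budget at size_factor 1 must cover the planted intermediates
  n_linkers <- spec$n_planted_paths * (spec$path_length - 1L)
  budget <- spec$n_planted_dm + spec$n_planted_dd + spec$n_targets
  if (n_linkers > budget) {
    mhl_stop(
      sprintf(
        "unsatisfiable spec: %d planted intermediates exceed linker budget %d",
        n_linkers, budget
      ),
      "mhl_generation_error"
    )
  }
  if (spec$window < 1 || spec$window %% 2 == 0) {
    mhl_stop("window must be an odd positive integer",
             "mhl_generation_error")
  }
  structure(spec, class = "mhl_fixture_spec")
}

rand_seq <- function(n, alphabet = BG_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

fixture_paths <- function(dir) {
  file.path(dir, c(
    microbial_fasta = "microbial_proteins.fasta",
    host_fasta = "host_proteins.fasta",
    microbial_domains = "microbial_domains.tsv",
    host_domains = "host_domains.tsv",
    host_localizations = "host_localizations.tsv",
    domain_pairs = "domain_pairs.tsv",
    motif_classes = "motif_classes.tsv",
    network = "network.tsv",
    targets = "targets.tsv",
    conditions = "conditions.tsv",
    terms = "terms.tsv",
    term_names = "term_names.tsv",
    ground_truth = "ground_truth.json"
  )) -> p
  stats::setNames(p, c(
    "microbial_fasta", "host_fasta", "microbial_domains", "host_domains",
    "host_localizations", "domain_pairs", "motif_classes", "network",
    "targets", "conditions", "terms", "term_names", "ground_truth"
  ))
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes a complete, self-consistent input directory for the pipeline --
#' proteomes, domain annotations, localization tags, gold domain pairs,
#' motif classes, multilayer network, target weights, condition map and
#' term annotations -- with known planted signal:
#' \itemize{
#'   \item `n_planted_dm` domain-motif interactions whose motif match is
#'     embedded in a poly-charged disordered stretch at least one window
#'     wide on each side (so the built-in disorder score provably passes it
#'     at `theta = 1`) and outside every globular annotation;
#'   \item `n_decoy_ordered` decoy matches placed strictly inside
#'     globular-flagged domains (provably rejected by steric QC);
#'   \item `n_planted_dd` domain-domain interactions via dedicated gold
#'     pairs;
#'   \item `n_planted_paths` receptor-to-target paths of `path_length`
#'     edges, PPI throughout except a terminal TRI step, with distractor
#'     edges confined to a disconnected partition so planted intermediates
#'     are the only nodes with positive min-heat.
#' }
#' Before returning, the generator re-reads its own files through the
#' package readers and re-derives the realizability of every planted
#' element (motif coordinates, disorder, decoy placement, path edges),
#' failing loudly if the self-check does not hold.
#'
#' @param spec An [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `inputs` (all parsed pipeline inputs), `truth`
#'   (planted ground truth), `files` (named paths) and `dir`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "mhl_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- fixture_paths(dir)
  with_seed(spec$seed, {
    n_dm <- spec$n_planted_dm
    n_dd <- spec$n_planted_dd
    n_decoy <- spec$n_decoy_ordered
    w <- spec$window

    # --- motif classes: unique literal words over the motif alphabet
    n_classes <- n_dm + 1L # one extra class that never matches anything
    patterns <- character(0)
    while (length(patterns) < n_classes) {
      patterns <- unique(c(patterns, rand_seq(4, MOTIF_ALPHABET)))
    }
    patterns <- patterns[seq_len(n_classes)]
    class_ids <- sprintf("LIG_SYN_%02d", seq_len(n_classes))
    binding <- sprintf("DMB%02d", seq_len(n_classes))

    # --- microbial proteome
    micro_ids <- sprintf("MICRO%03d", seq_len(spec$n_microbial))
    micro_seqs <- vapply(micro_ids, function(i) rand_seq(120), character(1))
    micro_annot <- list()
    for (i in seq_len(n_dm)) {
      micro_annot[[length(micro_annot) + 1L]] <- data.frame(
        protein_id = micro_ids[i], domain_acc = binding[i],
        start = 10L, end = 60L, globular = "true",
        stringsAsFactors = FALSE
      )
    }
    for (j in seq_len(n_dd)) {
      micro_annot[[length(micro_annot) + 1L]] <- data.frame(
        protein_id = micro_ids[n_dm + j],
        domain_acc = sprintf("DDA%02d", j),
        start = 15L, end = 70L, globular = "true", stringsAsFactors = FALSE
      )
    }
    rest <- setdiff(seq_len(spec$n_microbial), seq_len(n_dm + n_dd))
    for (i in rest) {
      micro_annot[[length(micro_annot) + 1L]] <- data.frame(
        protein_id = micro_ids[i], domain_acc = sprintf("ZZM%02d", i),
        start = 5L, end = 40L, globular = "true", stringsAsFactors = FALSE
      )
    }
    micro_annot <- do.call(rbind, micro_annot)

    # --- host proteome
    host_ids <- sprintf("HOST%03d", seq_len(spec$n_host))
    dm_hosts <- host_ids[seq_len(n_dm)]
    dd_hosts <- host_ids[n_dm + seq_len(n_dd)]
    decoy_hosts <- host_ids[n_dm + n_dd + seq_len(n_decoy)]
    other_hosts <- setdiff(host_ids, c(dm_hosts, dd_hosts, decoy_hosts))

    host_seqs <- character(spec$n_host)
    names(host_seqs) <- host_ids
    host_annot <- list()
    loc_rows <- list()
    truth_dm <- list()
    truth_decoy <- list()

    pre <- 30L
    for (i in seq_len(n_dm)) {
      motif <- patterns[i]
      seq <- paste0(
        rand_seq(pre), rand_seq(w, CHARGED_ALPHABET), motif,
        rand_seq(w, CHARGED_ALPHABET), rand_seq(30)
      )
      host_seqs[dm_hosts[i]] <- seq
      s <- pre + w + 1L
      truth_dm[[i]] <- data.frame(
        microbial_id = micro_ids[i], host_id = dm_hosts[i],
        class_id = class_ids[i], start = s, end = s + nchar(motif) - 1L,
        stringsAsFactors = FALSE
      )
      # a folded domain elsewhere on the protein, far from the motif
      host_annot[[length(host_annot) + 1L]] <- data.frame(
        protein_id = dm_hosts[i], domain_acc = sprintf("HGLOB%02d", i),
        start = 2L, end = 20L, globular = "true", stringsAsFactors = FALSE
      )
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        protein_id = dm_hosts[i], localization = "plasma_membrane",
        stringsAsFactors = FALSE
      )
    }
    for (j in seq_len(n_dd)) {
      host_seqs[dd_hosts[j]] <- rand_seq(150)
      host_annot[[length(host_annot) + 1L]] <- data.frame(
        protein_id = dd_hosts[j], domain_acc = sprintf("DDB%02d", j),
        start = 20L, end = 80L, globular = "true", stringsAsFactors = FALSE
      )
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        protein_id = dd_hosts[j], localization = "plasma_membrane",
        stringsAsFactors = FALSE
      )
    }
    for (d in seq_len(n_decoy)) {
      ci <- (d - 1L) %% n_dm + 1L
      motif <- patterns[ci]
      seq <- paste0(rand_seq(60), motif, rand_seq(60))
      host_seqs[decoy_hosts[d]] <- seq
      s <- 61L
      truth_decoy[[d]] <- data.frame(
        host_id = decoy_hosts[d], class_id = class_ids[ci],
        start = s, end = s + nchar(motif) - 1L, stringsAsFactors = FALSE
      )
      # globular domain strictly containing the decoy match
      host_annot[[length(host_annot) + 1L]] <- data.frame(
        protein_id = decoy_hosts[d], domain_acc = sprintf("GLOBD%02d", d),
        start = 50L, end = 75L, globular = "true", stringsAsFactors = FALSE
      )
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        protein_id = decoy_hosts[d], localization = "extracellular",
        stringsAsFactors = FALSE
      )
    }
    for (h in other_hosts) {
      host_seqs[h] <- rand_seq(150)
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        protein_id = h,
        localization = sample(c("cytoplasm", "nucleus"), 1),
        stringsAsFactors = FALSE
      )
    }
    host_annot <- do.call(rbind, host_annot)

    # --- gold domain pairs (planted plus one pair nobody carries)
    gold <- data.frame(
      domain_a = c(sprintf("DDA%02d", seq_len(n_dd)), "ZZX01"),
      domain_b = c(sprintf("DDB%02d", seq_len(n_dd)), "ZZX02"),
      stringsAsFactors = FALSE
    )

    # --- multilayer network with planted paths
    targets <- sprintf("TGT%02d", seq_len(spec$n_targets))
    receptors <- c(dm_hosts, dd_hosts)
    edges <- list()
    paths <- list()
    used_targets <- character(0)
    for (p in seq_len(spec$n_planted_paths)) {
      r <- dm_hosts[p]
      tgt <- targets[(p - 1L) %% spec$n_targets + 1L]
      used_targets <- union(used_targets, tgt)
      mids <- if (spec$path_length > 2) {
        sprintf("INT%02d_%d", p, seq_len(spec$path_length - 2L))
      } else {
        character(0)
      }
      tf <- sprintf("TF%02d", p)
      nodes <- c(r, mids, tf, tgt)
      layers <- c(rep("PPI", spec$path_length - 1L), "TRI")
      for (e in seq_len(length(nodes) - 1L)) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = nodes[e], target = nodes[e + 1L], layer = layers[e],
          sign = sample(c(-1L, 0L, 1L), 1), stringsAsFactors = FALSE
        )
      }
      paths[[p]] <- list(
        nodes = nodes, layers = layers, microbial_id = micro_ids[p],
        receptor = r, target = tgt,
        condition = spec$conditions[(p - 1L) %% 2L + 1L]
      )
    }
    dis <- sprintf("DIS%02d", seq_len(spec$n_distractor_nodes))
    # receptors without a planted path still live in the network, feeding
    # the distractor partition (forward heat only; never target-reachable)
    off_path <- if (length(paths) > 0) {
      setdiff(receptors, vapply(paths, `[[`, character(1), "receptor"))
    } else {
      receptors
    }
    if (length(dis) == 0) off_path <- character(0)
    for (i in seq_along(off_path)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = off_path[i],
        target = dis[(i - 1L) %% length(dis) + 1L],
        layer = "PPI", sign = 0L, stringsAsFactors = FALSE
      )
    }
    # targets not used by any planted path get a dead-end TF feeding them
    for (tgt in setdiff(targets, used_targets)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = paste0("D", tgt), target = tgt, layer = "TRI",
        sign = 0L, stringsAsFactors = FALSE
      )
    }
    # distractor edges strictly within the distractor partition
    n_de <- spec$n_distractor_edges
    if (length(dis) >= 2 && n_de > 0) {
      seen <- character(0)
      while (n_de > 0) {
        st <- sample(dis, 2)
        key <- paste(st, collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        edges[[length(edges) + 1L]] <- data.frame(
          source = st[1], target = st[2],
          layer = sample(c("PPI", "TRI"), 1, prob = c(0.8, 0.2)),
          sign = sample(c(-1L, 0L, 1L), 1), stringsAsFactors = FALSE
        )
        n_de <- n_de - 1L
      }
    }
    edges <- do.call(rbind, edges)

    # --- target weights, conditions, terms
    target_tbl <- data.frame(
      node = targets,
      weight = sprintf("%.3f", stats::runif(length(targets), 0.5, 2)),
      direction = sample(c(-1L, 1L), length(targets), replace = TRUE),
      stringsAsFactors = FALSE
    )
    cond_rows <- list()
    for (i in seq_len(spec$n_microbial)) {
      conds <- if (i <= spec$n_planted_paths) {
        spec$conditions[(i - 1L) %% 2L + 1L]
      } else if (stats::runif(1) < spec$p_both) {
        spec$conditions
      } else {
        sample(spec$conditions, 1)
      }
      for (cc in conds) {
        cond_rows[[length(cond_rows) + 1L]] <- data.frame(
          microbial_id = micro_ids[i], condition = cc,
          stringsAsFactors = FALSE
        )
      }
    }
    cond_tbl <- do.call(rbind, cond_rows)

    path_nodes <- sort(unique(unlist(lapply(paths, `[[`, "nodes"))))
    all_net_nodes <- sort(unique(c(edges$source, edges$target)))
    term_rows <- list()
    add_term <- function(id, prots) {
      for (pr in sort(unique(prots))) {
        term_rows[[length(term_rows) + 1L]] <<- data.frame(
          term_id = id, protein_id = pr, stringsAsFactors = FALSE
        )
      }
    }
    add_term("TERM01", path_nodes)
    add_term("TERM02", c(dis, utils::head(receptors, 2)))
    for (t in 3:5) {
      add_term(sprintf("TERM%02d", t),
               sample(all_net_nodes, min(6, length(all_net_nodes))))
    }
    term_tbl <- do.call(rbind, term_rows)
    term_names <- data.frame(
      term_id = sprintf("TERM%02d", 1:5),
      term_name = c(
        "signal transduction", "distractor process",
        "random process A", "random process B", "random process C"
      ),
      stringsAsFactors = FALSE
    )

    # --- write everything
    write_fasta(
      data.frame(id = micro_ids, sequence = unname(micro_seqs),
                 stringsAsFactors = FALSE),
      files[["microbial_fasta"]]
    )
    write_fasta(
      data.frame(id = host_ids, sequence = unname(host_seqs),
                 stringsAsFactors = FALSE),
      files[["host_fasta"]]
    )
    write_tsv_table(micro_annot, files[["microbial_domains"]])
    write_tsv_table(host_annot, files[["host_domains"]])
    write_tsv_table(do.call(rbind, loc_rows), files[["host_localizations"]])
    write_tsv_table(gold, files[["domain_pairs"]])
    write_tsv_table(
      data.frame(
        class_id = class_ids, pattern = patterns,
        binding_domains = binding, stringsAsFactors = FALSE
      ),
      files[["motif_classes"]]
    )
    write_tsv_table(edges, files[["network"]])
    write_tsv_table(target_tbl, files[["targets"]])
    write_tsv_table(cond_tbl, files[["conditions"]])
    write_tsv_table(term_tbl, files[["terms"]])
    write_tsv_table(term_names, files[["term_names"]])

    truth <- list(
      dm = do.call(rbind, truth_dm),
      dd = data.frame(
        microbial_id = micro_ids[n_dm + seq_len(n_dd)],
        host_id = dd_hosts,
        domain_a = sprintf("DDA%02d", seq_len(n_dd)),
        domain_b = sprintf("DDB%02d", seq_len(n_dd)),
        stringsAsFactors = FALSE
      ),
      decoys = if (n_decoy > 0) do.call(rbind, truth_decoy) else NULL,
      paths = paths,
      receptors = sort(receptors),
      targets = targets
    )
    jsonlite::write_json(
      truth, files[["ground_truth"]],
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    truth
  }) -> truth

  inputs <- read_fixture_inputs(files)
  validate_fixture(spec, inputs, truth)
  list(inputs = inputs, truth = truth, files = files, dir = dir)
}

read_fixture_inputs <- function(files) {
  microbial <- read_protein_fasta(files[["microbial_fasta"]], "microbial")
  host <- read_protein_fasta(files[["host_fasta"]], "host")
  host <- attach_localizations(
    host, read_localizations(files[["host_localizations"]])
  )
  list(
    microbial = microbial,
    host = host,
    microbial_domains = read_domain_annotations(
      files[["microbial_domains"]], microbial
    ),
    host_domains = read_domain_annotations(files[["host_domains"]], host),
    gold = read_domain_pairs(files[["domain_pairs"]]),
    classes = read_motif_classes(files[["motif_classes"]]),
    network = read_edge_list(files[["network"]]),
    targets = read_weighted_nodes(files[["targets"]]),
    conditions = read_conditions(files[["conditions"]]),
    terms = read_term_annotations(files[["terms"]], files[["term_names"]])
  )
}

# Re-derive the realizability of every planted element from the re-read
# inputs; any failure is a generator bug surfaced at generation time.
validate_fixture <- function(spec, inputs, truth) {
  fail <- function(msg) {
    mhl_stop(paste0("fixture self-check failed: ", msg),
             "mhl_generation_error")
  }
  scan <- scan_motifs(inputs$host, inputs$classes)
  profiles <- disorder_profiles(inputs$host, window = spec$window)
  scan <- apply_steric_qc(scan, profiles, inputs$host_domains, theta = 1.0)
  for (i in seq_len(nrow(truth$dm))) {
    hit <- scan[
      scan$protein_id == truth$dm$host_id[i] &
        scan$class_id == truth$dm$class_id[i] &
        scan$start == truth$dm$start[i], , drop = FALSE
    ]
    if (nrow(hit) != 1 || !hit$passes_qc) {
      fail(sprintf("planted motif %d not recovered as QC-passing", i))
    }
  }
  if (!is.null(truth$decoys)) {
    for (d in seq_len(nrow(truth$decoys))) {
      hit <- scan[
        scan$protein_id == truth$decoys$host_id[d] &
          scan$start == truth$decoys$start[d], , drop = FALSE
      ]
      if (nrow(hit) < 1 || any(hit$passes_qc)) {
        fail(sprintf("decoy %d not present or not rejected", d))
      }
    }
  }
  key <- paste(inputs$network$source, inputs$network$target,
               inputs$network$layer, sep = "\r")
  for (p in truth$paths) {
    for (e in seq_along(p$layers)) {
      k <- paste(p$nodes[e], p$nodes[e + 1], p$layers[e], sep = "\r")
      if (!k %in% key) fail(sprintf("planted path edge missing: %s", k))
    }
  }
  invisible(TRUE)
}

#' Generate a null fixture (same shape, no planted signal)
#'
#' Produces inputs with the same marginal structure as
#' [generate_fixture()] but with nothing planted: host sequences are pure
#' background (no motif pattern can match, by alphabet construction), no
#' host protein carries a gold-pair domain, and the network contains no
#' receptor-to-target connectivity (receptors feed the distractor
#' partition; targets are fed only by dead-end regulator nodes).
#'
#' @param spec An [fixture_spec()].
#' @param dir Output directory.
#' @return A list with `inputs`, `files` and `dir` (no ground truth: there
#'   is none).
#' @export
generate_null_fixture <- function(spec, dir = tempfile("nullfixture")) {
  stopifnot(inherits(spec, "mhl_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- fixture_paths(dir)
  with_seed(spec$seed, {
    n_classes <- spec$n_planted_dm + 1L
    patterns <- character(0)
    while (length(patterns) < n_classes) {
      patterns <- unique(c(patterns, rand_seq(4, MOTIF_ALPHABET)))
    }
    patterns <- patterns[seq_len(n_classes)]
    class_ids <- sprintf("LIG_SYN_%02d", seq_len(n_classes))
    binding <- sprintf("DMB%02d", seq_len(n_classes))

    micro_ids <- sprintf("MICRO%03d", seq_len(spec$n_microbial))
    micro_seqs <- vapply(micro_ids, function(i) rand_seq(120), character(1))
    micro_annot <- data.frame(
      protein_id = micro_ids,
      domain_acc = c(
        binding[seq_len(min(spec$n_planted_dm, spec$n_microbial))],
        sprintf("ZZM%02d", seq_len(spec$n_microbial))
      )[seq_len(spec$n_microbial)],
      start = 10L, end = 60L, globular = "true", stringsAsFactors = FALSE
    )

    host_ids <- sprintf("HOST%03d", seq_len(spec$n_host))
    host_seqs <- vapply(host_ids, function(i) rand_seq(150), character(1))
    host_annot <- data.frame(
      protein_id = host_ids, domain_acc = sprintf("ZZH%03d",
                                                  seq_len(spec$n_host)),
      start = 20L, end = 60L, globular = "true", stringsAsFactors = FALSE
    )
    n_recep <- min(spec$n_planted_dm + spec$n_planted_dd, spec$n_host)
    loc_tbl <- data.frame(
      protein_id = host_ids,
      localization = c(
        rep("plasma_membrane", n_recep),
        rep("cytoplasm", spec$n_host - n_recep)
      ),
      stringsAsFactors = FALSE
    )
    gold <- data.frame(
      domain_a = sprintf("DDA%02d", seq_len(max(spec$n_planted_dd, 1))),
      domain_b = sprintf("DDB%02d", seq_len(max(spec$n_planted_dd, 1))),
      stringsAsFactors = FALSE
    )

    targets <- sprintf("TGT%02d", seq_len(spec$n_targets))
    receptors <- host_ids[seq_len(n_recep)]
    dis <- sprintf("DIS%02d", seq_len(max(spec$n_distractor_nodes, 2)))
    edges <- list()
    for (i in seq_along(receptors)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = receptors[i], target = dis[(i - 1L) %% length(dis) + 1L],
        layer = "PPI", sign = 0L, stringsAsFactors = FALSE
      )
    }
    for (tgt in targets) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = paste0("D", tgt), target = tgt, layer = "TRI", sign = 0L,
        stringsAsFactors = FALSE
      )
    }
    n_de <- spec$n_distractor_edges
    seen <- character(0)
    while (n_de > 0) {
      st <- sample(dis, 2)
      key <- paste(st, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      edges[[length(edges) + 1L]] <- data.frame(
        source = st[1], target = st[2],
        layer = sample(c("PPI", "TRI"), 1, prob = c(0.8, 0.2)),
        sign = sample(c(-1L, 0L, 1L), 1), stringsAsFactors = FALSE
      )
      n_de <- n_de - 1L
    }
    edges <- do.call(rbind, edges)

    target_tbl <- data.frame(
      node = targets,
      weight = sprintf("%.3f", stats::runif(length(targets), 0.5, 2)),
      direction = sample(c(-1L, 1L), length(targets), replace = TRUE),
      stringsAsFactors = FALSE
    )
    cond_tbl <- data.frame(
      microbial_id = micro_ids,
      condition = sample(spec$conditions, spec$n_microbial, replace = TRUE),
      stringsAsFactors = FALSE
    )
    all_net_nodes <- sort(unique(c(edges$source, edges$target)))
    term_tbl <- data.frame(
      term_id = "TERM01",
      protein_id = sample(all_net_nodes, min(6, length(all_net_nodes))),
      stringsAsFactors = FALSE
    )
    term_names <- data.frame(
      term_id = "TERM01", term_name = "random process",
      stringsAsFactors = FALSE
    )

    write_fasta(
      data.frame(id = micro_ids, sequence = unname(micro_seqs),
                 stringsAsFactors = FALSE),
      files[["microbial_fasta"]]
    )
    write_fasta(
      data.frame(id = host_ids, sequence = unname(host_seqs),
                 stringsAsFactors = FALSE),
      files[["host_fasta"]]
    )
    write_tsv_table(micro_annot, files[["microbial_domains"]])
    write_tsv_table(host_annot, files[["host_domains"]])
    write_tsv_table(loc_tbl, files[["host_localizations"]])
    write_tsv_table(gold, files[["domain_pairs"]])
    write_tsv_table(
      data.frame(class_id = class_ids, pattern = patterns,
                 binding_domains = binding, stringsAsFactors = FALSE),
      files[["motif_classes"]]
    )
    write_tsv_table(edges, files[["network"]])
    write_tsv_table(target_tbl, files[["targets"]])
    write_tsv_table(cond_tbl, files[["conditions"]])
    write_tsv_table(term_tbl, files[["terms"]])
    write_tsv_table(term_names, files[["term_names"]])
  })
  files <- files[setdiff(names(files), "ground_truth")]
  list(inputs = read_fixture_inputs(files), files = files, dir = dir)
}
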