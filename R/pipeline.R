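#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names all input files and the tunable parameters of
#' the pipeline. It can be given as an R list or as a YAML file with the
#' same keys. Validation is fail-fast: every referenced path must exist and
#' every parameter must lie in its documented range before any compute
#' starts.
#'
#' Recognized keys: input paths `microbial_fasta`, `host_fasta`,
#' `microbial_domains`, `host_domains`, `host_localizations`,
#' `domain_pairs`, `motif_classes`, `network`, `targets`, `conditions`
#' (all required), `terms` and `term_names` (optional), `disorder_dir`
#' (optional directory of `<protein_id>.tsv` score files); parameters
#' `theta` (default 1), `window` (51), `restart` (0.15), `size_factor`
#' (1), `max_chain_length` (4), `q_max` (0.05), `allowed_localizations`
#' (extracellular, plasma_membrane), `filter_microbial_localization`
#' (FALSE), `disorder_source` ("builtin" or "files"); and `out_dir`.
#'
#' @param config A named list or the path to a YAML file.
#' @return The validated configuration list with defaults filled in, class
#'   `mhl_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    mhl_stop("config must be a list or a YAML file path",
             "mhl_validation_error")
  }
  required <- c(
    "microbial_fasta", "host_fasta", "microbial_domains", "host_domains",
    "host_localizations", "domain_pairs", "motif_classes", "network",
    "targets", "conditions"
  )
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    mhl_stop(
      sprintf("config missing required key(s): %s",
              paste(missing, collapse = ", ")),
      "mhl_validation_error"
    )
  }
  for (key in c(required, intersect(c("terms", "term_names"),
                                    names(config)))) {
    if (!file.exists(config[[key]])) {
      mhl_stop(
        sprintf("config path for '%s' does not exist: %s", key,
                config[[key]]),
        "mhl_validation_error"
      )
    }
  }
  if (!is.null(config$disorder_dir) && !dir.exists(config$disorder_dir)) {
    mhl_stop(
      sprintf("disorder_dir does not exist: %s", config$disorder_dir),
      "mhl_validation_error"
    )
  }
  defaults <- list(
    theta = 1.0, window = 51L, restart = 0.15, size_factor = 1.0,
    max_chain_length = 4L, q_max = 0.05,
    allowed_localizations = c("extracellular", "plasma_membrane"),
    filter_microbial_localization = FALSE,
    disorder_source = "builtin", tol = 1e-9, max_iter = 10000L,
    out_dir = NULL
  )
  for (key in names(defaults)) {
    config[[key]] <- config[[key]] %||% defaults[[key]]
  }
  checks <- list(
    theta = config$theta >= 0 && config$theta <= 1,
    window = config$window >= 1 && config$window %% 2 == 1,
    restart = config$restart > 0 && config$restart < 1,
    size_factor = config$size_factor > 0,
    max_chain_length = config$max_chain_length >= 1,
    q_max = config$q_max >= 0 && config$q_max <= 1,
    disorder_source = config$disorder_source %in% c("builtin", "files"),
    allowed_localizations = length(config$allowed_localizations) > 0
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad) > 0) {
    mhl_stop(
      sprintf("config parameter(s) out of range: %s",
              paste(bad, collapse = ", ")),
      "mhl_validation_error"
    )
  }
  if (config$disorder_source == "files" && is.null(config$disorder_dir)) {
    mhl_stop("disorder_source 'files' requires disorder_dir",
             "mhl_validation_error")
  }
  structure(config, class = c("mhl_config", "list"))
}

#' Run the full pipeline
#'
#' Executes the stages end-to-end: localization filtering, domain-domain
#' and domain-motif interaction prediction with steric QC, receptor
#' weighting, forward diffusion from the receptors and reverse diffusion
#' from the targets, min-heat linker selection, chain enumeration,
#' condition-exclusivity and terminal-TRI filtering, final-model
#' construction and term over-representation analysis; all stage outputs
#' and a run manifest are written under `out_dir`.
#'
#' The pipeline is deterministic: rerunning an unchanged configuration
#' reproduces byte-identical outputs. The manifest records the parameter
#' values, the MD5 of every input file, and the record count after every
#' stage (each filtering stage is non-increasing). An empty intermediate
#' result (e.g. no receptor survives prediction) terminates cleanly with
#' `status = "empty_result"` and an explanatory message rather than an
#' error.
#'
#' @param config A configuration accepted by [run_config()].
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return The manifest, invisibly: a list with `status`, `parameters`,
#'   `input_md5`, `counts` and `outputs`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    mhl_stop("no output directory given", "mhl_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, mhl_error = function(e) {
      mhl_stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
               class(e)[1])
    })
  }
  counts <- list()
  note <- function(name, n) counts[[name]] <<- as.integer(n)

  input_keys <- c(
    "microbial_fasta", "host_fasta", "microbial_domains", "host_domains",
    "host_localizations", "domain_pairs", "motif_classes", "network",
    "targets", "conditions",
    intersect(c("terms", "term_names"), names(config))
  )
  input_md5 <- vapply(
    input_keys, function(k) unname(tools::md5sum(config[[k]])), character(1)
  )
  params <- config[c(
    "theta", "window", "restart", "size_factor", "max_chain_length",
    "q_max", "allowed_localizations", "filter_microbial_localization",
    "disorder_source", "tol", "max_iter"
  )]

  finish <- function(status, message, outputs = character(0)) {
    manifest <- list(
      status = status, message = message, parameters = params,
      input_md5 = as.list(input_md5), counts = counts,
      outputs = as.list(outputs)
    )
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    message(sprintf("pipeline finished: %s (%s)", status, message))
    invisible(manifest)
  }

  # --- read inputs ---------------------------------------------------
  inputs <- stage("read_inputs", {
    microbial <- read_protein_fasta(config$microbial_fasta, "microbial")
    host <- read_protein_fasta(config$host_fasta, "host")
    host <- attach_localizations(
      host, read_localizations(config$host_localizations)
    )
    list(
      microbial = microbial, host = host,
      microbial_domains = read_domain_annotations(
        config$microbial_domains, microbial
      ),
      host_domains = read_domain_annotations(config$host_domains, host),
      gold = read_domain_pairs(config$domain_pairs),
      classes = read_motif_classes(config$motif_classes),
      network = read_edge_list(config$network),
      targets = read_weighted_nodes(config$targets),
      conditions = read_conditions(config$conditions),
      terms = if (!is.null(config$terms)) {
        read_term_annotations(config$terms, config$term_names)
      } else {
        NULL
      }
    )
  })
  note("microbial_proteins", nrow(inputs$microbial))
  note("host_proteins", nrow(inputs$host))
  note("network_edges", nrow(inputs$network))

  # --- localization filter -------------------------------------------
  host <- stage("localization_filter", {
    filter_by_localization(inputs$host, config$allowed_localizations)
  })
  microbial <- inputs$microbial
  if (isTRUE(config$filter_microbial_localization)) {
    microbial <- stage("localization_filter", {
      filter_by_localization(microbial, config$allowed_localizations)
    })
  }
  note("host_proteins_localized", nrow(host))
  if (nrow(host) == 0) {
    return(finish("empty_result",
                  "no host protein in an accessible compartment"))
  }

  # --- interaction prediction ----------------------------------------
  host_annots <- inputs$host_domains[
    inputs$host_domains$protein_id %in% host$id, , drop = FALSE
  ]
  micro_annots <- inputs$microbial_domains[
    inputs$microbial_domains$protein_id %in% microbial$id, , drop = FALSE
  ]
  dd <- stage("domain_domain", {
    predict_domain_domain(micro_annots, host_annots, inputs$gold)
  })
  note("dd_predictions", nrow(dd))
  instances <- stage("motif_scan", scan_motifs(host, inputs$classes))
  note("motif_instances", nrow(instances))
  profiles <- stage("disorder", {
    if (config$disorder_source == "files") {
      pr <- lapply(host$id, function(id) {
        path <- file.path(config$disorder_dir, paste0(id, ".tsv"))
        if (!file.exists(path)) {
          mhl_stop(sprintf("no disorder score file for protein '%s'", id),
                   "mhl_io_error")
        }
        read_disorder_profile(path)
      })
      stats::setNames(pr, host$id)
    } else {
      disorder_profiles(host, window = config$window)
    }
  })
  instances <- stage("steric_qc", {
    apply_steric_qc(instances, profiles, host_annots, theta = config$theta)
  })
  note("motif_instances_passing", sum(instances$passes_qc))
  dm <- stage("domain_motif", {
    predict_domain_motif(micro_annots, instances, inputs$classes)
  })
  note("dm_predictions", nrow(dm))
  merged <- stage("merge_predictions", merge_predictions(dd, dm))
  note("predicted_interactions", nrow(merged$interactions))
  note("receptors", nrow(merged$receptor_weights))

  outputs <- character(0)
  # outputs are recorded by file name (not absolute path) so the manifest
  # of an unchanged config is byte-identical wherever it is written
  emit <- function(name, writer) {
    writer(file.path(out_dir, name))
    outputs <<- c(outputs, name)
  }
  emit("predictions.tsv", function(p) {
    write_tsv_table(merged$interactions, p)
  })
  emit("receptor_weights.tsv", function(p) {
    write_tsv_table(merged$receptor_weights, p)
  })

  if (nrow(merged$receptor_weights) == 0) {
    return(finish("empty_result",
                  "no host receptor predicted to bind a microbial protein",
                  outputs))
  }

  # --- diffusion and linker selection --------------------------------
  receptors_in_net <- intersect(merged$receptor_weights$node,
                                network_nodes(inputs$network))
  targets_in_net <- intersect(inputs$targets$node,
                              network_nodes(inputs$network))
  if (length(receptors_in_net) == 0 || length(targets_in_net) == 0) {
    return(finish("empty_result",
                  "receptors or targets absent from the network", outputs))
  }
  h_fwd <- stage("diffusion_forward", suppressWarnings(
    diffuse(inputs$network, merged$receptor_weights,
            restart = config$restart, direction = "forward",
            tol = config$tol, max_iter = config$max_iter)
  ))
  h_rev <- stage("diffusion_reverse", suppressWarnings(
    diffuse(inputs$network, inputs$targets, restart = config$restart,
            direction = "reverse", tol = config$tol,
            max_iter = config$max_iter)
  ))
  L <- linker_scores(h_fwd, h_rev)
  sub <- stage("linker_selection", {
    select_subnetwork(inputs$network, L, receptors_in_net, targets_in_net,
                      size_factor = config$size_factor)
  })
  note("subnetwork_nodes", length(sub$nodes))
  note("subnetwork_edges", nrow(sub$edges))
  emit("heat_forward.tsv", function(p) write_heat(h_fwd, p))
  emit("heat_reverse.tsv", function(p) write_heat(h_rev, p))
  emit("linker_scores.tsv", function(p) write_heat(L, p))
  emit("subnetwork_edges.tsv", function(p) write_edge_list(sub$edges, p))
  emit("subnetwork_roles.tsv", function(p) write_tsv_table(sub$roles, p))

  # --- chains ---------------------------------------------------------
  chains <- stage("chain_enumeration", {
    enumerate_chains(
      sub, receptors_in_net, targets_in_net,
      max_len = config$max_chain_length,
      receptor_microbes = receptor_microbe_map(merged$interactions)
    )
  })
  note("chains_enumerated", nrow(chains))
  emit("chains_all.tsv", function(p) write_chains(chains, p))
  chains_cond <- stage("condition_filter", {
    filter_condition_specific(chains, inputs$conditions)
  })
  note("chains_condition_specific", nrow(chains_cond))
  chains_final <- stage("tri_last_filter", filter_tri_last(chains_cond))
  note("chains_final", nrow(chains_final))
  if (nrow(chains_final) == 0) {
    return(finish("empty_result",
                  "no signalling chain survives the filters", outputs))
  }

  # --- final model and enrichment ------------------------------------
  model <- stage("final_model", {
    chains_to_network(chains_final, inputs$network)
  })
  note("model_edges", nrow(model))
  note("model_nodes", length(network_nodes(model)))
  paths <- write_model(model, chains_final, file.path(out_dir, "model"))
  outputs <- c(outputs, basename(unname(paths)))

  if (!is.null(inputs$terms)) {
    enr <- stage("enrichment", {
      background <- network_nodes(inputs$network)
      study <- intersect(network_nodes(model), background)
      enrich(study, background, inputs$terms, q_max = config$q_max)
    })
    note("enriched_terms", sum(enr$significant))
    emit("enrichment.tsv", function(p) write_tsv_table(enr, p))
  }

  finish("ok", "pipeline completed", outputs)
}
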