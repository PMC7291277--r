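make_proteins <- function(ids, seqs, side = "host",
                          locs = NULL) {
  df <- data.frame(id = ids, sequence = seqs, side = side,
                   stringsAsFactors = FALSE)
  df$localizations <- locs %||% rep(list(character(0)), nrow(df))
  df
}

test_that("localization filter keeps accessible proteins only", {
  prots <- make_proteins(
    c("h1", "h2", "h3"), c("MK", "MK", "MK"),
    locs = list("plasma_membrane", c("cytoplasm", "nucleus"), character(0))
  )
  kept <- filter_by_localization(prots,
                                 c("extracellular", "plasma_membrane"))
  expect_equal(kept$id, "h1")
  # no-evidence proteins are excluded even with a permissive allowed set
  all_tags <- unique(unlist(prots$localizations))
  expect_equal(filter_by_localization(prots, all_tags)$id, c("h1", "h2"))
  expect_error(filter_by_localization(prots, character(0)), "nonempty")
})

test_that("domain-domain prediction matches forced and vacuous cases", {
  micro <- data.frame(protein_id = "m1", domain_acc = "PF00069",
                      start = 1L, end = 10L, globular = TRUE,
                      stringsAsFactors = FALSE)
  host <- data.frame(protein_id = "h1", domain_acc = "PF00017",
                     start = 5L, end = 20L, globular = TRUE,
                     stringsAsFactors = FALSE)
  gold <- data.frame(domain_a = "PF00017", domain_b = "PF00069",
                     stringsAsFactors = FALSE)
  pred <- predict_domain_domain(micro, host, gold)
  expect_equal(nrow(pred), 1)
  expect_equal(pred$microbial_id, "m1")
  expect_equal(pred$host_id, "h1")

  expect_equal(nrow(predict_domain_domain(micro, host, gold[0, ])), 0)
})

test_that("domain-domain prediction equals brute force on random instances", {
  set.seed(42)
  for (rep in 1:40) {
    inst <- random_dd_instance()
    pred <- predict_domain_domain(inst$micro, inst$host, inst$gold)
    expect_identical(
      dd_to_keys(pred),
      brute_force_dd(inst$micro, inst$host, inst$gold)
    )
  }
})

test_that("adding gold pairs never decreases domain-domain predictions", {
  set.seed(7)
  inst <- random_dd_instance()
  base <- predict_domain_domain(inst$micro, inst$host, inst$gold)
  more <- rbind(inst$gold, data.frame(domain_a = "PF00001",
                                      domain_b = "PF00002"))
  expanded <- predict_domain_domain(inst$micro, inst$host, more)
  expect_true(all(dd_to_keys(base) %in% dd_to_keys(expanded)))
})

test_that("motif scanning reports overlapping, position-distinct matches", {
  prots <- make_proteins("h1", "APKPA")
  classes <- data.frame(class_id = "LIG_X", pattern = "P.P",
                        stringsAsFactors = FALSE)
  classes$binding_domains <- list("PF00018")
  inst <- scan_motifs(prots, classes)
  expect_equal(nrow(inst), 1)
  expect_equal(c(inst$start, inst$end), c(2L, 4L))
  expect_equal(inst$matched_subsequence, "PKP")

  prots2 <- make_proteins("h1", "AAA")
  classes2 <- classes
  classes2$pattern <- "AA"
  inst2 <- scan_motifs(prots2, classes2)
  expect_equal(inst2$start, c(1L, 2L))
  expect_equal(inst2$end, c(2L, 3L))
  expect_true(all(inst2$passes_qc)) # QC fields initialized passing
})

test_that("motif scanning equals anchored per-position matching", {
  set.seed(11)
  patterns <- c("P.P", "AA", "K[DE]{1,2}L", "W(AG)+", "M.{2}C")
  for (rep in 1:60) {
    seq <- paste(sample(c("A", "G", "P", "K", "D", "E", "L", "W", "C", "M"),
                        sample(5:50, 1), replace = TRUE), collapse = "")
    pat <- sample(patterns, 1)
    prots <- make_proteins("h1", seq)
    classes <- data.frame(class_id = "c1", pattern = pat,
                          stringsAsFactors = FALSE)
    classes$binding_domains <- list("PF1")
    got <- scan_motifs(prots, classes)
    want <- motif_scan_oracle(seq, pat)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      want_m <- do.call(rbind, want)
      expect_equal(got$start, sort(want_m[, 1]))
      expect_equal(got$end, want_m[order(want_m[, 1]), 2])
    }
  }
})

test_that("windowed fold index separates charged from hydrophobic tracts", {
  # window covering only K: FI = 2.785 * (0.6 / 9) - 1 - 1.151, about -1.965
  polyk <- list(id = "k", sequence = strrep("K", 25))
  sk <- compute_disorder(polyk, window = 5)
  fi_k <- 2.785 * ((-3.9 + 4.5) / 9) - 1 - 1.151
  expect_equal(sk[10], 0.5 - fi_k / (2 * 3.936), tolerance = 1e-12)
  expect_true(all(sk > 0.5)) # disordered

  # poly-I: FI = 2.785 * 1 - 0 - 1.151, about +1.634
  polyi <- list(id = "i", sequence = strrep("I", 25))
  si <- compute_disorder(polyi, window = 5)
  fi_i <- 2.785 * 1 - 0 - 1.151
  expect_equal(si[10], 0.5 - fi_i / (2 * 3.936), tolerance = 1e-12)
  expect_true(all(si < 0.5)) # ordered

  # structural invariant: profile length equals sequence length
  for (n in c(1, 3, 10, 120)) {
    p <- list(id = "x", sequence = strrep("AK", ceiling(n / 2)))
    p$sequence <- substr(p$sequence, 1, n)
    expect_length(compute_disorder(p, window = 51), n)
  }

  expect_error(compute_disorder(polyk, window = 4), "odd")
})

test_that("steric QC applies disorder threshold and globular overlap", {
  inst <- data.frame(
    protein_id = "h1", class_id = "c1", start = 5L, end = 8L,
    matched_subsequence = "XXXX", disordered_fraction = 1,
    overlaps_globular = FALSE, passes_qc = TRUE, stringsAsFactors = FALSE
  )
  profiles <- list(h1 = rep(1, 20))
  annots <- data.frame(protein_id = "h1", domain_acc = "PF1",
                       start = 15L, end = 20L, globular = TRUE,
                       stringsAsFactors = FALSE)
  out <- apply_steric_qc(inst, profiles, annots, theta = 1.0)
  expect_true(out$passes_qc)

  # one-residue overlap with a globular domain fails regardless of disorder
  annots2 <- annots
  annots2$start <- 8L
  out2 <- apply_steric_qc(inst, profiles, annots2, theta = 0)
  expect_true(out2$overlaps_globular)
  expect_false(out2$passes_qc)

  # a non-globular annotation does not trigger the overlap rule
  annots3 <- annots2
  annots3$globular <- FALSE
  expect_true(apply_steric_qc(inst, profiles, annots3, theta = 0)$passes_qc)

  # theta = 0 with no globular overlap always passes
  profiles_low <- list(h1 = rep(0, 20))
  expect_true(apply_steric_qc(inst, profiles_low, annots,
                              theta = 0)$passes_qc)
  expect_false(apply_steric_qc(inst, profiles_low, annots,
                               theta = 1)$passes_qc)

  expect_error(apply_steric_qc(inst, list(), annots), "h1")
})

test_that("raising theta never increases the passing set", {
  set.seed(3)
  inst <- data.frame(
    protein_id = "h1", class_id = "c1",
    start = sample(1:40, 15, replace = TRUE),
    stringsAsFactors = FALSE
  )
  inst$end <- pmin(inst$start + sample(2:6, 15, replace = TRUE), 50L)
  inst$matched_subsequence <- ""
  inst$disordered_fraction <- 1
  inst$overlaps_globular <- FALSE
  inst$passes_qc <- TRUE
  profiles <- list(h1 = stats::runif(50))
  annots <- data.frame(protein_id = "h1", domain_acc = "PF1",
                       start = 20L, end = 28L, globular = TRUE,
                       stringsAsFactors = FALSE)
  prev <- NULL
  for (theta in c(0, 0.25, 0.5, 0.75, 1)) {
    cur <- which(apply_steric_qc(inst, profiles, annots, theta)$passes_qc)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("domain-motif prediction equals brute force on random instances", {
  set.seed(99)
  doms <- sprintf("PF%03d", 1:6)
  for (rep in 1:40) {
    n_m <- sample(1:10, 1)
    micro <- data.frame(
      protein_id = sprintf("m%02d", seq_len(n_m)),
      domain_acc = sample(doms, n_m, replace = TRUE),
      start = 1L, end = 10L, globular = TRUE, stringsAsFactors = FALSE
    )
    classes <- data.frame(class_id = sprintf("c%d", 1:3),
                          pattern = "XX", stringsAsFactors = FALSE)
    classes$binding_domains <- replicate(3, sample(doms, sample(1:3, 1)),
                                         simplify = FALSE)
    n_i <- sample(1:10, 1)
    inst <- data.frame(
      protein_id = sprintf("h%02d", sample(1:5, n_i, replace = TRUE)),
      class_id = sample(classes$class_id, n_i, replace = TRUE),
      start = sample(1:20, n_i, replace = TRUE),
      stringsAsFactors = FALSE
    )
    inst$end <- inst$start + 3L
    inst$matched_subsequence <- "XXXX"
    inst$disordered_fraction <- 1
    inst$overlaps_globular <- FALSE
    inst$passes_qc <- sample(c(TRUE, FALSE), n_i, replace = TRUE)
    pred <- predict_domain_motif(micro, inst, classes)
    expect_identical(dm_to_keys(pred), brute_force_dm(micro, inst, classes))
  }
})

test_that("domain-motif prediction rejects unknown classes", {
  micro <- data.frame(protein_id = "m1", domain_acc = "PF1", start = 1L,
                      end = 5L, globular = TRUE, stringsAsFactors = FALSE)
  classes <- data.frame(class_id = "c1", pattern = "XX",
                        stringsAsFactors = FALSE)
  classes$binding_domains <- list("PF1")
  inst <- data.frame(protein_id = "h1", class_id = "cUNKNOWN", start = 1L,
                     end = 2L, matched_subsequence = "XX",
                     disordered_fraction = 1, overlaps_globular = FALSE,
                     passes_qc = TRUE, stringsAsFactors = FALSE)
  expect_error(predict_domain_motif(micro, inst, classes), "cUNKNOWN")
})

test_that("merged receptor weights count distinct microbes, not evidence", {
  dd <- data.frame(
    microbial_id = c("m1", "m2"), host_id = c("h1", "h1"),
    evidence = "domain_domain", microbial_domain = "PF1",
    host_domain = "PF2", m_start = 1L, m_end = 2L, h_start = 1L,
    h_end = 2L, stringsAsFactors = FALSE
  )
  dm <- data.frame(
    microbial_id = "m1", host_id = "h1", evidence = "domain_motif",
    microbial_domain = "PF1", class_id = "c1", motif_start = 1L,
    motif_end = 4L, matched_subsequence = "XXXX", stringsAsFactors = FALSE
  )
  res <- merge_predictions(dd, dm)
  expect_equal(nrow(res$interactions), 3) # evidence types kept separately
  expect_equal(res$receptor_weights$weight, 2) # m1, m2

  # duplicated evidence rows do not change the weights
  res2 <- merge_predictions(rbind(dd, dd), rbind(dm, dm, dm))
  expect_identical(res2$receptor_weights, res$receptor_weights)

  res3 <- merge_predictions(dd[0, ], dm[0, ])
  expect_equal(nrow(res3$interactions), 0)
  expect_equal(nrow(res3$receptor_weights), 0)
})
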