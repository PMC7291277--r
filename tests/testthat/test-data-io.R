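test_that("FASTA parsing maps headers, case and ambiguity codes", {
  fa <- write_lines_tmp(c(">p1 some description", "mkv", ">p2", "ACDU"),
                        ext = ".fasta")
  prots <- read_protein_fasta(fa, side = "host")
  expect_equal(prots$id, c("p1", "p2"))
  expect_equal(prots$sequence, c("MKV", "ACDX")) # uppercased, U -> X
  expect_equal(prots$side, rep("host", 2))

  empty <- write_lines_tmp(character(0), ext = ".fasta")
  expect_equal(nrow(read_protein_fasta(empty, "microbial")), 0)
})

test_that("FASTA parsing rejects duplicates and invalid residues", {
  dup <- write_lines_tmp(c(">p1", "MK", ">p1", "MK"), ext = ".fasta")
  expect_error(read_protein_fasta(dup, "host"), "duplicate.*p1")

  bad <- write_lines_tmp(c(">p1", "MKO"), ext = ".fasta")
  expect_error(read_protein_fasta(bad, "host"), "position 3")
})

test_that("domain annotation parsing validates schema and coordinates", {
  path <- write_lines_tmp(c(
    "protein_id\tdomain_acc\tstart\tend\tglobular",
    "p1\tPF00069\t10\t40\ttrue",
    "p2\tPF00018\t5\t25\tfalse"
  ))
  ann <- read_domain_annotations(path)
  expect_equal(ann$start, c(10L, 5L))
  expect_equal(ann$globular, c(TRUE, FALSE))

  # globular defaults to TRUE when the column is absent
  path2 <- write_lines_tmp(c(
    "protein_id\tdomain_acc\tstart\tend", "p1\tPF1\t1\t5"
  ))
  expect_true(read_domain_annotations(path2)$globular)

  rev_coords <- write_lines_tmp(c(
    "protein_id\tdomain_acc\tstart\tend", "p1\tPF1\t50\t40"
  ))
  expect_error(read_domain_annotations(rev_coords), "interval")

  non_int <- write_lines_tmp(c(
    "protein_id\tdomain_acc\tstart\tend", "p1\tPF1\tten\t40"
  ))
  expect_error(read_domain_annotations(non_int), "non-integer")

  no_col <- write_lines_tmp(c("protein_id\tdomain_acc\tstart", "p1\tPF1\t1"))
  expect_error(read_domain_annotations(no_col), "missing required column")

  header_only <- write_lines_tmp("protein_id\tdomain_acc\tstart\tend")
  expect_equal(nrow(read_domain_annotations(header_only)), 0)
})

test_that("domain pairs are unordered, deduplicated, self-pairs allowed", {
  path <- write_lines_tmp(c(
    "domain_a\tdomain_b", "B\tA", "A\tB", "A\tC", "D\tD"
  ))
  pairs <- read_domain_pairs(path)
  expect_equal(pairs$domain_a, c("A", "A", "D"))
  expect_equal(pairs$domain_b, c("B", "C", "D"))
})

test_that("motif class parsing validates regexes and binding domains", {
  path <- write_lines_tmp(c(
    "class_id\tpattern\tbinding_domains",
    "LIG_X\tP.P\tPF00018",
    "LIG_Y\t[ED]{2,3}W\tPF1, PF2"
  ))
  classes <- read_motif_classes(path)
  expect_equal(classes$class_id, c("LIG_X", "LIG_Y"))
  expect_equal(classes$binding_domains[[2]], c("PF1", "PF2"))

  bad_re <- write_lines_tmp(c(
    "class_id\tpattern\tbinding_domains", "LIG_Z\t((\tPF1"
  ))
  expect_error(read_motif_classes(bad_re), "LIG_Z")

  no_dom <- write_lines_tmp(c(
    "class_id\tpattern\tbinding_domains", "LIG_Z\tP.P\t "
  ))
  expect_error(read_motif_classes(no_dom), "empty binding_domains")
})

test_that("edge list parsing collapses duplicates and surfaces conflicts", {
  path <- write_lines_tmp(c(
    "source\ttarget\tlayer\tsign",
    "a\tb\tPPI\t1", "b\tt\tTRI\t0", "a\tb\tPPI\t0"
  ))
  net <- read_edge_list(path)
  expect_equal(nrow(net), 2)
  expect_equal(net$sign[net$source == "a"], 1L)
  expect_equal(network_nodes(net), c("a", "b", "t"))

  conflict <- write_lines_tmp(c(
    "source\ttarget\tlayer\tsign", "a\tb\tPPI\t1", "a\tb\tPPI\t-1"
  ))
  expect_error(read_edge_list(conflict), "sign conflict")

  bad_layer <- write_lines_tmp(c(
    "source\ttarget\tlayer", "a\tb\tXXX"
  ))
  expect_error(read_edge_list(bad_layer), "unknown layer")
})

test_that("parsing is row-order insensitive", {
  rows <- c("a\tb\tPPI\t1", "b\tc\tTRI\t-1", "c\td\tPPI\t0")
  p1 <- write_lines_tmp(c("source\ttarget\tlayer\tsign", rows))
  p2 <- write_lines_tmp(c("source\ttarget\tlayer\tsign", rev(rows)))
  expect_identical(read_edge_list(p1), read_edge_list(p2))

  prows <- c("B\tA", "C\tA", "D\tD")
  q1 <- write_lines_tmp(c("domain_a\tdomain_b", prows))
  q2 <- write_lines_tmp(c("domain_a\tdomain_b", rev(prows)))
  expect_identical(read_domain_pairs(q1), read_domain_pairs(q2))
})

test_that("model writer round-trips through the readers", {
  net <- make_net(data.frame(
    source = c("m1", "r", "x"), target = c("r", "x", "t"),
    layer = c("PPI", "PPI", "TRI"), sign = c(1L, 0L, -1L),
    stringsAsFactors = FALSE
  ))
  chains <- enumerate_chains(net, "m1", "t", max_len = 3)
  prefix <- tempfile("model")
  paths <- write_model(net, chains, prefix)

  expect_identical(read_edge_list(paths[["edges"]]), net)
  sif <- readLines(paths[["sif"]])
  expect_length(sif, 3)
  expect_true("x\tTRI:-1\tt" %in% sif)

  back <- read_chains(paths[["chains"]])
  expect_equal(chains_to_keys(back), chains_to_keys(chains))

  expect_error(write_model(net[0, ], chains, tempfile()), "empty")
})

test_that("chain serialization matches the documented row format", {
  chains <- enumerate_chains(
    make_net(data.frame(
      source = c("r", "x"), target = c("x", "t"),
      layer = c("PPI", "TRI"), sign = 0L, stringsAsFactors = FALSE
    )),
    "r", "t", max_len = 2,
    receptor_microbes = list(r = "m1")
  )
  chains$condition <- "CD"
  path <- tempfile(fileext = ".tsv")
  write_chains(chains, path)
  expect_equal(readLines(path)[2], "m1\tCD\tr|x|t\tPPI|TRI")
})

test_that("weighted node sets and disorder profiles validate their ranges", {
  ok <- write_lines_tmp(c("node\tweight\tdirection", "g1\t1.5\t-1",
                          "g2\t0\t0"))
  w <- read_weighted_nodes(ok)
  expect_equal(w$weight, c(1.5, 0))

  allzero <- write_lines_tmp(c("node\tweight", "g1\t0"))
  expect_error(read_weighted_nodes(allzero), "positive")

  neg <- write_lines_tmp(c("node\tweight", "g1\t-2"))
  expect_error(read_weighted_nodes(neg), "nonnegative")

  prof <- write_lines_tmp(c("position\tscore", "1\t0.2", "2\t0.8"))
  expect_equal(read_disorder_profile(prof), c(0.2, 0.8))
  bad <- write_lines_tmp(c("position\tscore", "1\t1.2"))
  expect_error(read_disorder_profile(bad), "\\[0, 1\\]")
  gap <- write_lines_tmp(c("position\tscore", "1\t0.2", "3\t0.8"))
  expect_error(read_disorder_profile(gap), "contiguous")
})
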