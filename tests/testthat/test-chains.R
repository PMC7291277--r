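chain_net <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$sign)) df$sign <- 0L
  make_net(df)
}

test_that("chain enumeration respects the edge budget", {
  net <- chain_net(
    source = c("r", "x", "r"), target = c("x", "t", "t"),
    layer = c("PPI", "TRI", "TRI")
  )
  two <- enumerate_chains(net, "r", "t", max_len = 2)
  expect_equal(nrow(two), 2)
  one <- enumerate_chains(net, "r", "t", max_len = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$nodes[[1]], c("r", "t"))
  expect_error(enumerate_chains(net, "r", "t", max_len = 0), "max_len")
})

test_that("cycles terminate and never produce non-simple paths", {
  net <- chain_net(
    source = c("r", "x"), target = c("x", "r"), layer = c("PPI", "PPI")
  )
  expect_equal(nrow(enumerate_chains(net, "r", "x", max_len = 10)), 1)
  net2 <- chain_net(
    source = c("r", "x", "x"), target = c("x", "r", "t"),
    layer = c("PPI", "PPI", "TRI")
  )
  chains <- enumerate_chains(net2, "r", "t", max_len = 10)
  expect_equal(nrow(chains), 1)
  expect_equal(chains$nodes[[1]], c("r", "x", "t"))
})

test_that("chains carry the microbial proteins bound to their receptor", {
  net <- chain_net(source = "r", target = "t", layer = "TRI")
  chains <- enumerate_chains(net, "r", "t", max_len = 1,
                             receptor_microbes = list(r = c("m2", "m1")))
  expect_equal(chains$microbial_ids[[1]], c("m1", "m2"))
})

test_that("enumeration equals the all-simple-paths oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:40) {
    edges <- random_graph_edges()
    net <- make_net(edges)
    nodes <- network_nodes(net)
    receptors <- sample(nodes, min(3, length(nodes)))
    targets <- sample(nodes, min(3, length(nodes)))
    max_len <- sample(2:4, 1)
    got <- enumerate_chains(net, receptors, targets, max_len = max_len)
    want <- chain_oracle(edges, receptors, targets, max_len)
    expect_identical(chains_to_keys(got), want)
    expect_equal(nrow(got), length(chains_to_keys(got))) # no duplicates
  }
})

cmap_fixture <- list(
  mCD = "CD", mH = "healthy", mBoth = c("CD", "healthy")
)

mk_chain <- function(microbes, nodes, layers, condition = "unassigned") {
  df <- data.frame(condition = condition, stringsAsFactors = FALSE)
  df$microbial_ids <- list(microbes)
  df$nodes <- list(nodes)
  df$edge_layers <- list(layers)
  df[, c("microbial_ids", "condition", "nodes", "edge_layers")]
}

test_that("condition filter keeps single-condition initiators only", {
  chains <- rbind(
    mk_chain("mBoth", c("r1", "x1", "t"), c("PPI", "TRI")),
    mk_chain("mCD", c("r2", "x2", "t"), c("PPI", "TRI")),
    mk_chain(c("mCD", "mBoth"), c("r3", "x3", "t"), c("PPI", "TRI"))
  )
  out <- filter_condition_specific(chains, cmap_fixture)
  expect_equal(nrow(out), 2)
  expect_true(all(out$condition == "CD"))
  # the "both" initiator is removed from the surviving chain
  r3 <- out[vapply(out$nodes, function(n) n[1], character(1)) == "r3", ]
  expect_equal(r3$microbial_ids[[1]], "mCD")
})

test_that("mixed single-condition initiators split the chain per condition", {
  chains <- mk_chain(c("mCD", "mH"), c("r1", "x1", "t"), c("PPI", "TRI"))
  out <- filter_condition_specific(chains, cmap_fixture)
  # identical route now shared by both conditions: x1 is a penultimate
  # (direct-regulator) node, so both copies are retained
  expect_equal(sort(out$condition), c("CD", "healthy"))
  expect_equal(out$microbial_ids[[1]],
               if (out$condition[1] == "CD") "mCD" else "mH")
})

test_that("shared non-penultimate intermediates drop chains, penultimate survive", {
  chains <- rbind(
    mk_chain("mCD", c("r1", "shared", "tf1", "t"), c("PPI", "PPI", "TRI")),
    mk_chain("mH", c("r2", "shared", "tf2", "t"), c("PPI", "PPI", "TRI")),
    mk_chain("mCD", c("r3", "tfS", "t"), c("PPI", "TRI")),
    mk_chain("mH", c("r4", "tfS", "t"), c("PPI", "TRI"))
  )
  out <- filter_condition_specific(chains, cmap_fixture)
  first_nodes <- vapply(out$nodes, function(n) n[1], character(1))
  # 'shared' sits mid-chain in both conditions: those chains are dropped
  expect_false(any(first_nodes %in% c("r1", "r2")))
  # 'tfS' directly regulates the target (penultimate): chains retained
  expect_true(all(c("r3", "r4") %in% first_nodes))
})

test_that("condition filter is idempotent and errors on unmapped microbes", {
  chains <- rbind(
    mk_chain(c("mCD", "mBoth"), c("r1", "x1", "t"), c("PPI", "TRI")),
    mk_chain("mH", c("r2", "t"), "TRI")
  )
  once <- filter_condition_specific(chains, cmap_fixture)
  twice <- filter_condition_specific(once, cmap_fixture)
  expect_identical(once, twice)

  expect_error(
    filter_condition_specific(mk_chain("mX", c("r", "t"), "TRI"),
                              cmap_fixture),
    "mX"
  )
})

test_that("terminal-TRI filter keeps exactly TRI-last chains", {
  chains <- rbind(
    mk_chain("mCD", c("r", "x", "t"), c("PPI", "TRI")),
    mk_chain("mCD", c("r", "y", "t"), c("PPI", "PPI")),
    mk_chain("mCD", c("r", "t"), "TRI")
  )
  out <- filter_tri_last(chains)
  expect_equal(nrow(out), 2)
  expect_true(all(vapply(out$edge_layers, function(l) l[length(l)],
                         character(1)) == "TRI"))
  expect_equal(nrow(filter_tri_last(chains[0, ])), 0)
})

test_that("condition and TRI-last filters commute on sharing-free chains", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    chains <- do.call(rbind, lapply(seq_len(n), function(i) {
      len <- sample(1:3, 1)
      nodes <- c(sprintf("r%d_%d", rep, i),
                 if (len > 1) sprintf("x%d_%d_%d", rep, i, seq_len(len - 1)),
                 "t")
      mk_chain(sample(names(cmap_fixture), sample(1:2, 1)),
               nodes, sample(c("PPI", "TRI"), len, replace = TRUE))
    }))
    a <- filter_tri_last(filter_condition_specific(chains, cmap_fixture))
    b <- filter_condition_specific(filter_tri_last(chains), cmap_fixture)
    expect_identical(a, b)
  }
})

test_that("chain union recovers the model network with original signs", {
  net <- chain_net(
    source = c("r", "x"), target = c("x", "t"), layer = c("PPI", "TRI"),
    sign = c(1L, -1L)
  )
  chains <- enumerate_chains(net, "r", "t", max_len = 2)
  model <- chains_to_network(chains, net)
  expect_identical(as.data.frame(model), as.data.frame(net))
  expect_equal(nrow(chains_to_network(chains[0, ])), 0)
})
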