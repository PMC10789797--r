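# brute-force bipartition oracle: the set of tip-label sets below each
# internal edge, computed by direct recursion over the edge list
bipartitions <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  below <- function(v) {
    if (v <= ntip) return(tr$tip.label[v])
    sort(unlist(lapply(kids[[as.character(v)]], below)))
  }
  internal <- tr$edge[tr$edge[, 2] > ntip, 2]
  sets <- lapply(internal, function(v) paste(below(v), collapse = "|"))
  sort(unlist(sets))
}

test_that("newick read/write round-trips topology, labels and lengths", {
  tr <- read_newick(text = "(A:1,B:2)R;")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(tr$node.label, "R")
  expect_equal(sort(tr$edge.length), c(1, 2))
  rt <- read_newick(text = write_newick(tr))
  expect_equal(rt$tip.label, tr$tip.label)
  expect_equal(rt$edge.length, tr$edge.length)
  # quoted labels containing spaces survive
  trq <- read_newick(text = "('Asgard sp. A':1,'MK D1':2)root;")
  expect_true("Asgard sp. A" %in% trq$tip.label)
  expect_error(read_newick(text = "(A:1,B:2"), "malformed|parse")
})

test_that("write-then-read is a fixed point on a large random tree", {
  set.seed(31)
  tr <- ape::rtree(100, rooted = TRUE)
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  once <- read_newick(text = write_newick(tr))
  twice <- read_newick(text = write_newick(once))
  expect_equal(write_newick(once), write_newick(twice))
  # bipartition sets agree with the brute-force enumerator
  expect_equal(bipartitions(once), bipartitions(tr))
  expect_equal(bipartitions(twice), bipartitions(tr))
})

test_that("annotation attaches estimates and validates labels", {
  tr <- read_newick(text = "((MKD1:1,Loki3:1)Loki:1,(Thor:1,Heim:1)X:1)LAsCA;")
  est <- data.frame(label = c("LAsCA", "MKD1", "Loki"),
                    ogt = c(65.5, 20.5, 57.5),
                    ci_lower = c(65.2, 19, 56.1),
                    ci_upper = c(65.7, 24.1, 60.2),
                    lifestyle = classify_lifestyle(c(65.5, 20.5, 57.5)))
  at <- annotate_nodes(tr, est)
  expect_s3_class(at, "ogt_tree")
  expect_equal(nrow(at$annotations), 3L)
  # root carries the ancestral value
  expect_equal(at$annotations$ogt[at$annotations$label == "LAsCA"], 65.5)
  # idempotent on re-application with the same estimates
  at2 <- annotate_nodes(at, est)
  expect_equal(at2$annotations, at$annotations)
  # empty estimates leave the tree unannotated but valid
  expect_equal(nrow(annotate_nodes(tr, est[0, ])$annotations), 0L)
  # unknown and duplicate labels are refused, naming the offender
  expect_error(annotate_nodes(tr, transform(est, label = c("LAsCA", "Nope", "Loki"))),
               "Nope")
  expect_error(annotate_nodes(tr, est[c(1, 1, 2), ]), "duplicate")
})

test_that("annotated newick export carries tags and an authoritative sidecar", {
  tr <- read_newick(text = "((MKD1:1,Loki3:1)Loki:1,Thor:2)LAsCA;")
  est <- data.frame(label = c("LAsCA", "MKD1"), ogt = c(65.5, 20.5),
                    ci_lower = c(65.2, 19), ci_upper = c(65.7, 24.1),
                    lifestyle = classify_lifestyle(c(65.5, 20.5)))
  at <- annotate_nodes(tr, est)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  side <- withr::local_tempfile(fileext = ".tsv")
  write_newick(at, nwk, sidecar = side)
  txt <- readLines(nwk)
  expect_match(txt, "MKD1[&ogt=20.5,lifestyle=mesophile]", fixed = TRUE)
  expect_match(txt, "LAsCA[&ogt=65.5", fixed = TRUE)
  d <- read.delim(side)
  expect_equal(names(d), c("node", "ogt", "ci_lower", "ci_upper",
                           "lifestyle"))
  expect_equal(d$ogt[d$node == "LAsCA"], 65.5)
})

test_that("trajectory table uses nearest annotated ancestors and telescopes", {
  tr <- read_newick(
    text = "(((MKD1:1,Loki3:1)Loki:1,Thor:1)Mid:1,(Heim:1,Kari:1)X:1)LAsCA;")
  # Mid and X are NOT annotated: their descendants must link to LAsCA/Loki
  est <- data.frame(label = c("LAsCA", "Loki", "MKD1", "Loki3", "Thor"),
                    ogt = c(65.5, 57.5, 20.5, 50.1, 33.8),
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    lifestyle = classify_lifestyle(c(65.5, 57.5, 20.5, 50.1,
                                                     33.8)))
  tt <- trajectory_table(annotate_nodes(tr, est))
  expect_equal(nrow(tt), 4L)  # every annotated node except the root
  expect_equal(tt$parent[tt$node == "Loki"], "LAsCA")
  expect_equal(tt$parent[tt$node == "Thor"], "LAsCA")  # skips bare Mid
  expect_equal(tt$parent[tt$node == "MKD1"], "Loki")
  expect_equal(tt$delta[tt$node == "MKD1"], 20.5 - 57.5)
  # telescoping: root-to-leaf deltas sum exactly to leaf - root
  path_delta <- tt$delta[tt$node == "Loki"] + tt$delta[tt$node == "MKD1"]
  expect_equal(path_delta, 20.5 - 65.5, tolerance = 1e-12)
  # two-node chain: delta is a plain subtraction
  chain <- read_newick(text = "(MKD1:1,Dummy:1)LAsCA;")
  est2 <- data.frame(label = c("LAsCA", "MKD1"), ogt = c(65.5, 20.5),
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     lifestyle = classify_lifestyle(c(65.5, 20.5)))
  tt2 <- trajectory_table(annotate_nodes(chain, est2))
  expect_equal(tt2$delta, -45)
  # single annotated root: empty table; no annotations: error
  tt3 <- trajectory_table(annotate_nodes(chain, est2[1, ]))
  expect_equal(nrow(tt3), 0L)
  expect_error(trajectory_table(annotate_nodes(chain, est2[0, ])),
               "no annotated")
})

test_that("telescoping holds on every path of a simulated trait tree", {
  sim <- simulate_trait_tree(n_leaves = 8, seed = 7)
  est <- data.frame(label = names(sim$ogt), ogt = unname(sim$ogt),
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    lifestyle = classify_lifestyle(unname(sim$ogt)))
  at <- annotate_nodes(sim$tree, est)
  tt <- trajectory_table(at)
  delta_by_node <- setNames(tt$delta, tt$node)
  parent_by_node <- setNames(tt$parent, tt$node)
  root_lab <- setdiff(est$label, tt$node)
  expect_length(root_lab, 1L)
  for (leaf in sim$tree$tip.label) {
    tot <- 0
    v <- leaf
    while (v %in% names(parent_by_node)) {
      tot <- tot + delta_by_node[[v]]
      v <- parent_by_node[[v]]
    }
    expect_equal(tot, unname(sim$ogt[leaf] - sim$ogt[root_lab]), tolerance = 1e-12)
  }
})

test_that("the OGT-coloured tree plot renders", {
  sim <- simulate_trait_tree(n_leaves = 5, seed = 2)
  est <- data.frame(label = names(sim$ogt), ogt = unname(sim$ogt),
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    lifestyle = classify_lifestyle(unname(sim$ogt)))
  at <- annotate_nodes(sim$tree, est)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(at))
})
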