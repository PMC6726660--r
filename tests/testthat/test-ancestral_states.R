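traits_of <- function(states, trait = "motif") {
  data.frame(taxon = names(states), trait = trait,
             state = as.character(states), stringsAsFactors = FALSE)
}

test_that("a constant trait reconstructs with zero changes", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  fit <- fitch_reconstruct(tree, traits_of(c(A = 1, B = 1, C = 1, D = 1)),
                           "motif")
  expect_equal(fit$changes, 0L)
  internal <- fit$nodes[!fit$nodes$is_tip, ]
  expect_true(all(internal$state_set == "1"))
})

test_that("a single discordant tip costs one change and leaves the root at presence", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  tt <- traits_of(c(A = 1, B = 1, C = 0, D = 1))
  fit <- fitch_reconstruct(tree, tt, "motif")
  root <- ape::Ntip(tree) + 1L
  expect_equal(fit$changes, 1L)
  expect_equal(fit$nodes$state_set[root], "1")
  oracle <- enum_parsimony(tree, c(A = 1, B = 1, C = 0, D = 1))
  expect_equal(fit$changes, oracle$changes)
})

test_that("changes and state sets match exhaustive enumeration on small trees", {
  topologies <- c("((A,B),(C,D));",
                  "(((A,B),C),(D,E));",
                  "((A,B,C),(D,E));",          # polytomy
                  "(((A,B),(C,D)),(E,F));",
                  "((((A,B),C),D),(E,F));",
                  "(A,B,C,D,E);")              # star
  for (nwk in topologies) {
    tree <- ape::read.tree(text = nwk)
    tips <- tree$tip.label
    n <- length(tips)
    for (code in 1:(2^n - 2)) {  # skip the two constant cases? keep all
      states <- as.integer(intToBits(code))[seq_len(n)]
      names(states) <- tips
      fit <- fitch_reconstruct(tree, traits_of(states), "motif")
      oracle <- enum_parsimony(tree, states)
      expect_equal(fit$changes, oracle$changes, info = paste(nwk, code))
      expect_equal(fit$nodes$state_set, oracle$state_sets,
                   info = paste(nwk, code))
    }
  }
})

test_that("parsimony length agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  tree <- ape::rtree(12)
  for (i in 1:10) {
    states <- stats::setNames(sample(0:1, 12, replace = TRUE),
                              tree$tip.label)
    if (length(unique(states)) == 1L) next
    fit <- fitch_reconstruct(tree, traits_of(states), "motif")
    dat <- phangorn::phyDat(matrix(as.character(states),
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fit$changes,
                 as.integer(phangorn::parsimony(tree, dat,
                                                method = "sankoff")))
  }
})

test_that("unknown-state tips are pruned with a warning; degenerate inputs error", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  tt <- traits_of(c(A = 1, B = 1, C = 0, D = 1))
  tt$state[tt$taxon == "D"] <- "?"
  expect_warning(fit <- fitch_reconstruct(tree, tt, "motif"), "pruning")
  expect_equal(ape::Ntip(fit$tree), 3L)

  expect_error(fitch_reconstruct(tree, tt, "short_tail"), "absent from table")
  all_unk <- traits_of(c(A = "?", B = "?", C = "?", D = "?"))
  expect_error(suppressWarnings(fitch_reconstruct(tree, all_unk, "motif")),
               "unknown state")
})

test_that("ambiguous nodes resolve by the stated convention", {
  tree <- ape::read.tree(text = "(A,B);")
  fit <- fitch_reconstruct(tree, traits_of(c(A = 1, B = 0)), "motif")
  root <- 3L
  expect_equal(fit$nodes$state_set[root], "01")
  expect_equal(fit$nodes$resolved[root], "1")  # presence preferred at root
})

test_that("Dollo places a single gain and counts minimal losses", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  all1 <- dollo_reconstruct(tree, traits_of(c(A = 1, B = 1, C = 1, D = 1)),
                            "motif")
  expect_equal(all1$gain_node, 5L)  # root
  expect_equal(all1$losses, 0L)

  two <- ape::read.tree(text = "(A,B);")
  d <- dollo_reconstruct(two, traits_of(c(A = 1, B = 0)), "motif")
  expect_equal(d$gain_node, which(two$tip.label == "A"))
  expect_equal(d$losses, 0L)

  tt <- traits_of(c(A = 1, B = 0, C = 0, D = 1))
  d2 <- dollo_reconstruct(tree, tt, "motif")
  expect_equal(d2$losses, 2L)

  none <- traits_of(c(A = 0, B = 0, C = 0, D = 0))
  expect_error(dollo_reconstruct(tree, none, "motif"), "no single-origin")
})

test_that("Fitch change count never exceeds Dollo losses plus one", {
  set.seed(14)
  tree <- ape::stree(16, "balanced")
  for (i in 1:25) {
    sim <- simulate_traits(tree, gain = 0.15, loss = 0.15, root_state = 1)
    if (!any(sim$traits$state == "1")) next
    fit <- fitch_reconstruct(tree, sim$traits, "motif")
    dol <- dollo_reconstruct(tree, sim$traits, "motif")
    expect_lte(fit$changes, dol$losses + 1L)
  }
})

test_that("the fixture tree places the motif in the gnathostome ancestor", {
  tree <- read_cx_tree(cx_extdata("beta_connexin_tree.nwk"))
  traits <- read_trait_table(cx_extdata("beta_connexin_traits.tsv"))
  fit <- suppressWarnings(fitch_reconstruct(tree, traits, "motif"))
  root <- ape::Ntip(fit$tree) + 1L  # MRCA of the gnathostome A and B clades
  expect_equal(fit$nodes$state_set[root], "1")
  expect_equal(fit$changes, 2L)

  dol <- suppressWarnings(dollo_reconstruct(tree, traits, "motif"))
  expect_equal(dol$gain_node, ape::Ntip(dol$tree) + 1L)
  expect_equal(dol$losses, 2L)
  loss_sets <- lapply(dol$loss_nodes, function(n) clade_tips(dol$tree, n))
  cur <- curated_set()
  nonmam_cx30 <- cur$taxon[cur$gene_label == "Cx30" & cur$motif_state == "0"]
  actino_cx303 <- cur$taxon[cur$gene_label == "Cx30.3"]
  expect_true(any(vapply(loss_sets, setequal, TRUE, y = nonmam_cx30)))
  expect_true(any(vapply(loss_sets, setequal, TRUE, y = actino_cx303)))
})
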