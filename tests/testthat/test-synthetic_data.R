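test_that("zero rates propagate the root state to every tip", {
  tree <- ape::stree(8, "balanced")
  sim <- simulate_traits(tree, gain = 0, loss = 0, root_state = 1, seed = 1)
  expect_true(all(sim$traits$state == "1"))
  expect_true(all(sim$internal_states == 1L))
})

test_that("all three generators are deterministic under a fixed seed", {
  tree <- ape::stree(8, "balanced")
  t1 <- simulate_traits(tree, seed = 99)
  t2 <- simulate_traits(tree, seed = 99)
  expect_identical(t1, t2)

  traits <- rbind(t1$traits,
                  within(t1$traits, trait <- "short_tail"))
  f1 <- simulate_family(traits, seed = 100)
  f2 <- simulate_family(traits, seed = 100)
  expect_identical(f1, f2)

  a1 <- simulate_assay(c(x = "insensitive"), seed = 101)
  a2 <- simulate_assay(c(x = "insensitive"), seed = 101)
  expect_identical(a1, a2)
})

test_that("constructed determinants are recovered by the annotation pipeline", {
  traits <- rbind(
    data.frame(taxon = c("t_can_short", "t_abs_short", "t_can_ext"),
               trait = "motif", state = c("1", "0", "1")),
    data.frame(taxon = c("t_can_short", "t_abs_short", "t_can_ext"),
               trait = "short_tail", state = c("1", "1", "0")))
  fam <- simulate_family(traits, seed = 5)
  report <- phenotype_report(fam$records)
  expect_equal(report$motif_status[report$id == "t_can_short"], "canonical")
  expect_equal(report$length_class[report$id == "t_can_short"], "short")
  expect_equal(report$motif_status[report$id == "t_abs_short"], "absent")
  expect_equal(report$length_class[report$id == "t_can_ext"], "extended")
})

test_that("window-proline mode also destroys the canonical call", {
  traits <- rbind(
    data.frame(taxon = "t0", trait = "motif", state = "0"),
    data.frame(taxon = "t0", trait = "short_tail", state = "1"))
  fam <- simulate_family(traits, motif_loss_mode = "window_proline",
                         seed = 6)
  report <- phenotype_report(fam$records)
  expect_equal(report$motif_status, "proline_modified")
})

test_that("a 100-record family annotates to its ground truth labels", {
  set.seed(12)
  tree <- ape::rtree(100)
  motif <- simulate_traits(tree, trait_name = "motif", root_state = 1,
                           gain = 0.05, loss = 0.05)
  tail <- simulate_traits(tree, trait_name = "short_tail", root_state = 0,
                          gain = 0.1, loss = 0.1)
  fam <- simulate_family(rbind(motif$traits, tail$traits), seed = 13)
  report <- phenotype_report(fam$records)
  m <- merge(report, fam$truth, by.x = "id", by.y = "taxon")
  expect_equal(nrow(m), 100L)
  motif_ok <- (m$motif_state == "1") == (m$motif_status == "canonical")
  tail_ok <- (m$tail_state == "1") == (m$length_class == "short")
  expect_gte(mean(motif_ok & tail_ok), 0.99)
})

test_that("generated FASTA round-trips through the readers unchanged", {
  traits <- rbind(
    data.frame(taxon = c("a", "b"), trait = "motif", state = "1"),
    data.frame(taxon = c("a", "b"), trait = "short_tail", state = c("1", "0")))
  fam <- simulate_family(traits, seed = 8)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_cx_fasta(fam$records, f)
  back <- read_cx_fasta(f)
  expect_equal(back$id, fam$records$id)
  expect_equal(back$residues, fam$records$residues)
})

test_that("injected transfer delays are recovered to one sample interval", {
  for (delay in c(60, 240, 300)) {
    tr <- simulate_transfer_trace(delay)
    call <- call_transfer_time(tr)
    expect_false(call$censored)
    expect_lte(abs(call$time - delay), 10)
    expect_lt(abs(call$interpolated - delay), 1)
  }
})

test_that("closed gap junctions delay the simulated transfer past the CO2 window", {
  sim <- simulate_assay(c(gj = "insensitive"),
                        gap_junction = c(gj = "closes"), seed = 15)
  t35 <- call_transfer_time(sim$traces[["gj.pco2_35"]])
  t55 <- call_transfer_time(sim$traces[["gj.pco2_55"]])
  expect_lt(t35$time, 120)
  expect_gte(t55$time, 120)
})

test_that("simulated dye loading reproduces the qualitative response pattern", {
  sim <- simulate_assay(c(amniote = "opens_moderate_pco2",
                          amphibian = "insensitive",
                          fish32 = "opens_high_pco2_only"), seed = 16)
  deltas <- list()
  for (cons in unique(sim$loading$construct)) {
    sub <- sim$loading[sim$loading$construct == cons, ]
    s <- dye_loading_summary(sub[, setdiff(names(sub), "construct")])
    agg <- stats::aggregate(delta ~ condition, data = s$delta, FUN = mean)
    deltas[[cons]] <- stats::setNames(agg$delta, agg$condition)
  }
  # moderate PCO2 separates the amniote-like class from the insensitive one
  expect_gt(deltas$amniote["pco2_55"], deltas$amphibian["pco2_55"] + 40)
  # the Cx32-like class loads little at 55 and strongly at 70
  expect_lt(deltas$fish32["pco2_55"], deltas$amniote["pco2_55"] / 2)
  expect_gt(deltas$fish32["pco2_70"], deltas$fish32["pco2_55"] + 40)
  # the positive control loads everything
  for (d in deltas) expect_gt(d["zero_ca"], 100)
})
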