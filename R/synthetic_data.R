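#' Simulate binary trait evolution on a tree
#'
#' Traits evolve from the root towards the tips with per-branch Bernoulli
#' transitions: a present trait is lost with probability `loss` per branch, an
#' absent one gained with probability `gain`. True internal states are
#' retained so reconstruction accuracy can be scored against the truth.
#' Branch lengths are ignored (rates are per branch), matching the
#' parsimony-only reconstruction the package performs.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param gain,loss per-branch transition probabilities.
#' @param root_state 0, 1, or `NA` to draw it uniformly.
#' @param trait_name name recorded in the output trait table.
#' @param seed optional integer seed (full determinism for a fixed seed).
#' @return a list: `traits` (a taxon/trait/state table for the tips),
#'   `internal_states` (named integer vector by ape node id),
#'   `root_state`.
#' @export
simulate_traits <- function(tree, gain = 0.05, loss = 0.05, root_state = NA,
                            trait_name = "motif", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  total <- ntip + tree$Nnode
  root <- ntip + 1L
  state <- integer(total)
  state[root] <- if (is.na(root_state)) stats::rbinom(1L, 1L, 0.5) else
    as.integer(root_state)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(po)))) {  # parents before children
    parent <- po[i, 1L]; child <- po[i, 2L]
    p_change <- if (state[parent] == 1L) loss else gain
    flip <- stats::runif(1L) < p_change
    state[child] <- if (flip) 1L - state[parent] else state[parent]
  }
  traits <- data.frame(taxon = tree$tip.label, trait = trait_name,
                       state = as.character(state[seq_len(ntip)]),
                       stringsAsFactors = FALSE)
  internal <- state[(ntip + 1L):total]
  names(internal) <- as.character((ntip + 1L):total)
  list(traits = traits, internal_states = internal,
       root_state = state[root])
}

#' Simulate a connexin-like protein family from trait states
#'
#' Each tip sequence is a mutated copy of the bundled Cx26 scaffold. Tips
#' with motif state 0 receive either the K125R substitution (default) or a
#' proline in the 123-124 window; tips with an extended tail receive an
#' appended C-terminal tail of Poisson-distributed length whose residues are
#' proline with probability `tail_proline_prob`. Background substitutions
#' avoid the anchor sites (104, 123-125) and never introduce prolines, so
#' the ground-truth determinants are exactly the ones constructed.
#'
#' @param traits a trait table containing traits `motif` and `short_tail`
#'   (states 0/1) for every taxon to simulate.
#' @param subst_prob per-site background substitution probability.
#' @param tail_length_mean mean appended tail length for extended-tail tips.
#' @param tail_proline_prob per-residue proline probability in appended
#'   tails.
#' @param motif_loss_mode how motif-0 tips lose the motif.
#' @param seed optional integer seed.
#' @return a list: `records` (a [cx_records] collection), `truth` (data
#'   frame: taxon, motif_state, tail_state, n_tail_prolines).
#' @export
simulate_family <- function(traits, subst_prob = 0.02, tail_length_mean = 40,
                            tail_proline_prob = 0.05,
                            motif_loss_mode = c("K125R", "window_proline"),
                            seed = NULL) {
  motif_loss_mode <- match.arg(motif_loss_mode)
  if (!is.null(seed)) set.seed(seed)
  scaffold <- bundled_reference("cx26")$residues
  n <- nchar(scaffold)
  anchor_sites <- c(104L, 123L, 124L, 125L)
  motif <- traits[traits$trait == "motif", ]
  tail <- traits[traits$trait == "short_tail", ]
  taxa <- motif$taxon
  stopifnot(all(taxa %in% tail$taxon))
  motif_state <- stats::setNames(motif$state, motif$taxon)
  tail_state <- stats::setNames(tail$state, tail$taxon)
  non_p <- setdiff(.AA_LETTERS, "P")

  recs <- list(); truth <- list()
  for (tx in taxa) {
    res <- scaffold
    free_sites <- setdiff(seq_len(n), anchor_sites)
    hit <- free_sites[stats::runif(length(free_sites)) < subst_prob]
    for (pos in hit) {
      cur <- substr(res, pos, pos)
      substr(res, pos, pos) <- sample(setdiff(non_p, cur), 1L)
    }
    if (motif_state[tx] == "0") {
      if (motif_loss_mode == "K125R") {
        substr(res, 125L, 125L) <- "R"
      } else {
        substr(res, 123L, 123L) <- "P"
      }
    }
    n_pro <- 0L
    if (tail_state[tx] == "0") {  # extended tail
      len <- max(20L, stats::rpois(1L, tail_length_mean))
      tail_res <- ifelse(stats::runif(len) < tail_proline_prob, "P",
                         sample(non_p, len, replace = TRUE))
      n_pro <- sum(tail_res == "P")
      res <- paste0(res, paste(tail_res, collapse = ""))
    }
    recs[[tx]] <- res
    truth[[tx]] <- data.frame(taxon = tx, motif_state = motif_state[tx],
                              tail_state = tail_state[tx],
                              n_tail_prolines = n_pro,
                              stringsAsFactors = FALSE)
  }
  records <- cx_records(id = taxa, residues = unlist(recs[taxa]),
                        gene_label = "simulated")
  truth <- do.call(rbind, truth[taxa])
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

.DEFAULT_EFFECTS <- rbind(
  opens_moderate_pco2  = c(pco2_55 = 80, pco2_70 = 100, zero_ca = 150),
  opens_high_pco2_only = c(pco2_55 = 15, pco2_70 = 90,  zero_ca = 150),
  insensitive          = c(pco2_55 = 0,  pco2_70 = 0,   zero_ca = 150))

#' Simulate dye-loading tables and dye-transfer traces
#'
#' Cell intensities are `background + baseline + class effect + noise`, with
#' a fresh background offset per image (replicate x condition) and Gaussian
#' cell-level noise. Effects are the mean intensity change over the control
#' condition per hemichannel class (units: arbitrary fluorescence). Default
#' design matches the study: 40 cells per condition, 5 independent
#' replicates.
#'
#' Transfer traces (one per construct and trace condition) have a constant
#' donor plateau and a logistic acceptor rise whose threshold crossing is
#' placed at `trace_delay` seconds; for a CO2-closed gap junction under
#' hypercapnia the rise is additionally held until the control saline is
#' restored at `hypercapnia_hold` seconds.
#'
#' @param hemichannel named character vector, construct id ->
#'   hemichannel class (a row name of the effect matrix).
#' @param gap_junction optional named character vector, construct id ->
#'   `"closes"` or `"insensitive"`; traces are only generated when supplied.
#' @param effects effect matrix (classes x conditions).
#' @param n_cells,n_replicates design size.
#' @param cell_sd cell-level noise standard deviation.
#' @param baseline nonspecific loading above background, control condition.
#' @param background_range uniform range of per-image background offsets.
#' @param trace_delay base transfer delay (s); `hypercapnia_hold` the CO2
#'   application window (s).
#' @param seed optional integer seed.
#' @return a list: `loading` (data frame: construct, replicate, condition,
#'   cell, intensity, background), `traces` (named list of
#'   time/donor/acceptor/condition lists).
#' @export
simulate_assay <- function(hemichannel, gap_junction = NULL,
                           effects = .DEFAULT_EFFECTS,
                           n_cells = 40, n_replicates = 5, cell_sd = 20,
                           baseline = 20, background_range = c(50, 150),
                           trace_delay = 60, hypercapnia_hold = 120,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(hemichannel %in% rownames(effects)))
  conditions <- c("pco2_35", colnames(effects))
  rows <- list()
  for (construct in names(hemichannel)) {
    cls <- hemichannel[[construct]]
    for (rep_i in seq_len(n_replicates)) {
      for (cond in conditions) {
        bg <- stats::runif(1L, background_range[1L], background_range[2L])
        eff <- if (cond == "pco2_35") 0 else effects[cls, cond]
        intensity <- pmax(0, bg + baseline + eff +
                            stats::rnorm(n_cells, 0, cell_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          construct = construct, replicate = rep_i, condition = cond,
          cell = seq_len(n_cells), intensity = intensity, background = bg,
          stringsAsFactors = FALSE)
      }
    }
  }
  loading <- do.call(rbind, rows)
  rownames(loading) <- NULL

  traces <- list()
  if (!is.null(gap_junction)) {
    for (construct in names(gap_junction)) {
      for (cond in c("pco2_35", "pco2_55")) {
        delay <- if (gap_junction[[construct]] == "closes" &&
                     cond == "pco2_55") {
          hypercapnia_hold + trace_delay
        } else {
          trace_delay
        }
        traces[[paste(construct, cond, sep = ".")]] <-
          c(simulate_transfer_trace(delay), list(condition = cond,
                                                 construct = construct))
      }
    }
  }
  list(loading = loading, traces = traces)
}

#' Simulate a single donor/acceptor dye-transfer trace
#'
#' Constant donor plateau; logistic acceptor rise positioned so that the
#' continuous-time 10% threshold crossing falls exactly at `delay_s`. Only
#' the crossing time is contract-relevant; the logistic shape is a modelling
#' convenience.
#'
#' @param delay_s threshold-crossing time (s).
#' @param interval_s sampling interval (10 s, the acquisition rate).
#' @param duration_s trace length (s).
#' @param donor donor plateau (fluorescence units).
#' @param tau logistic time constant (s).
#' @param transfer_fraction fraction of donor defining the crossing.
#' @param noise_sd optional Gaussian noise on the acceptor.
#' @return a list: `time`, `donor`, `acceptor`.
#' @export
simulate_transfer_trace <- function(delay_s, interval_s = 10,
                                    duration_s = 600, donor = 1000, tau = 15,
                                    transfer_fraction = 0.10, noise_sd = 0) {
  time <- seq(0, duration_s, by = interval_s)
  amp <- 3 * transfer_fraction * donor
  # logistic reaches transfer_fraction * donor exactly at delay_s
  t_mid <- delay_s + tau * log(amp / (transfer_fraction * donor) - 1)
  acceptor <- amp / (1 + exp(-(time - t_mid) / tau))
  if (noise_sd > 0) acceptor <- pmax(0, acceptor +
                                       stats::rnorm(length(time), 0, noise_sd))
  list(time = time, donor = rep(donor, length(time)), acceptor = acceptor)
}
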