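#' Run manifest
#'
#' Provenance block attached to every machine-readable report: command,
#' package version, seed, configuration values and md5 digests of the input
#' files.
#'
#' @param command subcommand name.
#' @param inputs character vector of input paths (digested if they exist).
#' @param config named list of configuration values.
#' @param seed integer seed or `NA`.
#' @return a named list.
#' @export
run_manifest <- function(command, inputs = character(0), config = list(),
                         seed = NA) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  list(command = command,
       package = "connexinCO2",
       version = as.character(utils::packageVersion("connexinCO2")),
       seed = seed,
       config = config,
       input_digests = digests,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_report <- function(table, manifest, out_prefix) {
  tsv <- paste0(out_prefix, ".tsv")
  json <- paste0(out_prefix, ".json")
  write.table(table, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(manifest = manifest, rows = table), json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}

#' Annotate a FASTA of connexin sequences end-to-end
#'
#' Reads the FASTA, runs clade assignment, anchored alignment, motif scan,
#' tail profiling and the phenotype rules, and writes twin TSV/JSON reports.
#'
#' @param fasta path to a protein FASTA.
#' @param out_prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @param short_threshold,min_prolines tail classification parameters.
#' @return the report data frame, invisibly.
#' @export
cmd_annotate <- function(fasta, out_prefix, short_threshold = 15,
                         min_prolines = 2) {
  records <- read_cx_fasta(fasta)
  report <- phenotype_report(records, short_threshold = short_threshold,
                             min_prolines = min_prolines)
  manifest <- run_manifest("annotate", fasta,
                           list(short_threshold = short_threshold,
                                min_prolines = min_prolines))
  .write_report(report, manifest, out_prefix)
  invisible(report)
}

#' Ancestral-state reconstruction from files
#'
#' @param tree_file newick tree path.
#' @param traits_file trait table path (TSV).
#' @param trait trait name to reconstruct.
#' @param method `"fitch"` or `"dollo"`.
#' @param out_prefix output path prefix; writes a per-node TSV, a JSON twin,
#'   and an annotated newick (`<prefix>.nwk`) with resolved states as node
#'   labels.
#' @return the `cx_recon` object, invisibly.
#' @export
cmd_ancestral <- function(tree_file, traits_file, trait,
                          method = c("fitch", "dollo"), out_prefix) {
  method <- match.arg(method)
  tree <- read_cx_tree(tree_file)
  traits <- read_trait_table(traits_file)
  recon <- if (method == "fitch") {
    fitch_reconstruct(tree, traits, trait)
  } else {
    dollo_reconstruct(tree, traits, trait)
  }
  manifest <- run_manifest("ancestral", c(tree_file, traits_file),
                           list(trait = trait, method = method))
  extra <- if (method == "dollo") {
    list(gain_node = recon$gain_node, losses = recon$losses)
  } else list()
  tsv <- paste0(out_prefix, ".tsv")
  write.table(recon$nodes, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(manifest = manifest, changes = recon$changes),
                         extra, list(nodes = recon$nodes)),
                       paste0(out_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  annotated <- recon$tree
  ntip <- ape::Ntip(annotated)
  annotated$node.label <- recon$nodes$resolved[recon$nodes$node > ntip]
  ape::write.tree(annotated, file = paste0(out_prefix, ".nwk"))
  invisible(recon)
}

#' Dye-loading assay report from a measurement table
#'
#' Reads a per-cell intensity table (TSV with columns construct, replicate,
#' condition, cell, intensity, background), computes per-replicate
#' background-corrected medians and deltas against the control condition,
#' runs the group statistics per condition across constructs, and writes
#' twin TSV/JSON reports. All thresholds in force are recorded in the
#' manifest.
#'
#' @param loading_file path to the measurement TSV.
#' @param out_prefix output path prefix.
#' @param config a [assay_config].
#' @param alpha significance level.
#' @param force allow fewer than `config$min_replicates` replicates
#'   (otherwise an error).
#' @return a list with `delta`, `tests` and `box` components, invisibly.
#' @export
cmd_assay <- function(loading_file, out_prefix, config = assay_config(),
                      alpha = 0.05, force = FALSE) {
  table <- read.delim(loading_file, sep = "\t")
  req <- c("construct", "replicate", "condition", "cell", "intensity",
           "background")
  if (!all(req %in% names(table))) {
    stop("assay table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  deltas <- list()
  for (construct in unique(table$construct)) {
    sub <- table[table$construct == construct, ]
    n_rep <- length(unique(sub$replicate))
    if (n_rep < config$min_replicates && !force) {
      stop("construct '", construct, "': ", n_rep, " replicate(s) < ",
           "min_replicates (", config$min_replicates,
           "); use force = TRUE to override", call. = FALSE)
    }
    s <- dye_loading_summary(sub[, setdiff(names(sub), "construct")], config)
    s$delta$construct <- construct
    deltas[[construct]] <- s$delta
  }
  delta <- do.call(rbind, deltas)
  rownames(delta) <- NULL

  tests <- list(); box <- list()
  for (cond in unique(delta$condition)) {
    d <- delta[delta$condition == cond, ]
    if (length(unique(d$construct)) >= 2L) {
      tests[[cond]] <- group_tests(d$delta, d$construct, alpha)
    }
    for (construct in unique(d$construct)) {
      box[[paste(construct, cond, sep = ".")]] <-
        box_whisker_stats(d$delta[d$construct == construct], config = config)
    }
  }
  manifest <- run_manifest("assay", loading_file,
                           c(unclass(config), list(alpha = alpha)))
  .write_report(delta, manifest, paste0(out_prefix, "_delta"))
  jsonlite::write_json(list(manifest = manifest, tests = tests, box = box),
                       paste0(out_prefix, "_stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(delta = delta, tests = tests, box = box))
}

#' Transfer-time report for a set of traces
#'
#' @param traces_file TSV with columns trace_id, time, donor, acceptor.
#' @param out_prefix output path prefix.
#' @param config a [assay_config].
#' @return data frame of calls, invisibly.
#' @export
cmd_transfer <- function(traces_file, out_prefix, config = assay_config()) {
  x <- read.delim(traces_file, sep = "\t")
  stopifnot(all(c("trace_id", "time", "donor", "acceptor") %in% names(x)))
  rows <- lapply(split(x, x$trace_id), function(tr) {
    tr <- tr[order(tr$time), ]
    call <- call_transfer_time(tr, config)
    data.frame(trace_id = tr$trace_id[1L], time = call$time,
               interpolated = call$interpolated, censored = call$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  manifest <- run_manifest("transfer", traces_file, unclass(config))
  .write_report(out, manifest, out_prefix)
  invisible(out)
}

#' Codon-fragility report
#'
#' @param out_prefix output path prefix.
#' @return the fragility data frame, invisibly.
#' @export
cmd_fragility <- function(out_prefix) {
  report <- motif_fragility_report()
  manifest <- run_manifest("fragility")
  .write_report(report, manifest, out_prefix)
  invisible(report)
}

#' Generate a complete synthetic input set
#'
#' Writes a simulated trait table, protein family FASTA and dye-loading
#' table (plus transfer traces as TSV) under `out_dir`, all derived from one
#' seed.
#'
#' @param out_dir output directory (created if needed).
#' @param tree a rooted tree; default a 16-tip balanced tree.
#' @param seed integer seed; per-stream sub-seeds are derived from it so the
#'   three generators can be re-run independently.
#' @return named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, tree = ape::stree(16, "balanced"),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  sub <- seed + c(traits = 101L, tails = 211L, family = 307L, assay = 401L)
  tr_motif <- simulate_traits(tree, trait_name = "motif", seed = sub["traits"])
  tr_tail <- simulate_traits(tree, trait_name = "short_tail",
                             seed = sub["tails"])
  traits <- rbind(tr_motif$traits, tr_tail$traits)
  fam <- simulate_family(traits, seed = sub["family"])
  labels <- stats::setNames(
    ifelse(tr_motif$traits$state == "1" & tr_tail$traits$state == "1",
           "opens_moderate_pco2", "insensitive"),
    tr_motif$traits$taxon)
  assay <- simulate_assay(labels[1:3], seed = sub["assay"])

  paths <- c(traits = file.path(out_dir, "traits.tsv"),
             fasta = file.path(out_dir, "family.fasta"),
             tree = file.path(out_dir, "tree.nwk"),
             loading = file.path(out_dir, "loading.tsv"))
  write_trait_table(traits, paths["traits"])
  write_cx_fasta(fam$records, paths["fasta"])
  ape::write.tree(tree, file = paths["tree"])
  write.table(assay$loading, paths["loading"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
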