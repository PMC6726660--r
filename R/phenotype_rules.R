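#' PCO2 levels used throughout (mmHg)
#'
#' Control, moderate and high CO2 partial pressures of the standard recording
#' protocol.
#' @return named numeric vector.
#' @export
pco2_levels <- function() c(control = 35, moderate = 55, high = 70)

.norm_motif <- function(motif) {
  if (inherits(motif, "cx_motif")) return(motif$status)
  match.arg(motif, c("canonical", "proline_modified", "absent"))
}

.norm_tail <- function(tail) {
  if (inherits(tail, "cx_tail")) {
    if (tail$length_class == "short") return("short")
    return(if (tail$restricted) "extended_restricted" else
      "extended_unrestricted")
  }
  match.arg(tail, c("short", "extended_unrestricted", "extended_restricted"))
}

#' Predict CO2 phenotypes from structural determinants
#'
#' Implements the inferred functionality model: CO2 sensitivity requires the
#' carbamylation motif; hemichannel opening additionally requires either a
#' short C-terminal tail (amniote Cx26 configuration; opens at moderate
#' PCO2) or a proline-restricted extended tail (Cx32 configuration; the
#' Cx32-clade channels open robustly only at high PCO2, while a
#' proline-restricted Cx26-like channel opens under the standard moderate
#' protocol). Gap-junction closure by CO2 tracks Cx26-like clade identity
#' rather than tail structure — long-tailed Cx26-like gap junctions close
#' even though their hemichannels are insensitive, and Cx32 gap junctions do
#' not close at the doses tested — so the gap-junction half of the prediction
#' is keyed on the clade explicitly.
#'
#' Rules, applied in order:
#' \describe{
#'   \item{R1}{motif not canonical: hemichannel insensitive; gap junction
#'     `untested_rule` (extrapolated).}
#'   \item{R2}{canonical motif + short tail: hemichannel
#'     `opens_moderate_pco2`; gap junction `closes` for Cx26-like (tested),
#'     `untested_rule` for Cx32 (no short-tailed Cx32 has been observed).}
#'   \item{R3}{canonical + extended unrestricted tail: hemichannel
#'     insensitive; gap junction `closes` for Cx26-like (tested),
#'     `insensitive` for Cx32 (extrapolated).}
#'   \item{R4}{canonical + extended restricted tail: hemichannel
#'     `opens_high_pco2_only` for Cx32, `opens_moderate_pco2` for Cx26-like
#'     (the proline-gain mutant opened under the standard moderate
#'     protocol and was never pushed to high PCO2); gap junction `closes`
#'     for Cx26-like, `insensitive` for Cx32.}
#' }
#'
#' @param motif a `cx_motif` (or its status string).
#' @param tail a `cx_tail` (or one of `"short"`, `"extended_unrestricted"`,
#'   `"extended_restricted"`).
#' @param clade `"cx26_like"` or `"cx32"`.
#' @return an object of class `cx_phenotype`: `hemichannel`, `gap_junction`,
#'   `rule_id`, `confidence`, and the PCO2 constants.
#' @export
predict_phenotype <- function(motif, tail, clade = c("cx26_like", "cx32")) {
  clade <- match.arg(clade)
  m <- .norm_motif(motif)
  t <- .norm_tail(tail)
  if (m != "canonical") {
    out <- list(hemichannel = "insensitive", gap_junction = "untested_rule",
                rule_id = "R1", confidence = "extrapolated")
  } else if (t == "short") {
    out <- list(hemichannel = "opens_moderate_pco2",
                gap_junction = if (clade == "cx26_like") "closes" else
                  "untested_rule",
                rule_id = "R2",
                confidence = if (clade == "cx26_like") "tested_experimentally" else
                  "extrapolated")
  } else if (t == "extended_unrestricted") {
    out <- list(hemichannel = "insensitive",
                gap_junction = if (clade == "cx26_like") "closes" else
                  "insensitive",
                rule_id = "R3",
                confidence = if (clade == "cx26_like") "tested_experimentally" else
                  "extrapolated")
  } else {
    out <- list(hemichannel = if (clade == "cx32") "opens_high_pco2_only" else
      "opens_moderate_pco2",
      gap_junction = if (clade == "cx26_like") "closes" else "insensitive",
      rule_id = "R4", confidence = "tested_experimentally")
  }
  out$clade <- clade
  out$pco2_levels_mmHg <- pco2_levels()
  class(out) <- "cx_phenotype"
  out
}

#' @export
print.cx_phenotype <- function(x, ...) {
  cat(sprintf("<cx_phenotype> hemichannel %s; gap junction %s (%s, %s, %s)\n",
              x$hemichannel, x$gap_junction, x$rule_id, x$clade,
              x$confidence))
  invisible(x)
}

# end-to-end annotation of one record against the bundled (or given)
# references
.annotate_one <- function(rec, references, short_threshold = 15,
                          min_prolines = 2) {
  clade <- assign_clade(rec, references)
  ref <- references[if (clade == "cx26_like") 1L else 2L, , drop = FALSE]
  anchors <- reference_anchors(clade)
  pmap <- align_to_reference(rec, ref)
  motif <- scan_motif(rec, pmap, anchors)
  tail <- profile_tail(rec, pmap, anchors, short_threshold, min_prolines)
  phen <- predict_phenotype(motif, tail, clade)
  data.frame(id = rec$id, species = rec$species, gene_label = rec$gene_label,
             clade = clade, motif_status = motif$status,
             aa104 = motif$residue_at_104, aa125 = motif$residue_at_125,
             window_prolines = paste(motif$window_prolines, collapse = ","),
             tail_start = tail$tail_start_query_pos,
             tail_length = tail$tail_length,
             length_class = tail$length_class,
             n_tail_prolines = length(tail$proline_positions),
             tail_prolines = paste(tail$proline_positions, collapse = ","),
             restricted = tail$restricted,
             hemichannel = phen$hemichannel, gap_junction = phen$gap_junction,
             rule_id = phen$rule_id, confidence = phen$confidence,
             stringsAsFactors = FALSE)
}

#' Determinant + phenotype report for a sequence collection
#'
#' Runs the whole annotation pipeline (clade assignment, anchored alignment,
#' motif scan, tail profile, phenotype rules) per record and binds the
#' results into one table, in input order. Duplicate ids are kept with a
#' warning.
#'
#' @param records a [cx_records] collection (an empty data frame yields an
#'   empty report).
#' @param references optional two-row reference set (Cx26 then Cx32).
#' @param short_threshold,min_prolines passed to [profile_tail].
#' @return a data frame, one row per input record.
#' @export
phenotype_report <- function(records, references = NULL, short_threshold = 15,
                             min_prolines = 2) {
  if (is.null(references)) {
    references <- rbind(bundled_reference("cx26"), bundled_reference("cx32"))
  }
  if (nrow(records) == 0L) {
    return(.annotate_one(bundled_reference("cx26"), references)[0L, ])
  }
  if (anyDuplicated(records$id)) {
    warning("duplicate sequence ids in report: ",
            paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    .annotate_one(records[i, , drop = FALSE], references, short_threshold,
                  min_prolines)
  })
  do.call(rbind, rows)
}

#' The experimentally tested construct panel
#'
#' Assembles the twelve constructs whose CO2 phenotypes anchor the rule
#' engine: the wild-type Cx26 of two reptiles, an amphibian, a lungfish and
#' the short-tailed coelacanth paralog; the tail-swap and truncation mutants
#' (tail-truncated amphibian Cx26 ending in PV; human Cx26 carrying the
#' amphibian tail); wild-type Cx32 of human, zebrafish and whale shark; the
#' Cx32 tail with all four prolines mutated to glycine; and the lungfish
#' Cx26 with two tail glycines mutated to proline. Wild-type non-human
#' records are bundled synthetic stand-ins (see
#' `inst/extdata/constructs_synthetic.fasta`) built to carry each
#' construct's documented determinants; the four mutants are derived here
#' with [apply_substitutions] and sequence surgery, mirroring the original
#' mutagenesis.
#'
#' @return a [cx_records] collection of 12 constructs.
#' @export
tested_constructs <- function() {
  wt <- read_cx_fasta(cx_extdata("constructs_synthetic.fasta"))
  h26 <- bundled_reference("cx26")
  h32 <- bundled_reference("cx32")
  xen <- wt[wt$id == "xtCx26", , drop = FALSE]
  lep <- wt[wt$id == "lpCx26", , drop = FALSE]

  # tail truncation at the compact junction; final two residues already PV
  xen_dpv <- cx_records(id = "xtCx26dPV",
                        residues = substr(xen$residues, 1L, 218L),
                        species = xen$species, gene_label = "Cx26")
  stopifnot(substr(xen_dpv$residues, 217L, 218L) == "PV")

  # human Cx26 carrying the amphibian C-terminal tail
  xen_tail <- substr(xen$residues, 219L, nchar(xen$residues))
  h26_xct <- cx_records(id = "hCx26+XenCT",
                        residues = paste0(h26$residues, xen_tail),
                        species = "Homo sapiens", gene_label = "Cx26")

  p2g <- data.frame(position = c(228L, 229L, 242L, 268L), from = "P", to = "G")
  h32_pg <- apply_substitutions(h32, p2g)
  g2p <- data.frame(position = c(222L, 238L), from = "G", to = "P")
  lep_gp <- apply_substitutions(lep, g2p)

  out <- rbind(wt[wt$id != "pmCx27.5", , drop = FALSE],
               h32, xen_dpv, h26_xct, h32_pg, lep_gp)
  class(out) <- c("cx_records", "data.frame")
  out
}

#' Expected phenotypes of the tested construct panel
#'
#' The truth table the rule engine is held to: per construct, the observed
#' hemichannel response class and (where dye-transfer was measured) the
#' gap-junction response. `NA` marks outcomes that were never measured.
#'
#' @return a data frame keyed by construct `id`.
#' @export
construct_truth_table <- function() {
  read.delim(cx_extdata("construct_phenotypes.tsv"), sep = "\t",
             colClasses = "character", na.strings = "NA")
}
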