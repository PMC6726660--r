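#' Call the carbamylation-motif status of a sequence
#'
#' The motif that lets CO2 carbamylate Lys125 and form a salt bridge to
#' Arg104 of the neighbouring subunit is called from three mapped sites on
#' the reference: the Lys125 homolog, the Arg104 homolog, and the 123-124
#' window, which must be free of prolines for the carbamylated lysine to
#' orient correctly.
#'
#' * `canonical`  — K at the 125-homolog, R at the 104-homolog, no proline in
#'   the window;
#' * `proline_modified` — K and R present but at least one window proline
#'   (the configuration seen in lamprey Cx27.5, which carries two); a single
#'   window proline is untested experimentally and is flagged
#'   `low_confidence`;
#' * `absent` — anything else, including a deletion at either site.
#'
#' Degenerate alignments never raise an error here: truncation that removes
#' a site removes the function, so the call is `absent`.
#'
#' @param query a one-row [cx_records].
#' @param pmap a `cx_posmap` of `query` against the reference carrying the
#'   anchors.
#' @param anchors a `cx_anchors` object (see [reference_anchors]).
#' @return an object of class `cx_motif` with fields `status`,
#'   `residue_at_125`, `residue_at_104`, `window_prolines` (query positions)
#'   and `low_confidence`.
#' @export
scan_motif <- function(query, pmap, anchors) {
  stopifnot(inherits(pmap, "cx_posmap"), inherits(anchors, "cx_anchors"))
  res <- .one_record(query)$residues
  aa_at <- function(ref_pos) {
    q <- map_position(pmap, ref_pos)
    if (is.na(q)) "deleted" else substr(res, q, q)
  }
  aa125 <- aa_at(anchors$lysine_site)
  aa104 <- aa_at(anchors$arginine_site)
  window_q <- vapply(anchors$proline_block_window,
                     function(p) map_position(pmap, p), integer(1))
  window_q <- window_q[!is.na(window_q)]
  window_pro <- window_q[vapply(window_q,
                                function(q) substr(res, q, q) == "P",
                                logical(1))]
  kr_present <- identical(aa125, "K") && identical(aa104, "R")
  status <- if (kr_present && length(window_pro) == 0L) {
    "canonical"
  } else if (kr_present) {
    "proline_modified"
  } else {
    "absent"
  }
  out <- list(status = status, residue_at_125 = aa125, residue_at_104 = aa104,
              window_prolines = as.integer(window_pro),
              low_confidence = status == "proline_modified" &&
                length(window_pro) == 1L)
  class(out) <- "cx_motif"
  out
}

#' @export
print.cx_motif <- function(x, ...) {
  cat(sprintf("<cx_motif> %s (aa104 %s, aa125 %s, window prolines: %s)%s\n",
              x$status, x$residue_at_104, x$residue_at_125,
              if (length(x$window_prolines)) {
                paste(x$window_prolines, collapse = ",")
              } else "none",
              if (isTRUE(x$low_confidence)) " [low confidence]" else ""))
  invisible(x)
}

#' Motif calls for a collection, as a table
#'
#' @param records a [cx_records] collection.
#' @param references optional two-row reference set (see [assign_clade]).
#' @return data frame with columns `id`, `status`, `aa104`, `aa125`,
#'   `window_prolines`.
#' @export
motif_table <- function(records, references = NULL) {
  if (is.null(references)) {
    references <- rbind(bundled_reference("cx26"), bundled_reference("cx32"))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    clade <- assign_clade(rec, references)
    ref <- references[if (clade == "cx26_like") 1L else 2L, , drop = FALSE]
    m <- scan_motif(rec, align_to_reference(rec, ref),
                    reference_anchors(clade))
    data.frame(id = rec$id, status = m$status, aa104 = m$residue_at_104,
               aa125 = m$residue_at_125,
               window_prolines = paste(m$window_prolines, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
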