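#' Profile the C-terminal tail of a query connexin
#'
#' The tail is everything past the query column homologous to the reference
#' tail boundary (the final residue of the frozen human Cx26 reference, or
#' the equivalent column of the Cx32 reference). When the boundary itself
#' sits opposite a gap, the nearest mapped reference position before it is
#' used, so truncated queries get a tail of length 0 rather than an error.
#'
#' Length class: `short` when `tail_length <= short_threshold` (amniote Cx26
#' tails are "a few amino acids"); `extended` otherwise. An extended tail is
#' `restricted` when it carries at least `min_prolines` prolines — the
#' conformational restriction that lets the long-tailed Cx32 hemichannel
#' still open to CO2. Two introduced prolines sufficed for gain of function
#' experimentally, hence the default `min_prolines = 2`; no spacing
#' requirement is imposed.
#'
#' @inheritParams scan_motif
#' @param short_threshold maximum residue count for a `short` tail.
#' @param min_prolines prolines needed for an extended tail to count as
#'   restricted.
#' @return an object of class `cx_tail`: `tail_start_query_pos`,
#'   `tail_length`, `tail_seq`, `proline_positions` (query coordinates),
#'   `length_class`, `restricted`.
#' @export
profile_tail <- function(query, pmap, anchors, short_threshold = 15,
                         min_prolines = 2) {
  stopifnot(inherits(pmap, "cx_posmap"), inherits(anchors, "cx_anchors"))
  res <- .one_record(query)$residues
  qlen <- nchar(res)
  boundary_q <- .boundary_query_pos(pmap, anchors$tail_boundary)
  tail_start <- boundary_q + 1L
  tail_seq <- if (tail_start > qlen) "" else substr(res, tail_start, qlen)
  tail_length <- nchar(tail_seq)
  pro_rel <- gregexpr("P", tail_seq, fixed = TRUE)[[1]]
  pro_pos <- if (tail_length > 0L && pro_rel[1L] != -1L) {
    as.integer(pro_rel) + tail_start - 1L
  } else integer(0)
  length_class <- if (tail_length <= short_threshold) "short" else "extended"
  out <- list(tail_start_query_pos = tail_start, tail_length = tail_length,
              tail_seq = tail_seq, proline_positions = pro_pos,
              length_class = length_class,
              restricted = length_class == "extended" &&
                length(pro_pos) >= min_prolines)
  class(out) <- "cx_tail"
  out
}

# query position of the last reference residue at/before the boundary that is
# actually aligned; 0 if none is (degenerate alignment => whole query is tail)
.boundary_query_pos <- function(pmap, boundary) {
  p <- pmap$pairs
  ok <- !is.na(p$ref_pos) & p$ref_pos <= boundary & !is.na(p$query_pos)
  if (!any(ok)) return(0L)
  max(p$query_pos[ok])
}

#' @export
print.cx_tail <- function(x, ...) {
  cat(sprintf("<cx_tail> %s, %d aa from %d%s%s\n", x$length_class,
              x$tail_length, x$tail_start_query_pos,
              if (length(x$proline_positions)) {
                paste0(", prolines at ",
                       paste(x$proline_positions, collapse = ","))
              } else "",
              if (x$restricted) " [restricted]" else ""))
  invisible(x)
}

#' Apply point substitutions to a sequence record
#'
#' Mirrors stepwise mutagenesis: each edit states the expected residue, and a
#' mismatch between the stated and the actual residue is an error naming the
#' position. The record id is suffixed with the edit string (e.g.
#' `"_P228G+P229G"`).
#'
#' @param record a one-row [cx_records].
#' @param edits a data frame with columns `position`, `from`, `to` (1-based
#'   positions, single amino-acid letters).
#' @return a new one-row [cx_records].
#' @export
apply_substitutions <- function(record, edits) {
  stopifnot(is.data.frame(edits),
            all(c("position", "from", "to") %in% names(edits)))
  res <- record$residues[1L]
  for (i in seq_len(nrow(edits))) {
    pos <- as.integer(edits$position[i])
    if (pos < 1L || pos > nchar(res)) {
      stop("edit position ", pos, " outside sequence (length ", nchar(res),
           ")", call. = FALSE)
    }
    actual <- substr(res, pos, pos)
    if (actual != edits$from[i]) {
      stop("edit at position ", pos, ": expected ", edits$from[i],
           ", found ", actual, call. = FALSE)
    }
    substr(res, pos, pos) <- edits$to[i]
  }
  suffix <- paste0(edits$from, edits$position, edits$to, collapse = "+")
  cx_records(id = paste0(record$id[1L], "_", suffix), residues = res,
             species = record$species[1L], gene_label = record$gene_label[1L],
             clade_hint = record$clade_hint[1L])
}

#' Tail profiles for a collection, as a table
#'
#' @inheritParams motif_table
#' @param short_threshold,min_prolines passed to [profile_tail].
#' @return data frame with one row per record.
#' @export
tail_table <- function(records, references = NULL, short_threshold = 15,
                       min_prolines = 2) {
  if (is.null(references)) {
    references <- rbind(bundled_reference("cx26"), bundled_reference("cx32"))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    clade <- assign_clade(rec, references)
    ref <- references[if (clade == "cx26_like") 1L else 2L, , drop = FALSE]
    tl <- profile_tail(rec, align_to_reference(rec, ref),
                       reference_anchors(clade), short_threshold, min_prolines)
    data.frame(id = rec$id, tail_start = tl$tail_start_query_pos,
               tail_length = tl$tail_length, length_class = tl$length_class,
               n_prolines = length(tl$proline_positions),
               proline_positions = paste(tl$proline_positions, collapse = ","),
               restricted = tl$restricted, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
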