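#' Reference anchors for the carbamylation motif and tail boundary
#'
#' Positions are in the coordinates of the bundled reference for the given
#' clade. Both bundled references share the same anchor coordinates by
#' construction: lysine 125, arginine 104, the proline-restriction window at
#' 123-124, and the cytoplasmic tail boundary at 226 (the final residue of
#' the human Cx26 reference; for the Cx32 reference, the column homologous to
#' it under the frozen reference-pair alignment).
#'
#' @param clade `"cx26_like"` or `"cx32"`.
#' @return an object of class `cx_anchors`.
#' @export
reference_anchors <- function(clade = c("cx26_like", "cx32")) {
  clade <- match.arg(clade)
  a <- list(clade = clade,
            reference_id = if (clade == "cx26_like") "hCx26" else "hCx32syn",
            lysine_site = 125L,
            arginine_site = 104L,
            proline_block_window = c(123L, 124L),
            tail_boundary = 226L)
  stopifnot(a$lysine_site > a$arginine_site)
  class(a) <- "cx_anchors"
  a
}

.load_blosum <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Align a query connexin to a reference and map residue numbering
#'
#' Pairwise alignment with affine gap penalties under a standard substitution
#' matrix. The default mode is semi-global on the reference side: the
#' reference is aligned end-to-end while query overhangs (in particular a
#' long C-terminal tail) are free, so an extended tail cannot be penalised
#' into a misalignment. `type = "global"` gives ordinary end-to-end
#' Needleman-Wunsch for both sequences.
#'
#' A gap of length L costs `gap_open + L * gap_extend` (the convention of the
#' underlying aligner).
#'
#' @param query,reference one-row [cx_records] data frames (or objects
#'   coercible via their `residues` column).
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @param matrix name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param type `"semiglobal"` (reference global, query ends free; default) or
#'   `"global"`.
#' @return an object of class `cx_posmap`: reference/query ids, the aligned
#'   column table `pairs` (`ref_pos`, `ref_aa`, `query_pos`, `query_aa`, with
#'   `NA` positions at gaps), the alignment `score`, and sequence lengths.
#' @export
align_to_reference <- function(query, reference,
                               gap_open = 10, gap_extend = 1,
                               matrix = "BLOSUM62",
                               type = c("semiglobal", "global")) {
  type <- match.arg(type)
  qres <- .one_record(query)
  rres <- .one_record(reference)
  for (r in list(qres, rres)) {
    if (!nzchar(gsub("X", "", r$residues))) {
      stop("uninformative sequence (only X): ", r$id, call. = FALSE)
    }
  }
  mat <- .load_blosum(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rres$residues), Biostrings::AAString(qres$residues),
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend,
    type = if (type == "semiglobal") "global-local" else "global")
  pal <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sal <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qoff <- Biostrings::start(Biostrings::subject(aln)) - 1L
  rp <- 0L
  qp <- qoff
  n <- length(pal)
  ref_pos <- integer(n); query_pos <- integer(n)
  for (i in seq_len(n)) {
    if (pal[i] != "-") rp <- rp + 1L
    if (sal[i] != "-") qp <- qp + 1L
    ref_pos[i] <- if (pal[i] == "-") NA_integer_ else rp
    query_pos[i] <- if (sal[i] == "-") NA_integer_ else qp
  }
  pairs <- data.frame(ref_pos = ref_pos, ref_aa = ifelse(pal == "-", NA, pal),
                      query_pos = query_pos,
                      query_aa = ifelse(sal == "-", NA, sal),
                      stringsAsFactors = FALSE)
  out <- list(reference_id = rres$id, query_id = qres$id, pairs = pairs,
              score = Biostrings::score(aln), type = type,
              ref_length = nchar(rres$residues),
              query_length = nchar(qres$residues))
  class(out) <- "cx_posmap"
  out
}

.one_record <- function(x) {
  if (inherits(x, "cx_records") || is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single sequence record", call. = FALSE)
    return(list(id = x$id[1L], residues = x$residues[1L]))
  }
  if (is.character(x) && length(x) == 1L) {
    return(list(id = "query", residues = toupper(x)))
  }
  stop("cannot interpret sequence record", call. = FALSE)
}

#' Map a reference residue number to query coordinates
#'
#' @param pmap a `cx_posmap` from [align_to_reference].
#' @param ref_pos 1-based reference position.
#' @return the 1-based query position aligned to `ref_pos`, or `NA_integer_`
#'   when the reference position sits opposite a gap ("deleted" in the
#'   query).
#' @export
map_position <- function(pmap, ref_pos) {
  stopifnot(inherits(pmap, "cx_posmap"), length(ref_pos) == 1L)
  if (is.na(ref_pos) || ref_pos < 1L || ref_pos > pmap$ref_length) {
    stop("ref_pos out of range 1..", pmap$ref_length, call. = FALSE)
  }
  hit <- which(!is.na(pmap$pairs$ref_pos) & pmap$pairs$ref_pos == ref_pos)
  if (length(hit) == 0L) return(NA_integer_)  # outside the aligned span
  pmap$pairs$query_pos[hit]
}

#' Assign a query to the Cx26-like or Cx32 clade by reference alignment
#'
#' The query is aligned to both bundled references; the clade of the
#' higher-scoring alignment wins. A `clade_hint` on the record overrides the
#' score comparison. An exact score tie is refused rather than guessed.
#'
#' @inheritParams align_to_reference
#' @param references a two-row [cx_records] with the Cx26 and Cx32
#'   references, in that order (defaults to the bundled pair).
#' @return `"cx26_like"` or `"cx32"`, with the two scores as the
#'   `"scores"` attribute.
#' @export
assign_clade <- function(query, references = NULL, gap_open = 10,
                         gap_extend = 1, matrix = "BLOSUM62") {
  qrec <- .one_record(query)
  hint <- if (is.data.frame(query) && "clade_hint" %in% names(query)) {
    query$clade_hint[1L]
  } else NA_character_
  if (!is.na(hint)) return(hint)
  if (is.null(references)) {
    references <- rbind(bundled_reference("cx26"), bundled_reference("cx32"))
  }
  s26 <- align_to_reference(query, references[1L, , drop = FALSE],
                            gap_open, gap_extend, matrix)$score
  s32 <- align_to_reference(query, references[2L, , drop = FALSE],
                            gap_open, gap_extend, matrix)$score
  if (s26 == s32) {
    stop("ambiguous clade for '", qrec$id, "'; supply clade_hint",
         call. = FALSE)
  }
  out <- if (s26 > s32) "cx26_like" else "cx32"
  attr(out, "scores") <- c(cx26_like = s26, cx32 = s32)
  out
}

#' Alignment dump as a table
#'
#' One row per alignment column: `ref_pos`, `ref_aa`, `query_pos`,
#' `query_aa`. Suitable for writing as TSV.
#'
#' @param pmap a `cx_posmap`.
#' @return a data frame.
#' @export
posmap_as_table <- function(pmap) {
  stopifnot(inherits(pmap, "cx_posmap"))
  pmap$pairs
}

#' @export
print.cx_posmap <- function(x, ...) {
  n_aligned <- sum(!is.na(x$pairs$ref_pos) & !is.na(x$pairs$query_pos))
  cat(sprintf("<cx_posmap> %s -> %s  (%s, score %.1f, %d aligned columns)\n",
              x$reference_id, x$query_id, x$type, x$score, n_aligned))
  invisible(x)
}
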