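# codon sets of the standard genetic code (table 1), stop codons excluded
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

#' Minimum nucleotide substitutions between two amino acids
#'
#' The minimum Hamming distance between any codon of `from_aa` and any codon
#' of `to_aa` under the standard genetic code; stop codons are excluded as
#' intermediates and endpoints. This quantifies mutational fragility: K to R
#' needs only a single base change, which is what makes the
#' motif-destroying K125R substitution so accessible.
#'
#' The witness pair is the lexicographically smallest codon pair achieving
#' the minimum, so results are deterministic.
#'
#' @param from_aa,to_aa single amino-acid letters (standard 20).
#' @return a list: `from_aa`, `to_aa`, `min_substitutions` (0..3),
#'   `witness_pair` (two codons).
#' @export
min_codon_substitutions <- function(from_aa, to_aa) {
  tab <- .codons_by_aa()
  for (aa in c(from_aa, to_aa)) {
    if (!aa %in% names(tab)) {
      stop("not a standard amino acid: '", aa, "'", call. = FALSE)
    }
  }
  best <- 4L
  witness <- c(NA_character_, NA_character_)
  for (c1 in sort(tab[[from_aa]])) {
    for (c2 in sort(tab[[to_aa]])) {
      d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      if (d < best) {
        best <- d
        witness <- c(c1, c2)
      }
    }
  }
  list(from_aa = from_aa, to_aa = to_aa, min_substitutions = best,
       witness_pair = witness)
}

#' Full 20 x 20 minimum-substitution matrix
#'
#' @return an integer matrix with amino-acid letters as dimnames; symmetric,
#'   zero diagonal, entries in 0..3.
#' @export
codon_distance_matrix <- function() {
  aas <- sort(names(.codons_by_aa()))
  m <- matrix(0L, length(aas), length(aas), dimnames = list(aas, aas))
  for (i in seq_along(aas)) {
    for (j in seq_along(aas)) {
      if (j < i) {
        m[i, j] <- m[j, i]
      } else if (j > i) {
        m[i, j] <- min_codon_substitutions(aas[i], aas[j])$min_substitutions
      }
    }
  }
  m
}

#' Mutational fragility of the carbamylation-motif sites
#'
#' For each motif site (the required lysine and arginine), the minimum codon
#' distance from the required residue to every other amino acid, flagging the
#' residues reachable in a single base change ("fragile neighbours"). The
#' persistence of the motif over hundreds of millions of years despite such
#' one-step escape routes is the signature of selection.
#'
#' @param anchors a `cx_anchors` object (default Cx26-like numbering).
#' @return a data frame: `site`, `required_aa`, `to_aa`, `min_substitutions`,
#'   `fragile_neighbor`.
#' @export
motif_fragility_report <- function(anchors = reference_anchors("cx26_like")) {
  sites <- data.frame(site = c(anchors$lysine_site, anchors$arginine_site),
                      required_aa = c("K", "R"), stringsAsFactors = FALSE)
  m <- codon_distance_matrix()
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    req <- sites$required_aa[i]
    data.frame(site = sites$site[i], required_aa = req,
               to_aa = colnames(m), min_substitutions = m[req, ],
               fragile_neighbor = m[req, ] == 1L,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
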