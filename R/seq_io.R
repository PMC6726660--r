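#' @importFrom utils read.delim write.table data
NULL

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALPHABET <- c(.AA_LETTERS, "X")

#' Construct a collection of connexin sequence records
#'
#' A `cx_records` object is a plain data frame with one row per protein
#' sequence and columns `id`, `species`, `gene_label`, `residues` and
#' `clade_hint`. Residue strings are 1-based throughout the package, matching
#' the conventional human Cx26 numbering (K125, R104, ...).
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of amino-acid strings (standard 20-letter
#'   alphabet plus `X`).
#' @param species,gene_label optional annotation columns.
#' @param clade_hint optional per-record clade override, one of
#'   `"cx26_like"`, `"cx32"` or `NA` (unknown).
#' @return a data frame of class `cx_records`.
#' @export
cx_records <- function(id, residues, species = "", gene_label = "",
                       clade_hint = NA_character_) {
  stopifnot(length(id) == length(residues))
  x <- data.frame(id = as.character(id),
                  species = rep_len(as.character(species), length(id)),
                  gene_label = rep_len(as.character(gene_label), length(id)),
                  residues = toupper(as.character(residues)),
                  clade_hint = rep_len(as.character(clade_hint), length(id)),
                  stringsAsFactors = FALSE)
  validate_cx_records(x)
  class(x) <- c("cx_records", "data.frame")
  x
}

validate_cx_records <- function(x) {
  if (nrow(x) == 0L) stop("no sequences", call. = FALSE)
  if (anyDuplicated(x$id)) {
    stop("duplicate sequence id: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    res <- x$residues[i]
    if (!nzchar(res)) stop("record '", x$id[i], "': empty sequence", call. = FALSE)
    letters_i <- strsplit(res, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(letters_i), .AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("record '", x$id[i], "': non-amino-acid character '", bad[1L], "'",
           call. = FALSE)
    }
  }
  hint <- x$clade_hint
  ok <- is.na(hint) | hint %in% c("cx26_like", "cx32")
  if (!all(ok)) stop("clade_hint must be 'cx26_like', 'cx32' or NA", call. = FALSE)
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Headers of the form `id|species|gene_label` are split into the three
#' annotation fields; any other header is kept whole as the record id (the
#' accessions used in the field are bare ids).
#'
#' @param path path to a protein FASTA file.
#' @return a [cx_records] data frame, in file order.
#' @export
read_cx_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read without alphabet restriction so invalid residues are reported by
  # our own validator (naming record and symbol) instead of silently dropped
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("no sequences", call. = FALSE))
  if (length(set) == 0L) stop("no sequences", call. = FALSE)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1L)
  species <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
  gene <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", "")
  cx_records(id = trimws(id), residues = as.character(set),
             species = trimws(species), gene_label = trimws(gene))
}

#' Write sequence records to FASTA
#'
#' Records whose `species` or `gene_label` is non-empty get a pipe-delimited
#' three-field header; bare ids otherwise. 60-column wrapping.
#'
#' @param x a [cx_records] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_fasta <- function(x, path) {
  validate_cx_records(x)
  headers <- ifelse(nzchar(x$species) | nzchar(x$gene_label),
                    paste(x$id, x$species, x$gene_label, sep = "|"),
                    x$id)
  set <- Biostrings::AAStringSet(x$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' Wraps [ape::read.tree] with the validation the pipeline needs: named,
#' unique tip labels and a rooted topology (basal bifurcation or trifurcation
#' both accepted). On a parse failure the error reports the character offset
#' of the first structural problem found by a bracket scan.
#'
#' @param path path to a newick file.
#' @return an [ape::phylo] tree.
#' @export
read_cx_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                   error = function(e) NULL)
  if (is.null(tree)) {
    stop("unparseable newick at character offset ", .newick_offset(txt),
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tree) && .basal_degree(tree) > 3L) {
    stop("tree is not rooted (basal polytomy of degree > 3)", call. = FALSE)
  }
  tree
}

# first offset at which the bracket balance goes negative, or where an
# unclosed bracket / missing ';' is detected
.newick_offset <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  length(chars)
}

.basal_degree <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  sum(tree$edge[, 1L] == root)
}

#' Read / write a binary trait table
#'
#' Trait tables are TSV files with a `taxon<TAB>trait<TAB>state` header and
#' states in `{0, 1, ?}`; `?` marks a tip whose state could not be annotated.
#'
#' @param path path to a TSV file.
#' @return a data frame with columns `taxon`, `trait`, `state` (character).
#' @export
read_trait_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  required <- c("taxon", "trait", "state")
  if (!all(required %in% names(x))) {
    stop("trait table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, required]
  bad <- setdiff(unique(x$state), c("0", "1", "?"))
  if (length(bad) > 0L) stop("invalid trait state: ", bad[1L], call. = FALSE)
  dup <- duplicated(x[, c("taxon", "trait")])
  if (any(dup)) stop("duplicate taxon/trait pair: ", x$taxon[dup][1L], call. = FALSE)
  x
}

#' @rdname read_trait_table
#' @param x a trait data frame as returned by `read_trait_table`.
#' @export
write_trait_table <- function(x, path) {
  write.table(x[, c("taxon", "trait", "state")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled reference sequences
#'
#' The package ships two frozen reference proteins that all coordinate logic
#' keys off: human Cx26 (GJB2, 226 residues, the numbering in which the
#' carbamylation motif is conventionally given: Lys125, Arg104, window
#' 123-124) and a human Cx32 composite. The Cx32 record is a synthetic
#' composite (see the package vignette): it was assembled so that every
#' literature-named coordinate — the cytoplasmic tail boundary and the tail
#' prolines at 228, 229, 242 and 268 — sits at its published position, and so
#' that the carbamylation-motif homologs align to the same coordinates as in
#' Cx26. It is not a verbatim database record, and its FASTA filename says so.
#'
#' @param which `"cx26"` or `"cx32"`.
#' @return a one-row [cx_records] data frame.
#' @export
bundled_reference <- function(which = c("cx26", "cx32")) {
  which <- match.arg(which)
  file <- switch(which,
                 cx26 = "reference_cx26_human.fasta",
                 cx32 = "reference_cx32_human_synthetic.fasta")
  read_cx_fasta(cx_extdata(file))
}

#' Path to a bundled data file
#' @param file file name under the package's `extdata` directory.
#' @return absolute path.
#' @export
cx_extdata <- function(file) {
  p <- system.file("extdata", file, package = "connexinCO2", mustWork = FALSE)
  if (!nzchar(p)) stop("no bundled file '", file, "'", call. = FALSE)
  p
}

#' Curated beta-connexin sequence set
#'
#' Bookkeeping table for the curated set of beta-connexin family members used
#' throughout the package examples: 53 sequences from 24 vertebrate species,
#' annotated with clade (A = Cx26-like, B = Cx32), carbamylation-motif state
#' and C-terminal tail class. Accessions printed in the study's methods are
#' carried verbatim; all other rows are figure-derived annotations
#' (`source = "figure"`) reconstructed from the published tree's colour
#' coding, and are replaceable by the user.
#'
#' @return a data frame, one row per curated sequence.
#' @export
curated_set <- function() {
  read.delim(cx_extdata("curated_set.tsv"), sep = "\t",
             colClasses = "character")
}
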