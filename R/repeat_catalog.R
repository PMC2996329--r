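## Repeat catalog: an ordered, validated collection of annotated repeat
## elements (id, family, chromosome, 0-based half-open interval, strand) with
## their nucleotide sequences and a free-text provenance trail.

#' Classify a repeat element family from its identifier
#'
#' Yeast repeat identifiers encode the family (`YCRWTy1-2`, `YDRCTy2-1`,
#' `YCRCdelta6`, ...).  This helper maps an identifier to one of the family
#' labels `TY1`, `TY2`, `LTR`, `OTHER` and is used when an annotation source
#' (e.g. BED) carries no explicit family column.
#'
#' @param ids Character vector of element identifiers.
#' @return Character vector of family labels, same length as `ids`.
#' @export
#' @examples
#' classify_family(c("YCRWTy1-2", "YCRCdelta6", "YPLWTy2-1", "rDNA"))
classify_family <- function(ids) {
  stopifnot(is.character(ids))
  fam <- rep("OTHER", length(ids))
  fam[grepl("ty2", ids, ignore.case = TRUE)] <- "TY2"
  fam[grepl("ty1", ids, ignore.case = TRUE)] <- "TY1"
  fam[grepl("delta|\\bltr", ids, ignore.case = TRUE)] <- "LTR"
  fam
}

validate_sequences <- function(sequences) {
  bad <- grepl("[^ACGTN]", as.character(sequences))
  if (any(bad)) {
    stop("non-ACGTN character in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(sequences) == 0L)) {
    stop("empty sequence(s): ",
         paste(names(sequences)[Biostrings::width(sequences) == 0L],
               collapse = ", "), call. = FALSE)
  }
  invisible(sequences)
}

#' Construct a repeat catalog
#'
#' The catalog is the central container of the homology pipeline.  Coordinates
#' are stored 0-based half-open; minus-strand elements are expected to carry
#' the element's own 5'->3' sequence.  Elements are kept in a deterministic
#' order (chromosome, start, element_id) so that matrices and rankings are
#' reproducible across runs.
#'
#' @param elements `data.frame` with columns `element_id`, `family` (one of
#'   `TY1`, `TY2`, `LTR`, `OTHER`), `chromosome`, `start`, `end` (0-based
#'   half-open; may be `NA` in sequence-only mode), `strand` (`"+"`/`"-"`).
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) with one entry per `element_id`.
#' @param provenance Character vector recording source files and applied
#'   corrections.
#' @return An object of class `repeat_catalog`: a list with components
#'   `elements`, `sequences` and `provenance`.
#' @export
repeat_catalog <- function(elements, sequences, provenance = character()) {
  stopifnot(is.data.frame(elements))
  required <- c("element_id", "family", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(required, names(elements))
  if (length(missing_cols)) {
    stop("elements is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  elements <- as.data.frame(elements)[required]
  elements$element_id <- as.character(elements$element_id)
  elements$family <- as.character(elements$family)
  elements$chromosome <- as.character(elements$chromosome)
  elements$strand <- as.character(elements$strand)
  if (anyDuplicated(elements$element_id)) {
    stop("duplicate element_id(s): ",
         paste(unique(elements$element_id[duplicated(elements$element_id)]),
               collapse = ", "))
  }
  if (!all(elements$family %in% FAMILY_LEVELS)) {
    stop("family must be one of ", paste(FAMILY_LEVELS, collapse = ", "))
  }
  if (!all(elements$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (is.null(names(sequences))) stop("sequences must be named by element_id")
  missing_seq <- setdiff(elements$element_id, names(sequences))
  if (length(missing_seq)) {
    stop("no sequence for element(s): ", paste(missing_seq, collapse = ", "))
  }
  sequences <- sequences[elements$element_id]
  validate_sequences(sequences)
  has_coord <- !is.na(elements$start) & !is.na(elements$end)
  if (any(has_coord & elements$end <= elements$start)) {
    stop("end must be > start (0-based half-open) for: ",
         paste(elements$element_id[has_coord & elements$end <= elements$start],
               collapse = ", "))
  }
  len_mismatch <- has_coord &
    (elements$end - elements$start) != Biostrings::width(sequences)
  if (any(len_mismatch)) {
    stop("coordinate span does not equal sequence length for: ",
         paste(elements$element_id[len_mismatch], collapse = ", "))
  }
  ord <- order(elements$chromosome, elements$start, elements$element_id,
               method = "radix")
  elements <- elements[ord, , drop = FALSE]
  rownames(elements) <- NULL
  structure(
    list(elements = elements,
         sequences = sequences[elements$element_id],
         provenance = as.character(provenance)),
    class = "repeat_catalog")
}

#' @export
print.repeat_catalog <- function(x, ...) {
  fam <- table(factor(x$elements$family, levels = FAMILY_LEVELS))
  cat("repeat_catalog with", nrow(x$elements), "elements (",
      paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), ")\n")
  if (length(x$provenance)) {
    cat("provenance:\n")
    cat(paste0("  ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.repeat_catalog <- function(x) nrow(x$elements)

#' Retrieve an element sequence as a character string
#' @param catalog A `repeat_catalog`.
#' @param element_id Element identifier.
#' @return Upper-case nucleotide string.
#' @export
catalog_sequence <- function(catalog, element_id) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  if (!element_id %in% names(catalog$sequences)) {
    stop("unknown element_id: ", element_id)
  }
  as.character(catalog$sequences[[element_id]])
}

#' Load a repeat catalog from FASTA plus an annotation file
#'
#' Coordinates are converted to the internal 0-based half-open convention at
#' the I/O boundary: BED is already 0-based half-open, GFF3 is 1-based
#' inclusive.  In strict mode every FASTA record must be annotated and every
#' annotation record must have a FASTA sequence; mismatches are hard errors
#' naming the offending identifiers.
#'
#' @param fasta_source Path to a FASTA file of element sequences, named by
#'   element id (first whitespace-separated token of the header).
#' @param annotation_source Optional path to a BED (6 columns) or GFF3 file.
#'   `NULL` selects sequence-only mode (coordinates absent, family inferred
#'   from ids via [classify_family()]).
#' @param dialect `"bed"` or `"gff3"`.
#' @param fasta_strand Either `"element"` (default; FASTA records are the
#'   element's own 5'->3' sequence, as deposited repeat sequences usually are)
#'   or `"reference"` (records follow the reference strand; minus-strand
#'   elements are reverse complemented on load so the catalog always stores
#'   element-oriented sequences).
#' @param strict If `TRUE` (default), require a 1:1 match between FASTA and
#'   annotation ids.
#' @return A [repeat_catalog()].
#' @export
load_catalog <- function(fasta_source, annotation_source = NULL,
                         dialect = c("bed", "gff3"),
                         fasta_strand = c("element", "reference"),
                         strict = TRUE) {
  dialect <- match.arg(dialect)
  fasta_strand <- match.arg(fasta_strand)
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  provenance <- paste0("loaded FASTA ", fasta_source, " (", length(seqs),
                       " records)")

  if (is.null(annotation_source)) {
    elements <- data.frame(
      element_id = names(seqs),
      family = classify_family(names(seqs)),
      chromosome = NA_character_,
      start = NA_integer_, end = NA_integer_,
      strand = "+",
      stringsAsFactors = FALSE)
    return(repeat_catalog(elements, seqs,
                          c(provenance, "sequence-only mode (no annotation)")))
  }

  gr <- rtracklayer::import(annotation_source, format = dialect)
  meta <- S4Vectors::mcols(gr)
  ids <- if (dialect == "bed") as.character(meta$name) else {
    if (!"ID" %in% names(meta)) stop("GFF3 attributes must carry ID")
    as.character(meta$ID)
  }
  if (any(is.na(ids) | ids == "")) stop("annotation record without an id")
  family <- if (dialect == "gff3" && "family" %in% names(meta)) {
    as.character(meta$family)
  } else {
    classify_family(ids)
  }
  ann_only <- setdiff(ids, names(seqs))
  if (length(ann_only)) {
    stop("annotation id(s) with no FASTA record: ",
         paste(ann_only, collapse = ", "))
  }
  fasta_only <- setdiff(names(seqs), ids)
  if (strict && length(fasta_only)) {
    stop("FASTA record(s) absent from annotation: ",
         paste(fasta_only, collapse = ", "))
  }
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "+"
  elements <- data.frame(
    element_id = ids,
    family = family,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    ## GRanges is 1-based inclusive whatever the on-disk dialect was
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand_chr,
    stringsAsFactors = FALSE)
  seqs <- seqs[ids]
  if (fasta_strand == "reference") {
    minus <- elements$strand == "-"
    if (any(minus)) {
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    }
  }
  repeat_catalog(elements, seqs,
                 c(provenance,
                   paste0("loaded ", dialect, " annotation ",
                          annotation_source, " (", length(ids), " records)")))
}

#' Write a catalog back to FASTA + BED (+ optional TSV dump)
#'
#' Inverse of [load_catalog()]: a load -> write -> load round trip reproduces
#' the catalog exactly.
#'
#' @param catalog A `repeat_catalog`.
#' @param fasta_path,bed_path,tsv_path Output paths (`NULL` to skip one).
#' @return Invisibly, the catalog.
#' @export
write_catalog <- function(catalog, fasta_path = NULL, bed_path = NULL,
                          tsv_path = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  el <- catalog$elements
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(catalog$sequences, fasta_path, width = 70L)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(el$chromosome, el$start, el$end, el$element_id, 0L,
                      el$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    dump <- data.frame(element_id = el$element_id, family = el$family,
                       chromosome = el$chromosome, start = el$start,
                       end = el$end, strand = el$strand,
                       length = Biostrings::width(catalog$sequences))
    write.table(dump, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(catalog)
}

#' Describe a set of catalog corrections
#'
#' Resequencing of repeat clusters typically adds previously unannotated
#' elements and removes obsolete ones.  Removals are applied before additions.
#'
#' @param additions `NULL`, or a list with `elements` (data.frame as in
#'   [repeat_catalog()]) and `sequences` (named character/DNAStringSet).
#' @param removals Character vector of element ids to drop.
#' @return An object of class `correction_list`.
#' @export
correction_list <- function(additions = NULL, removals = character()) {
  if (!is.null(additions)) {
    stopifnot(is.list(additions), !is.null(additions$elements),
              !is.null(additions$sequences))
  }
  structure(list(additions = additions, removals = as.character(removals)),
            class = "correction_list")
}

#' Apply a correction list to a catalog
#'
#' @param catalog A `repeat_catalog`.
#' @param corrections A [correction_list()].
#' @return The corrected catalog; its provenance records each change and the
#'   element count equals `old - |removals| + |additions|`.
#' @export
apply_corrections <- function(catalog, corrections) {
  stopifnot(inherits(catalog, "repeat_catalog"),
            inherits(corrections, "correction_list"))
  el <- catalog$elements
  seqs <- catalog$sequences
  prov <- catalog$provenance
  missing_rm <- setdiff(corrections$removals, el$element_id)
  if (length(missing_rm)) {
    stop("removal of unknown element id(s): ",
         paste(missing_rm, collapse = ", "))
  }
  if (length(corrections$removals)) {
    keep <- !el$element_id %in% corrections$removals
    el <- el[keep, , drop = FALSE]
    seqs <- seqs[el$element_id]
    prov <- c(prov, paste0("removed: ",
                           paste(corrections$removals, collapse = ", ")))
  }
  if (!is.null(corrections$additions)) {
    add_el <- as.data.frame(corrections$additions$elements)
    add_seq <- corrections$additions$sequences
    if (!methods::is(add_seq, "DNAStringSet")) {
      add_seq <- Biostrings::DNAStringSet(toupper(add_seq))
    }
    clash <- intersect(add_el$element_id, el$element_id)
    if (length(clash)) {
      stop("addition collides with surviving id(s): ",
           paste(clash, collapse = ", "))
    }
    el <- rbind(el, add_el[names(el)])
    seqs <- c(seqs, add_seq[add_el$element_id])
    prov <- c(prov, paste0("added: ",
                           paste(add_el$element_id, collapse = ", ")))
  }
  repeat_catalog(el, seqs, prov)
}

#' Enumerate all unordered element pairs of a (sub-)catalog
#'
#' For `n` selected elements exactly `n * (n - 1) / 2` pairs are returned:
#' no self pairs, each unordered pair once, `id_a < id_b` lexicographically,
#' rows sorted by (`id_a`, `id_b`).
#'
#' @param catalog A `repeat_catalog`.
#' @param families Optional character vector of family labels to select
#'   (e.g. `c("TY1", "TY2")`); `NULL` selects all elements.
#' @return `data.frame` with columns `id_a`, `id_b`.
#' @export
enumerate_pairs <- function(catalog, families = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  ids <- catalog$elements$element_id
  if (!is.null(families)) {
    ids <- ids[catalog$elements$family %in% families]
  }
  ids <- sort(ids, method = "radix")
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  data.frame(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]],
             stringsAsFactors = FALSE)
}
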