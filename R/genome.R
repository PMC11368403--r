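#' Genome assembly: named replicons with sequence and circularity
#'
#' The coordinate frame for every track, interval and annotation in the
#' package. All coordinates in the package are 0-based, half-open; circular
#' replicons allow *windows* to wrap across the origin, but stored intervals
#' never wrap (a wrapping region is represented as two intervals).
#'
#' @param sequences named character vector of IUPAC DNA sequences, one per
#'   replicon. Names must be unique.
#' @param circular logical flag(s), recycled across replicons.
#' @return An object of class `genome_assembly`: a list with elements
#'   `seq` (named upper-case character vector) and `circular` (named logical).
#' @examples
#' asm <- genome_assembly(c(chr = "ACGTACGT", pSmall = "AATT"),
#'                        circular = c(TRUE, TRUE))
#' replicon_lengths(asm)
#' @export
genome_assembly <- function(sequences, circular = FALSE) {
  if (length(sequences) == 0L) stop_fmt("no records: empty assembly")
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop_fmt("every replicon needs a name")
  if (anyDuplicated(names(sequences)))
    stop_fmt("replicon names must be unique")
  seqs <- toupper(as.character(sequences))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad))
    stop_fmt("replicon '%s' contains non-IUPAC characters",
             names(sequences)[bad][1L])
  names(seqs) <- names(sequences)
  circular <- rep_len(as.logical(circular), length(seqs))
  names(circular) <- names(seqs)
  structure(list(seq = seqs, circular = circular),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  len <- replicon_lengths(x)
  cat(sprintf("<genome_assembly> %d replicon(s), %s bp total\n",
              length(len), format(sum(len), big.mark = ",")))
  for (nm in names(len))
    cat(sprintf("  %-12s %9d bp  %s\n", nm, len[[nm]],
                if (x$circular[[nm]]) "circular" else "linear"))
  invisible(x)
}

#' Replicon names and lengths
#' @param assembly a `genome_assembly`.
#' @return `replicon_names()`: character vector; `replicon_lengths()`:
#'   named integer vector of sequence lengths in bp.
#' @export
replicon_lengths <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  vapply(assembly$seq, nchar, integer(1L))
}

#' @rdname replicon_lengths
#' @export
replicon_names <- function(assembly) names(assembly$seq)

#' Read a genome assembly from FASTA
#'
#' Sequence names are the first whitespace-delimited token of each header.
#' FASTA carries no circularity flag, so it is supplied here.
#'
#' @param path path to a FASTA file.
#' @param circular logical, recycled across records.
#' @return a [genome_assembly()].
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop_fmt("malformed FASTA '%s': %s", path,
                             conditionMessage(e)))
  if (length(set) == 0L) stop_fmt("no records in FASTA '%s'", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  genome_assembly(seqs, circular = circular)
}

#' Write a genome assembly to FASTA
#' @param assembly a `genome_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  set <- Biostrings::DNAStringSet(assembly$seq)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Gene annotations
#'
#' A plain data frame of gene features on the assembly, one row per gene,
#' with 0-based half-open coordinates. `tu_id` groups genes into
#' transcriptional units (operon-level units); it may be `NA` for genes
#' without a TU assignment. `is_insertion_sequence` flags IS-element genes.
#'
#' @param gene_id,replicon character vectors.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-".
#' @param is_insertion_sequence logical.
#' @param tu_id character, `NA` permitted.
#' @return a `data.frame` with class `gene_annotations` prepended.
#' @export
gene_annotations <- function(gene_id, replicon, start, end, strand = "+",
                             is_insertion_sequence = FALSE, tu_id = NA_character_) {
  n <- length(gene_id)
  ann <- data.frame(
    gene_id = as.character(gene_id),
    replicon = rep_len(as.character(replicon), n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    is_insertion_sequence = rep_len(as.logical(is_insertion_sequence), n),
    tu_id = rep_len(as.character(tu_id), n),
    stringsAsFactors = FALSE)
  if (any(ann$start < 0L)) stop_fmt("negative start coordinate")
  if (any(ann$start >= ann$end))
    stop_fmt("start >= end for gene '%s'", ann$gene_id[ann$start >= ann$end][1L])
  if (!all(ann$strand %in% c("+", "-")))
    stop_fmt("strand must be '+' or '-'")
  if (anyDuplicated(ann$gene_id)) stop_fmt("duplicated gene_id")
  class(ann) <- c("gene_annotations", class(ann))
  ann
}

#' Check annotations against an assembly
#'
#' Errors if a gene names an unknown replicon or extends past its end.
#' @param ann a `gene_annotations` frame.
#' @param assembly a `genome_assembly`.
#' @return `ann`, invisibly.
#' @export
validate_annotations <- function(ann, assembly) {
  len <- replicon_lengths(assembly)
  unknown <- setdiff(unique(ann$replicon), names(len))
  if (length(unknown))
    stop_fmt("annotation names unknown replicon '%s'", unknown[1L])
  over <- ann$end > len[ann$replicon]
  if (any(over))
    stop_fmt("gene '%s' extends beyond replicon '%s' (%d > %d)",
             ann$gene_id[over][1L], ann$replicon[over][1L],
             ann$end[over][1L], len[[ann$replicon[over][1L]]])
  invisible(ann)
}

#' Read gene annotations from GFF3 or BED6
#'
#' GFF3 is 1-based inclusive and BED 0-based half-open on disk; both are
#' normalized to the package's 0-based half-open convention on read.
#' GFF3 attributes `ID` (or `locus_tag`/`Name`), `tu_id` and `is_is` are
#' honoured; BED6 carries only the name and strand.
#'
#' @param path input path.
#' @param format `"gff3"` or `"bed6"`.
#' @param assembly optional `genome_assembly` for bounds checking.
#' @return a `gene_annotations` data frame.
#' @export
read_annotations <- function(path, format = c("gff3", "bed6"),
                             assembly = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("annotation file not found: %s", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stop_fmt("malformed %s '%s': %s", format, path,
                                 conditionMessage(e)))
  if (length(gr) == 0L) stop_fmt("no records in '%s'", path)
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    keep <- if (!is.null(mc$type)) as.character(mc$type) %in%
      c("gene", "CDS", "mobile_genetic_element") else rep(TRUE, length(gr))
    gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
    if (length(gr) == 0L) stop_fmt("no gene records in '%s'", path)
    ids <- mc$ID %||% mc$locus_tag %||% mc$Name
    if (is.null(ids)) stop_fmt("GFF3 '%s' lacks ID/locus_tag attributes", path)
    tu <- as.character(mc$tu_id %||% rep(NA_character_, length(gr)))
    tu[!is.na(tu) & tu %in% c("NA", "")] <- NA_character_
    is_is <- tolower(as.character(mc$is_is %||% rep("false", length(gr)))) %in%
      c("true", "1", "yes")
  } else {
    ids <- mc$name %||% paste0("feat", seq_along(gr))
    tu <- rep(NA_character_, length(gr))
    is_is <- rep(FALSE, length(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  ann <- gene_annotations(
    gene_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand, is_insertion_sequence = is_is, tu_id = tu)
  if (!is.null(assembly)) validate_annotations(ann, assembly)
  ann
}

#' Write gene annotations to GFF3 or BED6
#' @inheritParams read_annotations
#' @param ann a `gene_annotations` frame.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("gff3", "bed6")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    ann$replicon,
    IRanges::IRanges(ann$start + 1L, ann$end),
    strand = ann$strand)
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- ann$gene_id
    gr$tu_id <- ifelse(is.na(ann$tu_id), "NA", ann$tu_id)
    gr$is_is <- ifelse(ann$is_insertion_sequence, "true", "false")
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- ann$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}
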