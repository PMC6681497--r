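#' Read a FASTA file of nucleotide or protein sequences
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Record
#' identifiers are preserved verbatim, lowercase letters are normalized to
#' uppercase, and IUPAC ambiguity codes are retained.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @param allow_empty Permit a file with zero records (default `FALSE`).
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, type = c("dna", "protein"), allow_empty = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    if (allow_empty) {
      return(if (type == "dna") Biostrings::DNAStringSet()
             else Biostrings::AAStringSet())
    }
    stop("FASTA format error in '", path, "': file is empty (line 1)",
         call. = FALSE)
  }
  if (!startsWith(first, ">"))
    stop("FASTA format error in '", path,
         "': line 1 does not start with '>'", call. = FALSE)
  set <- tryCatch(
    if (type == "dna") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L && !allow_empty)
    stop("FASTA format error in '", path, "': no records", call. = FALSE)
  toupper_set <- if (type == "dna")
    Biostrings::DNAStringSet(toupper(as.character(set)))
  else Biostrings::AAStringSet(toupper(as.character(set)))
  names(toupper_set) <- names(set)
  toupper_set
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `XStringSet`.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

# Flatten annotated copies into a GRanges with parent/child features.
copies_to_granges <- function(copies) {
  rows <- list()
  for (cp in copies) {
    id <- cp$copy_id
    b <- cp$boundaries
    if (is.null(b) || any(is.na(c(b$start, b$end)))) next
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = id, start = b$start, end = b$end, strand = "+",
      type = "mobile_element", ID = paste0(id, ".element"), Parent = NA,
      status = cp$status, architecture = cp$architecture$class,
      role = NA, label = NA, pair_identity = NA, phase = NA_integer_,
      stringsAsFactors = FALSE)
    orfs <- cp$orfs
    if (!is.null(orfs) && nrow(orfs)) {
      for (i in seq_len(nrow(orfs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = id, start = orfs$start[i], end = orfs$end[i],
          strand = orfs$strand[i], type = "CDS",
          ID = paste0(id, ".", orfs$orf_id[i]),
          Parent = paste0(id, ".element"),
          status = NA, architecture = NA, role = orfs$role[i],
          label = NA, pair_identity = NA, phase = 0L,
          stringsAsFactors = FALSE)
      }
    }
    units <- cp$repeat_units
    if (!is.null(units) && nrow(units)) {
      for (i in seq_len(nrow(units))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = id, start = units$start[i], end = units$end[i],
          strand = "+", type = "direct_repeat",
          ID = paste0(id, ".repeat.", units$label[i], ".", i),
          Parent = paste0(id, ".element"),
          status = NA, architecture = NA, role = NA,
          label = units$label[i], pair_identity = units$pair_identity[i],
          phase = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, ID = df$ID, Parent = df$Parent, status = df$status,
    architecture = df$architecture, role = df$role, label = df$label,
    pair_identity = df$pair_identity, phase = df$phase)
  gr
}

#' Write annotated copies as GFF3
#'
#' One `mobile_element` feature per copy with `CDS` (ORF) and
#' `direct_repeat` child features; status and architecture are carried as
#' attributes. Coordinates are 1-based inclusive.
#'
#' @param copies List of annotated copies from [annotate_copy()] or
#'   [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(copies, path) {
  gr <- copies_to_granges(copies)
  if (length(gr) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  keep <- !vapply(S4Vectors::mcols(gr), function(col) all(is.na(col)),
                  logical(1))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a per-dataset summary as TSV
#'
#' @param summary A `genome_summary` data frame from [summarize_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
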