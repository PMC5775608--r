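#' Read genome sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param species_id Species identifier attached to every record; defaults to
#'   the file name without extension.
#' @param n_policy `"reject"` errors on letters outside A/C/G/T/N;
#'   `"coerce"` silently maps them to N.
#'
#' @return A tibble with one row per record: `species_id`, `contig_id`,
#'   `seq` (uppercase), `length`.
#' @export
read_genome_fasta <- function(path, species_id = NULL,
                              n_policy = c("reject", "coerce")) {
  n_policy <- match.arg(n_policy)
  if (!file.exists(path)) stop("read_genome_fasta: no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("read_genome_fasta: malformed FASTA in ", path,
                             ": ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("read_genome_fasta: no records in ", path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("read_genome_fasta: empty record(s): ",
         paste(names(set)[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(bad) > 0L)) {
    if (n_policy == "reject") {
      stop("read_genome_fasta: characters outside {A,C,G,T,N} in record(s) ",
           paste(names(set)[nchar(bad) > 0L], collapse = ", "),
           " (offending: ", paste(unique(strsplit(paste(bad, collapse = ""),
                                                  "")[[1]]), collapse = ""),
           "); use n_policy = \"coerce\" to map them to N")
    }
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1),
                   USE.NAMES = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(
    species_id = species_id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                     basename(path)),
    contig_id = ids,
    seq = unname(seqs),
    length = nchar(seqs)
  )
}

#' Write genome sequences to a FASTA file
#'
#' @param genomes Tibble with `contig_id` and `seq` columns (as produced by
#'   [read_genome_fasta()] or the simulator).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  set <- Biostrings::BStringSet(genomes$seq)
  names(set) <- genomes$contig_id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write and read loci in BED6 format
#'
#' Coordinates are written 0-based half-open, name is the locus id, the score
#' column carries percent identity times ten (capped at 1000), the strand
#' column the locus strand. A written file reads back to the same records.
#'
#' @param loci Tibble with `contig_id`, `start0`, `end0`, `locus_id`,
#'   `identity`, `strand` columns.
#' @param path File path.
#' @param contig_lengths Optional named vector of contig lengths; when
#'   given, intervals exceeding their contig raise an error.
#' @return `path` (write) or a loci tibble (read).
#' @export
write_bed <- function(loci, path, contig_lengths = NULL) {
  if (nrow(loci)) {
    if (any(loci$start0 < 0L) || any(loci$end0 <= loci$start0)) {
      stop("write_bed: invalid interval(s)")
    }
    if (!is.null(contig_lengths)) {
      lim <- contig_lengths[loci$contig_id]
      if (any(is.na(lim)) || any(loci$end0 > lim)) {
        stop("write_bed: interval exceeds contig length")
      }
    }
  }
  df <- data.frame(
    chrom = loci$contig_id,
    start = as.integer(loci$start0),
    end = as.integer(loci$end0),
    name = loci$locus_id,
    score = as.integer(pmin(round(loci$identity * 1000), 1000L)),
    strand = loci$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble::tibble(contig_id = character(), start0 = integer(),
                          end0 = integer(), locus_id = character(),
                          identity = numeric(), strand = character()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character"))
  tibble::tibble(contig_id = df$chrom, start0 = df$start, end0 = df$end,
                 locus_id = df$name, identity = df$score / 1000,
                 strand = df$strand)
}
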