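# Required columns of the gene-table TSV, in canonical order.
GENE_TABLE_COLUMNS <- c(
  "genome_id", "species_id", "circular", "length_bp", "gene_id", "family_id",
  "strand", "start", "end", "cog_id", "cog_category", "is_transposase"
)

#' Construct a genome record
#'
#' A genome record holds one circular (or linear) replicon and its ordered
#' gene annotation. Coordinates are 1-based inclusive on the forward strand;
#' genes wrapping the circular origin (`end < start`) are rejected.
#'
#' @param genome_id,species_id Identifier strings.
#' @param circular Logical; whether the chromosome is circular.
#' @param length_bp Chromosome length in base pairs.
#' @param genes A `data.frame` with columns `gene_id`, `family_id`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `cog_id`, `cog_category`,
#'   `is_transposase`. Sorted by `start` on construction.
#' @param sequence Optional nucleotide string of length `length_bp`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, species_id, circular, length_bp, genes,
                          sequence = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  needed <- setdiff(GENE_TABLE_COLUMNS, c("genome_id", "species_id",
                                          "circular", "length_bp"))
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0)
    stop("gene table missing column(s): ", paste(missing, collapse = ", "))
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("invalid strand for gene(s): ",
         paste(genes$gene_id[bad_strand], collapse = ", "),
         " (must be '+' or '-')")
  bad_coord <- genes$end < genes$start | genes$start < 1
  if (any(bad_coord))
    stop("invalid coordinates (end < start or start < 1) for gene(s): ",
         paste(genes$gene_id[bad_coord], collapse = ", "),
         "; genes wrapping the circular origin are not supported")
  genes <- genes[order(genes$start, genes$end, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  if (!is.null(sequence) && nchar(sequence) != length_bp)
    stop("sequence length (", nchar(sequence), ") does not match length_bp (",
         length_bp, ") for genome ", genome_id)
  structure(
    list(genome_id = as.character(genome_id),
         species_id = as.character(species_id),
         circular = isTRUE(circular) || identical(circular, "TRUE") ||
           identical(circular, "true") || identical(circular, 1L),
         length_bp = as.numeric(length_bp),
         genes = genes,
         sequence = sequence),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, " (", x$species_id, "): ",
      nrow(x$genes), " genes, ", x$length_bp, " bp, ",
      if (x$circular) "circular" else "linear",
      if (!is.null(x$sequence)) ", sequence attached" else "", "\n", sep = "")
  invisible(x)
}

#' Bundle genome records of one species
#'
#' @param genomes List of [genome_record()] objects sharing a `species_id`.
#' @param alignment Optional core-genome alignment (see [read_alignment()]).
#' @return An object of class `species_set`.
#' @export
species_set <- function(genomes, alignment = NULL) {
  if (length(genomes) < 1) stop("species_set needs at least one genome")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate genome_id: ", ids[duplicated(ids)][1])
  sp <- unique(vapply(genomes, function(g) g$species_id, character(1)))
  if (length(sp) != 1)
    stop("genomes belong to more than one species: ",
         paste(sp, collapse = ", "))
  names(genomes) <- ids
  structure(list(species_id = sp, genomes = genomes, alignment = alignment),
            class = "species_set")
}

#' Read a gene-table TSV into genome records
#'
#' The table has one row per gene and the columns
#' `genome_id, species_id, circular, length_bp, gene_id, family_id, strand,
#' start, end, cog_id, cog_category, is_transposase`. Coordinates are 1-based
#' inclusive. An empty `family_id` marks an unclustered gene; an empty
#' `cog_id`/`cog_category` marks an unannotated gene.
#'
#' @param path Path to a TSV file with a header line.
#' @return A list of [genome_record()], one per `genome_id`, genes sorted by
#'   `start`.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE)
  missing <- setdiff(GENE_TABLE_COLUMNS, names(tab))
  if (length(missing) > 0)
    stop("gene table ", path, " missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0) return(list())
  tab$start <- suppressWarnings(as.numeric(tab$start))
  tab$end <- suppressWarnings(as.numeric(tab$end))
  bad <- which(is.na(tab$start) | is.na(tab$end))
  if (length(bad) > 0)
    stop("non-numeric coordinates at data line(s): ",
         paste(bad, collapse = ", "), " of ", path)
  bad <- which(tab$end < tab$start | tab$start < 1)
  if (length(bad) > 0)
    stop("end < start (or start < 1) at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, " (gene ",
         paste(tab$gene_id[bad], collapse = ", "), ")")
  bad <- which(!tab$strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("invalid strand at data line(s) ", paste(bad, collapse = ", "),
         " of ", path, " (gene ", paste(tab$gene_id[bad], collapse = ", "),
         "); strand must be '+' or '-'")
  tab$is_transposase <- tab$is_transposase %in% c("TRUE", "true", "1")
  recs <- lapply(split(tab, tab$genome_id), function(g) {
    genome_record(
      genome_id = g$genome_id[1], species_id = g$species_id[1],
      circular = g$circular[1] %in% c("TRUE", "true", "1"),
      length_bp = as.numeric(g$length_bp[1]),
      genes = g[, c("gene_id", "family_id", "strand", "start", "end",
                    "cog_id", "cog_category", "is_transposase")]
    )
  })
  recs[order(names(recs))]
}

#' Write genome records to a gene-table TSV
#'
#' Round-trips exactly through [read_gene_table()].
#'
#' @param records List of [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    g <- r$genes
    data.frame(genome_id = r$genome_id, species_id = r$species_id,
               circular = r$circular, length_bp = r$length_bp,
               gene_id = g$gene_id, family_id = g$family_id,
               strand = g$strand, start = g$start, end = g$end,
               cog_id = g$cog_id, cog_category = g$cog_category,
               is_transposase = g$is_transposase,
               stringsAsFactors = FALSE)
  })
  write_tsv_report(do.call(rbind, rows), path)
}

#' Read a FASTA file into a named vector of sequences
#'
#' The first whitespace-delimited token of each header is the genome id.
#' Sequences are uppercased; non-ACGT characters are preserved and their
#' count stored in the `"n_non_acgt"` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  n_other <- sum(nchar(gsub("[ACGT]", "", seqs)))
  attr(seqs, "n_non_acgt") <- n_other
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a concatenated core-genome alignment
#'
#' @param path FASTA file of equal-length aligned sequences; gaps are `-`.
#' @return Named character vector of class `core_alignment` with attribute
#'   `L` (alignment length in columns).
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  as_alignment(seqs)
}

#' Mark a named set of equal-length sequences as an alignment
#'
#' @param seqs Named character vector, equal lengths.
#' @return `core_alignment` object with attribute `L`.
#' @export
as_alignment <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) stop("sequences have unequal lengths")
  attr(seqs, "L") <- unname(lens[1])
  class(seqs) <- "core_alignment"
  seqs
}

#' Read a square PHYLIP distance matrix
#'
#' Hook for supplying externally computed evolutionary distances in place of
#' alignment substitution counts.
#'
#' @param path PHYLIP square-matrix file (first line: n; then one row per
#'   taxon: id followed by n distances).
#' @return Numeric matrix with dimnames.
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1)
    stop("malformed PHYLIP matrix in ", path)
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(toks) != n + 1)
      stop("row ", i, " of ", path, " has ", length(toks) - 1,
           " values, expected ", n)
    ids[i] <- toks[1]
    m[i, ] <- as.numeric(toks[-1])
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a data frame as a TSV report
#'
#' Deterministic column order, one header line, no quoting; round-trips
#' through `read.delim`.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
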