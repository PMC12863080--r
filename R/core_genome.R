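#' Call the core gene families of a species
#'
#' A family is core when it is present in at least `freq` of the genomes of
#' the species and is single-copy in every genome where it occurs. Families
#' duplicated in any genome are excluded entirely: within-species duplicates
#' are more likely paralogs than positional markers, and a family present
#' twice has no defined place in a gene-order permutation.
#'
#' @param species A [species_set()].
#' @param freq Minimum presence fraction (inclusive, default 0.90).
#' @return Object of class `core_genome`: `species_id`, `core_families`
#'   (sorted character vector), `C` (its length), `freq_threshold`.
#' @export
call_core_families <- function(species, freq = 0.90) {
  stopifnot(inherits(species, "species_set"))
  n <- length(species$genomes)
  if (n < 2) stop("core calling needs at least 2 genomes")
  per_genome <- lapply(species$genomes, function(g) {
    fam <- g$genes$family_id
    fam[nzchar(fam)]
  })
  all_fams <- sort(unique(unlist(per_genome)))
  presence <- vapply(all_fams, function(f)
    sum(vapply(per_genome, function(v) f %in% v, logical(1))), numeric(1))
  duplicated_anywhere <- vapply(all_fams, function(f)
    any(vapply(per_genome, function(v) sum(v == f) > 1, logical(1))),
    logical(1))
  core <- all_fams[presence >= freq * n & !duplicated_anywhere]
  if (length(core) == 0)
    stop("no family passes the core filter (freq = ", freq, ", n = ", n, ")")
  structure(list(species_id = species$species_id,
                 core_families = core,
                 C = length(core),
                 freq_threshold = freq),
            class = "core_genome")
}

#' @export
print.core_genome <- function(x, ...) {
  cat("<core_genome> ", x$species_id, ": C = ", x$C,
      " families at freq >= ", x$freq_threshold, "\n", sep = "")
  invisible(x)
}

#' Project a genome onto its signed circular core-gene permutation
#'
#' Reduces a genome to the ordered list of its core gene families, signed by
#' strand. Accessory (and non-core) genes are skipped but counted per
#' inter-core interval so block gene content can later include them.
#'
#' @param genome A [genome_record()].
#' @param core A `core_genome` from [call_core_families()].
#' @return Object of class `core_order`: `genome_id`, `families`, `signs`
#'   (+1/-1), `positions` (gene midpoints, bp), `interval_extra` (number of
#'   non-core genes between core gene i and the next core gene, circularly),
#'   `circular`, `genome_length`.
#' @export
project_core_order <- function(genome, core) {
  stopifnot(inherits(genome, "genome_record"), inherits(core, "core_genome"))
  g <- genome$genes
  is_core <- g$family_id %in% core$core_families
  if (sum(is_core) < 2)
    stop("genome ", genome$genome_id, " has ", sum(is_core),
         " core families; need at least 2")
  idx <- which(is_core)
  # genes between core i and core i+1 (wrapping to the first core gene)
  n <- length(idx)
  interval_extra <- integer(n)
  for (i in seq_len(n)) {
    lo <- idx[i]
    hi <- if (i < n) idx[i + 1] else idx[1] + nrow(g)
    interval_extra[i] <- (hi - lo - 1L)
  }
  core_order(
    families = g$family_id[idx],
    signs = ifelse(g$strand[idx] == "+", 1L, -1L),
    genome_id = genome$genome_id,
    positions = (g$start[idx] + g$end[idx]) / 2,
    interval_extra = interval_extra,
    circular = genome$circular,
    genome_length = genome$length_bp
  )
}

#' Construct a signed circular core-gene permutation
#'
#' Low-level constructor used by [project_core_order()], the rearrangement
#' simulator and tests.
#'
#' @param families Character (or integer) vector of family identifiers, in
#'   genomic order; each exactly once.
#' @param signs Integer vector of +1/-1, one per family (default all +1).
#' @param genome_id Identifier.
#' @param positions Optional gene midpoints (bp).
#' @param interval_extra Optional non-core gene count per interval.
#' @param circular Logical.
#' @param genome_length Optional chromosome length (bp).
#' @return Object of class `core_order`.
#' @export
core_order <- function(families, signs = rep(1L, length(families)),
                       genome_id = "genome", positions = NULL,
                       interval_extra = NULL, circular = TRUE,
                       genome_length = NULL) {
  families <- as.character(families)
  if (anyDuplicated(families))
    stop("core_order families must be unique; duplicated: ",
         families[duplicated(families)][1])
  if (length(signs) != length(families))
    stop("signs and families lengths differ")
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  if (is.null(interval_extra)) interval_extra <- integer(length(families))
  structure(list(genome_id = genome_id, families = families,
                 signs = as.integer(signs), positions = positions,
                 interval_extra = as.integer(interval_extra),
                 circular = circular, genome_length = genome_length),
            class = "core_order")
}

#' @export
print.core_order <- function(x, ...) {
  cat("<core_order> ", x$genome_id, ": ", length(x$families),
      " core genes, ", if (x$circular) "circular" else "linear", "\n",
      sep = "")
  invisible(x)
}

#' @export
length.core_order <- function(x) length(x$families)
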