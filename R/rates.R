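# Simulation-calibrated conversion of block counts into rearrangement-event
# estimates, substitution counting, and the B_cs rearrangement rate.

#' Simulation parameters for block-count calibration
#'
#' @param C Core genome size (number of single-copy families).
#' @param k_grid Integer vector of event counts to simulate; must include 0
#'   and span at least 4 distinct values for calibration.
#' @param p_inversion Probability that an event is an inversion (else a
#'   translocation).
#' @param seg_len_dist Segment-length law: `list(kind = "uniform", min, max)`
#'   or `list(kind = "geometric", mean)`. Lengths are truncated to
#'   \[2, C - 2\]: a 1-gene segment would be a discarded singleton.
#' @param replicates Replicates per k.
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(C, k_grid = 0:20, p_inversion = 0.5,
                       seg_len_dist = list(kind = "uniform", min = 2,
                                           max = max(2, C %/% 10)),
                       replicates = 100, seed = 1) {
  if (C < 4) stop("C must be at least 4")
  if (any(k_grid < 0)) stop("event counts must be non-negative")
  if (seg_len_dist$kind == "uniform" && seg_len_dist$min < 2)
    stop("minimum segment length is 2")
  structure(list(C = C, k_grid = sort(unique(as.integer(k_grid))),
                 p_inversion = p_inversion, seg_len_dist = seg_len_dist,
                 replicates = replicates, seed = seed),
            class = "sim_params")
}

draw_segment_length <- function(dist, C) {
  lmax <- C - 2
  if (lmax < 2) stop("C = ", C, " too small for any 2-gene segment")
  if (dist$kind == "uniform") {
    lo <- max(2, dist$min); hi <- min(lmax, dist$max)
    if (hi < lo) hi <- lo
    sample(lo:hi, 1)
  } else if (dist$kind == "geometric") {
    repeat {
      l <- 2 + stats::rgeom(1, prob = 1 / max(dist$mean - 1, 1))
      if (l <= lmax) return(l)
    }
  } else stop("unknown segment length distribution: ", dist$kind)
}

# Apply one event to a signed circular permutation given as a list of
# (families, signs). Returns the modified list plus an event descriptor.
apply_event <- function(fams, signs, type, start, len, dest = NA) {
  C <- length(fams)
  idx <- ((start:(start + len - 1)) - 1L) %% C + 1L
  if (type == "inversion") {
    fams[idx] <- fams[rev(idx)]
    signs[idx] <- -signs[rev(idx)]
  } else {
    seg_f <- fams[idx]; seg_s <- signs[idx]
    keep <- setdiff(seq_len(C), idx)
    # rotate the remainder so it starts right after the excised arc
    after <- keep[order((keep - idx[length(idx)] - 1L) %% C)]
    rest_f <- fams[after]; rest_s <- signs[after]
    # insert after position `dest` of the remainder (1..C-len); dest = C-len
    # reinserts at the excision point (disallowed by the caller)
    fams <- append(rest_f, seg_f, after = dest)
    signs <- append(rest_s, seg_s, after = dest)
  }
  list(fams = fams, signs = signs)
}

#' Apply an explicit list of rearrangement events to a core-gene permutation
#'
#' Deterministic event application used for worked examples, tests and the
#' synthetic-species generator. An inversion reverses a contiguous circular
#' arc and flips its signs; a translocation excises an arc and reinserts it,
#' orientation preserved, at another inter-gene adjacency.
#'
#' @param order A [core_order()].
#' @param events List of events, each `list(type = "inversion"|
#'   "translocation", start, len, dest)`: `start` = 1-based index of the
#'   arc's first element in the current permutation, `len` = arc length in
#'   genes, `dest` (translocations) = insertion point, the arc is placed
#'   after element `dest` of the remainder permutation (0 <= dest <= C-len-1,
#'   counted from just after the excision point).
#' @return List with `order` (rearranged `core_order`) and `truth` (the
#'   event list).
#' @export
plant_rearrangements <- function(order, events) {
  fams <- order$families; signs <- order$signs
  for (ev in events) {
    res <- apply_event(fams, signs, ev$type, ev$start, ev$len,
                       dest = if (!is.null(ev$dest)) ev$dest else NA)
    fams <- res$fams; signs <- res$signs
  }
  out <- core_order(fams, signs, genome_id = order$genome_id,
                    circular = order$circular,
                    genome_length = order$genome_length)
  list(order = out, truth = events)
}

#' Simulate k random rearrangement events on a core-gene permutation
#'
#' Events are applied sequentially. Each is an inversion with probability
#' `p_inversion`, else a translocation. Arc start is uniform; arc length is
#' drawn from `params$seg_len_dist` truncated to \[2, C - 2\]; translocation
#' insertion points are uniform over the adjacencies of the remainder,
#' excluding the excision point (which would be a no-op).
#'
#' @param order A [core_order()] (commonly the identity permutation).
#' @param k Number of events (>= 0).
#' @param params A [sim_params()] (only `p_inversion`/`seg_len_dist` used).
#' @return List with `order` and `truth` as in [plant_rearrangements()].
#' @export
simulate_rearrangements <- function(order, k, params) {
  C <- length(order$families)
  if (C < 4) stop("need at least 4 core genes to rearrange")
  events <- vector("list", k)
  if (k > 0) {
    for (i in seq_len(k)) {
      type <- if (stats::runif(1) < params$p_inversion) "inversion" else
        "translocation"
      len <- draw_segment_length(params$seg_len_dist, C)
      start <- sample.int(C, 1)
      dest <- NULL
      if (type == "translocation") {
        # remainder has C - len elements, hence C - len circular adjacencies;
        # adjacency C - len is the excision point itself
        dest <- sample.int(C - len - 1, 1)
      }
      events[[i]] <- list(type = type, start = start, len = len, dest = dest)
    }
  }
  plant_rearrangements(order, events)
}

#' Calibrate the blocks-to-events quadratic model by simulation
#'
#' For each event count k in the grid, random rearrangement histories are
#' simulated on an identity permutation of C core genes and the resulting
#' mean retained-block count is recorded; a quadratic `mean_blocks =
#' a + b k + c k^2` is then fitted. The quadratic captures the saturation of
#' block counts as breakpoints begin to coincide.
#'
#' @param params A [sim_params()].
#' @return Object of class `quadratic_model`: `a`, `b`, `c`, `rmse`, `C`,
#'   `k_grid`, `mean_blocks`, `value_at_zero` (should be about 1: an
#'   unrearranged genome is a single block).
#' @export
calibrate_blocks_to_events <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (length(params$k_grid) < 4 || !(0 %in% params$k_grid))
    stop("k_grid must include 0 and span at least 4 distinct event counts")
  set.seed(params$seed)
  identity <- core_order(sprintf("f%05d", seq_len(params$C)))
  means <- vapply(params$k_grid, function(k) {
    mean(vapply(seq_len(params$replicates), function(r) {
      sim <- simulate_rearrangements(identity, k, params)
      # only the block count matters here; strand-noise classification
      # warnings from overlapping simulated events are irrelevant
      suppressWarnings(find_blocks(identity, sim$order)$n_blocks)
    }, numeric(1)))
  }, numeric(1))
  fit <- fit_quadratic(params$k_grid, means)
  structure(list(a = fit$a, b = fit$b, c = fit$c, rmse = fit$rmse,
                 C = params$C, k_grid = params$k_grid, mean_blocks = means,
                 value_at_zero = fit$a),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("<quadratic_model> blocks = ", signif(x$a, 4), " + ", signif(x$b, 4),
      " k + ", signif(x$c, 4), " k^2  (C = ", x$C, ", RMSE = ",
      signif(x$rmse, 3), ")\n", sep = "")
  invisible(x)
}

#' Predict the number of rearrangement events from an observed block count
#'
#' Inverts the calibrated quadratic: solves `a + b k + c k^2 = B` and takes
#' the smallest non-negative real root (parsimony: the fewest events that
#' explain the blocks). Falls back to the linear solution when the quadratic
#' term is negligible; clamps small negative roots to 0, so a single block
#' (B = 1) maps to 0 events.
#'
#' @param B Observed retained-block count (>= 1; vectorized).
#' @param model A `quadratic_model`.
#' @param tol Threshold below which `|c|` is treated as 0.
#' @return Predicted event count(s) N >= 0.
#' @export
predict_events <- function(B, model, tol = 1e-8) {
  vapply(B, function(bb) {
    if (bb < 1) stop("block counts below 1 are impossible")
    # one block is the unrearranged state by definition, whatever the fit's
    # intercept ended up as
    if (bb == 1) return(0)
    a <- model$a; b <- model$b; cc <- model$c
    if (abs(cc) < tol) return(max(0, (bb - a) / b))
    disc <- b^2 - 4 * cc * (a - bb)
    if (disc < 0) {
      warning("block count ", bb, " outside the calibrated range; ",
              "using linear extrapolation")
      return(max(0, (bb - a) / b))
    }
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * cc))
    nonneg <- roots[roots >= -tol * 100]
    if (length(nonneg) == 0) return(0)
    max(0, nonneg[1])
  }, numeric(1))
}

#' Count pairwise substitutions on a core-genome alignment
#'
#' A substitution is a column where both genomes carry an unambiguous
#' nucleotide (A/C/G/T) and the two differ. Columns with a gap or ambiguity
#' code in either genome are excluded from both the count and the
#' comparable length.
#'
#' @param aln A `core_alignment` (see [read_alignment()]).
#' @param g1,g2 Genome ids present in the alignment.
#' @return List: `S` (substitutions), `L_eff` (comparable columns), `L`
#'   (full alignment length).
#' @export
pairwise_substitutions <- function(aln, g1, g2) {
  for (id in c(g1, g2))
    if (!id %in% names(aln)) stop("genome ", id, " absent from alignment")
  a <- strsplit(toupper(unclass(aln)[[g1]]), "")[[1]]
  b <- strsplit(toupper(unclass(aln)[[g2]]), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  list(S = sum(a[ok] != b[ok]), L_eff = sum(ok), L = length(a))
}

#' The B_cs rearrangement rate
#'
#' B_cs = N / (C * S * L): predicted rearrangement events per substitution,
#' normalized by core genome size (genes) and core alignment length (nt), so
#' rates are comparable between species with different core genomes.
#'
#' @param N Predicted number of rearrangement events.
#' @param C Core genome size (genes).
#' @param S Substitution count between the pair.
#' @param L Core alignment length (nt).
#' @return The rate (0 when N = 0).
#' @export
rearrangement_rate <- function(N, C, S, L) {
  if (C <= 0 || L <= 0) stop("C and L must be positive")
  if (S <= 0)
    stop("S = 0: identical genomes have an undefined rearrangement rate")
  if (N < 0) stop("N must be non-negative")
  N / (as.numeric(C) * as.numeric(S) * as.numeric(L))
}

#' Per-pair rearrangement rates for a species
#'
#' Convenience wrapper: for each partition against the reference, predicts
#' events from the block count, counts substitutions on the alignment, and
#' computes B_cs. Pairs with S = 0 get `NA` with a note.
#'
#' @param partitions List of `block_partition` (query vs reference).
#' @param aln `core_alignment` containing all genomes.
#' @param model `quadratic_model` calibrated for the species' core size.
#' @param C Core genome size.
#' @param distances Optional precomputed distance matrix (e.g. from
#'   [read_phylip_distances()]); when given, `S` is replaced by
#'   `distance * L_eff`.
#' @return Data frame: `ref_id`, `query_id`, `B`, `N`, `C`, `S`, `L`,
#'   `B_cs`.
#' @export
estimate_rates <- function(partitions, aln, model, C, distances = NULL) {
  rows <- lapply(partitions, function(p) {
    if (p$query_id == p$ref_id) return(NULL)
    B <- p$n_blocks
    N <- predict_events(B, model)
    sub <- pairwise_substitutions(aln, p$ref_id, p$query_id)
    S <- if (is.null(distances)) sub$S else
      distances[p$ref_id, p$query_id] * sub$L_eff
    L <- sub$L
    bcs <- if (S > 0) rearrangement_rate(N, C, S, L) else NA_real_
    data.frame(ref_id = p$ref_id, query_id = p$query_id, B = B, N = N,
               C = C, S = S, L = L, B_cs = bcs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
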