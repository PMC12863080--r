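# Ori/Ter localization from cumulative GC skew and replichore-relative
# positioning of rearranged blocks.

#' Compute a windowed cumulative GC-skew profile
#'
#' The genome is cut into consecutive non-overlapping windows; per window
#' the skew S = (G - C)/(G + C) is computed (0 where the window has no G or
#' C) and accumulated. Replication-associated strand mutation bias makes
#' the cumulative curve fall along one replichore and rise along the other,
#' so its global minimum marks the origin of replication (Ori) and its
#' global maximum the terminus (Ter). Window and genome coordinates are
#' 1-based; reported Ori/Ter positions are window midpoints.
#'
#' @param sequence Nucleotide string (circular chromosome).
#' @param window_bp Window size in bp (default 1000).
#' @param genome_id Identifier for reporting.
#' @param prominence_frac,min_sep_frac Passed to [flag_ambiguous()].
#' @return Object of class `skew_profile`: `genome_id`, `window_bp`, `S_w`,
#'   `cumS`, `ori_bp`, `ter_bp`, `seq_length`, `ambiguous`,
#'   `ambiguity_reason`.
#' @export
gc_skew_profile <- function(sequence, window_bp = 1000, genome_id = "genome",
                            prominence_frac = 0.2, min_sep_frac = 0.05) {
  len <- nchar(sequence)
  if (len < 2 * window_bp)
    stop("sequence of ", len, " bp is shorter than two windows of ",
         window_bp, " bp")
  n_win <- len %/% window_bp  # trailing partial window is dropped
  raw <- charToRaw(toupper(sequence))[seq_len(n_win * window_bp)]
  # per-window counts from cumulative sums at window boundaries
  cuts <- seq(0, n_win * window_bp, by = window_bp)
  g <- diff(c(0, cumsum(raw == charToRaw("G")))[cuts + 1])
  c_ <- diff(c(0, cumsum(raw == charToRaw("C")))[cuts + 1])
  tot <- g + c_
  S_w <- ifelse(tot == 0, 0, (g - c_) / pmax(tot, 1))
  cumS <- cumsum(S_w)
  ori_win <- which.min(cumS)
  ter_win <- which.max(cumS)
  mid <- function(w) (w - 1) * window_bp + window_bp / 2
  prof <- structure(list(genome_id = genome_id, window_bp = window_bp,
                         S_w = S_w, cumS = cumS,
                         ori_bp = mid(ori_win), ter_bp = mid(ter_win),
                         seq_length = n_win * window_bp,
                         ambiguous = FALSE, ambiguity_reason = ""),
                    class = "skew_profile")
  prof$ambiguous <- flag_ambiguous(prof, prominence_frac, min_sep_frac)
  prof$ambiguity_reason <- attr(prof$ambiguous, "reason")
  prof$ambiguous <- as.logical(prof$ambiguous)
  prof
}

#' @export
print.skew_profile <- function(x, ...) {
  cat("<skew_profile> ", x$genome_id, ": Ori ", x$ori_bp, " bp, Ter ",
      x$ter_bp, " bp over ", x$seq_length, " bp",
      if (x$ambiguous) paste0(" [AMBIGUOUS: ", x$ambiguity_reason, "]"),
      "\n", sep = "")
  invisible(x)
}

# Prominence of each local minimum of x: the height one must climb from the
# minimum before reaching a strictly lower value (classic peak prominence on
# the negated series). Returns a data.frame(index, value, prominence).
local_min_prominences <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), value = numeric(0),
                               prominence = numeric(0)))
  is_min <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n],
              FALSE)
  is_min[1] <- x[1] < x[2]
  is_min[n] <- x[n] < x[n - 1]
  idx <- which(is_min)
  prom <- vapply(idx, function(i) {
    v <- x[i]
    left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    climb <- function(side) {
      lower <- which(side < v)
      if (length(lower) == 0) return(max(side, v) - v)
      # nearest lower point bounds the climb window
      max(side[seq_len(min(lower) - 1)], v) - v
    }
    # walk outward from the minimum on each side
    lclimb <- climb(rev(left))
    rclimb <- climb(right)
    min(lclimb, rclimb)
  }, numeric(1))
  # edges and one-sided minima: if no lower value exists on a side, the climb
  # on that side is the full rise, handled above
  data.frame(index = idx, value = x[idx], prominence = prom)
}

#' Flag a GC-skew profile as ambiguous
#'
#' Real skew plots can show multiple peaks and valleys that make Ori/Ter
#' unidentifiable; such genomes must be excluded from positional analyses.
#' The profile is flagged when a secondary local minimum (or maximum) of the
#' cumulative skew has prominence at least `prominence_frac` of the total
#' cumulative range and lies at least `min_sep_frac` of the genome away from
#' the global one, or when the curve carries no skew signal at all.
#'
#' @param profile A `skew_profile`.
#' @param prominence_frac Prominence threshold as a fraction of the
#'   cumulative-skew range (default 0.2).
#' @param min_sep_frac Minimum separation from the global extremum as a
#'   fraction of genome length (default 0.05).
#' @return Logical with attribute `reason`.
#' @export
flag_ambiguous <- function(profile, prominence_frac = 0.2,
                           min_sep_frac = 0.05) {
  cumS <- profile$cumS
  rng <- max(cumS) - min(cumS)
  if (rng <= .Machine$double.eps * length(cumS))
    return(structure(TRUE, reason = "flat cumulative skew (no signal)"))
  n <- length(cumS)
  min_sep_win <- min_sep_frac * n
  check <- function(x, global_idx, what) {
    cand <- local_min_prominences(x)
    cand <- cand[cand$index != global_idx, , drop = FALSE]
    sep <- pmin(abs(cand$index - global_idx),
                n - abs(cand$index - global_idx))  # circular separation
    hit <- cand$prominence >= prominence_frac * rng & sep >= min_sep_win
    if (any(hit))
      paste0("secondary ", what, " at window ",
             cand$index[which(hit)[1]], " (prominence ",
             signif(cand$prominence[which(hit)[1]], 3), ")")
    else NULL
  }
  r1 <- check(cumS, which.min(cumS), "minimum")
  if (!is.null(r1)) return(structure(TRUE, reason = r1))
  r2 <- check(-cumS, which.max(cumS), "maximum")
  if (!is.null(r2)) return(structure(TRUE, reason = r2))
  structure(FALSE, reason = "")
}

#' Replichore-relative position of a genomic coordinate
#'
#' The two Ori-to-Ter arcs of a circular chromosome are the replichores.
#' A position is mapped to d in [0, 1]: 0 at Ori, 1 at Ter, proportional to
#' the arc distance along whichever replichore contains it, so d is
#' comparable between the two replichores and across genomes.
#'
#' @param midpoint_bp Coordinate in bp (1-based; vectorized).
#' @param profile An unambiguous `skew_profile` (or any list with `ori_bp`,
#'   `ter_bp`, `seq_length`).
#' @return Numeric vector of distances in \[0, 1\].
#' @export
relative_position <- function(midpoint_bp, profile) {
  G <- profile$seq_length
  if (any(midpoint_bp < 0 | midpoint_bp > G + 1))
    stop("midpoint outside [0, genome length]")
  ori <- profile$ori_bp
  ter <- profile$ter_bp
  arc1 <- (ter - ori) %% G          # replichore 1: Ori -> Ter ascending
  arc2 <- G - arc1                  # replichore 2: the other way round
  off <- (midpoint_bp - ori) %% G
  ifelse(off <= arc1, off / arc1, (G - off) / arc2)
}

#' Test positional bias of rearranged blocks toward Ori or Ter
#'
#' Under neutral placement the replichore-relative distance d of a block
#' midpoint is uniform with mean 0.5. A one-sample Wilcoxon signed-rank test
#' of d against 0.5 (two-sided) detects clustering toward Ori (median < 0.5)
#' or Ter (median > 0.5).
#'
#' @param distances Numeric vector of d values in \[0, 1\] (deduplicated
#'   block midpoints; single-block genomes excluded upstream).
#' @return List: `n`, `median_d`, `W_statistic`, `p_value`, `direction`
#'   (`"Ori"` or `"Ter"`).
#' @export
test_positional_bias <- function(distances) {
  if (length(distances) == 0) stop("no distances to test")
  if (any(distances < 0 | distances > 1))
    stop("distances must lie in [0, 1]")
  res <- wilcoxon_signed_rank(distances, mu = 0.5)
  med <- stats::median(distances)
  list(n = length(distances), median_d = med,
       W_statistic = res$statistic, p_value = res$p_value,
       direction = if (med < 0.5) "Ori" else "Ter")
}
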