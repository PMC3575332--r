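# The Maskov three-pass imputation algorithm.
#
# Pass 1 compresses missing values out of the encoded vector, pass 2
# detects recombination edges by convolving with an antisymmetric
# first-derivative mask, pass 3 fills the blocks between edges by
# winner-take-all and expands back to the original coordinates.

#' Maskov parameter set
#'
#' @param E positive integer, the maximum number of expected consecutive
#'   errors; sets the half-width of the convolution mask (length `2E+1`).
#' @param T positive edge-detection threshold; an edge needs
#'   `|convolved| > T`.  Defaults to `E`.
#' @param max_missing maximum tolerated missing-data fraction for an
#'   individual on a linkage group; above it the individual is passed
#'   through unimputed and flagged.  Default 0.70.
#' @return list of class `maskov_params`.
#' @export
maskov_params <- function(E = 5L, T = E, max_missing = 0.70) {
  E <- as.integer(E)
  if (is.na(E) || E < 1L) stop("E must be a positive integer (E >= 1)")
  if (!is.numeric(T) || T <= 0) stop("T must be positive")
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1)
    stop("max_missing must lie in [0, 1]")
  structure(list(E = E, T = as.numeric(T), max_missing = max_missing),
            class = "maskov_params")
}

#' Build the antisymmetric convolution mask
#'
#' The mask of length `2E+1` is the sign mask `(-1, ..., -1, 0, +1, ...,
#' +1)`, the discrete analogue of a first derivative over a `2E+1` window:
#' on a clean phase transition it scores exactly `2E`, and an isolated
#' cluster of `j` opposing genotypes scores `2j`, so with the default
#' threshold `T = E` clusters up to `floor(E/2)` stay below detection and
#' are corrected by the winner-take-all pass.
#'
#' @param E mask half-width, `E >= 1`.
#' @return integer vector of length `2E+1`; antisymmetric, zero center.
#' @export
build_mask <- function(E) {
  E <- as.integer(E)
  if (is.na(E) || E < 1L) stop("E must be a positive integer (E >= 1)")
  c(rep(-1L, E), 0L, rep(1L, E))
}

#' Remove missing values before edge detection
#'
#' Missing calls carry no recombination information and dilute the
#' convolution signal, so they are taken out first and restored after
#' block filling.
#'
#' @param values integer vector over `{1, 0, -1}`.
#' @return list with `values` (zeros removed) and `map`, the 1-based
#'   original position of each surviving entry (strictly increasing).
#' @export
compress_missing <- function(values) {
  values <- as.integer(values)
  idx <- which(values != 0L)
  list(values = values[idx], map = idx)
}

#' Convolve a compressed genotype vector with the edge mask
#'
#' Computes `sum_k x[i+k] * mask[E+k]` for every interior position
#' (`E` full positions required on both sides); positions with an
#' incomplete window are set to 0, where no edge is detectable.
#'
#' @param values compressed vector over `{1, -1}` (no zeros).
#' @param E mask half-width.
#' @return numeric vector of convolution scores, same length as `values`;
#'   all zero when `length(values) < 2E+1`.
#' @export
convolve_genotypes <- function(values, E) {
  E <- as.integer(E)
  n <- length(values)
  out <- numeric(n)
  if (n >= 2L * E + 1L) {
    S <- c(0, cumsum(values))          # S[i+1] = sum(values[1:i])
    i <- (E + 1L):(n - E)
    right <- S[i + E + 1L] - S[i + 1L] # sum over (i+1)..(i+E)
    left  <- S[i] - S[i - E]           # sum over (i-E)..(i-1)
    out[i] <- right - left
  }
  out
}

#' Detect recombination edges from a convolved vector
#'
#' Positions with `|convolved| > T` mark a phase transition; a contiguous
#' run of above-threshold positions sharing a sign collapses to a single
#' edge, placed between `m` and `m+1` where `m` is the leftmost position
#' attaining the run's maximum absolute score (a clean transition yields a
#' symmetric two-wide plateau whose leftmost maximum is the true
#' boundary).  The score's sign gives the transition direction.
#'
#' @param convolved output of [convolve_genotypes()].
#' @param params a [maskov_params()] (only `T` is used).
#' @return data frame with columns `left`, `right` (1-based compressed
#'   positions the edge lies between), `sign` (+1 for a -1 to +1
#'   transition, -1 for the reverse) and `score` (max `|convolved|`).
#' @export
detect_edges <- function(convolved, params) {
  state <- integer(length(convolved))
  above <- abs(convolved) > params$T
  state[above] <- sign(convolved[above])
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  if (length(keep) == 0L)
    return(data.frame(left = integer(), right = integer(),
                      sign = integer(), score = numeric()))
  left <- integer(length(keep))
  score <- numeric(length(keep))
  for (j in seq_along(keep)) {
    seg <- starts[keep[j]]:ends[keep[j]]
    m <- seg[which.max(abs(convolved[seg]))]   # leftmost maximum
    left[j] <- m
    score[j] <- abs(convolved[m])
  }
  data.frame(left = left, right = left + 1L,
             sign = r$values[keep], score = score)
}

#' Fill blocks between edges by winner-take-all
#'
#' Each maximal interval between consecutive edges (and the vector ends)
#' is set uniformly to the majority sign of its entries; an exact tie
#' takes the value of the block's first (leftmost) entry.  Adjacent blocks
#' that end up with equal sign are merged and the separating edge dropped.
#'
#' @param values compressed vector over `{1, -1}`.
#' @param edges data frame from [detect_edges()].
#' @return list with `values` (piecewise constant over `{1, -1}`) and
#'   `kept`, a logical marking which input edges survive the merge.
#' @export
fill_blocks <- function(values, edges) {
  n <- length(values)
  if (n == 0L) return(list(values = values, kept = logical(nrow(edges))))
  starts <- c(1L, edges$right)
  ends <- c(edges$left, n)
  bval <- integer(length(starts))
  for (b in seq_along(starts)) {
    blk <- values[starts[b]:ends[b]]
    s <- sum(blk)
    bval[b] <- if (s > 0L) 1L else if (s < 0L) -1L else blk[1L]
  }
  kept <- bval[-1L] != bval[-length(bval)]   # edge b sits between blocks b, b+1
  out <- integer(n)
  for (b in seq_along(starts)) out[starts[b]:ends[b]] <- bval[b]
  list(values = out, kept = kept)
}

#' Expand a corrected compressed vector back to original coordinates
#'
#' Non-missing positions take their corrected value; each formerly missing
#' position takes the value of its nearest non-missing neighbor in
#' original coordinates (so runs of missing interior to a block inherit
#' the block value), with equidistant ties going to the left (proximal)
#' neighbor; leading/trailing missing take the first/last corrected value.
#'
#' @param corrected corrected compressed values.
#' @param map 1-based original positions from [compress_missing()].
#' @param original_length length of the original vector.
#' @return integer vector of length `original_length` with no zeros, or
#'   `NULL` when `corrected` is empty (all-missing input).
#' @export
expand_to_original <- function(corrected, map, original_length) {
  if (length(corrected) == 0L) return(NULL)
  full <- integer(original_length)
  full[map] <- corrected
  gaps <- setdiff(seq_len(original_length), map)
  if (length(gaps)) {
    j <- findInterval(gaps, map)                    # index of left neighbor
    dl <- ifelse(j >= 1L, gaps - map[pmax(j, 1L)], Inf)
    dr <- ifelse(j < length(map), map[pmin(j + 1L, length(map))] - gaps, Inf)
    take_left <- dl <= dr
    full[gaps[take_left]] <- corrected[j[take_left]]
    full[gaps[!take_left]] <- corrected[j[!take_left] + 1L]
  }
  full
}

#' Impute and error-correct one encoded individual
#'
#' Runs the full three-pass composition (compress, convolve, detect,
#' fill, expand).  Individuals whose missing fraction exceeds
#' `max_missing` are returned unmodified and flagged `skipped`; likewise
#' all-missing vectors.
#'
#' @param values encoded vector over `{1, 0, -1}`.
#' @param params a [maskov_params()].
#' @return list with `values` (imputed vector; no zeros unless skipped),
#'   `edges` (data frame `left`, `right`, `sign`, `score` in 1-based
#'   original coordinates), and a `report` list: `n_missing_imputed`,
#'   `n_errors_corrected`, `n_edges`, `skipped`, `short_group` (vector
#'   shorter than one full convolution window).
#' @export
impute_individual <- function(values, params = maskov_params()) {
  values <- as.integer(values)
  if (!all(values %in% c(-1L, 0L, 1L)))
    stop("encoded values must lie in {1, 0, -1}")
  n <- length(values)
  n_missing <- sum(values == 0L)
  skip_report <- function(short = FALSE)
    list(n_missing_imputed = 0L, n_errors_corrected = 0L, n_edges = 0L,
         skipped = TRUE, short_group = short)
  if (n == 0L || n_missing == n)
    return(list(values = values, edges = empty_edges(), report = skip_report()))
  if (n_missing / n > params$max_missing)
    return(list(values = values, edges = empty_edges(), report = skip_report()))

  cm <- compress_missing(values)
  short <- length(cm$values) < 2L * params$E + 1L
  conv <- convolve_genotypes(cm$values, params$E)
  ed <- detect_edges(conv, params)
  fb <- fill_blocks(cm$values, ed)
  out <- expand_to_original(fb$values, cm$map, n)

  # surviving edges, re-expressed between adjacent original positions
  ch <- which(diff(out) != 0L)
  surv <- ed[fb$kept, , drop = FALSE]
  stopifnot(length(ch) == nrow(surv))
  edges <- data.frame(left = ch, right = ch + 1L,
                      sign = if (length(ch)) out[ch + 1L] else integer(),
                      score = surv$score)
  list(values = out, edges = edges,
       report = list(n_missing_imputed = n_missing,
                     n_errors_corrected = sum(values != 0L & out != values),
                     n_edges = nrow(edges),
                     skipped = FALSE, short_group = short))
}

empty_edges <- function() {
  data.frame(left = integer(), right = integer(),
             sign = integer(), score = numeric())
}

#' Impute a whole genotype matrix
#'
#' Applies [impute_individual()] to every individual on every linkage
#' group, decodes the corrected vectors back to genotype calls, and
#' aggregates an imputation report including the before/after mean number
#' of perceived recombination events per individual (summed over groups).
#'
#' @param gm a [geno_matrix()] with markers ordered within linkage groups.
#' @param phases named phase vector; computed with [assign_phases()] when
#'   `NULL`.
#' @param params a [maskov_params()].
#' @return list with `matrix` (imputed `geno_matrix`), `report` (one row
#'   per individual x linkage group), `edges` (one row per detected edge,
#'   with marker names and 0-based order indices), and `summary`
#'   (`mean_recomb_pre`, `mean_recomb_post`, `reduction_pct`, totals).
#' @export
impute_matrix <- function(gm, phases = NULL, params = maskov_params()) {
  validate_geno_matrix(gm)
  if (is.null(phases)) phases <- assign_phases(gm)
  groups <- unique(gm$lg)
  inds <- colnames(gm$calls)
  calls_out <- gm$calls
  report <- list()
  edges_out <- list()
  pre <- post <- setNames(numeric(length(inds)), inds)

  for (g in groups) {
    idx <- group_marker_index(gm, g)
    ids <- marker_ids(gm)[idx]
    X <- encode_group(gm, phases, g)
    for (ind in inds) {
      res <- impute_individual(X[, ind], params)
      pre[ind] <- pre[ind] + count_recombinations(X[, ind])
      post[ind] <- post[ind] + count_recombinations(res$values)
      if (!res$report$skipped)
        calls_out[idx, ind] <- decode(res$values, phases[ids])
      report[[length(report) + 1L]] <- data.frame(
        individual = ind, lg = g, n_markers = length(idx),
        n_missing = sum(X[, ind] == 0L),
        n_missing_imputed = res$report$n_missing_imputed,
        n_errors_corrected = res$report$n_errors_corrected,
        n_edges = res$report$n_edges,
        skipped = res$report$skipped,
        short_group = res$report$short_group)
      if (nrow(res$edges)) {
        e <- res$edges
        edges_out[[length(edges_out) + 1L]] <- data.frame(
          individual = ind, lg = g,
          left_marker = ids[e$left], right_marker = ids[e$right],
          left_order = e$left - 1L, right_order = e$right - 1L,
          sign = e$sign, score = e$score)
      }
    }
  }
  report <- do.call(rbind, report)
  edges_out <- if (length(edges_out)) do.call(rbind, edges_out) else
    data.frame(individual = character(), lg = character(),
               left_marker = character(), right_marker = character(),
               left_order = integer(), right_order = integer(),
               sign = integer(), score = numeric())
  out <- structure(list(calls = calls_out, lg = gm$lg, order = gm$order),
                   class = "geno_matrix")
  summary <- list(
    mean_recomb_pre = mean(pre), mean_recomb_post = mean(post),
    reduction_pct = if (mean(pre) > 0)
      percent_reduction(mean(pre), mean(post)) else NA_real_,
    total_missing_imputed = sum(report$n_missing_imputed),
    total_errors_corrected = sum(report$n_errors_corrected),
    total_edges = sum(report$n_edges),
    n_skipped = sum(report$skipped))
  list(matrix = out, report = report, edges = edges_out, summary = summary)
}
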