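# Map-building statistics for testcross matrices: recombination
# accounting, genotype binning, two-point linkage, Kosambi distances and
# the segregation-distortion scan.

#' Count recombination events along an encoded vector
#'
#' The number of sign changes between consecutive non-missing values;
#' missing entries are skipped, so a transition is counted between the
#' surviving neighbors.
#'
#' @param values encoded vector over `{1, 0, -1}`.
#' @return integer count.
#' @export
count_recombinations <- function(values) {
  v <- values[values != 0L]
  if (length(v) < 2L) return(0L)
  sum(diff(v) != 0L)
}

#' Mean perceived recombination events per individual
#'
#' Per individual, sign changes are counted on each linkage group
#' separately (no transition is counted across a group boundary) and
#' summed; the mean over individuals is returned.
#'
#' @param gm a [geno_matrix()].
#' @param phases named phase vector; computed with [assign_phases()] when
#'   `NULL`.
#' @return list with `mean` and the named `per_individual` totals.
#' @export
mean_recombinations <- function(gm, phases = NULL) {
  if (is.null(phases)) phases <- assign_phases(gm)
  inds <- colnames(gm$calls)
  totals <- setNames(numeric(length(inds)), inds)
  for (g in unique(gm$lg)) {
    X <- encode_group(gm, phases, g)
    totals <- totals + apply(X, 2L, count_recombinations)
  }
  list(mean = mean(totals), per_individual = totals)
}

#' Percent reduction between two rates
#'
#' `100 * (before - after) / before`, reported to one decimal place --
#' the scale on which map-size and recombination reductions are usually
#' quoted.
#'
#' @param before,after non-negative rates; `before` must be positive.
#' @return percent reduction, rounded to one decimal.
#' @export
percent_reduction <- function(before, after) {
  if (!is.numeric(before) || any(before <= 0))
    stop("`before` must be positive")
  round(100 * (before - after) / before, 1L)
}

#' Group markers of a linkage group into genotype bins
#'
#' Markers with identical (missing-free) genotype vectors across the
#' progeny co-segregate perfectly and are mapped as a single locus; the
#' bin's first member (by within-group order) is its representative.
#'
#' @param gm an imputed [geno_matrix()] (no missing calls in the group).
#' @param group linkage-group label.
#' @return list of class `marker_bins`: `group`, `bin_id` (per ordered
#'   marker), `members` (list of marker ids per bin), `representative`
#'   (marker id per bin), `position` (0-based bin rank), `n_bins`.
#' @export
bin_markers <- function(gm, group) {
  idx <- group_marker_index(gm, group)
  calls <- gm$calls[idx, , drop = FALSE]
  if (anyNA(calls))
    stop("group ", group, " contains missing calls; impute first ",
         "(see impute_matrix)")
  key <- apply(calls, 1L, paste, collapse = "")
  bin_id <- match(key, unique(key))
  members <- split(rownames(calls), bin_id)
  structure(list(group = as.character(group),
                 bin_id = bin_id,
                 marker_id = rownames(calls),
                 members = members,
                 representative = vapply(members, `[`, "", 1L),
                 position = seq_along(members) - 1L,
                 n_bins = length(members)),
            class = "marker_bins")
}

#' @export
print.marker_bins <- function(x, ...) {
  cat(sprintf("marker_bins: linkage group %s, %d markers in %d bins\n",
              x$group, length(x$bin_id), x$n_bins))
  invisible(x)
}

#' Two-point recombination fraction between two markers
#'
#' The fraction of informative meioses (individuals non-missing at both
#' markers) whose encoded signs differ.  A raw fraction above 0.5
#' indicates the complementary phase; the flip `r <- 1 - r` is applied and
#' recorded, as is standard testcross practice.
#'
#' @param v1,v2 encoded vectors over `{1, 0, -1}`, aligned on individuals.
#' @return list with `r_hat`, `n_informative`, `n_recombinant` (after any
#'   phase flip), `flipped`, and `undefined` (no informative pairs).
#' @export
recombination_fraction <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must be aligned")
  inf <- v1 != 0L & v2 != 0L
  n <- sum(inf)
  if (n == 0L)
    return(list(r_hat = NA_real_, n_informative = 0L, n_recombinant = NA_integer_,
                flipped = NA, undefined = TRUE))
  R <- sum(v1[inf] != v2[inf])
  flipped <- R > n - R
  if (flipped) R <- n - R
  list(r_hat = R / n, n_informative = n, n_recombinant = R,
       flipped = flipped, undefined = FALSE)
}

#' Two-point LOD score for linkage
#'
#' The base-10 log likelihood ratio of the estimated recombination
#' fraction against free recombination (r = 0.5) in a testcross:
#' `LOD = R log10(r/0.5) + (n - R) log10((1 - r)/0.5)` with `r = R/n`;
#' for `R = 0` this is `n log10 2`.
#'
#' @param v1,v2 encoded vectors over `{1, 0, -1}`, aligned on individuals.
#' @return list as [recombination_fraction()] plus `lod`.
#' @export
two_point_lod <- function(v1, v2) {
  res <- recombination_fraction(v1, v2)
  if (res$undefined) {
    res$lod <- NA_real_
    return(res)
  }
  res$lod <- lod_from_counts(res$n_recombinant, res$n_informative)
  res
}

lod_from_counts <- function(R, n) {
  r <- R / n
  t1 <- if (R == 0L) 0 else R * log10(r / 0.5)
  t2 <- if (R == n) 0 else (n - R) * log10((1 - r) / 0.5)
  t1 + t2
}

# Pairwise two-point statistics for a markers-x-individuals encoded
# matrix, computed with three matrix products.  Returns r (phase-flipped
# onto [0, 0.5]), lod and n matrices.
pairwise_linkage <- function(X) {
  X <- as.matrix(X)
  A <- abs(X)
  N <- A %*% t(A)                       # informative meioses
  C <- X %*% t(X)                       # concordant minus discordant
  R <- (N - C) / 2
  R2 <- pmin(R, N - R)                  # phase flip onto r <= 0.5
  r <- ifelse(N > 0, R2 / N, NA_real_)
  t1 <- ifelse(R2 > 0, R2 * log10(r / 0.5), 0)
  t2 <- ifelse(N - R2 > 0, (N - R2) * log10((1 - r) / 0.5), 0)
  lod <- ifelse(N > 0, t1 + t2, NA_real_)
  list(r = r, lod = lod, n = N)
}

#' Partition markers into linkage groups by two-point linkage
#'
#' Single-linkage clustering: two markers are joined when their two-point
#' LOD is at least `min_lod` and their recombination fraction at most
#' `max_r`; linkage groups are the connected components of the resulting
#' graph.
#'
#' @param gm a [geno_matrix()] (its stored `lg` labels are ignored), or an
#'   encoded markers-x-individuals matrix over `{1, 0, -1}`.
#' @param phases phase vector used when `gm` is a `geno_matrix`.
#' @param min_lod minimum LOD to join two markers (default 7).
#' @param max_r maximum recombination fraction to join (default 0.35).
#' @return named integer vector of group memberships (1, 2, ...),
#'   numbered by first marker appearance.
#' @export
group_markers <- function(gm, phases = NULL, min_lod = 7, max_r = 0.35) {
  if (inherits(gm, "geno_matrix")) {
    if (is.null(phases)) phases <- assign_phases(gm)
    X <- do.call(rbind, lapply(unique(gm$lg),
                               function(g) encode_group(gm, phases, g)))
  } else {
    X <- as.matrix(gm)
  }
  pl <- pairwise_linkage(X)
  adj <- !is.na(pl$lod) & pl$lod >= min_lod & pl$r <= max_r
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gr)$membership
  # renumber components by first appearance for stable output
  setNames(match(memb, unique(memb)), rownames(X))
}

#' Kosambi map distance
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centi-Morgans, the mapping function
#' allowing partial crossover interference.  Defined for `0 <= r < 0.5`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return distance(s) in cM.
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("Kosambi distance requires 0 <= r < 0.5")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Map length and marker density along a given bin order
#'
#' The group length is the sum of Kosambi distances between consecutive
#' bin representatives in the given order -- a sequential approximation
#' to multipoint regression mapping.
#'
#' @param gm an imputed [geno_matrix()].
#' @param group linkage-group label.
#' @param phases named phase vector; computed when `NULL`.
#' @param bins optional [bin_markers()] result for the group.
#' @return one-row data frame: `lg`, `length_cM`, `n_markers`, `n_bins`,
#'   `cM_per_marker`, `cM_per_bin`.
#' @export
map_length_along_order <- function(gm, group, phases = NULL, bins = NULL) {
  if (is.null(phases)) phases <- assign_phases(gm)
  if (is.null(bins)) bins <- bin_markers(gm, group)
  X <- encode_group(gm, phases, group)
  reps <- X[bins$representative, , drop = FALSE]
  len <- 0
  if (nrow(reps) > 1L) {
    for (b in seq_len(nrow(reps) - 1L)) {
      rf <- recombination_fraction(reps[b, ], reps[b + 1L, ])
      if (rf$undefined) stop("no informative meioses between adjacent bins")
      len <- len + kosambi_cM(rf$r_hat)
    }
  }
  data.frame(lg = bins$group, length_cM = len,
             n_markers = length(bins$bin_id), n_bins = bins$n_bins,
             cM_per_marker = len / length(bins$bin_id),
             cM_per_bin = len / bins$n_bins)
}

#' Per-group map summary table
#'
#' @param gm an imputed [geno_matrix()].
#' @param phases named phase vector; computed when `NULL`.
#' @return data frame with one row per linkage group plus a `Total` row
#'   (length and counts summed, densities recomputed).
#' @export
map_summary <- function(gm, phases = NULL) {
  if (is.null(phases)) phases <- assign_phases(gm)
  rows <- do.call(rbind, lapply(unique(gm$lg), function(g)
    map_length_along_order(gm, g, phases)))
  total <- data.frame(lg = "Total", length_cM = sum(rows$length_cM),
                      n_markers = sum(rows$n_markers),
                      n_bins = sum(rows$n_bins),
                      cM_per_marker = sum(rows$length_cM) / sum(rows$n_markers),
                      cM_per_bin = sum(rows$length_cM) / sum(rows$n_bins))
  rbind(rows, total)
}

#' Chi-squared segregation-distortion scan
#'
#' Tests every marker's two testcross classes against the expected 1:1
#' ratio with one degree of freedom: `chi2 = (o1 - o2)^2 / n`.  Raw
#' statistics are reported against the fixed significance thresholds
#' P = 0.05, 0.01 and 0.001 (3.841, 6.635, 10.828) for plotting distortion
#' along the map; no multiple-testing correction is applied unless
#' `fdr = TRUE` adds a Benjamini-Hochberg adjusted p column.
#'
#' @param gm a [geno_matrix()].
#' @param positions optional named numeric vector of map positions (cM)
#'   per marker; when given, output is ordered by linkage group and
#'   position.
#' @param fdr add a `p_adj` column (Benjamini-Hochberg).  Default `FALSE`.
#' @return data frame with columns `marker_id`, `lg`, `position_cM`, `n`,
#'   `count_class1` (het-like), `count_class2` (hom-like), `chi2`, `p`,
#'   `sig_level` (`""`, `"0.05"`, `"0.01"`, `"0.001"`).  Markers with no
#'   scored individuals get `NA` statistics.
#' @export
chi_square_scan <- function(gm, positions = NULL, fdr = FALSE) {
  calls <- gm$calls
  o1 <- rowSums(calls == .CALL_HET, na.rm = TRUE)
  o2 <- rowSums(calls == .CALL_HOM, na.rm = TRUE)
  n <- o1 + o2
  chi2 <- ifelse(n > 0, (o1 - o2)^2 / n, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  sig <- rep("", length(p))
  sig[!is.na(p) & p <= 0.05] <- "0.05"
  sig[!is.na(p) & p <= 0.01] <- "0.01"
  sig[!is.na(p) & p <= 0.001] <- "0.001"
  pos <- if (is.null(positions)) rep(NA_real_, length(n)) else
    unname(positions[rownames(calls)])
  out <- data.frame(marker_id = rownames(calls), lg = gm$lg,
                    position_cM = pos, n = n,
                    count_class1 = o1, count_class2 = o2,
                    chi2 = chi2, p = p, sig_level = sig)
  if (fdr) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  if (!is.null(positions))
    out <- out[order(out$lg, out$position_cM), ]
  rownames(out) <- NULL
  out
}

#' Order genotype bins by greedy nearest-neighbor chaining
#'
#' A deliberately simple ordering heuristic for synthetic end-to-end
#' runs: start from the bin pair with the smallest recombination
#' fraction and repeatedly append, to either chain end, the unplaced bin
#' closest to that end.  Ties break to the lower bin id.  Not a
#' substitute for multipoint ordering.
#'
#' @param reps bins-x-individuals encoded matrix of bin representatives.
#' @return integer vector: bin indices in chained order.
#' @export
order_markers_greedy <- function(reps) {
  reps <- as.matrix(reps)
  k <- nrow(reps)
  if (k <= 2L) return(seq_len(k))
  r <- pairwise_linkage(reps)$r
  diag(r) <- Inf
  r[is.na(r)] <- Inf
  start <- which(r == min(r), arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  chain <- as.integer(c(start[1L], start[2L]))
  left <- setdiff(seq_len(k), chain)
  while (length(left)) {
    d_head <- r[chain[1L], left]
    d_tail <- r[chain[length(chain)], left]
    if (min(d_head) <= min(d_tail)) {  # prefer head on exact tie
      nxt <- left[which.min(d_head)]   # which.min takes first (lowest id)
      chain <- c(nxt, chain)
    } else {
      nxt <- left[which.min(d_tail)]
      chain <- c(chain, nxt)
    }
    left <- setdiff(left, nxt)
  }
  chain
}
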