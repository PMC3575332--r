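# Independent oracles for the imputation algorithm.
#
# oracle_min_hamming(): brute-force enumeration of every piecewise
# constant +/-1 vector with a fixed number of sign changes; returns the
# one closest (Hamming) to the observed vector, flagging ties.
#
# qualifying_cases(): constructive enumeration of the vector class on
# which convolution imputation provably recovers the generating
# segmentation -- crossovers at least E+1 positions from the ends and
# separated by more than 2E+1; isolated error clusters of at most
# floor(E/2) calls (invisible to the threshold |conv| > E), pairwise
# separated by more than 2E+1 and at least E+1 positions from every
# crossover.

oracle_min_hamming <- function(observed, n_edges) {
  n <- length(observed)
  best <- NULL
  best_d <- Inf
  tie <- FALSE
  edge_sets <- if (n_edges == 0L) list(integer(0)) else
    utils::combn(n - 1L, n_edges, simplify = FALSE)
  for (es in edge_sets) {
    for (start in c(1L, -1L)) {
      v <- as.integer(start * (-1)^findInterval(seq_len(n) - 1L, es))
      d <- sum(v != observed)
      if (d < best_d) {
        best <- v; best_d <- d; tie <- FALSE
      } else if (d == best_d && !identical(v, best)) {
        tie <- TRUE
      }
    }
  }
  list(values = best, distance = best_d, tie = tie)
}

# Subsets of `positions` (sorted) with every pairwise gap > min_gap.
.spaced_subsets <- function(positions, min_gap, max_size) {
  out <- list(integer(0))
  if (max_size < 1L || length(positions) == 0L) return(out)
  grow <- list(integer(0))
  for (s in seq_len(max_size)) {
    nxt <- list()
    for (base in grow) {
      lo <- if (length(base)) max(base) + min_gap + 1L else -Inf
      for (p in positions[positions >= lo])
        nxt[[length(nxt) + 1L]] <- c(base, p)
    }
    if (length(nxt) == 0L) break
    out <- c(out, nxt)
    grow <- nxt
  }
  out
}

# Enumerate qualifying (truth, observed, edges, errors) cases for one E.
# Edges are identified by their left index p (edge between p and p+1,
# 1-based).  Error clusters of uniform size cs are represented by their
# leftmost position; cs = 0 is the error-free case.
qualifying_cases <- function(E, n_max = 16L, max_edges = 2L,
                             max_error_clusters = 2L) {
  max_cluster <- E %/% 2L
  cases <- list()
  add_case <- function(n, es, qs, cs) {
    for (start in c(1L, -1L)) {
      truth <- as.integer(start * (-1)^findInterval(seq_len(n) - 1L, es))
      observed <- truth
      for (q in qs) {
        span <- q:(q + cs - 1L)
        observed[span] <- -observed[span]
      }
      # correct calls must hold a strict majority in every block, else
      # the minimum-Hamming segmentation is ambiguous (tied)
      starts <- c(1L, es + 1L); ends <- c(es, n)
      ok <- all(vapply(seq_along(starts), function(b) {
        blk <- starts[b]:ends[b]
        sum(observed[blk]) * truth[starts[b]] > 0L
      }, logical(1)))
      if (!ok) next
      cases[[length(cases) + 1L]] <<-
        list(E = E, truth = truth, observed = observed,
             edges = es, errors = qs, cluster = cs)
    }
  }
  for (n in seq(2L, n_max)) {
    edge_pos <- if (n - E - 1L >= E + 1L) seq(E + 1L, n - E - 1L) else integer(0)
    for (es in .spaced_subsets(edge_pos, 2L * E + 1L, max_edges)) {
      add_case(n, es, integer(0), 0L)           # error-free
      for (cs in seq_len(max_cluster)) {
        # positions where a cluster [q, q+cs-1] may start: inside the
        # vector and >= E+1 positions from every crossover boundary
        q <- seq_len(n - cs + 1L)
        ok <- rep(TRUE, length(q))
        for (p in es)
          ok <- ok & (q + cs - 1L <= p - E - 1L | q >= p + E + 2L)
        for (qs in .spaced_subsets(q[ok], 2L * E + cs, max_error_clusters))
          if (length(qs)) add_case(n, es, qs, cs)
      }
    }
  }
  cases
}
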