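# Synthetic pseudo-testcross progenies with known crossovers, degraded
# with GBS-like missingness and genotyping error, for recovery testing.

#' Simulation parameters
#'
#' Defaults emulate the shape of a 71-seedling red-raspberry GBS progeny:
#' seven linkage groups with realistic cM lengths, 500 markers per group,
#' 36% missing data with strong per-individual variance, and a 2% per-call
#' genotyping-error rate.
#'
#' @param n_individuals progeny size (default 71).
#' @param lg_lengths_cM linkage-group lengths in cM.
#' @param markers_per_lg markers per group, recycled to the number of
#'   groups (default 500).
#' @param missing_mean target overall missing fraction (default 0.36).
#' @param missing_dispersion standard deviation of the per-individual
#'   missing rate (Beta-distributed between individuals, emulating
#'   sequencing-depth variance); 0 gives a uniform rate.  Default 0.10.
#' @param error_rate probability that a surviving call is flipped to the
#'   other testcross class (default 0.02).
#' @param randomize_phase draw each marker's phase at random instead of
#'   anchoring all markers at `"1-"`; exercises downstream phasing.
#' @param seed integer seed; every downstream operation is reproducible
#'   under a fixed seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 71L,
                       lg_lengths_cM = c(87.6, 46.4, 73.6, 78.5, 53.1, 68.4, 55.1),
                       markers_per_lg = 500L,
                       missing_mean = 0.36,
                       missing_dispersion = 0.10,
                       error_rate = 0.02,
                       randomize_phase = FALSE,
                       seed = NULL) {
  stopifnot(n_individuals >= 1L, all(lg_lengths_cM >= 0),
            missing_mean >= 0, missing_mean <= 1,
            missing_dispersion >= 0,
            error_rate >= 0, error_rate <= 1)
  markers_per_lg <- rep_len(as.integer(markers_per_lg), length(lg_lengths_cM))
  if (any(markers_per_lg < 2L)) stop("need at least 2 markers per group")
  structure(list(n_individuals = as.integer(n_individuals),
                 lg_lengths_cM = lg_lengths_cM,
                 markers_per_lg = markers_per_lg,
                 missing_mean = missing_mean,
                 missing_dispersion = missing_dispersion,
                 error_rate = error_rate,
                 randomize_phase = isTRUE(randomize_phase),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

#' Simulate a clean (complete, error-free) progeny
#'
#' Meiosis follows the standard no-interference model: per gamete and
#' linkage group the crossover count is Poisson with mean `length/100`
#' Morgans and crossover positions are uniform along the group.  Marker
#' positions are drawn uniformly.  Each individual's encoded vector is the
#' parental phase sequence cut at its crossovers.
#'
#' @param params a [sim_params()].
#' @return list of class `truth_set` with `clean` (a complete
#'   [geno_matrix()]), `phases`, `marker_pos` (named cM positions),
#'   `crossovers` (data frame per individual x group: `n_raw` simulated
#'   crossovers and `n_marker_resolved` sign changes at marker
#'   resolution), `crossover_positions` (list of cM positions), and
#'   `params`.  `observed` and the degradation masks are `NULL` until
#'   [degrade()] is applied.
#' @export
simulate_clean <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n_lg <- length(params$lg_lengths_cM)
  inds <- sprintf("ind%02d", seq_len(params$n_individuals))
  lg_names <- sprintf("LG%d", seq_len(n_lg))

  calls_all <- list(); lg_all <- list(); pos_all <- list()
  phases_all <- list()
  xov <- list(); xov_pos <- list()
  for (g in seq_len(n_lg)) {
    L <- params$lg_lengths_cM[g]
    m <- params$markers_per_lg[g]
    mpos <- sort(stats::runif(m, 0, max(L, 1e-9)))
    ids <- sprintf("%s_M%04d", lg_names[g], seq_len(m))
    enc <- matrix(0L, m, length(inds), dimnames = list(ids, inds))
    for (i in seq_along(inds)) {
      n_co <- stats::rpois(1L, L / 100)
      cpos <- sort(stats::runif(n_co, 0, max(L, 1e-9)))
      start <- sample(c(1L, -1L), 1L)
      # sign flips at every crossover left of the marker
      flips <- findInterval(mpos, cpos)
      v <- start * (-1L)^flips
      enc[, i] <- as.integer(v)
      xov[[length(xov) + 1L]] <- data.frame(
        individual = inds[i], lg = lg_names[g],
        n_raw = n_co, n_marker_resolved = count_recombinations(v))
      xov_pos[[length(xov_pos) + 1L]] <- cpos
    }
    phases <- if (params$randomize_phase)
      sample(c("1-", "0-"), m, replace = TRUE) else rep("1-", m)
    names(phases) <- ids
    calls <- matrix(decode(enc, rep(phases, ncol(enc))), m, ncol(enc),
                    dimnames = dimnames(enc))
    calls_all[[g]] <- calls
    lg_all[[g]] <- rep(lg_names[g], m)
    pos_all[[g]] <- setNames(mpos, ids)
    phases_all[[g]] <- phases
  }
  clean <- geno_matrix(do.call(rbind, calls_all), lg = unlist(lg_all))
  structure(list(clean = clean,
                 phases = unlist(phases_all),
                 marker_pos = unlist(unname(pos_all)),
                 crossovers = do.call(rbind, xov),
                 crossover_positions = xov_pos,
                 observed = NULL, missing_mask = NULL, error_mask = NULL,
                 params = params),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d markers x %d individuals, %d linkage group(s)%s\n",
              nrow(x$clean$calls), ncol(x$clean$calls),
              length(unique(x$clean$lg)),
              if (is.null(x$observed)) " (clean only)" else " (degraded)"))
  invisible(x)
}

#' Degrade a clean progeny with missingness and genotyping error
#'
#' Each individual's missing rate is drawn from a Beta distribution with
#' mean `missing_mean` and standard deviation `missing_dispersion`
#' (emulating between-individual sequencing-depth variance); cells are
#' dropped independently at that rate, and surviving calls are flipped to
#' the other testcross class with probability `error_rate`.  A missing
#' cell cannot also be an error.  Reseeds deterministically at
#' `params$seed + 1` so the operation is reproducible standalone.
#'
#' @param truth a `truth_set` from [simulate_clean()].
#' @return the `truth_set` with `observed` (degraded [geno_matrix()]),
#'   `missing_mask` and `error_mask` (logical matrices) filled in.
#' @export
degrade <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  params <- truth$params
  if (!is.null(params$seed)) set.seed(params$seed + 1L)
  calls <- truth$clean$calls
  n_mark <- nrow(calls); n_ind <- ncol(calls)

  m <- params$missing_mean; s <- params$missing_dispersion
  rates <- if (m == 0) rep(0, n_ind)
  else if (s == 0) rep(m, n_ind)
  else {
    if (s^2 >= m * (1 - m))
      stop("missing_dispersion too large for missing_mean")
    nu <- m * (1 - m) / s^2 - 1
    stats::rbeta(n_ind, m * nu, (1 - m) * nu)
  }
  missing_mask <- matrix(stats::runif(n_mark * n_ind) <
                           rep(rates, each = n_mark),
                         n_mark, n_ind, dimnames = dimnames(calls))
  error_mask <- matrix(stats::runif(n_mark * n_ind) < params$error_rate,
                       n_mark, n_ind, dimnames = dimnames(calls)) &
    !missing_mask
  observed <- calls
  observed[error_mask] <- ifelse(calls[error_mask] == .CALL_HET,
                                 .CALL_HOM, .CALL_HET)
  observed[missing_mask] <- NA_character_
  truth$observed <- structure(list(calls = observed, lg = truth$clean$lg,
                                   order = truth$clean$order),
                              class = "geno_matrix")
  truth$missing_mask <- missing_mask
  truth$error_mask <- error_mask
  truth
}

#' Simulate and degrade in one call
#'
#' @param params a [sim_params()].
#' @return a degraded `truth_set`; see [simulate_clean()] and [degrade()].
#' @export
simulate_progeny <- function(params) degrade(simulate_clean(params))

#' Score an imputed matrix against the simulation truth
#'
#' @param truth a degraded `truth_set`.
#' @param imputed the imputed [geno_matrix()] (same shape as the truth
#'   matrices).
#' @param phases phases used for recombination counting; defaults to the
#'   simulation truth phases.
#' @return list of metrics: `recovery_pct` (masked-missing cells imputed
#'   to the true call; unimputed cells count as failures),
#'   `error_correction_pct` (introduced errors restored),
#'   `residual_missing` (cells still missing after imputation),
#'   `crossover_bias_pct` (relative bias of the mean post-imputation
#'   recombination count against the true marker-resolved crossover
#'   mean), and `mean_recomb` with `true`, `pre`, `post` and
#'   `reduction_pct` components.
#' @export
evaluate_recovery <- function(truth, imputed, phases = truth$phases) {
  stopifnot(inherits(truth, "truth_set"), inherits(imputed, "geno_matrix"))
  if (is.null(truth$observed)) stop("truth set has not been degraded")
  clean <- truth$clean$calls
  imp <- imputed$calls
  if (!identical(dim(imp), dim(clean)) ||
      !identical(dimnames(imp), dimnames(clean)))
    stop("imputed matrix shape does not match the truth set")

  mm <- truth$missing_mask
  recov <- imp[mm] == clean[mm]
  recov[is.na(recov)] <- FALSE          # still-missing cells not recovered
  em <- truth$error_mask
  corr <- imp[em] == clean[em]
  corr[is.na(corr)] <- FALSE

  true_tot <- tapply(truth$crossovers$n_marker_resolved,
                     truth$crossovers$individual, sum)
  true_mean <- mean(true_tot)
  pre <- mean_recombinations(truth$observed, phases)$mean
  post <- mean_recombinations(imputed, phases)$mean
  list(recovery_pct = 100 * mean(recov),
       error_correction_pct = if (any(em)) 100 * mean(corr) else NA_real_,
       residual_missing = sum(is.na(imp)),
       crossover_bias_pct = 100 * (post - true_mean) / true_mean,
       mean_recomb = list(true = true_mean, pre = pre, post = post,
                          reduction_pct = percent_reduction(pre, post)))
}
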