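# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

# Small genotype matrix from a character vector, column-major.
make_gm <- function(values, n_markers, n_individuals,
                    lg = rep("LG1", n_markers)) {
  m <- matrix(values, n_markers, n_individuals,
              dimnames = list(sprintf("M%02d", seq_len(n_markers)),
                              sprintf("i%02d", seq_len(n_individuals))))
  geno_matrix(m, lg = lg)
}

# Random valid genotype matrix for round-trip property tests.
random_gm <- function(n_markers = 12, n_individuals = 6, n_lg = 2,
                      p_missing = 0.3) {
  calls <- matrix(sample(c("h", "a", NA), n_markers * n_individuals,
                         replace = TRUE,
                         prob = c((1 - p_missing) / 2, (1 - p_missing) / 2,
                                  p_missing)),
                  n_markers, n_individuals,
                  dimnames = list(sprintf("M%03d", seq_len(n_markers)),
                                  sprintf("i%02d", seq_len(n_individuals))))
  geno_matrix(calls, lg = sort(rep_len(sprintf("LG%d", seq_len(n_lg)),
                                       n_markers)))
}

# Random encoded vector over {1, 0, -1}.
random_encoded <- function(n, p_missing = 0.3) {
  sample(c(1L, 0L, -1L), n, replace = TRUE,
         prob = c((1 - p_missing) / 2, p_missing, (1 - p_missing) / 2))
}
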