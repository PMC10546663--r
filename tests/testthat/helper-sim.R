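# Shared fixtures: small simulated cohorts and matrices built in code.

# Small single-species two-subtype cohort.
small_cohort <- function(seed = 1, n_genes = 300, n_per = 15,
                         effect_size = 2, bio_sd = 1) {
  simulate_cohort(sim_config(
    n_genes = n_genes, n_panel_genes = 20,
    subtypes = list(sp = setNames(c(n_per, n_per), c("A", "B"))),
    n_informative = 30, effect_size = effect_size, bio_sd = bio_sd,
    seed = seed))
}

# Deterministic block matrix: two sample blocks with shifted gene blocks,
# plus noise. Rows/cols named.
block_matrix <- function(n_genes = 60, n_per = 10, shift = 3, noise = 0.3,
                         seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * 2 * n_per, 5, noise), n_genes, 2 * n_per)
  X[1:(n_genes / 2), 1:n_per] <- X[1:(n_genes / 2), 1:n_per] + shift
  X[(n_genes / 2 + 1):n_genes, (n_per + 1):(2 * n_per)] <-
    X[(n_genes / 2 + 1):n_genes, (n_per + 1):(2 * n_per)] + shift
  dimnames(X) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(2 * n_per)))
  pmax(X, 0)
}

block_truth <- function(n_per = 10) rep(c(1L, 2L), each = n_per)

# Named matrix helper.
named_matrix <- function(data, nrow, ncol) {
  matrix(data, nrow, ncol,
         dimnames = list(sprintf("g%02d", seq_len(nrow)),
                         sprintf("s%02d", seq_len(ncol))))
}
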