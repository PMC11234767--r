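# Shared fixtures, generated in code. Sizes are kept small; the heavier
# desk-scale study used by the acceptance checks is built once and memoized.

.fixture_env <- new.env(parent = emptyenv())

# small multi-generation population with genotypes and pedigree
small_population <- function() {
  if (is.null(.fixture_env$pop)) {
    model <- ld_model(n_snps = 400, n_chromosomes = 4, ld_decay = 5)
    pop <- simulate_founders(model, 120, seed = 101)
    .fixture_env$founders <- pop
    gen1 <- advance_generation(pop, 120, seed = 102)
    gen2 <- advance_generation(gen1, 120, seed = 103)
    .fixture_env$pop <- list(founders = pop, gen1 = gen1, gen2 = gen2)
  }
  .fixture_env$pop
}

# a PSD relationship matrix with ids, from random genotypes
random_W <- function(n, m = 50, seed = 1, ids = sprintf("id%02d", seq_len(n))) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n)]),
                n, m, dimnames = list(ids, sprintf("v%03d", seq_len(m))))
  keep <- apply(dos, 2, function(x) length(unique(x)) > 1)
  W <- tcrossprod(center_scale(dos[, keep, drop = FALSE])$values)
  W + diag(1e-6, n)   # keep it comfortably positive definite
}

# desk-scale erosion study shared by the heavier scientific checks;
# computed once per test run
acceptance_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- run_study(study_config(seed = 1234))
  .fixture_env$study
}

# trio pedigree CSV on disk
write_trio_csv <- function(path) {
  writeLines(c("id,sire,dam", "kid,papa,mama", "papa,0,0", "mama,0,0"), path)
  path
}
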