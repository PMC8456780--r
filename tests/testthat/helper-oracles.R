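# Independent oracles used to verify the package's statistics, plus small
# fixture builders. Oracles are deliberately written as brute-force or
# closed-form recomputations that share no code with the implementation.

# Exhaustive two-sided rank-sum p: enumerate every assignment of the pooled
# ranks to group A and count arrangements with |U - E[U]| at least as
# extreme as observed. Valid for distinct pooled values.
oracle_wilcoxon_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, probabilities from products of binomial coefficients.
oracle_fisher_exact <- function(x_in, n_in, x_out, n_out) {
  m <- x_in + x_out
  supp <- max(0, m - n_out):min(m, n_in)
  prob <- vapply(supp, function(x)
    choose(n_in, x) * choose(n_out, m - x) / choose(n_in + n_out, m), 0)
  obs <- prob[match(x_in, supp)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Dense O(N) running-sum enrichment score: direct cumulative sum over the
# full ranked list (weight exponent 1), extremum by first maximal |value|.
oracle_es_dense <- function(scores_sorted, hit_logical) {
  N <- length(scores_sorted)
  s <- sum(hit_logical)
  w <- abs(scores_sorted)
  sw <- sum(w[hit_logical])
  inc <- if (sw > 0) w / sw else rep(1 / s, N)
  step <- ifelse(hit_logical, inc, -1 / (N - s))
  run <- cumsum(step)
  run[[which.max(abs(run))]]
}

# Brute-force cosine k nearest neighbours (ties by ascending index).
oracle_cosine_knn <- function(coords, k) {
  rn <- sqrt(rowSums(coords^2)); rn[rn == 0] <- 1
  y <- coords / rn
  sim <- y %*% t(y)
  t(vapply(seq_len(nrow(coords)), function(i) {
    s <- sim[i, ]; s[i] <- -Inf
    order(-s, seq_along(s))[seq_len(k)]
  }, integer(k)))
}

# Small deterministic CountMatrix from a dense integer matrix.
cm_from_dense <- function(m, samples = NULL) {
  CountMatrix(as(m, "CsparseMatrix"), sample_of_cell = samples)
}

# Small random NB count fixture.
random_counts <- function(n_cells, n_genes, mu = 2, size = 2, seed = 1,
                          samples = NULL) {
  set.seed(seed)
  m <- matrix(rnbinom(n_cells * n_genes, mu = mu, size = size),
              n_cells, n_genes)
  cm_from_dense(m, samples)
}

# Memoised heavy benchmark artifacts shared by the acceptance tests.
.bench_env <- new.env(parent = emptyenv())

bench_sim <- function() {
  if (is.null(.bench_env$sim)) .bench_env$sim <- default_benchmark()
  .bench_env$sim
}

bench_run <- function() {
  if (is.null(.bench_env$run)) {
    sim <- bench_sim()
    .bench_env$run <- suppressWarnings(
      run_supervised_integration(split_by_sample(sim$counts),
                                 config = list(n_perm = 300)))
  }
  .bench_env$run
}

# Planted type of every cell retained in the merged integrated object.
bench_truth_types <- function() {
  sim <- bench_sim(); run <- bench_run()
  key <- sub("^[^:]+:", "", cell_ids(run$merged))
  sim$truth$type[match(key, cell_ids(sim$counts))]
}
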