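# naive reference implementations, independent of the package's vectorized
# code paths: plain double loops and per-cell recounts.

naive_intersect <- function(a, b) {
  out <- character(0)
  for (g in a) {
    hit <- FALSE
    for (h in b) if (g == h) hit <- TRUE
    if (hit && !g %in% out) out <- c(out, g)
  }
  out
}

naive_subtract <- function(a, b) {
  out <- character(0)
  for (g in a) {
    hit <- FALSE
    for (h in b) if (g == h) hit <- TRUE
    if (!hit && !g %in% out) out <- c(out, g)
  }
  out
}

naive_down <- function(lfc, p, alpha = 0.05, cut = 0) {
  p < alpha & lfc < cut
}

# per-cell recount of a down-call matrix
naive_matrix <- function(genes, datasets, alpha = 0.05) {
  m <- matrix("NOT_MEASURED", length(genes), length(datasets),
              dimnames = list(genes,
                              vapply(datasets, `[[`, "", "dataset_id")))
  for (i in seq_along(genes)) {
    for (j in seq_along(datasets)) {
      d <- datasets[[j]]$data
      k <- which(d$gene == genes[i])
      if (length(k) == 1L) {
        m[i, j] <- if (naive_down(d$log2fc[k], d$pvalue[k], alpha)) "DOWN"
                   else "NOT_DOWN"
      }
    }
  }
  m
}

naive_round2 <- function(m) {
  rownames(m)[apply(m, 1, function(r) {
    any_down <- FALSE
    for (cell in r) if (cell == "DOWN") any_down <- TRUE
    any_down
  })]
}

naive_round3 <- function(m, targets, high, k) {
  pass <- character(0)
  for (g in rownames(m)) {
    hit <- character(0)
    for (j in seq_len(ncol(m))) {
      if (m[g, j] == "DOWN" && targets[j] %in% high) {
        hit <- union(hit, targets[j])
      }
    }
    if (length(hit) >= k) pass <- c(pass, g)
  }
  pass
}

# quick builders --------------------------------------------------------

mk_de <- function(genes, lfc, p, id = "D1", target = "CTLA4",
                  species = "human") {
  de_table(id, target, species,
           data.frame(gene = genes, log2fc = lfc, pvalue = p))
}

rand_symbols <- function(n, prefix = "G") sprintf("%s%04d", prefix, seq_len(n))

# random screening instance: gene pool, candidate table, DE datasets
rand_instance <- function(seed, n_genes = 30, n_ds = 6, n_targets = 3) {
  set.seed(seed)
  pool <- rand_symbols(n_genes)
  membrane <- gene_set(sample(pool, n_genes * 0.8), "mem")
  fox <- gene_set(sample(pool, n_genes * 0.5), "fox")
  treg <- gene_set(sample(pool, n_genes * 0.4), "treg")
  known <- gene_set(sample(pool, 3), "known")
  cand <- build_candidates(membrane, fox, treg, known)
  targets <- rand_symbols(n_targets, "T")
  datasets <- lapply(seq_len(n_ds), function(j) {
    meas <- sample(pool, rbinom(1, n_genes, 0.8))
    mk_de(meas, rnorm(length(meas)), runif(length(meas)),
          id = sprintf("DS%02d", j),
          target = targets[((j - 1) %% n_targets) + 1])
  })
  list(pool = pool, candidates = cand, datasets = datasets,
       targets = targets)
}

# the reference fixture and its screen run, computed once per suite
ref_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$run)) {
      env$spec <- reference_fixture_spec()
      env$fix <- simulate_fixture(env$spec, seed = 42)
      env$run <- run_screen(env$fix, config = env$fix$config)
    }
    list(spec = env$spec, fix = env$fix, run = env$run)
  }
})
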