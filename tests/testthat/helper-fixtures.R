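# Shared fixture builders: everything is generated in code at test time.

# z-score each row (sample SD), the shape clustering inputs always have
zscore_rows <- function(x) {
  t(apply(x, 1, function(r) (r - mean(r)) / stats::sd(r)))
}

# planted clustering samples: k zero-mean templates + gaussian noise, z-scored
planted_samples <- function(n_per_state, templates, noise_sd, seed) {
  k <- nrow(templates)
  labels <- rep(seq_len(k), each = n_per_state)
  x <- withr_seed(seed, {
    templates[labels, , drop = FALSE] +
      matrix(stats::rnorm(length(labels) * ncol(templates), sd = noise_sd),
             length(labels), ncol(templates))
  })
  list(samples = zscore_rows(x), labels = labels)
}

# orthogonal-ish block templates over d regions
block_templates <- function(k, d) {
  stopifnot(d %% k == 0)
  tpl <- matrix(-1 / (k - 1), k, d)
  b <- d / k
  for (s in seq_len(k)) tpl[s, ((s - 1) * b + 1):(s * b)] <- 1
  tpl
}

# random symmetric weighted graph with zero diagonal
random_graph <- function(n, density = 0.5, seed = 1) {
  withr_seed(seed, {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- sample(ut, max(2, round(density * length(ut))))
    W[on] <- stats::runif(length(on), 0.1, 1)
    W + t(W)
  })
}

# local seed without touching the session RNG
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# write a small TSV time-series file, returns path
write_ts_file <- function(m, labels = colnames(m)) {
  path <- tempfile(fileext = ".tsv")
  df <- as.data.frame(m)
  names(df) <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
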