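# Shared fixtures and independent oracles, built in code.

make_design <- function(r = 2) {
  data.frame(
    sample_id = paste(rep(c("control", "sigA", "sigB", "both"), each = r),
                      rep(seq_len(r), 4), sep = "_"),
    treatment = rep(c("control", "sigA", "sigB", "both"), each = r),
    replicate = rep(seq_len(r), 4),
    stringsAsFactors = FALSE
  )
}

# genes x samples matrix from a per-gene vector of 4 treatment means (+ noise)
make_matrix <- function(group_means, r = 2, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- as.matrix(group_means)  # genes x 4, columns control/sigA/sigB/both
  G <- nrow(gm)
  m <- gm[, rep(1:4, each = r), drop = FALSE]
  if (noise_sd > 0) m <- m + matrix(rnorm(G * 4 * r, 0, noise_sd), G)
  dimnames(m) <- list(sprintf("g%03d", seq_len(G)), make_design(r)$sample_id)
  m
}

rand_matrix <- function(G, r = 2, sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(G * 4 * r, 0, sd), G)
  dimnames(m) <- list(sprintf("g%03d", seq_len(G)), make_design(r)$sample_id)
  m
}

## --- independent multiple-testing oracles (literal definitions, O(n^2)) ---

brute_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    # adjusted_(k) = max_{j <= k} (n - j + 1) * p_(j), capped at 1
    adj[o[k]] <- min(1, max((n - seq_len(k) + 1) * p[o[seq_len(k)]]))
  }
  adj
}

brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (k in seq_len(n)) {
    # adjusted_(k) = min_{j >= k} min(1, (n / j) * p_(j))
    adj[o[k]] <- min(1, (n / (k:n)) * ps[k:n])
  }
  adj
}

# all permutations of a vector (recursive; for brute-force label enumeration)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(rest) c(v[i], rest))
  }))
}
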