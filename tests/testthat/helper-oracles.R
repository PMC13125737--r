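# Independent brute-force oracles and small fixture builders.

# long methylation tibble from a samples x CpGs matrix (single replicate)
make_meth <- function(values, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(values)))
  tibble::tibble(
    sample = rep(samples, each = ncol(values)),
    replicate = 1L,
    cpg = rep(seq_len(ncol(values)), nrow(values)),
    percent = as.vector(t(values))
  )
}

# naive all-windows CpG island oracle: mark positions covered by any passing
# window, merge runs, keep runs >= min_len
oracle_islands <- function(sequence, min_len = 200, gc_min = 0.5,
                           obs_exp_min = 0.6, window = 200) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  L <- length(ch)
  if (L < window) return(data.frame(start = integer(0), end = integer(0)))
  covered <- logical(L)
  for (s in 1:(L - window + 1)) {
    win <- ch[s:(s + window - 1)]
    nc <- sum(win == "C"); ng <- sum(win == "G")
    ncpg <- sum(win[-window] == "C" & win[-1] == "G")
    gc <- (nc + ng) / window
    expd <- nc * ng / window
    oe <- if (expd > 0) ncpg / expd else 0
    if (gc >= gc_min && oe >= obs_exp_min) covered[s:(s + window - 1)] <- TRUE
  }
  r <- rle(covered)
  e <- cumsum(r$lengths); b <- e - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = b[keep] - 1L, end = e[keep])
}

# recursive enumeration of all size-k index subsets of 1..n (own code path,
# not utils::combn) for the Mann-Whitney oracle
subsets_of <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  if (k == n) return(list(seq_len(n)))
  with_n <- lapply(subsets_of(n - 1, k - 1), function(s) c(s, n))
  without_n <- subsets_of(n - 1, k)
  c(without_n, with_n)
}

# exact two-sided Mann-Whitney p by enumeration over group assignments,
# deviation-based with midranks
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  mu <- na * length(b) / 2
  u_of <- function(ix) sum(r[ix]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  devs <- vapply(subsets_of(n, na), function(ix) abs(u_of(ix) - mu), numeric(1))
  mean(devs >= abs(u_obs - mu) - 1e-9)
}

# exhaustive 4^w word enumeration for PWM p-values; scores on the same
# integer grid the scanner uses (independent computation path) and on the
# real-valued scale
oracle_pwm_enumeration <- function(logodds, background, granularity) {
  w <- ncol(logodds)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  real <- numeric(nrow(words))
  grid <- numeric(nrow(words))
  prob <- numeric(nrow(words))
  int_cols <- round(logodds * granularity)
  for (i in seq_len(nrow(words))) {
    idx <- cbind(words[i, ], seq_len(w))
    real[i] <- sum(logodds[idx])
    grid[i] <- sum(int_cols[idx])
    prob[i] <- prod(background[words[i, ]])
  }
  list(real = real, grid = grid, prob = prob)
}

# near-consensus PFM for a given consensus string (high information content)
consensus_pfm <- function(consensus, strong = 97, weak = 1,
                          id = "TEST", name = "test") {
  bases <- c("A", "C", "G", "T")
  w <- nchar(consensus)
  counts <- matrix(weak, 4, w, dimnames = list(bases, NULL))
  idx <- match(strsplit(consensus, "")[[1]], bases)
  counts[cbind(idx, seq_len(w))] <- strong
  list(motif_id = id, motif_name = name, counts = counts, width = w)
}

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
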