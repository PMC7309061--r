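# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths.

# discrete Frechet by exhaustive recursion over monotone couplings
brute_frechet <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  memo <- new.env()
  d <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 1 && j == 1) d(1, 1)
    else if (i == 1) max(rec(1, j - 1), d(1, j))
    else if (j == 1) max(rec(i - 1, 1), d(i, 1))
    else max(min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1)), d(i, j))
    memo[[key]] <- val
    val
  }
  rec(nrow(a), nrow(b))
}

# maximum-weight assignment by permutation enumeration (n <= 6)
brute_assignment_max <- function(sim) {
  if (nrow(sim) > ncol(sim)) sim <- t(sim)
  n <- nrow(sim); m <- ncol(sim)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(m))) {
    val <- sum(sim[cbind(seq_len(n), p[seq_len(n)])])
    if (val > best) best <- val
  }
  best
}

# independent fixed-point neighbor-matching oracle (adjacency matrices,
# permutation assignment, tight eps)
oracle_neighbor_matching <- function(adj1, adj2, eps = 1e-6, max_iter = 500) {
  n1 <- nrow(adj1); n2 <- nrow(adj2)
  deg1 <- rowSums(adj1); deg2 <- rowSums(adj2)
  x <- matrix(1, n1, n2)
  for (it in seq_len(max_iter)) {
    xn <- matrix(0, n1, n2)
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      ni <- which(adj1[i, ] > 0); nj <- which(adj2[j, ] > 0)
      dmax <- max(deg1[i], deg2[j])
      xn[i, j] <- if (dmax == 0) 1
      else if (!length(ni) || !length(nj)) 0
      else brute_assignment_max(x[ni, nj, drop = FALSE]) / dmax
    }
    if (max(abs(xn - x)) < eps) { x <- xn; break }
    x <- xn
  }
  brute_assignment_max(x) / max(n1, n2)
}

# Jaro-Winkler by an independent boolean-matrix formulation
oracle_jw <- function(s1, s2, p = 0.1, max_l = 4) {
  a <- utf8ToInt(s1); b <- utf8ToInt(s2)
  if (!length(a) && !length(b)) return(list(jaro = 1, jw = 1))
  if (!length(a) || !length(b)) return(list(jaro = 0, jw = 0))
  win <- max(0, floor(max(length(a), length(b)) / 2) - 1)
  used_b <- logical(length(b)); ma <- integer(0); mb <- integer(0)
  for (i in seq_along(a)) {
    lo <- max(1, i - win); hi <- min(length(b), i + win)
    if (lo > hi) next
    for (j in lo:hi) if (!used_b[j] && a[i] == b[j]) {
      used_b[j] <- TRUE; ma <- c(ma, i); mb <- c(mb, j); break
    }
  }
  m <- length(ma)
  if (!m) return(list(jaro = 0, jw = 0))
  t <- sum(a[ma] != b[sort(mb)]) / 2
  jaro <- mean(c(m / length(a), m / length(b), (m - t) / m))
  l <- 0
  for (i in seq_len(min(length(a), length(b), max_l))) {
    if (a[i] == b[i]) l <- l + 1 else break
  }
  list(jaro = jaro, jw = jaro + l * p * (1 - jaro))
}

random_curve <- function(n, scale = 10) {
  cbind(stats::runif(n, 0, scale), stats::runif(n, 0, scale))
}

make_sine_clip <- function(freq, duration_s = 1, rate = 48000, amp = 0.8) {
  t <- seq_len(round(duration_s * rate)) / rate
  audio_clip(amp * sin(2 * pi * freq * t), rate)
}

# tiny separable 2-class tabular problem
toy_clusters <- function(n_per = 20, gap = 6, d = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d, mean = gap), n_per))
  list(X = X, y = rep(c(0L, 1L), each = n_per))
}

zero_effects <- function() {
  e <- cogscreen:::healthy_effect_defaults()
  e$tremor_amp_px <- 0; e$jitter_px <- 0; e$latency_shift_ms <- 0
  e
}
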