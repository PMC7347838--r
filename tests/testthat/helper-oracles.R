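# Independent oracles used to freeze expected values. These deliberately
# use different algorithms from the package implementation.

# ---- exact big-integer arithmetic (little-endian base-1e7 digit vectors)

big_norm <- function(r) {
  carry <- 0
  for (i in seq_along(r)) {
    v <- r[i] + carry
    r[i] <- v %% 1e7
    carry <- v %/% 1e7
  }
  while (carry > 0) {
    r <- c(r, carry %% 1e7)
    carry <- carry %/% 1e7
  }
  while (length(r) > 1 && r[length(r)] == 0) r <- r[-length(r)]
  r
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    ix <- i:(i + length(b) - 1)
    res[ix] <- res[ix] + a[i] * b
  }
  big_norm(res)
}

big_to_num <- function(a) sum(a * 1e7^(seq_along(a) - 1))

# Pascal's triangle of exact binomial coefficients, rows 0..nmax
big_pascal <- function(nmax) {
  rows <- vector("list", nmax + 1)
  rows[[1]] <- list(1)
  for (n in seq_len(nmax)) {
    prev <- rows[[n]]
    row <- vector("list", n + 1)
    row[[1]] <- 1
    row[[n + 1]] <- 1
    if (n > 1) {
      for (k in 2:n) row[[k]] <- big_add(prev[[k - 1]], prev[[k]])
    }
    rows[[n + 1]] <- row
  }
  rows
}

# exact upper-tail hypergeometric P(X >= k) as a ratio of big integers
oracle_hyper_upper <- function(N, K, n, k, pascal) {
  if (k > min(K, n)) return(0)
  num <- 0
  for (i in seq(k, min(K, n))) {
    if (i < 0 || n - i < 0 || n - i > N - K) next
    term <- big_mul(pascal[[K + 1]][[i + 1]], pascal[[N - K + 1]][[n - i + 1]])
    num <- big_add(num, term)
  }
  big_to_num(num) / big_to_num(pascal[[N + 1]][[n + 1]])
}

# ---- brute-force rearrangement-event oracle (exhaustive subsets, n <= ~12)

oracle_rearrangement_events <- function(tpos, strand) {
  n <- length(tpos)
  best <- NULL
  for (orient in c("+", "-")) {
    if (!any(strand == orient)) next
    bestO <- NULL
    for (mask in seq_len(2^n - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (any(strand[S] != orient)) next
      tp <- tpos[S]
      if (length(tp) > 1) {
        if (orient == "+" && any(diff(tp) <= 0)) next
        if (orient == "-" && any(diff(tp) >= 0)) next
      }
      comp <- setdiff(seq_len(n), S)
      runs <- if (length(comp) == 0) 0 else sum(diff(comp) > 1) + 1
      cand <- c(length(S), runs)
      if (is.null(bestO) || cand[1] > bestO[1] ||
          (cand[1] == bestO[1] && cand[2] < bestO[2])) bestO <- cand
    }
    if (is.null(bestO)) next
    if (is.null(best) || bestO[1] > best[1] ||
        (bestO[1] == best[1] && bestO[2] < best[2])) best <- bestO
  }
  best[2]
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# ---- brute-force N50/L50 over all prefix sets of the sorted lengths

oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(as.numeric(s))
  for (i in seq_along(s)) {
    if (sum(as.numeric(s[1:i])) >= tot / 2) return(list(n50 = s[i], l50 = i))
  }
}

# ---- brute-force junction support (per-read loop, no vectorization)

oracle_span_support <- function(junctions, aln, min_flank, min_mapq) {
  vapply(seq_len(nrow(junctions)), function(i) {
    cnt <- 0
    for (r in seq_len(nrow(aln))) {
      if (aln$tname[r] != junctions$seq_id[i]) next
      if (aln$mapq[r] < min_mapq) next
      left <- junctions$pos[i] - aln$tstart[r]
      right <- aln$tend[r] - junctions$pos[i]
      if (left >= min_flank && right >= min_flank) cnt <- cnt + 1
    }
    cnt
  }, numeric(1))
}
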