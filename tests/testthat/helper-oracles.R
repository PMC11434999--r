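# Independent oracles used to cross-check the package implementations.

# Two-sided Fisher exact p by direct enumeration of all tables with the
# observed margins, point probabilities from log-binomial coefficients
# (independent of the dhyper-based package route). Ties admitted at the
# same 1e-7 relative tolerance the test definition states.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  lp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  p <- exp(lp)
  p_obs <- p[a - lo + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Brute-force Ward minimum-variance agglomeration: at every step merge the
# pair of clusters whose union minimally increases the total within-cluster
# sum of squares, recomputed from scratch. Returns, per step, the two
# merged member sets (sorted) and the SS increase.
oracle_ward_merges <- function(x) {
  cl <- lapply(seq_len(nrow(x)), identity)
  ss <- function(idx) {
    if (length(idx) == 1) return(0)
    xc <- x[idx, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }
  merges <- vector("list", nrow(x) - 1)
  for (s in seq_along(merges)) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      d <- ss(c(cl[[i]], cl[[j]])) - ss(cl[[i]]) - ss(cl[[j]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
    }
    merges[[s]] <- list(sets = list(sort(cl[[best[1]]]), sort(cl[[best[2]]])),
                        delta_ss = best_d)
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  merges
}

# Canonical string for a pair of merged member sets (order-free).
merge_key <- function(sets) {
  s <- lapply(sets, sort)
  s <- s[order(vapply(s, `[`, numeric(1), 1))]
  paste(vapply(s, paste, "", collapse = ","), collapse = "|")
}

# Merge sets of an hclust tree, per step.
hclust_merges <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    a <- get(hc$merge[s, 1]); b <- get(hc$merge[s, 2])
    sets[[s]] <- c(a, b)
    out[[s]] <- list(sets = list(sort(a), sort(b)), height = hc$height[s])
  }
  out
}

# Rand index between two partitions (plain, not adjusted).
rand_index <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  s <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * s - a - b) / choose(n, 2)
}
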