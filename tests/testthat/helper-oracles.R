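# Independent brute-force oracles used to validate the statistical
# primitives.  These deliberately re-derive every quantity from first
# principles, sharing no code with the package internals.

# Tie-corrected Kruskal-Wallis H computed directly from the formula.
kw_H_direct <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gs <- split(r, groups)
  H <- 12 / (N * (N + 1)) * sum(vapply(gs, function(g)
    sum(g)^2 / length(g), numeric(1))) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else H / corr
}

# Enumerate all distinct assignments of the observations to groups with the
# observed group sizes; exact permutation p = fraction of assignments with
# H >= observed H.
perm_kw_p <- function(values, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  labs <- names(sizes)
  n <- length(values)
  h_obs <- kw_H_direct(values, groups)
  assignments <- list(rep(NA_character_, n))
  avail <- function(a) which(is.na(a))
  # recursively choose index sets for each group
  build <- function(a, gi) {
    if (gi > length(labs)) return(list(a))
    free <- which(is.na(a))
    picks <- utils::combn(free, sizes[[gi]], simplify = FALSE)
    out <- list()
    for (p in picks) {
      a2 <- a
      a2[p] <- labs[gi]
      out <- c(out, build(a2, gi + 1))
    }
    out
  }
  # fix the last group's members implicitly by enumerating all but skipping
  # duplicates: combn over remaining handles it naturally
  all_a <- build(rep(NA_character_, n), 1)
  hs <- vapply(all_a, function(a) kw_H_direct(values, a), numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins.
fisher_enum_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand implementation of the BH step-up adjustment.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Naive Ward agglomeration: Lance-Williams recurrence on squared
# dissimilarities, returning the sequence of merge heights (on the original
# distance scale, i.e. sqrt of the squared-criterion values).
ward_oracle_heights <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (D2[i, j] < bestv) { bestv <- D2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Small labelled two-class Gaussian dataset with named marker columns.
make_two_class <- function(n0, n1, delta, p_noise = 0, sd = 1, seed = 1) {
  set.seed(seed)
  p <- length(delta) + p_noise
  x <- matrix(rnorm((n0 + n1) * p, sd = sd), n0 + n1, p,
              dimnames = list(NULL, paste0("m", seq_len(p))))
  y <- c(rep(FALSE, n0), rep(TRUE, n1))
  for (j in seq_along(delta)) x[y, j] <- x[y, j] + delta[j]
  list(x = x, y = y)
}

# Cohort-table builder for hand-crafted matrices.
toy_cohort <- function(values, ids = NULL) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("mk", seq_len(ncol(values)))
  }
  if (!is.null(ids)) rownames(values) <- ids
  mk <- do.call(rbind, lapply(colnames(values), function(id)
    marker_descriptor(id, "global", id, "concentration", "ng/mL")))
  cohort_table(values, markers = mk)
}
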