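## Shared fixtures and independent oracles for the test suite.

## small asymmetric map with deterministic, pixel-identifiable values
tiny_map <- function(height = 2, width = 3, axis = wn_axis(c(100, 110, 125))) {
  cube <- array(0, dim = c(height, width, length(axis)))
  for (r in seq_len(height)) for (cl in seq_len(width))
    cube[r, cl, ] <- (r * 100 + cl * 10) + seq_along(axis)
  hyperspec_map(axis, cube, pixel_size = 1)
}

## dense closed-form Lorentzian evaluation (oracle for band quantifiers)
lorentz <- function(nu, center, hwhm, amp) amp * hwhm^2 / ((nu - center)^2 + hwhm^2)

## brute-force exact k-partition minimiser of within-cluster sum of squares
## (oracle for the radius-0 SOM / k-means equivalence on tiny instances)
brute_force_wss <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 12)
  best <- Inf
  assign_wss <- function(lab) {
    s <- 0
    for (j in unique(lab)) {
      mem <- X[lab == j, , drop = FALSE]
      ctr <- colMeans(mem)
      s <- s + sum(sweep(mem, 2, ctr)^2)
    }
    s
  }
  ## enumerate all label vectors over k symbols (small n only)
  grid <- rep(list(seq_len(k)), n)
  labs <- as.matrix(expand.grid(grid))
  for (i in seq_len(nrow(labs))) {
    lab <- labs[i, ]
    if (length(unique(lab)) < k) next
    s <- assign_wss(lab)
    if (s < best) best <- s
  }
  best
}

wss_of_result <- function(X, labels) {
  s <- 0
  for (j in unique(labels)) {
    mem <- X[labels == j, , drop = FALSE]
    ctr <- colMeans(mem)
    s <- s + sum(sweep(mem, 2, ctr)^2)
  }
  s
}

## hand rank-arithmetic Kruskal-Wallis H (tie-corrected) -- independent of
## stats::kruskal.test
hand_kw_h <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

## hand Dunn z for a pair of groups within a full set
hand_dunn_z <- function(groups, i, j) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  ties <- table(values)
  v <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (rbar[i] - rbar[j]) /
    sqrt(v * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
}

## a small noiseless two-group map for clustering tests: `na` pixels of
## spectrum a, `nb` of spectrum b, on a 1 x (na+nb) grid
two_group_map <- function(a, b, na = 4, nb = 4, axis = wn_axis(seq_len(length(a)))) {
  cube <- array(0, dim = c(1, na + nb, length(a)))
  for (i in seq_len(na)) cube[1, i, ] <- a
  for (i in seq_len(nb)) cube[1, na + i, ] <- b
  hyperspec_map(axis, cube)
}
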