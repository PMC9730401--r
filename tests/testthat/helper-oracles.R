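# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation).

oracle_overlap_counts <- function(a, b) {
  n_a <- 0L; n_b <- 0L; n_ab <- 0L; n_union <- 0L
  for (i in seq_along(a)) {
    ai <- a[i] == 1; bi <- b[i] == 1
    if (ai) n_a <- n_a + 1L
    if (bi) n_b <- n_b + 1L
    if (ai && bi) n_ab <- n_ab + 1L
    if (ai || bi) n_union <- n_union + 1L
  }
  list(a = n_a, b = n_b, ab = n_ab, union = n_union)
}

oracle_dice <- function(a, b) {
  cnt <- oracle_overlap_counts(a, b)
  if (cnt$a + cnt$b == 0) return(1)
  2 * cnt$ab / (cnt$a + cnt$b)
}

oracle_jaccard <- function(a, b) {
  cnt <- oracle_overlap_counts(a, b)
  if (cnt$union == 0) return(1)
  cnt$ab / cnt$union
}

# 6-neighbor surface scan by explicit voxel loop (3D only).
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    on_surface <- FALSE
    for (nb in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                    c(0, 0, -1), c(0, 0, 1))) {
      ii <- i + nb[1]; jj <- j + nb[2]; kk <- k + nb[3]
      outside <- ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]
      if (outside || mask[ii, jj, kk] != 1) { on_surface <- TRUE; break }
    }
    if (on_surface) out <- rbind(out, c(i, j, k))
  }
  if (is.null(out)) matrix(integer(), 0, 3) else out
}

# linear-interpolation percentile on a sorted copy (quantile type 7 rule,
# written out directly)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 2 > n) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# all-pairs directed surface distances in mm
oracle_directed_dists <- function(sa, sb, spacing) {
  out <- numeric(nrow(sa))
  for (i in seq_len(nrow(sa))) {
    best <- Inf
    for (j in seq_len(nrow(sb))) {
      s <- 0
      for (k in seq_len(ncol(sa))) {
        dv <- (sa[i, k] - sb[j, k]) * spacing[k]
        s <- s + dv * dv
      }
      if (s < best) best <- s
    }
    out[i] <- sqrt(best)
  }
  out
}

oracle_hd95 <- function(a, b, spacing) {
  sa <- oracle_surface(a); sb <- oracle_surface(b)
  dab <- oracle_directed_dists(sa, sb, spacing)
  dba <- oracle_directed_dists(sb, sa, spacing)
  oracle_percentile(c(dab, dba), 0.95)
}

oracle_ahd <- function(a, b, spacing) {
  sa <- oracle_surface(a); sb <- oracle_surface(b)
  0.5 * (mean(oracle_directed_dists(sa, sb, spacing)) +
           mean(oracle_directed_dists(sb, sa, spacing)))
}

# centroid by explicit moment sums
oracle_centroid <- function(mask2d) {
  sr <- 0; sc <- 0; n <- 0
  for (i in seq_len(nrow(mask2d))) for (j in seq_len(ncol(mask2d))) {
    if (mask2d[i, j] == 1) { sr <- sr + i; sc <- sc + j; n <- n + 1 }
  }
  c(sr / n, sc / n)
}
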