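# Independent oracles used across the suite. These deliberately take a
# different computational route than the package code they check.

# Brute-force MaxLFQ oracle: assemble the full pairwise-difference design
# matrix and solve the least-squares system with a pseudo-inverse (the
# minimum-norm solution is sum-zero on each connected component), then
# anchor each component to its summed observed intensity.
oracle_maxlfq <- function(mat, min_shared = 1) {
  m <- mat
  m[!is.na(m) & m <= 0] <- NA
  nc <- ncol(m)
  lm2 <- log2(m)
  rows <- list()
  rvec <- numeric(0)
  adj <- matrix(FALSE, nc, nc)
  for (a in seq_len(nc - 1)) {
    for (b in seq(a + 1, nc)) {
      sh <- which(!is.na(lm2[, a]) & !is.na(lm2[, b]))
      if (length(sh) < min_shared) next
      row <- numeric(nc)
      row[a] <- -1
      row[b] <- 1
      rows[[length(rows) + 1]] <- row
      rvec <- c(rvec, median(lm2[sh, b] - lm2[sh, a]))
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  observed <- colSums(!is.na(m)) > 0
  reach <- adj
  diag(reach) <- TRUE
  for (i in seq_len(nc)) reach <- (reach %*% reach) > 0  # transitive closure
  comp <- rep(NA_integer_, nc)
  cid <- 0L
  for (j in which(observed)) {
    if (!is.na(comp[j])) next
    cid <- cid + 1L
    comp[reach[j, ] & observed] <- cid
  }
  A <- if (length(rows) > 0) do.call(rbind, rows) else matrix(0, 0, nc)
  out <- rep(NA_real_, nc)
  for (k in seq_len(cid)) {
    cols <- which(comp == k)
    total <- sum(m[, cols], na.rm = TRUE)
    if (length(cols) == 1) {
      out[cols] <- total
      next
    }
    sel <- which(apply(A[, cols, drop = FALSE] != 0, 1, any))
    x <- as.numeric(MASS::ginv(A[sel, cols, drop = FALSE]) %*% rvec[sel])
    out[cols] <- 2^(x + log2(total) - log2(sum(2^x)))
  }
  names(out) <- colnames(mat)
  out
}

# random small precursor-by-column matrix with missingness
random_peptide_matrix <- function(ncol_max = 6, nrow_max = 8, missing = 0.3) {
  nc <- sample(2:ncol_max, 1)
  nr <- sample(1:nrow_max, 1)
  m <- matrix(2^rnorm(nr * nc, 15, 2), nr, nc)
  m[runif(nr * nc) < missing] <- NA
  if (all(is.na(m))) m[1, 1] <- 1000
  colnames(m) <- paste0("c", seq_len(nc))
  m
}

expect_same_lfq <- function(got, want, tol = 1e-9) {
  expect_identical(is.na(got), is.na(want))
  ok <- !is.na(got)
  if (any(ok)) {
    expect_lt(max(abs(got[ok] - want[ok]) / pmax(abs(want[ok]), 1e-300)), tol)
  }
}

# exact hypergeometric upper tail by direct enumeration of combinations
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# minimal hand-built precursor tibble for io/filter tests
make_precursor_tbl <- function(n = 3, protein_group = paste0("P", seq_len(n)),
                               q = 0.001, cq = 0.001, tq = 0.001) {
  tibble::tibble(
    protein_group = protein_group,
    gene = paste0("G", seq_len(n)),
    stripped_sequence = paste0("PEPTIDE", LETTERS[seq_len(n)], "K"),
    modified_sequence = paste0("PEPTIDE", LETTERS[seq_len(n)], "K"),
    charge = 2L,
    channel = rep(c("L", "M", "H"), length.out = n),
    run = "run1",
    ms1_quantity = 1000 + seq_len(n),
    ms2_quantity = 2000 + seq_len(n),
    q_value = rep_len(q, n),
    channel_q_value = rep_len(cq, n),
    translated_q_value = rep_len(tq, n),
    is_contaminant = FALSE)
}

# compare precursor records ignoring provenance attributes
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}
expect_same_records <- function(a, b) {
  expect_identical(strip_attrs(a), strip_attrs(b))
}
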