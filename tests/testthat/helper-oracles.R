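# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive loops and first-principles
# formulas, not the package's code paths.

# co-occurrence counts by explicit pixel-pair enumeration
naive_glcm <- function(gray, mask, offset, Ng) {
  q <- perirad::quantize_gray(gray, Ng)
  counts <- matrix(0, Ng, Ng)
  nr <- nrow(gray); nc <- ncol(gray)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        mask[r, c] && mask[r2, c2]) {
      counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
    }
  }
  counts <- counts + t(counts)
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# the seven Haralick statistics from first-principles loops
naive_haralick <- function(P) {
  Ng <- nrow(P)
  asm <- 0; contrast <- 0; entropy <- 0
  p_sum <- rep(0, 2 * Ng); p_diff <- rep(0, Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    if (p > 0) entropy <- entropy - p * log2(p)
    p_sum[i + j] <- p_sum[i + j] + p
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + p
  }
  sum_avg <- sum((1:(2 * Ng)) * p_sum)
  sum_var <- sum(((1:(2 * Ng)) - sum_avg)^2 * p_sum)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  c(asm = asm, contrast = contrast, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = ent(p_sum),
    entropy = entropy, difference_entropy = ent(p_diff))
}

# run-length counts by explicit line walking
naive_glrlm <- function(gray, mask, direction, Ng) {
  q <- perirad::quantize_gray(gray, Ng)
  nr <- nrow(gray); nc <- ncol(gray)
  step <- switch(direction, h = c(0, 1), v = c(1, 0), d = c(1, 1),
                 a = c(1, -1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    inside_prev <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc
    if (!inside_prev) starts[[length(starts) + 1]] <- c(r, c)
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_lev <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      lev <- if (mask[r, c]) q[r, c] else NA
      if (!is.na(lev) && !is.na(cur_lev) && lev == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- lev; cur_len <- if (is.na(lev)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (length(runs) == 0) return(matrix(0, Ng, 1))
  rmax <- max(vapply(runs, `[`, 0, 2))
  m <- matrix(0, Ng, rmax)
  for (rn in runs) m[rn[1], rn[2]] <- m[rn[1], rn[2]] + 1
  m
}

naive_glrlm_stats <- function(R, n_pixels) {
  nr <- sum(R)
  out <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = 0, lgre = 0, hgre = 0,
           srlge = 0, srhge = 0, lrlge = 0, lrhge = 0)
  for (l in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    x <- R[l, j]
    out["sre"] <- out["sre"] + x / j^2
    out["lre"] <- out["lre"] + x * j^2
    out["lgre"] <- out["lgre"] + x / l^2
    out["hgre"] <- out["hgre"] + x * l^2
    out["srlge"] <- out["srlge"] + x / (l^2 * j^2)
    out["srhge"] <- out["srhge"] + x * l^2 / j^2
    out["lrlge"] <- out["lrlge"] + x * j^2 / l^2
    out["lrhge"] <- out["lrhge"] + x * j^2 * l^2
  }
  out[c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")] <-
    out[c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")] / nr
  out["gln"] <- sum(rowSums(R)^2) / nr
  out["rln"] <- sum(colSums(R)^2) / nr
  out["rp"] <- nr / n_pixels
  out
}

# AUC by counting all positive/negative pairs, ties half credit
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# random masked test image
random_masked_image <- function(nr, nc, p_mask = 0.7) {
  gray <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) < p_mask, nr, nc)
  list(gray = gray, mask = mask)
}

# small deterministic disk mask
disk_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((ii - center[1])^2 + (jj - center[2])^2) <= r
}

# small flat-lung phantom slice wrapper for region tests
flat_ct <- function(mat, spacing = 1) perirad::ct_slice(mat, spacing, "test")
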