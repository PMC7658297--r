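# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops over windows, pairs and thresholds) so
# they share no code path with the implementation they check.

AA <- AA_ALPHABET

random_sequence <- function(len) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

# CKSAAP by naive window enumeration: walk every position, paste the pair
# label, count into a named table.
naive_cksaap <- function(seq, gap) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  counts <- stats::setNames(rep(0, 400),
                            paste0(rep(AA, each = 20), AA))
  for (j in seq_len(n - gap - 1)) {
    pair <- paste0(chars[j], chars[j + gap + 1])
    counts[pair] <- counts[pair] + 1
  }
  counts / (n - gap - 1)
}

# CT by naive triple loop over the 343 class triads.
naive_ct <- function(seq) {
  cls_map <- ct_class_map()
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  v <- numeric(0)
  for (c1 in 1:7) for (c2 in 1:7) for (c3 in 1:7) {
    cnt <- 0
    for (j in seq_len(n - 2)) {
      if (cls_map[[chars[j]]] == c1 && cls_map[[chars[j + 1]]] == c2 &&
          cls_map[[chars[j + 2]]] == c3) cnt <- cnt + 1
    }
    v <- c(v, cnt)
  }
  (v - min(v)) / max(v)
}

# Textbook Pearson correlation, written out term by term.
naive_pcc <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  den <- sqrt(sum((x - mean(x))^2) / (n - 1)) *
    sqrt(sum((y - mean(y))^2) / (n - 1))
  num / den
}

# MRMD terms by explicit double loops over features.
naive_mrmd <- function(x, labels, scale = TRUE) {
  m <- ncol(x)
  if (scale) {
    xs <- x
    for (i in seq_len(m)) {
      rng <- range(x[, i])
      xs[, i] <- if (diff(rng) == 0) 0 else (x[, i] - rng[1]) / diff(rng)
    }
  } else xs <- x
  mr <- md <- numeric(m)
  for (i in seq_len(m)) {
    mr[i] <- abs(naive_pcc(x[, i], as.numeric(labels)))
    s <- 0
    for (k in seq_len(m)) {
      if (k != i) s <- s + sqrt(sum((xs[, i] - xs[, k])^2))
    }
    md[i] <- s / (m - 1)
  }
  list(MR = mr, MD = md, score = mr + md)
}

# AUC as the normalized Mann-Whitney U statistic: exhaustive pair counting
# with ties at half weight.
naive_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Small labeled feature matrix with two informative and some noise columns.
toy_feature_matrix <- function(n_pos = 20, n_neg = 30, n_noise = 4,
                               seed = 42) {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), c(n_pos, n_neg))
    n <- n_pos + n_neg
    x <- cbind(sig1 = labels + rnorm(n, sd = 0.3),
               sig2 = -labels + rnorm(n, sd = 0.3),
               matrix(runif(n * n_noise), n,
                      dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
    rownames(x) <- paste0("s", seq_len(n))
    feature_matrix(x, labels)
  })
}
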