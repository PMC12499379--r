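# Independent brute-force oracles and fixture generators. These stay
# deliberately naive (explicit loops, textbook formulas) so they cannot
# share a defect with the vectorized implementations they check.

# insulation ratio by explicit block means
oracle_insulation <- function(v, w) {
  n <- nrow(v)
  vals <- v[!is.na(v)]
  const <- mean(vals[vals != 0])
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    ls <- 0; lc <- 0; rs <- 0; rc <- 0; ms <- 0; mc <- 0
    for (a in (i - w):(i - 1)) for (b in (i - w):(i - 1)) {
      if (!is.na(v[a, b])) { ls <- ls + v[a, b]; lc <- lc + 1 }
    }
    for (a in (i + 1):(i + w)) for (b in (i + 1):(i + w)) {
      if (!is.na(v[a, b])) { rs <- rs + v[a, b]; rc <- rc + 1 }
    }
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) {
      if (!is.na(v[a, b])) { ms <- ms + v[a, b]; mc <- mc + 1 }
    }
    out[i] <- (ls / lc + rs / rc + const) / (ms / mc + const)
  }
  out
}

# loop nesting oracle: explicit scans and a parent-tree descent
oracle_hierarchy <- function(lower, upper) {
  n <- length(lower)
  encloses <- function(b, a) {  # loop b encloses loop a
    lower[b] <= lower[a] && upper[a] <= upper[b] &&
      !(lower[a] == lower[b] && upper[a] == upper[b])
  }
  parent <- rep(NA_integer_, n)
  is_main <- rep(TRUE, n)
  for (a in seq_len(n)) {
    best <- NA_integer_
    for (b in seq_len(n)) {
      if (b == a || !encloses(b, a)) next
      is_main[a] <- FALSE
      if (is.na(best) ||
          (upper[b] - lower[b]) < (upper[best] - lower[best])) {
        best <- b
      }
    }
    parent[a] <- best
  }
  valency <- rep(NA_integer_, n)
  for (m in which(is_main)) {
    count <- 0
    for (a in seq_len(n)) {
      if (a != m && encloses(m, a)) count <- count + 1
    }
    valency[m] <- count
  }
  list(parent = parent, is_main = is_main, valency = valency)
}

# Mann-Whitney style AUROC by exhaustive pair comparison
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# textbook Pearson r by explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random symmetric positive contact matrix
random_positive_matrix <- function(n, seed) {
  set.seed(seed)
  v <- matrix(stats::runif(n * n, 0.5, 5), n, n)
  (v + t(v)) / 2
}

# random laminar-friendly interval set on one chromosome
random_loop_set <- function(n, seed, span = 1000) {
  set.seed(seed)
  lower <- sample.int(span, n, replace = TRUE)
  width <- sample.int(span / 2, n, replace = TRUE)
  loop_table("chrT", lower, lower + width)
}

# planted checkerboard contact matrix and its labels
make_checkerboard <- function(n_bins = 120, block = 20, intra = 3,
                              inter = 1) {
  lab <- rep(rep(c("A", "B"), length.out = ceiling(n_bins / block)),
             each = block)[seq_len(n_bins)]
  s <- ifelse(lab == "A", 1, -1)
  v <- ifelse(outer(s, s) > 0, intra, inter)
  diag(v) <- intra
  list(m = contact_matrix(v, 1e5), labels = lab)
}

# label agreement up to a global A/B swap
label_accuracy <- function(called, truth) {
  flip <- ifelse(truth == "A", "B", "A")
  max(mean(called == truth), mean(called == flip))
}
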