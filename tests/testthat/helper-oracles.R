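# Independent oracles used to cross-check the package's own implementations.
# They share only the published constants / energy tables, never code paths.

# ---- exhaustive single-stem folding oracle ---------------------------------
# Memoised top-down enumeration of all single-hairpin structures (one chain of
# nested pairs; stacks, bulges, internal loops; hairpin loop >= 3). No cap on
# interior loop size, so for n <= 30 it covers strictly every structure the
# engine can build.
oracle_fold_energy <- function(seq, params = folding_params()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pt <- function(i, j) {
    p <- paste0(ch[i], ch[j])
    if (p %in% rownames(params$stack)) p else NA_character_
  }
  js <- params$js_coef
  tabval <- function(tab, size, lo) {
    hi <- lo + length(tab) - 1L
    if (size < lo) return(Inf)
    if (size <= hi) return(tab[size - lo + 1L])
    tab[length(tab)] + js * log(size / hi)
  }
  memo <- new.env()
  closed <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    p_out <- pt(i, j)
    if (is.na(p_out) || j - i - 1 < 3) {
      memo[[key]] <- Inf
      return(Inf)
    }
    best <- tabval(params$hairpin, j - i - 1L, 3L)
    for (k in seq(i + 1, j - 5, length.out = max(0, j - 5 - i))) {
      for (l in seq(k + 4, j - 1, length.out = max(0, j - 4 - k))) {
        inner <- closed(k, l)
        if (!is.finite(inner)) next
        s1 <- k - i - 1L
        s2 <- j - l - 1L
        e <- if (s1 == 0 && s2 == 0) {
          params$stack[p_out, pt(k, l)]
        } else if (s1 == 0 || s2 == 0) {
          tabval(params$bulge, s1 + s2, 1L)
        } else {
          tabval(params$internal, s1 + s2, 2L) +
            min(params$asym_max, params$asym_coef * abs(s1 - s2))
        }
        best <- min(best, inner + e)
      }
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  if (n >= 5) {
    for (i in 1:(n - 4)) {
      for (j in (i + 4):n) {
        best <- min(best, closed(i, j))
      }
    }
  }
  best
}

# ---- brute-force one-mismatch mapping oracle (Biostrings) ------------------
oracle_map <- function(tag, genome, max_mm = 1L) {
  rows <- list()
  for (ci in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ci]])
    fwd <- Biostrings::matchPattern(tag, subj, max.mismatch = max_mm)
    if (length(fwd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ci, start = BiocGenerics::start(fwd) - 1L,
        end = BiocGenerics::end(fwd), strand = "+")
    }
    rev <- Biostrings::matchPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag))),
      subj, max.mismatch = max_mm)
    if (length(rev)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ci, start = BiocGenerics::start(rev) - 1L,
        end = BiocGenerics::end(rev), strand = "-")
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  do.call(rbind, rows)
}

# ---- plain R DP for the seed-weighted duplex score -------------------------
oracle_duplex_score <- function(mirna, window) {
  L <- nchar(mirna)
  N <- nchar(window)
  r <- paste(rev(strsplit(mirna, "")[[1]]), collapse = "")
  rv <- strsplit(r, "")[[1]]
  uv <- strsplit(window, "")[[1]]
  w <- vapply(seq_len(L), function(i) {
    p <- L + 1 - i
    if (p >= 2 && p <= 8) 4 else 1
  }, numeric(1))
  subsc <- function(a, b) {
    wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")
    wob <- (a == "G" && b == "T") || (a == "T" && b == "G")
    if (wc) 5 else if (wob) 1 else -3
  }
  M <- matrix(0, L + 1, N + 1)
  Ix <- matrix(-Inf, L + 1, N + 1)
  Iy <- matrix(-Inf, L + 1, N + 1)
  best <- 0
  for (i in 1:L) {
    for (j in 1:N) {
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) +
                                  w[i] * subsc(rv[i], uv[j]))
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - 9 * w[i], Ix[i, j + 1] - 4 * w[i])
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - 9, Iy[i + 1, j] - 4)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# ---- exact hypergeometric tail for one-sided Fisher ------------------------
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b   # targets
  k <- a + c    # with term
  n_tot <- a + b + c + d
  ks <- a:min(m1, k)
  sum(choose(k, ks) * choose(n_tot - k, m1 - ks)) / choose(n_tot, m1)
}

random_tag <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# ---- adjusted Rand index (closed form over the contingency table) ----------
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
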