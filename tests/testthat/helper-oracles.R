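# Independent oracles used by the tests. Each is a deliberately naive
# implementation (brute force / enumeration / dynamic programming) that
# shares no code with the package's algorithms.

# Per-position copy numbers by union-find over aligned position pairs of
# GAPLESS chains (one node per genome position).
oracle_position_copy_number <- function(chains, scaffold_lengths) {
  offs <- c(0, cumsum(as.numeric(scaffold_lengths)))
  names(offs) <- c(names(scaffold_lengths), "_end")
  total <- sum(scaffold_lengths)
  parent <- seq_len(total)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  gid <- function(scaf, pos) as.integer(offs[[scaf]] + pos)
  for (ch in chains) {
    stopifnot(nrow(ch$blocks) == 1) # oracle handles gapless chains only
    b <- ch$blocks
    for (o in 0:(b$len - 1)) {
      qo <- if (ch$strand == "+") o else b$len - 1 - o
      a <- find(gid(ch$target, b$tstart + o))
      z <- find(gid(ch$query, b$qstart + qo))
      if (a != z) parent[a] <- z
    }
  }
  roots <- vapply(seq_len(total), find, integer(1))
  sizes <- table(roots)
  cn <- as.integer(sizes[as.character(roots)])
  split(cn, rep(names(scaffold_lengths), scaffold_lengths))
}

# Edit distance counting a substitution as 1 and a gap run of any length as
# 1 (three-state affine DP with gap open 1, extend 0).
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  INF <- 1e9
  M <- X <- Y <- matrix(INF, n + 1, m + 1)
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- 1  # gap run consuming a
  Y[1, 2:(m + 1)] <- 1
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- as.integer(a[i - 1] != b[j - 1])
      M[i, j] <- min(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- min(M[i - 1, j] + 1, X[i - 1, j], Y[i - 1, j] + 1)
      Y[i, j] <- min(M[i, j - 1] + 1, Y[i, j - 1], X[i, j - 1] + 1)
    }
  }
  min(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Naive canonical k-mer counter on plain strings.
oracle_count_kmers <- function(seqs, k) {
  revcomp_str <- function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    subs <- substring(s, 1:(n - k + 1), k:n)
    subs[!grepl("[^ACGT]", subs)]
  }))
  canon <- pmin(all, vapply(all, revcomp_str, character(1)))
  table(canon)
}

# Brute-force scaffold-specific mappability by canonical K-mer strings.
oracle_mappability <- function(seqs, K) {
  revcomp_str <- function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rows <- list()
  for (sc in names(seqs)) {
    s <- seqs[[sc]]
    n <- nchar(s) - K + 1
    if (n < 1) next
    w <- substring(s, 1:n, K:nchar(s))
    canon <- pmin(w, vapply(w, revcomp_str, character(1)))
    rows[[sc]] <- data.frame(scaffold = sc, pos = 1:n, kmer = canon)
  }
  df <- do.call(rbind, rows)
  nscaf <- tapply(df$scaffold, df$kmer, function(x) length(unique(x)))
  out <- lapply(names(seqs), function(sc) {
    d <- df[df$scaffold == sc, , drop = FALSE]
    as.integer(nscaf[d$kmer] == 1)
  })
  names(out) <- names(seqs)
  out
}

# Exhaustive multiplicity-pair enumeration over haplovariant subsets.
oracle_multiplicities <- function(configA, configB) {
  alphabet <- sort(unique(c(configA, configB)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(alphabet)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  pairs <- apply(combos, 1, function(sel) {
    u <- alphabet[as.logical(sel)]
    c(sum(configA %in% u), sum(configB %in% u))
  })
  unique(t(pairs))
}

# Monte-Carlo read placement for the mapping-bias closed form.
oracle_mapping_bias_mc <- function(f, n = 4e5, seed = 99) {
  set.seed(seed)
  origin <- sample(c("s", "s", "L1", "L2"), n, replace = TRUE)
  shared <- runif(n) < f
  placed <- ifelse(shared, sample(c("s", "L1", "L2"), n, replace = TRUE),
                   origin)
  cov <- table(placed) / (n / 4)
  as.numeric(cov[["s"]] / mean(c(cov[["L1"]], cov[["L2"]])))
}
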