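# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Tukey HSD pairwise p-values from first principles (studentized range).
oracle_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  N <- length(values)
  mse <- sum((values - ave(values, groups))^2) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  p <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    q <- abs(m[[pr[1]]] - m[[pr[2]]]) / se
    stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = p)
}

# Exhaustive-window wildcard matcher: shifted-vector AND over non-X positions.
oracle_scan <- function(protein, pattern) {
  chars <- strsplit(protein, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  m <- length(pat); L <- length(chars)
  if (m > L) return(integer(0))
  nw <- L - m + 1L
  ok <- rep(TRUE, nw)
  for (j in seq_len(m)) {
    if (pat[j] == "X") next
    ok <- ok & chars[j:(j + nw - 1L)] == pat[j]
  }
  which(ok)
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Random ORF of a given nucleotide length (multiple of 3): ATG + sense codons
# (no stops) + one stop codon.
random_orf <- function(nt_len) {
  stopifnot(nt_len %% 3 == 0, nt_len >= 6)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(sense, nt_len / 3 - 2, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

# Letters consistent with pairwise decisions?
cld_consistent <- function(letters_named, tukey_tab, alpha) {
  share <- function(a, b) {
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  }
  all(apply(tukey_tab, 1, function(row) {
    l1 <- letters_named[[row[["group1"]]]]
    l2 <- letters_named[[row[["group2"]]]]
    sig <- as.numeric(row[["p"]]) <= alpha
    share(l1, l2) == !sig
  }))
}
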