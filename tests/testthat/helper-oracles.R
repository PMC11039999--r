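# Independent brute-force oracles. These deliberately share no code with the
# package internals: the scanner oracle is a per-position regex, the matrix
# oracle a triple loop, the U oracle an exhaustive pair enumeration.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_rc <- function(pat) {
  paste(rev(ORACLE_COMP[strsplit(pat, "")[[1]]]), collapse = "")
}

oracle_regex <- function(pat) {
  chars <- strsplit(pat, "")[[1]]
  cls <- vapply(chars, function(cc) {
    set <- ORACLE_IUPAC[[cc]]
    if (cc == "N") set <- c(set, "N")  # genome N satisfies only pattern N
    paste0("[", paste(set, collapse = ""), "]")
  }, "")
  paste(cls, collapse = "")
}

# 0-based start positions of overlapping matches on the forward strand
oracle_fwd_starts <- function(seq, pat) {
  m <- gregexpr(paste0("(?=", oracle_regex(pat), ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# tibble(start, strand) of collapsed both-strand matches, mirroring the
# contract of scan_motif but computed by regex
oracle_scan <- function(seq, pat, collapse = TRUE) {
  fwd <- oracle_fwd_starts(seq, pat)
  rev <- oracle_fwd_starts(seq, oracle_rc(pat))
  if (collapse) rev <- setdiff(rev, fwd)
  out <- rbind(
    data.frame(start = fwd, strand = rep("+", length(fwd))),
    data.frame(start = rev, strand = rep("-", length(rev)))
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive k-mer enumeration of the per-position both-strand match count
oracle_kmer_matches <- function(pat, collapse = TRUE) {
  k <- nchar(pat)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, rep(list(bases), k))
  kmers <- apply(grid, 1L, paste, collapse = "")
  f <- grepl(paste0("^", oracle_regex(pat), "$"), kmers)
  r <- grepl(paste0("^", oracle_regex(oracle_rc(pat)), "$"), kmers)
  if (collapse) sum(f | r) else sum(f) + sum(r)
}

# naive O(anchors x bins x events) recount of a signal matrix
oracle_matrix <- function(events, anchors, flank, bin) {
  nb <- 2L * flank / bin
  ctr <- floor((anchors$start + anchors$end) / 2)
  vals <- matrix(0, nrow(anchors), nb)
  for (i in seq_len(nrow(anchors))) {
    pos <- events$pos[events$chrom == anchors$chrom[i]]
    for (j in seq_len(nb)) {
      lo <- ctr[i] - flank + (j - 1L) * bin
      vals[i, j] <- sum(pos >= lo & pos < lo + bin)
    }
  }
  vals
}

# Mann-Whitney U by exhaustive pair enumeration (ties count half)
oracle_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

random_seq <- function(n, with_n = FALSE) {
  if (with_n) {
    paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  } else {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
}
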