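# Shared fixtures and independent oracles used across test files.

fixture_path <- function() {
  p <- system.file("extdata", "sinentomon_annotation.tsv",
                   package = "mitoarch")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata",
                                 "sinentomon_annotation.tsv")
  p
}

read_fixture <- function(complete = TRUE) {
  read_annotation_tsv(fixture_path(), genome_id = "S_erythranum",
                      complete = complete)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1]] <- append(p, n, after = k)
  }
  out
}

# independent oracle: every outcome of one tandem-duplication-random-loss
# step on the identity block 1..n, by enumerating all 2^n per-gene
# copy-retention choices (retained copy-1 genes in order, then retained
# copy-2 genes in order)
tdrl_outcomes_bruteforce <- function(n) {
  keys <- character(0)
  for (mask in 0:(2^n - 1)) {
    keep1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    keep2 <- setdiff(seq_len(n), keep1)
    keys <- c(keys, paste(c(keep1, keep2), collapse = ","))
  }
  unique(keys)
}

# independent oracle for maximum nested base pairing: plain recursive
# enumeration over all nested structures (no memoization, no sharing with
# the package's dynamic program)
bruteforce_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(chartr("Uu", "Tt", toupper(seq)), "", fixed = TRUE)[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (ok(ch[k], ch[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
      }
    }
    best
  }
  n <- length(ch)
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

# a random contiguous block (length len) of the order, never touching the
# cox1 anchor at position 1
random_block <- function(ord, len) {
  n <- length(ord$labels)
  s <- sample(2:(n - len + 1L), 1)
  ord$labels[s:(s + len - 1L)]
}

# flank an array with random sequence whose boundary bases cannot extend the
# period by chance
flanked <- function(arr_seq, period, flank_len = 25,
                    freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  f1 <- mitoarch:::.break_period(rand_seq(flank_len, freqs), arr_seq,
                                 period, "left")
  f2 <- mitoarch:::.break_period(rand_seq(flank_len, freqs), arr_seq,
                                 period, "right")
  list(seq = paste0(f1, arr_seq, f2), offset = nchar(f1))
}

main_array <- function(res) {
  stopifnot(length(res) > 0)
  res[[which.max(vapply(res, function(a) a$end - a$start, 0L))]]
}
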