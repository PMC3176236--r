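# Tandem-repeat detection in control-region sequences.
#
# The detector is an exact-period autocorrelation scan: for each candidate
# period p it marks positions where s[i] == s[i + p] and extends maximal
# regions whose mismatch fraction stays within `max_divergence`. Indels
# within units are out of scope (no alignment); the design target is the
# clean head-to-tail arrays of mitochondrial control regions, with a
# fractional trailing copy and point substitutions.

#' Find tandem repeat arrays
#'
#' @param seq nucleotide string (case-insensitive).
#' @param min_period,max_period period search range in nucleotides.
#' @param max_divergence maximum tolerated mismatch fraction between a
#'   region and its period-shifted self (and minimum unit identity for the
#'   trailing partial copy to be counted).
#' @return object of class `tandem_repeat_set`: a list of
#'   `tandem_repeat_array` records (fields `start`, `end`, `period`,
#'   `copy_number` (0.1 resolution), `consensus`, `unit_identities`,
#'   `n_exact_units`, `n_full_units`, `identity`), non-overlapping after
#'   resolution by (longer array, higher identity, smaller period). Empty
#'   list when nothing repeats.
#' @export
#' @examples
#' arr <- find_tandem_repeats(strrep("TTTTGTTAAA", 11))[[1]]
#' c(arr$period, arr$copy_number, arr$n_exact_units)   # 10, 11, 11
find_tandem_repeats <- function(seq, min_period = 5L, max_period = 60L,
                                max_divergence = 0.2) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  cand <- list()
  if (n >= 2L * min_period) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in seq(min_period, min(max_period, n %/% 2L))) {
      m <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p]
      for (reg in .match_regions(m, max_divergence, p)) {
        bounds <- .refine_bounds(ch, reg[1], reg[2] + p, p)
        arr <- .build_array(ch, bounds[1], bounds[2], p, max_divergence)
        if (!is.null(arr)) cand[[length(cand) + 1]] <- arr
      }
    }
  }
  # drop period-multiple artifacts: a candidate whose own consensus is
  # tandemly periodic at an allowed shorter period, or whose span is
  # essentially covered by a candidate at a divisor period, is a disguised
  # multiple of the fundamental array, which is reported separately
  if (length(cand) > 1) {
    covered_by_divisor <- vapply(seq_along(cand), function(j) {
      aj <- cand[[j]]
      for (i in seq_along(cand)) {
        ai <- cand[[i]]
        if (i == j || ai$period >= aj$period ||
              aj$period %% ai$period != 0L) next
        ov <- min(ai$end, aj$end) - max(ai$start, aj$start) + 1L
        if (ov >= 0.8 * (aj$end - aj$start + 1L)) return(TRUE)
      }
      FALSE
    }, logical(1))
    cand <- cand[!covered_by_divisor]
  }
  cand <- Filter(function(a)
    !.is_period_multiple(a$consensus, min_period), cand)
  if (length(cand) == 0)
    return(structure(list(), class = "tandem_repeat_set"))
  # overlap resolution: longer array, then higher identity (whole-percent
  # grain, so that sampling noise cannot promote a period multiple), then
  # smaller period
  len <- vapply(cand, function(a) a$end - a$start + 1L, 0L)
  idy <- round(vapply(cand, `[[`, 0, "identity"))
  per <- vapply(cand, `[[`, 0L, "period")
  ord <- order(-len, -idy, per)
  kept <- list()
  occupied <- rep(FALSE, n)
  for (i in ord) {
    a <- cand[[i]]
    span <- a$start:a$end
    if (!any(occupied[span])) {
      kept[[length(kept) + 1]] <- a
      occupied[span] <- TRUE
    }
  }
  kept <- kept[order(vapply(kept, `[[`, 0L, "start"))]
  structure(kept, class = "tandem_repeat_set")
}

# maximal regions of the logical match vector m whose FALSE fraction is
# <= max_div; regions begin and end on TRUE and must span >= p matches
# (>= 2 full copies). TRUE-runs are merged across a FALSE gap only when the
# bridged stretch is locally within the divergence budget, so sparse chance
# matches in flanking sequence are not absorbed.
.match_regions <- function(m, max_div, p) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr <- which(r$values)
  if (length(tr) == 0) return(list())
  out <- list()
  i <- 1L
  while (i <= length(tr)) {
    a <- starts[tr[i]]
    b <- ends[tr[i]]
    j <- i
    while (j < length(tr)) {
      gap <- starts[tr[j + 1L]] - b - 1L
      run <- r$lengths[tr[j + 1L]]
      b2 <- ends[tr[j + 1L]]
      local_ok <- gap <= 4L || gap / (gap + run) <= max_div
      global_ok <- sum(!m[a:b2]) / (b2 - a + 1L) <= max_div
      if (local_ok && global_ok) {
        b <- b2
        j <- j + 1L
      } else break
    }
    if (b - a + 1L >= p) out[[length(out) + 1]] <- c(a, b)
    i <- j + 1L
  }
  out
}

# Refine array boundaries against the periodic extension of the region's own
# consensus: anchored at a unit boundary near the region middle, walk
# outward scoring +1 for a match and -2 for a mismatch, and place each
# boundary at the walk's score maximum. This pins the edges to where the
# sequence genuinely continues the repeat, instead of wherever chance
# period-matches in the flank peter out.
.refine_bounds <- function(ch, start, end, p) {
  n_full <- (end - start + 1L) %/% p
  if (n_full < 2L) return(c(start, end))
  umat <- matrix(ch[start:(start + n_full * p - 1L)], ncol = p, byrow = TRUE)
  cons <- apply(umat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  })
  anchor <- start + p * (n_full %/% 2L)   # unit boundary near the middle
  ideal <- function(x) cons[((x - anchor) %% p) + 1L]
  n <- length(ch)
  walk <- function(from, to, by) {
    if (by > 0 && from > to) return(integer(0))
    if (by < 0 && from < to) return(integer(0))
    xs <- seq(from, to, by = by)
    cum <- cumsum(ifelse(ch[xs] == ideal(xs), 1L, -2L))
    top <- max(cum)
    if (top <= 0) return(integer(0))
    xs[max(which(cum == top))]   # on ties, take the farther extension
  }
  left <- walk(anchor - 1L, max(1L, start - 2L * p), -1L)
  right <- walk(anchor, min(n, end + 2L * p), 1L)
  c(if (length(left)) left else anchor,
    if (length(right)) right else anchor - 1L)
}

# consensus internally periodic at a proper divisor >= min_period?
.is_period_multiple <- function(cons, min_period) {
  p <- nchar(cons)
  ch <- strsplit(cons, "", fixed = TRUE)[[1]]
  for (d in seq_len(p - 1L)) {
    if (d < min_period || p %% d != 0L) next
    mism <- sum(ch[seq_len(p - d)] != ch[seq_len(p - d) + d])
    if (mism / (p - d) <= 0.1) return(TRUE)
  }
  FALSE
}

# assemble a tandem_repeat_array record from a candidate region
# [start, end] (sequence coordinates) of period p; NULL if degenerate.
.build_array <- function(ch, start, end, p, max_div) {
  len <- end - start + 1L
  n_full <- len %/% p
  if (n_full < 2L) return(NULL)
  units <- vapply(seq_len(n_full), function(k) {
    paste(ch[(start + (k - 1L) * p):(start + k * p - 1L)], collapse = "")
  }, "")
  umat <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  consensus <- apply(umat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]   # ties broken alphabetically (A<C<G<T)
  })
  cons <- paste(consensus, collapse = "")
  unit_id <- apply(umat, 1, function(u) 100 * mean(u == consensus))
  # trailing partial copy: counted only if it matches the consensus prefix
  # at >= 1 - max_divergence
  partial_len <- len - n_full * p
  if (partial_len > 0L) {
    part <- ch[(start + n_full * p):end]
    part_id <- mean(part == consensus[seq_len(partial_len)])
    if (part_id < 1 - max_div) {
      end <- start + n_full * p - 1L
      len <- end - start + 1L
      partial_len <- 0L
    }
  }
  list(start = start, end = end, period = as.integer(p),
       copy_number = round(len / p, 1),
       consensus = cons,
       unit_identities = unname(unit_id),
       n_exact_units = sum(units == cons),
       n_full_units = n_full,
       identity = mean(unit_id))
}

#' @export
print.tandem_repeat_set <- function(x, ...) {
  if (length(x) == 0) { cat("no tandem repeats found\n"); return(invisible(x)) }
  for (a in x)
    cat(sprintf("  %d..%d  %.1f x %d bp  consensus %s  (%d/%d exact units)\n",
                a$start, a$end, a$copy_number, a$period,
                if (nchar(a$consensus) <= 40) a$consensus
                else paste0(substr(a$consensus, 1, 37), "..."),
                a$n_exact_units, a$n_full_units))
  invisible(x)
}

#' Per-unit alignment report for a repeat array
#'
#' Ungapped alignment of each full unit (and the trailing partial copy, if
#' any) against the array consensus.
#'
#' @param array one `tandem_repeat_array` record from
#'   [find_tandem_repeats()].
#' @param seq the sequence the array was called on.
#' @return data.frame with one row per unit: `unit`, `start`, `end`,
#'   `sequence`, `identity` (percent), `mismatch_positions`
#'   (comma-separated 1-based offsets within the unit), `partial` flag.
#' @export
unit_report <- function(array, seq) {
  seq <- toupper(as.character(seq))
  if (array$end > nchar(seq)) stop("array coordinates beyond sequence")
  cons <- strsplit(array$consensus, "", fixed = TRUE)[[1]]
  p <- array$period
  total <- array$end - array$start + 1L
  n_units <- ceiling(total / p)
  rows <- lapply(seq_len(n_units), function(k) {
    a <- array$start + (k - 1L) * p
    b <- min(array$start + k * p - 1L, array$end)
    u <- strsplit(substr(seq, a, b), "", fixed = TRUE)[[1]]
    mism <- which(u != cons[seq_along(u)])
    data.frame(unit = k, start = a, end = b,
               sequence = paste(u, collapse = ""),
               identity = 100 * mean(u == cons[seq_along(u)]),
               mismatch_positions = paste(mism, collapse = ","),
               partial = (b - a + 1L) < p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum nested base pairing (stem-loop stability proxy)
#'
#' Nussinov-style dynamic program maximizing the number of nested base pairs
#' (AU, GC and GU wobble all weighted 1) with a minimum hairpin loop of 3
#' unpaired nucleotides. This is a pairing-count proxy for stem-loop forming
#' potential, explicitly not a thermodynamic minimum-free-energy fold.
#'
#' @param seq nucleotide string (T and U equivalent), length >= 1.
#' @param min_loop minimum hairpin loop size (default 3).
#' @return list with `max_pairs`, `paired_fraction` = 2*max_pairs/length,
#'   and `structure` (dot-bracket string of one optimal structure).
#' @export
#' @examples
#' stemloop_score("GGGAAACCC")$max_pairs   # 3
stemloop_score <- function(seq, min_loop = 3L) {
  s <- chartr("Uu", "Tt", toupper(as.character(seq)))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pairs_ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  if (n < min_loop + 2L)
    return(list(max_pairs = 0L, paired_fraction = 0,
                structure = strrep(".", n)))
  D <- matrix(0L, n, n)
  for (span in seq(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- D[i, j - 1L]                       # j unpaired
      if (pairs_ok(ch[i], ch[j]))                # j paired with i
        best <- max(best, (if (j - 1L >= i + 1L) D[i + 1L, j - 1L] else 0L) + 1L)
      if (j - min_loop - 1L >= i + 1L) {
        for (k in seq(i + 1L, j - min_loop - 1L)) {  # j paired with k > i
          if (pairs_ok(ch[k], ch[j]))
            best <- max(best, D[i, k - 1L] + D[k + 1L, j - 1L] + 1L)
        }
      }
      D[i, j] <- best
    }
  }
  # traceback for one optimal structure
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (D[i, j] == D[i, j - 1L]) { j <- j - 1L; next }
      found <- FALSE
      for (k in seq(i, j - min_loop - 1L)) {
        if (!pairs_ok(ch[k], ch[j])) next
        left <- if (k - 1L >= i) D[i, k - 1L] else 0L
        inner <- if (j - 1L >= k + 1L) D[k + 1L, j - 1L] else 0L
        if (D[i, j] == left + inner + 1L) {
          db[k] <<- "("; db[j] <<- ")"
          if (k + 1L <= j - 1L) trace(k + 1L, j - 1L)
          j <- k - 1L
          found <- TRUE
          break
        }
      }
      if (!found) j <- j - 1L   # defensive; should not happen
    }
  }
  trace(1L, n)
  list(max_pairs = D[1L, n], paired_fraction = 2 * D[1L, n] / n,
       structure = paste(db, collapse = ""))
}
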