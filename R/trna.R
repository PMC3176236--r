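# Constrained cloverleaf model for (possibly truncated) mitochondrial tRNAs.
#
# The fitter assumes its input IS a tRNA (annotation comes from upstream
# tools) and exhaustively searches arm boundary placements within fixed
# windows, scoring Watson-Crick and GU pairs. It is a structural
# classifier -- which arms are present -- not a tRNA detector: no covariance
# model, no genome scanning.

# layout windows (nucleotides)
.cl_windows <- list(
  acceptor = 5:7,     # stem length; target 7, >= 5 accepted
  tail     = 0:1,     # unpaired 3' overhang (discriminator)
  spacer1  = 0:3,     # between acceptor 5' strand and the first arm
  d_stem   = 3:4,
  d_loop   = 4:12,
  spacer2  = 0:2,     # between D arm and anticodon arm
  ac_stem  = 4:5,
  ac_loop  = 7,       # fixed; anticodon at loop positions 3-5
  var      = 3:24,    # variable region (also the T-less 3' linker)
  t_stem   = 3:5,
  t_loop   = 3:9)

.pairable <- local({
  m <- matrix(FALSE, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "X"),
                              c("A", "C", "G", "T", "X")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE   # GU wobble, full weight
  m
})

#' Fit a constrained cloverleaf to a tRNA sequence
#'
#' Exhaustive search over arm boundary placements: acceptor stem 5-7 bp
#' (with 0-1 nt 3' overhang), optional DHU arm (stem 3-4 bp, loop 4-12 nt),
#' anticodon arm (stem 4-5 bp, loop 7 nt, anticodon at loop positions 3-5),
#' variable region 3-24 nt, optional T arm (stem 3-5 bp, loop 3-9 nt).
#' Each stem tolerates at most one non-pairing position; AU, GC and GU all
#' score 1. The best-scoring layout wins; ties break towards more arms
#' present, then a longer acceptor stem, then the leftmost layout. If no
#' layout gives an acceptor stem of >= 5 positions with at most one
#' mismatch, the sequence is reported unfoldable rather than erroring.
#'
#' @param seq nucleotide string, 50-75 nt (T and U equivalent).
#' @param anticodon optional 3-mer; when given, only layouts placing exactly
#'   this triplet at the anticodon position are considered.
#' @return object of class `cloverleaf`: list with `foldable`, `score`
#'   (total paired positions), `arms` (named logical: acceptor, D,
#'   anticodon, T), `layout` (named integer parameters), `anticodon`,
#'   `pairs` (2-column matrix of paired positions), `structure`
#'   (dot-bracket), `sequence`.
#' @export
fit_cloverleaf <- function(seq, anticodon = NULL) {
  s <- chartr("Uu", "Tt", toupper(as.character(seq)))
  n <- nchar(s)
  if (n < 50 || n > 75)
    stop("sequence length ", n, " outside the supported 50-75 nt range")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ci <- match(ch, c("A", "C", "G", "T"))
  ci[is.na(ci)] <- 5L
  if (!is.null(anticodon)) {
    anticodon <- chartr("Uu", "Tt", toupper(anticodon))
    stopifnot(nchar(anticodon) == 3)
  }
  P <- .pairable[ci, ci]
  w <- .cl_windows

  stem_eval <- function(i5, j3, len) {
    # pairs (i5 + k - 1, j3 - k + 1), k = 1..len
    hits <- P[cbind(i5 + seq_len(len) - 1L, j3 - seq_len(len) + 1L)]
    c(sum(hits), len - sum(hits))   # paired, mismatches
  }

  d_opts <- c(list(NULL),
              unlist(lapply(w$d_stem, function(d)
                lapply(w$d_loop, function(dl) c(d, dl))), recursive = FALSE))
  t_opts <- c(list(NULL),
              unlist(lapply(w$t_stem, function(t)
                lapply(w$t_loop, function(tl) c(t, tl))), recursive = FALSE))
  v_min <- min(w$var); v_max <- max(w$var)

  best <- NULL
  best_key <- c(-1, -1, -1)   # score, n_arms, acceptor length

  for (tail in w$tail) for (a in w$acceptor) {
    j3 <- n - tail                      # 3' end of acceptor stem
    acc <- stem_eval(1L, j3, a)
    if (acc[2] > 1) next                # acceptor must carry >= a-1 pairs
    for (s1 in w$spacer1) {
      for (dopt in d_opts) {
        d_len <- if (is.null(dopt)) 0L else 2L * dopt[1] + dopt[2]
        if (!is.null(dopt)) {
          dstem <- stem_eval(1L + a + s1, a + s1 + d_len, dopt[1])
          if (dstem[2] > 1) next
        } else dstem <- c(0L, 0L)
        s2_opts <- if (is.null(dopt)) 0L else w$spacer2
        for (s2 in s2_opts) {
          for (cc in w$ac_stem) {
            ac_start <- 1L + a + s1 + d_len + s2
            ac_len <- 2L * cc + w$ac_loop
            if (ac_start + ac_len - 1L > n - tail - a) next
            astem <- stem_eval(ac_start, ac_start + ac_len - 1L, cc)
            if (astem[2] > 1) next
            anti_at <- ac_start + cc + 2L
            anti <- substr(s, anti_at, anti_at + 2L)
            if (!is.null(anticodon) && anti != anticodon) next
            for (topt in t_opts) {
              t_len <- if (is.null(topt)) 0L else 2L * topt[1] + topt[2]
              v <- n - tail - a - (ac_start - 1L) - ac_len - t_len
              if (v < v_min || v > v_max) next
              if (!is.null(topt)) {
                t_start <- ac_start + ac_len + v
                tstem <- stem_eval(t_start, t_start + t_len - 1L, topt[1])
                if (tstem[2] > 1) next
              } else tstem <- c(0L, 0L)
              sc <- acc[1] + dstem[1] + astem[1] + tstem[1]
              n_arms <- 2L + !is.null(dopt) + !is.null(topt)
              key <- c(sc, n_arms, a)
              if (.key_better(key, best_key)) {
                best_key <- key
                pairs <- cbind(seq_len(a), j3 - seq_len(a) + 1L)
                if (!is.null(dopt)) {
                  p0 <- 1L + a + s1
                  pairs <- rbind(pairs,
                                 cbind(p0 + seq_len(dopt[1]) - 1L,
                                       a + s1 + d_len - seq_len(dopt[1]) + 1L))
                }
                pairs <- rbind(pairs,
                               cbind(ac_start + seq_len(cc) - 1L,
                                     ac_start + ac_len - seq_len(cc)))
                if (!is.null(topt)) {
                  t_start <- ac_start + ac_len + v
                  pairs <- rbind(pairs,
                                 cbind(t_start + seq_len(topt[1]) - 1L,
                                       t_start + t_len - seq_len(topt[1])))
                }
                best <- list(
                  score = sc,
                  arms = c(acceptor = TRUE, D = !is.null(dopt),
                           anticodon = TRUE, T = !is.null(topt)),
                  layout = c(acceptor = a, tail = tail, spacer1 = s1,
                             d_stem = if (is.null(dopt)) 0L else dopt[1],
                             d_loop = if (is.null(dopt)) 0L else dopt[2],
                             spacer2 = s2, ac_stem = cc,
                             variable = as.integer(v),
                             t_stem = if (is.null(topt)) 0L else topt[1],
                             t_loop = if (is.null(topt)) 0L else topt[2]),
                  anticodon = anti,
                  pairs = pairs)
              }
            }
          }
        }
      }
    }
  }

  if (is.null(best))
    return(structure(list(foldable = FALSE, score = 0L,
                          arms = c(acceptor = FALSE, D = FALSE,
                                   anticodon = FALSE, T = FALSE),
                          layout = NULL, anticodon = NA_character_,
                          pairs = NULL, structure = strrep(".", n),
                          sequence = s),
                     class = "cloverleaf"))
  db <- rep(".", n)
  keep <- P[best$pairs]              # only truly paired positions marked
  db[best$pairs[keep, 1]] <- "("
  db[best$pairs[keep, 2]] <- ")"
  structure(c(list(foldable = TRUE), best,
              list(structure = paste(db, collapse = ""), sequence = s)),
            class = "cloverleaf")
}

# lexicographic comparison on (score, n_arms, acceptor length); strict, so
# the leftmost layout under the fixed enumeration order wins ties
.key_better <- function(key, ref) {
  for (i in seq_along(key)) {
    if (key[i] > ref[i]) return(TRUE)
    if (key[i] < ref[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.cloverleaf <- function(x, ...) {
  if (!x$foldable) {
    cat("cloverleaf: unfoldable (no acceptor stem of >= 5 positions)\n")
    return(invisible(x))
  }
  cat(sprintf("cloverleaf: score %d, anticodon %s, %s\n", x$score,
              x$anticodon, classify_truncation(x)))
  cat(" ", x$sequence, "\n ", x$structure, "\n")
  invisible(x)
}

#' Classify the truncation of a fitted cloverleaf
#'
#' @param cl a `cloverleaf` from [fit_cloverleaf()].
#' @return `"full"`, `"lacks_T_arm"`, `"lacks_D_arm"`,
#'   `"lacks_D_and_T_arms"`, or `NA` for an unfoldable input.
#' @export
classify_truncation <- function(cl) {
  stopifnot(inherits(cl, "cloverleaf"))
  if (!cl$foldable) return(NA_character_)
  has_d <- cl$arms[["D"]]
  has_t <- cl$arms[["T"]]
  if (has_d && has_t) "full"
  else if (has_d) "lacks_T_arm"
  else if (has_t) "lacks_D_arm"
  else "lacks_D_and_T_arms"
}

#' Global pairwise identity of two short sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap -2
#' (linear gaps), via Biostrings. Identity is matches over alignment
#' columns, reported to whole percent.
#'
#' @param seq1,seq2 nucleotide strings (<= 100 nt each).
#' @return list with `identity` (percent, 0 dp), `matches`, `mismatches`,
#'   `indels` (gapped columns), `columns`, and the two aligned strings.
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")$identity   # 75
pairwise_identity <- function(seq1, seq2) {
  s1 <- chartr("Uu", "Tt", toupper(as.character(seq1)))
  s2 <- chartr("Uu", "Tt", toupper(as.character(seq2)))
  if (!nzchar(s1) || !nzchar(s2)) stop("empty sequence")
  if (nchar(s1) > 100 || nchar(s2) > 100)
    stop("sequences longer than 100 nt; this helper targets tRNA-scale input")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = 2)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(a1)
  gaps <- a1 == "-" | a2 == "-"
  matches <- sum(!gaps & a1 == a2)
  list(identity = round(100 * matches / cols),
       matches = matches,
       mismatches = sum(!gaps & a1 != a2),
       indels = sum(gaps),
       columns = cols,
       aligned1 = paste(a1, collapse = ""),
       aligned2 = paste(a2, collapse = ""))
}
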