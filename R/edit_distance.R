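#' Phoneme-level edit distance
#'
#' Levenshtein distance between two phoneme sequences with unit costs for
#' substitution, deletion and insertion. This is the tolerance underlying
#' the correctness rule: a response counts as a production of a target word
#' when it is within one phonemic substitution, omission or addition of it.
#'
#' @param a,b Character vectors of phoneme labels.
#' @return Non-negative integer distance.
#' @examples
#' phoneme_edit_distance(c("D", "AO", "G"), c("D", "AO", "T"))  # 1
#' @export
phoneme_edit_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    ai <- a[i]
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,          # deletion
                         cur[j] + 1L,                # insertion
                         prev[j] + (ai != b[j]))     # substitution / match
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

# Banded check: is dist(a, b) <= 1?  Much cheaper than the full DP and the
# only question the scorer ever asks per candidate.
within_one_edit <- function(a, b) {
  n <- length(a); m <- length(b)
  if (abs(n - m) > 1L) return(FALSE)
  if (n == m) {
    return(sum(a != b) <= 1L)
  }
  if (n > m) { tmp <- a; a <- b; b <- tmp; n <- length(a); m <- length(b) }
  # b is longer by one: skip exactly one element of b
  i <- 1L
  while (i <= n && a[i] == b[i]) i <- i + 1L
  all(a[seq.int(i, length.out = n - i + 1L)] ==
        b[seq.int(i + 1L, length.out = n - i + 1L)]) || i > n
}
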