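#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA. Non-ACGT
#' characters (e.g. `N`) are complemented to themselves.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Generate random DNA with a given GC fraction
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2. Uses the current RNG state; seed via [withr::with_seed()]
#' or a simulation config.
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in \[0, 1\].
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Round half away from zero
#'
#' Fixed-precision rounding where `.5` always rounds up in magnitude
#' (`round()` in R rounds half to even). Used for the reported
#' recombination and editing percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# substring of a molecule honouring circular topology; start may be < 1 or
# end > length for circular molecules (wraps). For linear molecules the
# interval is clamped and the truncation reported via attribute.
mol_substr <- function(seq, start, end, topology = "linear") {
  n <- nchar(seq)
  if (topology == "circular") {
    s <- paste0(seq, seq)
    start0 <- ((start - 1) %% n) + 1
    len <- end - start + 1
    if (len > 2 * n) stop("interval longer than doubled molecule")
    out <- substr(s, start0, start0 + len - 1)
    if (nchar(out) < len) {      # wraps more than once past the doubling
      out <- paste0(out, substr(s, 1, len - nchar(out)))
    }
    attr(out, "truncated") <- FALSE
    out
  } else {
    s0 <- max(1L, start); e0 <- min(n, end)
    out <- if (s0 > e0) "" else substr(seq, s0, e0)
    attr(out, "truncated") <- (s0 != start || e0 != end)
    out
  }
}

# split a string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic child seed derived from a base seed and a stream label,
# kept within 32-bit integer range
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' Convert between strand and descending-coordinate representation
#'
#' Output tables report reverse-orientation intervals with descending
#' coordinates (`start > end`), the convention used for repeat and MTPT
#' location columns. Internally intervals are ascending with a strand.
#'
#' @param start,end 1-based inclusive ascending coordinates.
#' @param strand `"+"` or `"-"`.
#' @return for `coords_to_table()`, a list with `start`, `end` (descending
#'   when `strand == "-"`); for `coords_from_table()`, a list with
#'   ascending `start`, `end` and `strand`.
#' @export
coords_to_table <- function(start, end, strand) {
  flip <- strand == "-"
  list(start = ifelse(flip, end, start), end = ifelse(flip, start, end))
}

#' @rdname coords_to_table
#' @export
coords_from_table <- function(start, end) {
  flip <- start > end
  list(start = ifelse(flip, end, start),
       end = ifelse(flip, start, end),
       strand = ifelse(flip, "-", "+"))
}
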