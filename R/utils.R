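# Low-level string / numeric helpers shared across modules.

PRG_ALPHABET <- c("A", "C", "G", "T", "N", "-")

# integer codes used by the C++ alignment core: A=0 C=1 G=2 T=3 N=4 gap=5
.base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 5L)
.code_base <- names(.base_code)

encode_bases <- function(chars) {
  out <- .base_code[chars]
  if (anyNA(out)) stop("non-ACGTN- character in sequence: ",
                       paste(unique(chars[is.na(out)]), collapse = ", "))
  unname(out)
}

decode_bases <- function(codes) .code_base[codes + 1L]

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_str <- function(x) paste(x, collapse = "")

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

revcomp <- function(x) {
  # plain-string reverse complement; N and '-' map to themselves
  sapply(x, function(s) {
    chars_str(rev(str_chars(chartr("ACGTacgt", "TGCAtgca", s))))
  }, USE.NAMES = FALSE)
}

#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Phred qualities <-> error probabilities. An error floor avoids -Inf scores
# from very high qualities; a ceiling keeps degenerate bases informative.
phred_to_eps <- function(qual_chars, floor = 1e-4, ceiling = 0.75) {
  q <- as.integer(charToRaw(qual_chars)) - 33L
  pmin(pmax(10^(-q / 10), floor), ceiling)
}

eps_to_phred_char <- function(eps) {
  q <- pmin(pmax(as.integer(round(-10 * log10(eps))), 2L), 40L)
  rawToChar(as.raw(q + 33L))
}

# all k-length substrings of a string (character vector, possibly empty)
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

canonical_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(kmers)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
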