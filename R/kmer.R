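# Graph k-mer index, background k-mer set, and the read-pair pre-filter.

#' Build the k-mer index of a PRG
#'
#' Enumerates every k-character gap-skipping walk of the graph: '-' edges
#' contribute no character, so k-mers can span graph-encoded deletions.
#' Walks containing 'N' edges are excluded ('N' appears in the inter-gene
#' spacers precisely to prevent cross-gene k-mers, and an N-containing k-mer
#' can never be matched by a read k-mer textually).
#'
#' @param prg a `prg`.
#' @param k k-mer length (default 31, matching the allele k-mer coverage
#'   quality metric).
#' @param max_frontier combinatorial blow-up guard: abort if the number of
#'   simultaneously open partial walks exceeds this, naming the window.
#' @return an object of class `prg_kmer_index` with fields `k`, `env`
#'   (hash: k-mer -> integer matrix of (start_level, end_level) walk
#'   positions), `n_kmers` and `total_positions`.
#' @export
build_graph_kmer_index <- function(prg, k = 31L, max_frontier = 5e4) {
  stopifnot(inherits(prg, "prg"), k >= 2L)
  k <- as.integer(k)
  csr <- prg_csr(prg)
  walks <- cpp_enumerate_kmer_walks(csr$ptr, csr$lab, k,
                                    as.integer(max_frontier))
  env <- new.env(hash = TRUE, parent = emptyenv())
  n <- length(walks$kmer)
  n_kmers <- 0L
  if (n > 0L) {
    pos <- cbind(walks$start, walks$end)
    groups <- split(seq_len(n), walks$kmer)
    n_kmers <- length(groups)
    nm <- names(groups)
    for (i in seq_along(groups))
      assign(nm[i], pos[groups[[i]], , drop = FALSE], envir = env)
  }
  structure(list(k = k, env = env, n_kmers = n_kmers,
                 total_positions = n),
            class = "prg_kmer_index")
}

#' @export
print.prg_kmer_index <- function(x, ...) {
  cat(sprintf("<prg_kmer_index> k=%d: %d distinct k-mers, %d positions\n",
              x$k, x$n_kmers, x$total_positions))
  invisible(x)
}

# positions of each k-mer (list of matrices; NULL where absent)
lookup_kmers <- function(index, kmers) {
  mget(kmers, envir = index$env, ifnotfound = list(NULL))
}

# forward-strand membership (no canonicalization)
kmers_in_index <- function(index, kmers) {
  vapply(kmers, exists, logical(1), envir = index$env, inherits = FALSE,
         USE.NAMES = FALSE)
}

# strand-canonicalized membership: a k-mer is "in the PRG" if it or its
# reverse complement is an indexed forward walk
kmers_in_index_canonical <- function(index, kmers) {
  if (length(kmers) == 0L) return(logical(0))
  fwd <- kmers_in_index(index, kmers)
  if (all(fwd)) return(fwd)
  rc <- revcomp_set(kmers[!fwd])
  fwd[!fwd] <- kmers_in_index(index, rc)
  fwd
}

revcomp_set <- function(kmers) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
}

#' Build the background k-mer set from reference sequences outside the PRG
#'
#' k-mers containing 'N' are skipped; the set is closed under reverse
#' complement.
#'
#' @param ref_sequences character vector (or `DNAStringSet`) of un-gapped
#'   sequences.
#' @param k k-mer length.
#' @return an object of class `prg_kmer_set`.
#' @export
build_background_kmer_set <- function(ref_sequences, k = 31L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  seqs <- toupper(as.character(ref_sequences))
  kms <- unlist(lapply(seqs, kmers_of, k = k))
  if (length(kms) > 0L) {
    kms <- kms[!grepl("N", kms, fixed = TRUE)]
    kms <- unique(c(kms, revcomp_set(kms)))
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (km in kms) assign(km, TRUE, envir = env)
  structure(list(k = k, env = env, n_kmers = length(kms)),
            class = "prg_kmer_set")
}

kmers_in_set <- function(set, kmers) {
  if (length(kmers) == 0L) return(logical(0))
  vapply(kmers, exists, logical(1), envir = set$env, inherits = FALSE,
         USE.NAMES = FALSE)
}

#' Positive/negative k-mer selection for one read pair
#'
#' Keep iff both hold: (a) the fraction of the pair's pooled k-mers
#' (strand-canonicalized) present in the graph index strictly exceeds
#' `thr$positive_fraction`; (b) at least one mate has >= 1 k-mer present in
#' the index and absent from the background ("unique to the PRG"), or at
#' least one mate has a background k-mer fraction strictly below
#' `thr$background_fraction`.
#'
#' @param seq1,seq2 mate sequences.
#' @param index a `prg_kmer_index`.
#' @param background a `prg_kmer_set` (may be empty).
#' @param thr a `prg_filter_thresholds`.
#' @param qual1,qual2 optional Phred strings (used only when
#'   `thr$mask_below_q` is set).
#' @return list with `keep` (logical), `reason` (`"kept"`, `"too_short"`,
#'   `"positive_selection"` or `"negative_selection"`), `positive_fraction`,
#'   `background_fractions`, `unique_kmers` (per mate counts).
#' @export
filter_read_pair <- function(seq1, seq2, index, background, thr,
                             qual1 = NULL, qual2 = NULL) {
  k <- index$k
  if (nchar(seq1) < k || nchar(seq2) < k)
    return(list(keep = FALSE, reason = "too_short",
                positive_fraction = NA_real_,
                background_fractions = c(NA_real_, NA_real_),
                unique_kmers = c(NA_integer_, NA_integer_)))
  if (!is.null(thr$mask_below_q)) {
    seq1 <- mask_low_quality(seq1, qual1, thr$mask_below_q)
    seq2 <- mask_low_quality(seq2, qual2, thr$mask_below_q)
  }
  km1 <- kmers_of(toupper(seq1), k); km2 <- kmers_of(toupper(seq2), k)
  # the reverse complements of a read's k-mers are the k-mers of the
  # reverse-complemented read, in reverse order (avoids per-k-mer RC calls)
  rc1 <- rev(kmers_of(revcomp(toupper(seq1)), k))
  rc2 <- rev(kmers_of(revcomp(toupper(seq2)), k))
  in1 <- kmers_in_index(index, km1) | kmers_in_index(index, rc1)
  in2 <- kmers_in_index(index, km2) | kmers_in_index(index, rc2)
  pos_frac <- mean(c(in1, in2))
  bg1 <- kmers_in_set(background, km1)
  bg2 <- kmers_in_set(background, km2)
  uniq <- c(sum(in1 & !bg1), sum(in2 & !bg2))
  bg_frac <- c(mean(bg1), mean(bg2))
  if (!(pos_frac > thr$positive_fraction))
    return(list(keep = FALSE, reason = "positive_selection",
                positive_fraction = pos_frac, background_fractions = bg_frac,
                unique_kmers = uniq))
  neg_ok <- !thr$require_unique || any(uniq >= 1L) ||
    any(bg_frac < thr$background_fraction)
  if (!neg_ok)
    return(list(keep = FALSE, reason = "negative_selection",
                positive_fraction = pos_frac, background_fractions = bg_frac,
                unique_kmers = uniq))
  list(keep = TRUE, reason = "kept", positive_fraction = pos_frac,
       background_fractions = bg_frac, unique_kmers = uniq)
}

mask_low_quality <- function(seq, qual, q) {
  if (is.null(qual)) return(seq)
  qs <- as.integer(charToRaw(qual)) - 33L
  ch <- str_chars(seq)
  ch[qs < q] <- "N"
  chars_str(ch)
}

#' Apply the pre-filter to a whole set of read pairs
#'
#' @param pairs a read-pair set as returned by [read_fastq_pairs()] or
#'   [simulate_diploid_reads()]: list with `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` character vectors.
#' @inheritParams filter_read_pair
#' @return a data.frame with one row per pair: `id`, `keep`, `reason`,
#'   `positive_fraction`, `bg_fraction1`, `bg_fraction2`.
#' @export
filter_read_pairs <- function(pairs, index, background,
                              thr = filter_thresholds()) {
  n <- length(pairs$id)
  keep <- logical(n); reason <- character(n)
  pf <- numeric(n); b1 <- numeric(n); b2 <- numeric(n)
  for (i in seq_len(n)) {
    d <- filter_read_pair(pairs$seq1[i], pairs$seq2[i], index, background,
                          thr, pairs$qual1[i], pairs$qual2[i])
    keep[i] <- d$keep; reason[i] <- d$reason
    pf[i] <- d$positive_fraction
    b1[i] <- d$background_fractions[1L]; b2[i] <- d$background_fractions[2L]
  }
  data.frame(id = pairs$id, keep = keep, reason = reason,
             positive_fraction = pf, bg_fraction1 = b1, bg_fraction2 = b2,
             stringsAsFactors = FALSE)
}
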