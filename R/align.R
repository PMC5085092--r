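# Seed-and-extend alignment of paired-end reads to the PRG.
#
# 1. k-mer hits against the graph index are chained into maximal exact
#    matches (seeds) on both strands;
# 2. each seed-implied window is extended by banded affine dynamic
#    programming over the graph (C++ core), allowing mismatches, read
#    insertions/deletions and free traversal of graph-encoded '-' edges;
# 3. mate alignments are combined into paired alignments scored with
#    orientation and insert-size terms;
# 4. the posterior over paired alignments gives the maximum-likelihood
#    alignment, its mapping quality, and per-position alignment qualities.

#' Find exact-match seeds of a read in the graph k-mer index
#'
#' k-mer hits at successive read offsets whose graph walks advance
#' consistently are chained into maximal exact matches; both strands are
#' searched. Matches shorter than `min_seed` are dropped.
#'
#' @param seq read sequence.
#' @param index a `prg_kmer_index`.
#' @param min_seed minimum seed length (default: the index k).
#' @param max_gap_run chaining slack in levels, allowing walks to advance by
#'   more than one level per base across graph-encoded gap runs.
#' @return data.frame with one row per seed: `strand`, `read_start`,
#'   `read_end` (1-based inclusive, in strand-local coordinates), `g_start`,
#'   `g_end` (first/last level of the walk), `n_kmers`.
#' @export
find_seeds <- function(seq, index, min_seed = NULL, max_gap_run = 8L) {
  ch <- seed_chains(seq, index, min_seed, max_gap_run)
  unique(data.frame(strand = ch$strand, read_start = ch$read_start,
                    read_end = ch$read_end, g_start = ch$g_start,
                    g_end = ch$g_end, n_kmers = ch$n_kmers,
                    stringsAsFactors = FALSE))
}

# internal fast path: plain vectors, no data.frame overhead
seed_chains <- function(seq, index, min_seed = NULL, max_gap_run = 8L) {
  k <- index$k
  min_seed <- min_seed %||% k
  m <- nchar(seq)
  out <- list(strand = character(0), read_start = integer(0),
              read_end = integer(0), g_start = integer(0),
              g_end = integer(0), n_kmers = integer(0))
  if (m < k) return(out)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else revcomp(toupper(seq))
    kms <- kmers_of(s, k)
    hits <- lookup_kmers(index, kms)
    nh <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h), integer(1))
    if (sum(nh) == 0L) next
    o <- rep.int(seq_along(hits), nh)
    hb <- do.call(rbind, hits[nh > 0L])
    gs <- hb[, 1L]; ge <- hb[, 2L]
    # chain within diagonals: k-mers at consecutive offsets whose walk start
    # advances by exactly one level per base (gap-crossing walks change
    # diagonal and start a new chain; the extension window covers the join)
    d <- gs - o
    ord <- order(d, o, ge)
    o <- o[ord]; gs <- gs[ord]; ge <- ge[ord]; d <- d[ord]
    n <- length(o)
    new_chain <- c(TRUE, d[-1L] != d[-n] | o[-1L] != o[-n] + 1L |
                     ge[-1L] - ge[-n] < 1L |
                     ge[-1L] - ge[-n] > 1L + max_gap_run)
    first <- which(new_chain)
    last <- c(first[-1L] - 1L, n)
    len <- o[last] + k - o[first]
    keep <- len >= min_seed
    if (!any(keep)) next
    out$strand <- c(out$strand, rep(strand, sum(keep)))
    out$read_start <- c(out$read_start, o[first][keep])
    out$read_end <- c(out$read_end, o[last][keep] + k - 1L)
    out$g_start <- c(out$g_start, gs[first][keep])
    out$g_end <- c(out$g_end, ge[last][keep])
    out$n_kmers <- c(out$n_kmers, (last - first + 1L)[keep])
  }
  out
}

# seed-implied extension windows, merged per strand, ranked by seed support;
# input and output are plain vector lists (see seed_chains)
candidate_windows <- function(seeds, read_len, n_levels, params) {
  if (length(seeds$strand) == 0L)
    return(list(strand = character(0), w0 = integer(0), w1 = integer(0)))
  margin <- params$window_margin
  w0 <- pmax(1L, seeds$g_start - (seeds$read_start - 1L) - margin)
  w1 <- pmin(n_levels, seeds$g_end + (read_len - seeds$read_end) + margin)
  support <- seeds$read_end - seeds$read_start + 1L
  o_strand <- character(0); o_w0 <- o_w1 <- o_sup <- integer(0)
  for (strand in unique(seeds$strand)) {
    i <- which(seeds$strand == strand)
    i <- i[order(w0[i])]
    cw0 <- w0[i[1L]]; cw1 <- w1[i[1L]]; csup <- support[i[1L]]
    for (r in i[-1L]) {
      if (w0[r] <= cw1) {
        cw1 <- max(cw1, w1[r]); csup <- csup + support[r]
      } else {
        o_strand <- c(o_strand, strand); o_w0 <- c(o_w0, cw0)
        o_w1 <- c(o_w1, cw1); o_sup <- c(o_sup, csup)
        cw0 <- w0[r]; cw1 <- w1[r]; csup <- support[r]
      }
    }
    o_strand <- c(o_strand, strand); o_w0 <- c(o_w0, cw0)
    o_w1 <- c(o_w1, cw1); o_sup <- c(o_sup, csup)
  }
  ord <- order(-o_sup, o_w0)[seq_len(min(length(o_sup), params$max_windows))]
  list(strand = o_strand[ord], w0 = o_w0[ord], w1 = o_w1[ord])
}

#' Extend a seed into a full graph alignment
#'
#' Runs the dynamic-programming extension over the window implied by the seed
#' (seed span widened by the unaligned read length plus a margin) and returns
#' the best-scoring alignment in that window. The DP allows mismatches, read
#' insertions and deletions (affine), free traversal of '-' edges, and soft
#' clipping; cells falling more than `params$score_drop` below the running
#' maximum are pruned.
#'
#' @param seed one row of the [find_seeds()] result.
#' @param seq,qual read sequence and Phred quality string.
#' @param prg a `prg`.
#' @param params a `prg_scoring_params`.
#' @param csr optional precomputed [prg_csr()] view.
#' @return a graph alignment (see [align_read_to_graph()]) or `NULL`.
#' @export
extend_seed <- function(seed, seq, qual, prg, params = scoring_params(),
                        csr = NULL) {
  csr <- csr %||% prg_csr(prg)
  m <- nchar(seq)
  w0 <- max(1L, seed$g_start - (seed$read_start - 1L) - params$window_margin)
  w1 <- min(prg$n_levels, seed$g_end + (m - seed$read_end) + params$window_margin)
  align_window(seq, qual, seed$strand, w0, w1, csr, params)
}

# run the C++ core on one window; returns an alignment record or NULL
align_window <- function(seq, qual, strand, w0, w1, csr, params,
                         drop = NULL, clip = NULL) {
  m <- nchar(seq)
  local_seq <- if (strand == "+") toupper(seq) else revcomp(toupper(seq))
  eps <- phred_to_eps(qual, params$eps_floor, params$eps_ceiling)
  if (strand == "-") eps <- rev(eps)
  codes <- encode_bases(str_chars(local_seq))
  res <- cpp_graph_align(csr$ptr, csr$lab, as.integer(w0), as.integer(w1),
                         codes, eps,
                         params$gap_open, params$gap_extend,
                         clip %||% params$clip,
                         drop %||% params$score_drop)
  if (!is.finite(res$score) || nrow(res$cols) == 0L) return(NULL)
  cols <- res$cols
  rp <- cols[, 2L]
  has_rp <- rp > 0L
  read_pos_orig <- rep(NA_integer_, length(rp))
  read_pos_orig[has_rp] <- if (strand == "+") rp[has_rp] else m - rp[has_rp] + 1L
  local_chars <- decode_bases(codes)
  base <- rep(NA_character_, length(rp))
  base[has_rp] <- local_chars[rp[has_rp]]
  col_eps <- rep(NA_real_, length(rp))
  col_eps[has_rp] <- eps[rp[has_rp]]
  lv <- cols[, 1L]
  level <- rep(NA_integer_, length(lv))
  level[lv > 0L] <- lv[lv > 0L]
  lab <- cols[, 4L]
  label <- rep(NA_character_, length(lab))
  label[lab >= 0L] <- decode_bases(lab[lab >= 0L])
  structure(list(
    strand = strand, score = res$score,
    start_level = min(lv[lv > 0L]), end_level = max(lv[lv > 0L]),
    clip_left = res$clip_left, clip_right = res$clip_right,
    level = level, op = cols[, 3L], label = label,
    base = base, eps = col_eps, read_pos = read_pos_orig,
    read_len = m),
    class = "prg_graph_alignment")
}

#' @export
print.prg_graph_alignment <- function(x, ...) {
  cat(sprintf("<graph alignment> strand %s, levels %d-%d, score %.3f, clips %d/%d\n",
              x$strand, x$start_level, x$end_level, x$score,
              x$clip_left, x$clip_right))
  invisible(x)
}

#' Align one read to the graph (all candidate placements)
#'
#' Seeds on both strands are grouped into extension windows; each window is
#' extended and the distinct resulting alignments are returned, best first.
#'
#' @inheritParams extend_seed
#' @param index a `prg_kmer_index`.
#' @return list of graph alignments (possibly empty).
#' @export
align_read_to_graph <- function(seq, qual, prg, index,
                                params = scoring_params(), csr = NULL) {
  csr <- csr %||% prg_csr(prg)
  seeds <- seed_chains(seq, index, min_seed = params$min_seed)
  wins <- candidate_windows(seeds, nchar(seq), prg$n_levels, params)
  alns <- list()
  if (length(wins$strand) > 0L) for (r in seq_along(wins$strand)) {
    a <- align_window(seq, qual, wins$strand[r], wins$w0[r], wins$w1[r],
                      csr, params)
    if (!is.null(a)) alns[[length(alns) + 1L]] <- a
  }
  if (length(alns) == 0L) return(alns)
  key <- vapply(alns, function(a)
    paste(a$strand, a$start_level, a$end_level, round(a$score, 9)), character(1))
  alns <- alns[!duplicated(key)]
  alns[order(-vapply(alns, `[[`, numeric(1), "score"))]
}

# walk string for deterministic tie-breaking
alignment_walk_string <- function(a) {
  if (is.null(a)) return("")
  paste0(a$start_level, ":", chars_str(a$label[!is.na(a$label)]))
}

#' Combine mate alignments into scored paired alignments
#'
#' The Cartesian product of the two candidate lists is formed; each pair is
#' scored as `score1 + score2` plus an insert-size log-density for proper
#' (opposite-strand, forward-reverse) pairs, or the improper-pair log-penalty
#' otherwise. If one mate has no alignments, single-ended pairs carrying the
#' improper-pair penalty are produced.
#'
#' @param alns1,alns2 lists of graph alignments for mate 1 and mate 2.
#' @param model a `prg_insert_model`.
#' @param params a `prg_scoring_params`.
#' @return list of paired alignments: `aln1`, `aln2` (either may be `NULL`),
#'   `loglik`, `insert`, `proper`.
#' @export
pair_and_score <- function(alns1, alns2, model, params = scoring_params()) {
  pairs <- list()
  if (length(alns1) == 0L && length(alns2) == 0L) return(pairs)
  if (length(alns1) == 0L || length(alns2) == 0L) {
    have <- if (length(alns1) > 0L) alns1 else alns2
    for (a in have) {
      p <- list(aln1 = if (length(alns1) > 0L) a else NULL,
                aln2 = if (length(alns2) > 0L) a else NULL,
                loglik = a$score + params$improper_pair,
                insert = NA_real_, proper = FALSE)
      pairs[[length(pairs) + 1L]] <- p
    }
    return(pairs)
  }
  for (a1 in alns1) for (a2 in alns2) {
    proper <- FALSE; ins <- NA_real_
    if (a1$strand != a2$strand) {
      plus <- if (a1$strand == "+") a1 else a2
      minus <- if (a1$strand == "+") a2 else a1
      ins <- minus$end_level - plus$start_level + 1
      proper <- ins > 0
    }
    term <- if (proper) model$log_density(ins) else params$improper_pair
    pairs[[length(pairs) + 1L]] <- list(
      aln1 = a1, aln2 = a2, loglik = a1$score + a2$score + term,
      insert = if (proper) ins else NA_real_, proper = proper)
  }
  pairs
}

#' Posterior over paired alignments, ML selection and position qualities
#'
#' Pair log-likelihoods are normalized by log-sum-exp into a posterior
#' distribution (summing to 1 within 1e-9). The maximum-posterior pair is
#' selected (ties broken by lowest start level, then lexicographic walk); its
#' posterior is the mapping quality. The per-position quality of an aligned
#' read base is the total posterior mass of candidate pairs that place the
#' same read base at the same graph level.
#'
#' @param pairs non-empty list from [pair_and_score()].
#' @return a `prg_paired_alignment`: the selected pair plus `mapq`,
#'   `posteriors` (full vector), and per-mate `pos_quality` data.frames
#'   (`read_pos`, `level`, `qual`).
#' @export
posterior_and_select <- function(pairs) {
  if (length(pairs) == 0L)
    stop("no candidate paired alignments; treat the pair as unmapped upstream")
  ll <- vapply(pairs, `[[`, numeric(1), "loglik")
  post <- exp(ll - logsumexp(ll))
  post <- post / sum(post)
  min_start <- vapply(pairs, function(p) {
    min(c(if (!is.null(p$aln1)) p$aln1$start_level,
          if (!is.null(p$aln2)) p$aln2$start_level))
  }, numeric(1))
  walk <- vapply(pairs, function(p)
    paste(alignment_walk_string(p$aln1), alignment_walk_string(p$aln2)),
    character(1))
  sel <- order(-post, min_start, walk)[1L]
  chosen <- pairs[[sel]]

  pos_quality <- function(mate) {
    a <- chosen[[mate]]
    if (is.null(a)) return(NULL)
    keep <- !is.na(a$read_pos) & !is.na(a$level)
    if (!any(keep)) return(data.frame(read_pos = integer(0),
                                      level = integer(0), qual = numeric(0)))
    keys <- a$read_pos[keep] * 2^26 + a$level[keep]
    if (length(pairs) == 1L) {
      qual <- rep(1, length(keys))
    } else {
      qual <- numeric(length(keys))
      for (i in seq_along(pairs)) {
        b <- pairs[[i]][[mate]]
        if (is.null(b)) next
        bk <- !is.na(b$read_pos) & !is.na(b$level)
        qual <- qual + post[i] * (keys %in% (b$read_pos[bk] * 2^26 + b$level[bk]))
      }
    }
    data.frame(read_pos = a$read_pos[keep], level = a$level[keep],
               qual = pmin(qual, 1))
  }

  structure(list(
    aln1 = chosen$aln1, aln2 = chosen$aln2,
    loglik = chosen$loglik, insert = chosen$insert, proper = chosen$proper,
    mapq = post[sel], posteriors = post, n_candidates = length(pairs),
    pos_quality1 = pos_quality("aln1"), pos_quality2 = pos_quality("aln2")),
    class = "prg_paired_alignment")
}

#' Align a read pair to the PRG
#'
#' Full per-pair driver: candidate alignments per mate, paired scoring,
#' posterior normalization and ML selection. Returns `NULL` when neither mate
#' has a seed (the pair is unmapped and excluded from genotyping).
#'
#' @param seq1,qual1,seq2,qual2 mate sequences and Phred quality strings.
#' @param prg a `prg`.
#' @param index a `prg_kmer_index`.
#' @param model a `prg_insert_model`.
#' @param params a `prg_scoring_params`.
#' @param csr optional precomputed [prg_csr()] view.
#' @return a `prg_paired_alignment` with an added `locus` field, or `NULL`.
#' @export
align_read_pair <- function(seq1, qual1, seq2, qual2, prg, index, model,
                            params = scoring_params(), csr = NULL) {
  csr <- csr %||% prg_csr(prg)
  alns1 <- align_read_to_graph(seq1, qual1, prg, index, params, csr)
  alns2 <- align_read_to_graph(seq2, qual2, prg, index, params, csr)
  pairs <- pair_and_score(alns1, alns2, model, params)
  if (length(pairs) == 0L) return(NULL)
  sel <- posterior_and_select(pairs)
  sel$locus <- assign_locus(sel, prg)
  sel
}

# majority locus over the aligned levels of the maximum-likelihood pair
assign_locus <- function(sel, prg) {
  lv <- c(if (!is.null(sel$aln1)) sel$aln1$level,
          if (!is.null(sel$aln2)) sel$aln2$level)
  lv <- lv[!is.na(lv)]
  loc <- prg$loci$locus[lv]
  loc <- loc[!is.na(loc) & loc != "spacer"]
  if (length(loc) == 0L) return(NA_character_)
  names(sort(table(loc), decreasing = TRUE))[1L]
}
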