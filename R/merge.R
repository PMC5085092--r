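# Merging tiered MSAs into a per-gene segmented alignment.
#
# The merge is anchored on "shared alleles" (allele ids present in both the
# inner, higher-resolution MSA and the outer MSA). For each shared allele the
# un-gapped inner sequence must occur as a substring of the un-gapped outer
# sequence; the consensus switch points G_L = max(P_L), G_R = min(P_R) define
# the inner-MSA column interval that replaces the corresponding outer
# sequence, and the per-allele outer flanks are re-aligned from scratch.

#' Compute consensus switch points between two MSA tiers
#'
#' For every shared allele, the 1-based inner-MSA column of its first non-gap
#' character is collected into `P_L` and the column of its last non-gap
#' character into `P_R`; the consensus switch points are `G_L = max(P_L)` and
#' `G_R = min(P_R)`. For example, a shared allele whose inner row is
#' `--ACGT...` contributes the value 3 to `P_L`.
#'
#' @param inner higher-resolution MSA (`prg_msa` or segmented gene).
#' @param outer lower-resolution MSA (`prg_msa`).
#' @return a list of class `prg_switch_points` with `P_L`, `P_R` (named
#'   integer vectors, one entry per shared allele), `G_L`, `G_R` and
#'   `shared` (the shared allele ids).
#' @export
compute_switch_points <- function(inner, outer) {
  inn <- as_gene_alignment(inner)
  stopifnot(inherits(outer, "prg_msa"))
  shared <- intersect(rownames(inn$mat), names(outer$sequences))
  if (length(shared) == 0L)
    stop("no shared alleles between tiers '", inn$tier, "' and '",
         outer$tier, "' for locus ", outer$locus,
         ": cannot anchor the merge")
  P_L <- P_R <- setNames(integer(length(shared)), shared)
  for (s in shared) {
    v <- inn$mat[s, ]
    nz <- which(!is.na(v) & v != "-")
    P_L[s] <- min(nz)
    P_R[s] <- max(nz)
    inner_seq <- chars_str(v[nz])
    outer_seq <- ungap(outer$sequences[[s]])
    if (!grepl(inner_seq, outer_seq, fixed = TRUE))
      stop("shared allele '", s, "': un-gapped inner sequence is not a ",
           "substring of the un-gapped outer sequence")
  }
  G_L <- max(P_L); G_R <- min(P_R)
  if (G_L > G_R)
    stop("consensus region empty for locus ", outer$locus,
         " (G_L = ", G_L, " > G_R = ", G_R, ")")
  structure(list(P_L = P_L, P_R = P_R, G_L = G_L, G_R = G_R, shared = shared),
            class = "prg_switch_points")
}

# normalise prg_msa / prg_segmented_gene to a common coverage-matrix view
as_gene_alignment <- function(x) {
  if (inherits(x, "prg_segmented_gene")) {
    list(mat = x$mat, features = x$features, tier = x$tier, locus = x$locus)
  } else if (inherits(x, "prg_msa")) {
    list(mat = msa_matrix(x), features = x$features, tier = x$tier,
         locus = x$locus)
  } else stop("expected a prg_msa or prg_segmented_gene")
}

#' Progressive multiple alignment of un-gapped flank sequences
#'
#' Built-in re-alignment procedure used for the outer flanks during tier
#' merging: pairwise global alignment (match +1, mismatch -1, gap -2) of each
#' sequence against the running profile, guide order = input order. An
#' external aligner may be substituted by passing any function with the same
#' contract (list of un-gapped strings in, rectangular gapped character matrix
#' out) to the merge functions.
#'
#' @param strings named character vector / list of un-gapped sequences.
#' @return character matrix (rows = inputs, columns = alignment columns).
#' @export
align_progressive <- function(strings) {
  strings <- unlist(strings)
  ids <- names(strings)
  n <- length(strings)
  if (n == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  prof <- matrix(str_chars(strings[[1L]]), nrow = 1)
  if (n > 1L) for (i in 2:n) {
    prof <- profile_align_one(prof, strings[[i]])
  }
  rownames(prof) <- ids
  prof
}

# align one un-gapped string against the running profile, returning the
# augmented profile (possibly with new all-gap columns for insertions)
profile_align_one <- function(prof, s) {
  ch <- if (nchar(s) > 0L) str_chars(s) else character(0)
  W <- ncol(prof); m <- length(ch)
  if (m == 0L) return(rbind(prof, rep("-", W)))
  if (W == 0L) {
    new <- matrix("-", nrow = nrow(prof) + 1L, ncol = m)
    new[nrow(new), ] <- ch
    return(new)
  }
  cons <- apply(prof, 2, function(col) {
    nz <- col[col != "-"]
    if (length(nz) == 0L) NA_character_ else names(sort(table(nz), decreasing = TRUE))[1L]
  })
  gap <- -2; match <- 1; mismatch <- -1
  # M[i+1, j+1]: best score aligning prof cols 1..i with chars 1..j
  M <- matrix(-Inf, W + 1L, m + 1L)
  B <- matrix(0L, W + 1L, m + 1L)   # 1 diag, 2 skip column, 3 insert column
  M[1L, ] <- gap * (0:m); B[1L, -1L] <- 3L
  skip_cost <- ifelse(is.na(cons), 0, gap)   # skipping an all-gap column is free
  M[, 1L] <- c(0, cumsum(skip_cost)); B[-1L, 1L] <- 2L
  for (i in seq_len(W)) {
    sub_sc <- if (is.na(cons[i])) rep(mismatch, m) else
      ifelse(ch == cons[i], match, mismatch)
    for (j in seq_len(m)) {
      d <- M[i, j] + sub_sc[j]
      u <- M[i, j + 1L] + skip_cost[i]
      l <- M[i + 1L, j] + gap
      best <- max(d, u, l)
      M[i + 1L, j + 1L] <- best
      B[i + 1L, j + 1L] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  # traceback: build the new row and record insertion points
  i <- W; j <- m
  row_rev <- character(0); col_src_rev <- integer(0)  # 0 = new all-gap column
  while (i > 0L || j > 0L) {
    b <- B[i + 1L, j + 1L]
    if (b == 1L) {
      row_rev <- c(row_rev, ch[j]); col_src_rev <- c(col_src_rev, i)
      i <- i - 1L; j <- j - 1L
    } else if (b == 2L) {
      row_rev <- c(row_rev, "-"); col_src_rev <- c(col_src_rev, i)
      i <- i - 1L
    } else {
      row_rev <- c(row_rev, ch[j]); col_src_rev <- c(col_src_rev, 0L)
      j <- j - 1L
    }
  }
  row <- rev(row_rev); col_src <- rev(col_src_rev)
  out <- matrix("-", nrow = nrow(prof) + 1L, ncol = length(row))
  keep <- col_src > 0L
  out[seq_len(nrow(prof)), keep] <- prof[, col_src[keep], drop = FALSE]
  out[nrow(out), ] <- row
  out
}

# Thread an un-gapped substring of an outer-only allele into an existing
# inner block (fixed width): global DP against the column-wise consensus,
# skipping all-gap columns for free. All substring characters must be placed.
thread_to_block <- function(sub, block_mat, allele = "?") {
  W <- ncol(block_mat)
  ch <- if (nchar(sub) > 0L) str_chars(sub) else character(0)
  m <- length(ch)
  if (m > W)
    stop("cannot thread allele '", allele, "' through inner block: ",
         "substring longer (", m, ") than block width (", W, ")")
  if (W == 0L) return(character(0))
  cons <- apply(block_mat, 2, function(col) {
    nz <- col[!is.na(col) & col != "-"]
    if (length(nz) == 0L) NA_character_ else names(sort(table(nz), decreasing = TRUE))[1L]
  })
  gap <- -2; match <- 1; mismatch <- -1
  M <- matrix(-Inf, W + 1L, m + 1L)
  B <- matrix(0L, W + 1L, m + 1L)   # 1 diag, 2 skip column
  skip_cost <- ifelse(is.na(cons), 0, gap)
  M[, 1L] <- c(0, cumsum(skip_cost)); B[-1L, 1L] <- 2L
  ties <- 0L
  for (i in seq_len(W)) {
    sub_sc <- if (is.na(cons[i])) rep(mismatch, m) else
      ifelse(ch == cons[i], match, mismatch)
    for (j in seq_len(m)) {
      d <- M[i, j] + sub_sc[j]
      u <- M[i, j + 1L] + skip_cost[i]
      if (d >= u) {
        if (d == u && is.finite(d)) ties <- ties + 1L
        M[i + 1L, j + 1L] <- d; B[i + 1L, j + 1L] <- 1L
      } else {
        M[i + 1L, j + 1L] <- u; B[i + 1L, j + 1L] <- 2L
      }
    }
  }
  if (!is.finite(M[W + 1L, m + 1L]))
    stop("cannot thread allele '", allele, "' through inner block")
  if (ties > 0L)
    message("threading of allele '", allele, "' through the inner block is ",
            "ambiguous (", ties, " tied DP cells); using the gap-late placement")
  row <- rep("-", W)
  i <- W; j <- m
  while (i > 0L) {
    if (B[i + 1L, j + 1L] == 1L) { row[i] <- ch[j]; j <- j - 1L }
    i <- i - 1L
  }
  row
}

#' Merge one or more inner MSA blocks into an outer MSA
#'
#' Implements the tier-merging step of PRG construction. The inner blocks
#' (e.g. one MSA per exon) are located within the outer alleles via the shared
#' alleles and the consensus switch points; for each shared allele the outer
#' sequence to the left and right of each extracted inner block is collected
#' and the flank sets are re-aligned with `realign`. Outer-only alleles are
#' cut at the consensus outer columns and their substrings threaded through
#' the inner blocks by best global alignment; inner-only alleles are carried
#' in the inner blocks and marked absent from the flank segments.
#'
#' @param inners list of inner blocks (`prg_msa` or `prg_segmented_gene`),
#'   ordered left to right along the outer sequences.
#' @param outer the outer `prg_msa`.
#' @param realign flank re-alignment procedure (see [align_progressive()]).
#' @param block_features character vector, one feature tag per inner block
#'   (used when the block itself carries no per-column features).
#' @param flank_features character vector of length `length(inners) + 1`
#'   tagging the re-aligned flank segments.
#' @return a `prg_segmented_gene`: coverage matrix `mat` (alleles x columns,
#'   `NA` where an allele is absent from a segment), per-column `features`,
#'   `tiers` and `segment` ids.
#' @export
merge_blocks <- function(inners, outer, realign = align_progressive,
                         block_features = NULL, flank_features = NULL) {
  stopifnot(inherits(outer, "prg_msa"))
  B <- length(inners)
  if (B == 0L) stop("at least one inner block is required")
  inns <- lapply(inners, as_gene_alignment)
  if (is.null(block_features)) block_features <- rep(NA_character_, B)
  if (is.null(flank_features)) flank_features <- rep(outer$tier, B + 1L)
  stopifnot(length(flank_features) == B + 1L)

  outer_ids <- names(outer$sequences)
  omat <- msa_matrix(outer)
  sp <- lapply(inns, function(inn) compute_switch_points_int(inn, outer))

  # per shared allele, locate each block's consensus-region content within the
  # un-gapped outer sequence (left to right, non-overlapping)
  mids <- list()   # per block: data.frame(allele, from, to) in outer un-gapped coords
  for (i in seq_len(B)) {
    inn <- inns[[i]]; spi <- sp[[i]]
    rows <- lapply(spi$shared, function(s) {
      v <- inn$mat[s, ]
      nz <- which(!is.na(v) & v != "-")
      l_s <- sum(nz < spi$G_L)
      sel <- nz[nz >= spi$G_L & nz <= spi$G_R]
      m_s <- length(sel)
      if (m_s == 0L)
        stop("shared allele '", s, "' has no characters inside the consensus ",
             "region of block ", i)
      I_s <- chars_str(v[nz])
      O_s <- ungap(outer$sequences[[s]])
      hits <- gregexpr(I_s, O_s, fixed = TRUE)[[1L]]
      prev_end <- if (i == 1L) 0L else mids[[i - 1L]]$to[mids[[i - 1L]]$allele == s]
      hits <- hits[hits > prev_end]
      if (length(hits) == 0L)
        stop("inner block ", i, " of shared allele '", s, "' cannot be ",
             "located after block ", i - 1L, " in the outer sequence")
      if (length(hits) > 1L)
        message("placement of inner block ", i, " in shared allele '", s,
                "' is ambiguous (", length(hits), " occurrences); using the ",
                "leftmost compatible one")
      o_s <- hits[1L]
      data.frame(allele = s, from = o_s + l_s, to = o_s + l_s + m_s - 1L,
                 stringsAsFactors = FALSE)
    })
    mids[[i]] <- do.call(rbind, rows)
  }

  # consensus outer cut columns for threading outer-only alleles
  cuts <- lapply(seq_len(B), function(i) {
    cl <- cr <- integer(0)
    for (r in seq_len(nrow(mids[[i]]))) {
      s <- mids[[i]]$allele[r]
      cols_nz <- which(omat[s, ] != "-")
      cl <- c(cl, cols_nz[mids[[i]]$from[r]])
      cr <- c(cr, cols_nz[mids[[i]]$to[r]])
    }
    c(C_L = max(cl), C_R = min(cr))
  })
  for (i in seq_len(B)) {
    if (cuts[[i]]["C_L"] > cuts[[i]]["C_R"])
      stop("shared alleles disagree on the outer coordinates of inner block ",
           i, ": consensus outer region empty")
    if (i > 1L && cuts[[i]]["C_L"] <= cuts[[i - 1L]]["C_R"])
      stop("consensus outer regions of inner blocks ", i - 1L, " and ", i,
           " overlap")
  }

  # split every outer allele into flank strings f_0..f_B and (for outer-only
  # alleles) raw mid substrings
  shared_all <- unique(unlist(lapply(sp, `[[`, "shared")))
  flanks <- lapply(seq_len(B + 1L), function(i) setNames(
    character(length(outer_ids)), outer_ids))
  mids_raw <- lapply(seq_len(B), function(i) setNames(
    rep(NA_character_, length(outer_ids)), outer_ids))
  for (id in outer_ids) {
    O <- ungap(outer$sequences[[id]])
    if (id %in% shared_all) {
      bounds <- vapply(seq_len(B), function(i) {
        r <- mids[[i]][mids[[i]]$allele == id, ]
        c(r$from, r$to)
      }, numeric(2))
      for (i in seq_len(B + 1L)) {
        from <- if (i == 1L) 1L else bounds[2L, i - 1L] + 1L
        to <- if (i == B + 1L) nchar(O) else bounds[1L, i] - 1L
        flanks[[i]][id] <- if (to >= from) substr(O, from, to) else ""
      }
    } else {
      row <- omat[id, ]
      nz_cum <- cumsum(row != "-")
      char_at <- function(col_from, col_to) {
        if (col_to < col_from) return("")
        sel <- row[col_from:col_to]
        chars_str(sel[sel != "-"])
      }
      for (i in seq_len(B + 1L)) {
        from <- if (i == 1L) 1L else cuts[[i - 1L]]["C_R"] + 1L
        to <- if (i == B + 1L) ncol(omat) else cuts[[i]]["C_L"] - 1L
        flanks[[i]][id] <- char_at(from, to)
      }
      for (i in seq_len(B))
        mids_raw[[i]][id] <- char_at(cuts[[i]]["C_L"], cuts[[i]]["C_R"])
    }
  }

  # re-align flank sets; thread outer-only alleles through the inner blocks
  flank_mats <- lapply(flanks, function(f) {
    mat <- realign(f)
    if (!is.matrix(mat) || nrow(mat) != length(f) ||
        (ncol(mat) > 0L && any(nchar(mat) != 1L)))
      stop("flank re-alignment produced a non-rectangular result")
    widths <- apply(mat, 1, function(r) sum(r != "-"))
    if (any(widths != nchar(f)))
      stop("flank re-alignment lost or added characters")
    rownames(mat) <- names(f)
    mat
  })

  inner_only <- setdiff(unique(unlist(lapply(inns, function(x) rownames(x$mat)))),
                        outer_ids)
  all_ids <- c(outer_ids, inner_only)

  block_mats <- lapply(seq_len(B), function(i) {
    inn <- inns[[i]]; spi <- sp[[i]]
    keep <- spi$G_L:spi$G_R
    # inner-only alleles must not carry sequence outside the consensus region
    outside <- setdiff(seq_len(ncol(inn$mat)), keep)
    for (id in setdiff(rownames(inn$mat), outer_ids)) {
      v <- inn$mat[id, outside]
      if (any(!is.na(v) & v != "-"))
        stop("inner-only allele '", id, "' has sequence outside the consensus ",
             "region [", spi$G_L, ", ", spi$G_R, "] of block ", i,
             "; it cannot be represented in the merged gene")
    }
    bm <- matrix(NA_character_, nrow = length(all_ids), ncol = length(keep),
                 dimnames = list(all_ids, NULL))
    bm[rownames(inn$mat), ] <- inn$mat[, keep, drop = FALSE]
    for (id in outer_ids) {
      if (!(id %in% rownames(inn$mat))) {
        bm[id, ] <- thread_to_block(mids_raw[[i]][id],
                                    inn$mat[, keep, drop = FALSE], allele = id)
      }
    }
    feats <- if (!is.null(inn$features)) inn$features[keep]
             else rep(block_features[i], length(keep))
    list(mat = bm, features = feats, tier = inn$tier)
  })

  # assemble segments: f_0 | block_1 | f_1 | ... | block_B | f_B
  seg_mats <- list(); seg_feats <- list(); seg_tiers <- list(); seg_ids <- list()
  seg <- 0L
  add_segment <- function(mat, feats, tier) {
    seg <<- seg + 1L
    seg_mats[[seg]] <<- mat
    seg_feats[[seg]] <<- feats
    seg_tiers[[seg]] <<- rep(tier, ncol(mat))
    seg_ids[[seg]] <<- rep(seg, ncol(mat))
  }
  for (i in seq_len(B)) {
    fm <- flank_mats[[i]]
    full <- matrix(NA_character_, nrow = length(all_ids), ncol = ncol(fm),
                   dimnames = list(all_ids, NULL))
    full[rownames(fm), ] <- fm
    add_segment(full, rep(flank_features[i], ncol(fm)), outer$tier)
    add_segment(block_mats[[i]]$mat, block_mats[[i]]$features,
                block_mats[[i]]$tier)
  }
  fm <- flank_mats[[B + 1L]]
  full <- matrix(NA_character_, nrow = length(all_ids), ncol = ncol(fm),
                 dimnames = list(all_ids, NULL))
  full[rownames(fm), ] <- fm
  add_segment(full, rep(flank_features[B + 1L], ncol(fm)), outer$tier)

  out <- structure(
    list(locus = outer$locus,
         mat = do.call(cbind, seg_mats),
         features = unlist(seg_feats),
         tiers = unlist(seg_tiers),
         segment = unlist(seg_ids),
         tier = outer$tier),
    class = "prg_segmented_gene"
  )
  validate_reconstruction(out, inners = inns, outer = outer)
  out
}

# thin internal wrapper so compute_switch_points can run on pre-normalised views
compute_switch_points_int <- function(inn, outer) {
  x <- inn
  class_holder <- structure(list(mat = x$mat, features = x$features,
                                 tier = x$tier, locus = x$locus),
                            class = "prg_segmented_gene")
  compute_switch_points(class_holder, outer)
}

#' Merge an inner MSA into an outer MSA (base case)
#'
#' Convenience wrapper around [merge_blocks()] for the single-block base case
#' (e.g. one exon MSA into the genomic MSA).
#'
#' @inheritParams merge_blocks
#' @param inner the single inner block.
#' @param block_feature feature tag for the inner block columns.
#' @return a `prg_segmented_gene`.
#' @export
merge_tiers <- function(inner, outer, realign = align_progressive,
                        block_feature = NA_character_,
                        flank_features = NULL) {
  merge_blocks(list(inner), outer, realign = realign,
               block_features = block_feature, flank_features = flank_features)
}

#' Build the full per-gene segmented alignment from all three tiers
#'
#' Applies the base-case merge once per exon block (exonic tier into the
#' genomic tier, left to right) and then merges the resulting gene alignment
#' into the regional-haplotype tier, which contributes the non-genic padding
#' sequence.
#'
#' @param exonic list of exonic-tier `prg_msa` blocks in gene order.
#' @param genomic genomic-tier `prg_msa`.
#' @param regional optional regional-haplotype-tier `prg_msa` (gene plus
#'   padding); if `NULL` the merged gene has no padding segments.
#' @param exon_numbers integer vector: exon number of each exonic block
#'   (used for `exon_k` feature tags).
#' @param realign flank re-alignment procedure.
#' @return a `prg_segmented_gene`.
#' @export
build_gene_msa <- function(exonic, genomic, regional = NULL,
                           exon_numbers = seq_along(exonic),
                           realign = align_progressive) {
  stopifnot(length(exon_numbers) == length(exonic))
  B <- length(exonic)
  flank_feats <- c("UTR",
                   if (B > 1L) paste0("intron_", exon_numbers[-B]) else character(0),
                   "UTR")
  gene <- merge_blocks(exonic, genomic, realign = realign,
                       block_features = paste0("exon_", exon_numbers),
                       flank_features = flank_feats)
  if (is.null(regional)) return(gene)
  merge_blocks(list(gene), regional, realign = realign,
               flank_features = c("padding", "padding"))
}

# every allele must reconstruct exactly from its row of the coverage matrix
validate_reconstruction <- function(seg, inners, outer) {
  for (id in rownames(seg$mat)) {
    v <- seg$mat[id, ]
    got <- chars_str(v[!is.na(v) & v != "-"])
    want <- if (id %in% names(outer$sequences)) {
      ungap(outer$sequences[[id]])
    } else {
      parts <- vapply(inners, function(inn) {
        if (!id %in% rownames(inn$mat)) return("")
        w <- inn$mat[id, ]
        chars_str(w[!is.na(w) & w != "-"])
      }, character(1))
      paste(parts, collapse = "")
    }
    if (!identical(got, want))
      stop("internal error: allele '", id, "' does not reconstruct after ",
           "merging (this is a bug in the merge, please report)")
  }
  invisible(TRUE)
}

#' Reconstruct an allele's un-gapped sequence from a segmented gene
#' @param seg a `prg_segmented_gene`.
#' @param allele allele id.
#' @return un-gapped sequence string.
#' @export
reconstruct_allele <- function(seg, allele) {
  stopifnot(inherits(seg, "prg_segmented_gene"))
  v <- seg$mat[allele, ]
  chars_str(v[!is.na(v) & v != "-"])
}

#' @export
print.prg_segmented_gene <- function(x, ...) {
  cat(sprintf("<prg_segmented_gene> locus=%s: %d alleles x %d columns, %d segments\n",
              x$locus, nrow(x$mat), ncol(x$mat), max(x$segment)))
  invisible(x)
}
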