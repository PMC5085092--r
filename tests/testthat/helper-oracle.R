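# Independent brute-force alignment oracle: enumerate every source-to-sink
# path sequence of a (small) PRG, align the read to each un-gapped sequence
# with a plain linear fitting affine DP, and take the best score. Written in
# pure R, independent of the C++ graph DP it is used to check.

# fitting affine alignment of `read` against one un-gapped sequence; at least
# one read base must be aligned (anchored); same scoring model as the graph
linear_fit_score <- function(path, read, eps, params) {
  p <- strsplit(path, "", fixed = TRUE)[[1]]
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(p); m <- length(r)
  NEG <- -1e18
  go <- params$gap_open; ge <- params$gap_extend
  M <- matrix(NEG, n + 1, m + 1); I <- M; D <- M
  aM <- matrix(FALSE, n + 1, m + 1); aI <- aM; aD <- aM
  M[, 1] <- 0
  best <- NEG
  for (i in 0:n) {
    for (j in 1:m) {
      cand <- c(M[i + 1, j] + go, I[i + 1, j] + ge, D[i + 1, j] + go)
      anc <- c(aM[i + 1, j], aI[i + 1, j], aD[i + 1, j])
      w <- order(-cand, !anc)[1]
      if (cand[w] > I[i + 1, j + 1]) {
        I[i + 1, j + 1] <- cand[w]; aI[i + 1, j + 1] <- anc[w]
      }
    }
    if (aM[i + 1, m + 1] && M[i + 1, m + 1] > best) best <- M[i + 1, m + 1]
    if (aI[i + 1, m + 1] && I[i + 1, m + 1] > best) best <- I[i + 1, m + 1]
    if (aD[i + 1, m + 1] && D[i + 1, m + 1] > best) best <- D[i + 1, m + 1]
    if (i == n) break
    c0 <- p[i + 1]
    for (j in 0:m) {
      cand <- c(M[i + 1, j + 1] + go, I[i + 1, j + 1] + go,
                D[i + 1, j + 1] + ge)
      anc <- c(aM[i + 1, j + 1], aI[i + 1, j + 1], aD[i + 1, j + 1])
      w <- order(-cand, !anc)[1]
      if (cand[w] > D[i + 2, j + 1]) {
        D[i + 2, j + 1] <- cand[w]; aD[i + 2, j + 1] <- anc[w]
      }
      if (j < m) {
        sc <- if (c0 == "N" || c0 == r[j + 1]) log1p(-eps[j + 1])
              else log(eps[j + 1] / 3)
        v <- max(M[i + 1, j + 1], I[i + 1, j + 1], D[i + 1, j + 1]) + sc
        if (v > M[i + 2, j + 2]) {
          M[i + 2, j + 2] <- v; aM[i + 2, j + 2] <- TRUE
        }
      }
    }
  }
  best
}

oracle_best_score <- function(prg, read, eps, params) {
  seqs <- enumerate_path_sequences(prg)
  max(vapply(seqs, linear_fit_score, numeric(1), read = read, eps = eps,
             params = params))
}

# random small PRG from a random allele matrix (SNPs + gap columns)
random_small_prg <- function(n_alleles = NULL, n_cols = NULL,
                             sub_rate = 0.15, gap_rate = 0.05,
                             max_paths = 1e4) {
  repeat {
    na <- n_alleles %||% sample(2:3, 1)
    nc <- n_cols %||% sample(8:16, 1)
    anc <- sample(c("A", "C", "G", "T"), nc, replace = TRUE)
    mat <- t(vapply(seq_len(na), function(i) {
      v <- anc
      hit <- runif(nc) < sub_rate
      v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      v[runif(nc) < gap_rate] <- "-"
      v
    }, character(nc)))
    mat[, 1] <- sample(c("A", "C", "G", "T"), na, replace = TRUE)
    rownames(mat) <- paste0("AL", seq_len(na))
    seg <- structure(list(locus = "X", mat = mat,
                          features = rep("exon_2", nc),
                          tiers = rep("genomic", nc),
                          segment = rep(1L, nc), tier = "genomic"),
                     class = "prg_segmented_gene")
    prg <- build_gene_graph(seg, pbs_exons = 2L)
    if (prod(lengths(prg$edges)) <= max_paths) return(prg)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# whole-graph forward-strand DP with clipping and pruning disabled
graph_best_score <- function(prg, read, qual, params) {
  res <- prgtyper:::align_window(read, qual, "+", 1L, prg$n_levels,
                                 prgtyper:::prg_csr(prg), params,
                                 drop = Inf, clip = -1e9)
  if (is.null(res)) -Inf else res$score
}

# draw a read from a random path of the graph, with nmut planted mismatches
read_from_graph <- function(prg, len_range = 6:14, nmut = 0L) {
  seqs <- enumerate_path_sequences(prg)
  src <- sample(seqs, 1L)
  if (nchar(src) < min(len_range)) src <- seqs[which.max(nchar(seqs))]
  len <- min(sample(len_range, 1L), nchar(src))
  a <- sample(nchar(src) - len + 1L, 1L)
  b <- a + len - 1L
  read <- substr(src, a, b)
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  for (x in sample(length(ch), min(nmut, length(ch))))
    ch[x] <- sample(c("A", "C", "G", "T"), 1L)
  paste(ch, collapse = "")
}
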