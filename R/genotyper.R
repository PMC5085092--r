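# Diploid G-group genotype inference from maximum-likelihood read alignments.
#
# For a locus with PBS levels (the peptide-binding-site exons), each aligned
# read pair r overlapping the PBS contributes observations (g_r, level): the
# read base (or read gap) placed at each PBS level by the fixed ML alignment.
# Against a candidate allele a with genotype g_a at that level,
#   L(r | a) = prod over observations of score(g_r, g_a)
#   L(r | (a1, a2)) = 1/2 L(r | a1) + 1/2 L(r | a2)
#   L(R | (a1, a2)) = prod over reads r of L(r | (a1, a2))
# and the posterior over unordered allele pairs is the normalized likelihood.

#' Extract PBS read evidence for a locus from selected paired alignments
#'
#' Only reads whose fixed maximum-likelihood alignment was assigned to the
#' locus and overlaps at least one PBS level contribute. Read bases aligned to
#' a PBS level give base observations; read deletions and gap-edge traversals
#' at a PBS level give read-gap observations. Read insertions carry no level
#' and are ignored.
#'
#' @param selected list of `prg_paired_alignment` objects (ML alignments).
#' @param prg a `prg`.
#' @param locus gene name.
#' @return a list of class `prg_read_evidence`: per read, `pbs_idx` (indices
#'   into the locus PBS levels), `obs` (read base or `-`), `eps`; plus
#'   `pbs_levels` and `locus`.
#' @export
collect_read_evidence <- function(selected, prg, locus) {
  pbs_levels <- prg$pbs[[locus]]
  if (is.null(pbs_levels)) stop("locus not in PRG: ", locus)
  reads <- list()
  for (s in selected) {
    if (!is.null(s$locus) && !is.na(s$locus) && s$locus != locus) next
    idx <- integer(0); obs <- character(0); eps <- numeric(0)
    for (mate in c("aln1", "aln2")) {
      a <- s[[mate]]
      if (is.null(a)) next
      hit <- !is.na(a$level) & a$level %in% pbs_levels
      if (!any(hit)) next
      pbs_idx <- match(a$level[hit], pbs_levels)
      ob <- ifelse(a$op[hit] == 1L, a$base[hit], "-")
      e <- ifelse(a$op[hit] == 1L, a$eps[hit], NA_real_)
      idx <- c(idx, pbs_idx); obs <- c(obs, ob); eps <- c(eps, e)
    }
    if (length(idx) > 0L)
      reads[[length(reads) + 1L]] <- list(pbs_idx = idx, obs = obs, eps = eps)
  }
  structure(list(reads = reads, pbs_levels = pbs_levels, locus = locus),
            class = "prg_read_evidence")
}

#' Log-likelihood of one aligned read given one allele PBS genotype
#'
#' Scoring per overlapping PBS position: read base matching the allele base
#' scores `log(1 - eps)`; a mismatch scores `log(eps / 3)`; a read base
#' against an allele gap takes the read-insertion penalty; a read gap against
#' an allele base takes the read-deletion penalty; gap against gap scores 0;
#' an 'N' allele base matches any read base.
#'
#' @param read one element of `prg_read_evidence$reads`.
#' @param genotype character vector: allele genotype over the PBS levels.
#' @param params a `prg_scoring_params`.
#' @return log L(r | a).
#' @export
read_likelihood <- function(read, genotype, params = scoring_params()) {
  g <- genotype[read$pbs_idx]
  o <- read$obs
  e <- read$eps
  sc <- numeric(length(o))
  read_gap <- o == "-"
  g_gap <- g == "-"
  sc[read_gap & g_gap] <- 0
  sc[read_gap & !g_gap] <- params$gap_open      # read deletion vs allele base
  sc[!read_gap & g_gap] <- params$gap_open      # read base vs allele gap
  both <- !read_gap & !g_gap
  mtch <- both & (g == o | g == "N")
  sc[mtch] <- log1p(-e[mtch])
  mism <- both & !(g == o | g == "N")
  sc[mism] <- log(e[mism] / 3)
  sum(sc)
}

# log-likelihood matrix: reads x candidate genotypes
likelihood_matrix <- function(evidence, geno_mat, params = scoring_params()) {
  n_reads <- length(evidence$reads)
  out <- matrix(0, nrow = n_reads, ncol = ncol(geno_mat),
                dimnames = list(NULL, colnames(geno_mat)))
  for (i in seq_len(n_reads)) {
    r <- evidence$reads[[i]]
    out[i, ] <- vapply(seq_len(ncol(geno_mat)), function(j)
      read_likelihood(r, geno_mat[, j], params), numeric(1))
  }
  out
}

#' Log-likelihood of the read set given an unordered allele pair
#'
#' `log L(R | (a1, a2)) = sum_r log( 1/2 L(r|a1) + 1/2 L(r|a2) )`, computed
#' stably in log space. For a homozygous pair this collapses exactly to
#' `sum_r log L(r | a)`.
#'
#' @param lm log-likelihood matrix (reads x alleles) from the evidence.
#' @param a1,a2 allele (column) names.
#' @return log L(R | (a1, a2)).
#' @export
pair_likelihood <- function(lm, a1, a2) {
  if (a1 == a2) return(sum(lm[, a1]))
  x <- lm[, a1]; y <- lm[, a2]
  hi <- pmax(x, y); lo <- pmin(x, y)
  sum(hi + log1p(exp(lo - hi)) + log(0.5))
}

#' Posterior distribution over unordered allele pairs at a locus
#'
#' Evaluates the pair likelihood for all `n (n + 1) / 2` unordered pairs
#' (including homozygous pairs) and normalizes by log-sum-exp.
#'
#' @param evidence a `prg_read_evidence`.
#' @param geno_mat character matrix: PBS levels x candidate alleles (G-group
#'   representatives), e.g. built from [allele_pbs_genotypes()].
#' @param params a `prg_scoring_params`.
#' @return a `prg_pair_posterior`: data.frame `pairs` with `a1`, `a2`,
#'   `loglik`, `posterior`, plus the `alleles` vector and the read count `n`.
#' @export
genotype_posterior <- function(evidence, geno_mat, params = scoring_params()) {
  alleles <- colnames(geno_mat)
  stopifnot(length(alleles) >= 1L)
  if (length(evidence$reads) == 0L)
    stop("no reads overlap the PBS of locus ", evidence$locus,
         ": no data, no call")
  lm <- likelihood_matrix(evidence, geno_mat, params)
  idx <- which(upper.tri(matrix(0, length(alleles), length(alleles)), diag = TRUE),
               arr.ind = TRUE)
  a1 <- alleles[idx[, 1L]]; a2 <- alleles[idx[, 2L]]
  ll <- vapply(seq_along(a1), function(i) pair_likelihood(lm, a1[i], a2[i]),
               numeric(1))
  post <- exp(ll - logsumexp(ll))
  post <- post / sum(post)
  structure(list(pairs = data.frame(a1 = a1, a2 = a2, loglik = ll,
                                    posterior = post, stringsAsFactors = FALSE),
                 alleles = alleles, n = length(evidence$reads),
                 locus = evidence$locus),
            class = "prg_pair_posterior")
}

#' Call the two best-guess alleles from a pair posterior
#'
#' The first allele is the one with the highest marginal probability of
#' occurring at least once (a homozygous pair contributes once); its marginal
#' is Q1. The second allele is chosen among pairs containing the first as the
#' pair with the highest posterior; that pair posterior is Q2. Ties are broken
#' lexicographically.
#'
#' @param post a `prg_pair_posterior`.
#' @return a list of class `prg_genotype_call` with `locus`, `allele1`, `Q1`,
#'   `allele2`, `Q2`, `n_reads`.
#' @export
call_best_guess <- function(post) {
  p <- post$pairs
  marg <- vapply(post$alleles, function(a)
    sum(p$posterior[p$a1 == a | p$a2 == a]), numeric(1))
  ord <- order(-marg, post$alleles)
  allele1 <- post$alleles[ord[1L]]
  Q1 <- unname(marg[ord[1L]])
  with1 <- p[p$a1 == allele1 | p$a2 == allele1, , drop = FALSE]
  partner <- ifelse(with1$a1 == allele1, with1$a2, with1$a1)
  ord2 <- order(-with1$posterior, partner)
  allele2 <- partner[ord2[1L]]
  Q2 <- with1$posterior[ord2[1L]]
  structure(list(locus = post$locus, allele1 = allele1, Q1 = Q1,
                 allele2 = allele2, Q2 = Q2, n_reads = post$n),
            class = "prg_genotype_call")
}

#' @export
print.prg_genotype_call <- function(x, ...) {
  cat(sprintf("<call> %s: %s (Q1=%.4f) / %s (Q2=%.4f), %d reads\n",
              x$locus, x$allele1, x$Q1, x$allele2, x$Q2, x$n_reads))
  invisible(x)
}

#' Auxiliary quality metrics for a genotype call
#'
#' `kmer_coverage`: per called allele, the proportion of the 31-mers of the
#' allele's full PRG path sequence (strand-canonicalized) that are observed in
#' the kept sample reads. `unaccounted_columns`: the number of PBS pileup
#' columns (from the fixed ML alignments, minimum depth `min_depth`) where
#' some residue reaches within-column frequency >= `freq` yet differs from
#' both called alleles' genotypes at that level.
#'
#' @param call a `prg_genotype_call`.
#' @param evidence the `prg_read_evidence` used for the call.
#' @param prg a `prg`.
#' @param ginfo result of [allele_pbs_genotypes()] for the locus.
#' @param read_kmers character vector of canonical k-mers observed in the kept
#'   reads (see [read_kmer_set()]).
#' @param k k-mer length for the coverage metric (default 31).
#' @param min_depth minimum pileup depth for the unaccounted-columns metric.
#' @param freq residue frequency threshold (default 0.2).
#' @return the call with added `kmer_coverage` (named, one per called allele)
#'   and `unaccounted_columns`.
#' @export
quality_metrics <- function(call, evidence, prg, ginfo, read_kmers,
                            k = 31L, min_depth = 5L, freq = 0.2) {
  cov <- vapply(unique(c(call$allele1, call$allele2)), function(g) {
    rep_allele <- min(ginfo$groups[[g]])
    # k-mers per coverage run: an exon-only allele contributes no spurious
    # exon-exon junction k-mers
    kms <- unlist(lapply(prg$paths[[rep_allele]], function(r)
      kmers_of(chars_str(r$labels[r$labels != "-"]), k)))
    kms <- canonical_kmers(unique(kms))
    if (length(kms) == 0L) return(NA_real_)
    mean(kms %in% read_kmers)
  }, numeric(1))

  g1 <- str_chars(ginfo$genotypes[[min(ginfo$groups[[call$allele1]])]])
  g2 <- str_chars(ginfo$genotypes[[min(ginfo$groups[[call$allele2]])]])
  idx <- unlist(lapply(evidence$reads, `[[`, "pbs_idx"))
  obs <- unlist(lapply(evidence$reads, `[[`, "obs"))
  unacc <- 0L
  for (lv in unique(idx)) {
    sel <- obs[idx == lv]
    depth <- length(sel)
    if (depth < min_depth) next
    tab <- table(sel) / depth
    bad <- names(tab)[tab >= freq & names(tab) != g1[lv] & names(tab) != g2[lv]]
    if (length(bad) > 0L) unacc <- unacc + 1L
  }
  call$kmer_coverage <- cov
  call$unaccounted_columns <- unacc
  call
}

#' Canonical k-mer set of a read collection
#' @param seqs character vector of read sequences.
#' @param k k-mer length.
#' @return character vector of distinct canonical k-mers (N-free).
#' @export
read_kmer_set <- function(seqs, k = 31L) {
  seqs <- toupper(seqs)
  # canonicalize via the k-mers of the reverse-complemented read (aligned
  # element-wise after reversal), avoiding per-k-mer reverse complements
  out <- lapply(seqs, function(s) {
    kf <- kmers_of(s, k)
    if (length(kf) == 0L) return(character(0))
    kr <- rev(kmers_of(revcomp(s), k))
    ifelse(kf <= kr, kf, kr)
  })
  kms <- unique(unlist(out))
  kms[!grepl("N", kms, fixed = TRUE)]
}

#' Genotype one locus from selected read alignments
#'
#' @param selected list of `prg_paired_alignment` (ML alignments, all loci).
#' @param prg a `prg`.
#' @param locus gene name.
#' @param read_kmers canonical k-mer set of the kept reads.
#' @param params a `prg_scoring_params`.
#' @param k k-mer length for the coverage metric.
#' @return a `prg_genotype_call` with quality metrics, or `NULL` when no read
#'   overlaps the locus PBS ("no data").
#' @export
genotype_locus <- function(selected, prg, locus, read_kmers = character(0),
                           params = scoring_params(), k = 31L) {
  ginfo <- allele_pbs_genotypes(prg, locus)
  groups <- names(ginfo$groups)
  geno_mat <- vapply(groups, function(g)
    str_chars(ginfo$genotypes[[min(ginfo$groups[[g]])]]),
    character(length(prg$pbs[[locus]])))
  if (!is.matrix(geno_mat)) geno_mat <- matrix(geno_mat, nrow = 1L,
                                               dimnames = list(NULL, groups))
  evidence <- collect_read_evidence(selected, prg, locus)
  if (length(evidence$reads) == 0L) {
    message("locus ", locus, ": no reads overlap the PBS; no call")
    return(NULL)
  }
  post <- genotype_posterior(evidence, geno_mat, params)
  call <- call_best_guess(post)
  call$posterior <- post
  quality_metrics(call, evidence, prg, ginfo, read_kmers, k = k)
}
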