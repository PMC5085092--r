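# helpers to fabricate read evidence directly (genotyper unit tests do not
# need the aligner)
ev_read <- function(idx, obs, eps = 1e-3) {
  list(pbs_idx = as.integer(idx), obs = obs, eps = rep(eps, length(obs)))
}
evidence_of <- function(reads, n_pbs, locus = "X") {
  structure(list(reads = reads, pbs_levels = seq_len(n_pbs), locus = locus),
            class = "prg_read_evidence")
}

test_that("read likelihood has the stated closed form", {
  params <- scoring_params()
  a <- strsplit("ACGTACGTAC", "")[[1]]
  b <- a; b[4] <- "G"
  eps <- 1e-3
  r <- ev_read(1:10, a, eps)
  expect_equal(read_likelihood(r, a, params), 10 * log1p(-eps),
               tolerance = 1e-12)
  # one differing overlapped column: same minus [log(1-e) - log(e/3)]
  expect_equal(read_likelihood(r, b, params),
               10 * log1p(-eps) - (log1p(-eps) - log(eps / 3)),
               tolerance = 1e-12)
  # gap and N handling
  g <- a; g[2] <- "-"
  expect_equal(read_likelihood(ev_read(2, "-"), g, params), 0)
  expect_equal(read_likelihood(ev_read(2, "C"), g, params), params$gap_open)
  expect_equal(read_likelihood(ev_read(1, "-"), a, params), params$gap_open)
  n <- a; n[1] <- "N"
  expect_equal(read_likelihood(ev_read(1, "T", eps), n, params),
               log1p(-eps), tolerance = 1e-12)
})

test_that("likelihood ratio at one Q30 column is (1-1e-3)/(1e-3/3)", {
  params <- scoring_params()
  geno <- cbind(x = c("A", "C"), y = c("A", "G"))
  ev <- evidence_of(list(ev_read(2, "C", 1e-3)), 2)
  lm <- prgtyper:::likelihood_matrix(ev, geno, params)
  expect_equal(unname(lm[1, "x"] - lm[1, "y"]),
               log((1 - 1e-3) / (1e-3 / 3)), tolerance = 1e-12)
})

test_that("homozygous collapse and pair symmetry hold to machine precision", {
  params <- scoring_params()
  set.seed(37)
  geno <- cbind(x = sample(c("A", "C", "G", "T"), 30, TRUE),
                y = sample(c("A", "C", "G", "T"), 30, TRUE))
  reads <- lapply(1:8, function(i) {
    idx <- sort(sample(30, 12))
    ev_read(idx, geno[idx, sample(2, 1)], 2e-3)
  })
  ev <- evidence_of(reads, 30)
  lm <- prgtyper:::likelihood_matrix(ev, geno, params)
  expect_identical(pair_likelihood(lm, "x", "x"), sum(lm[, "x"]))
  expect_identical(pair_likelihood(lm, "x", "y"), pair_likelihood(lm, "y", "x"))

  # two reads, two alleles: matches the hand-computed product over reads
  lm2 <- lm[1:2, , drop = FALSE]
  want <- sum(log(0.5 * exp(lm2[, "x"]) + 0.5 * exp(lm2[, "y"])))
  expect_equal(pair_likelihood(lm2, "x", "y"), want, tolerance = 1e-12)
})

test_that("genotype posterior enumerates all unordered pairs and normalizes", {
  params <- scoring_params()
  set.seed(41)
  n_all <- 5L
  geno <- vapply(seq_len(n_all), function(i)
    sample(c("A", "C", "G", "T"), 40, TRUE), character(40))
  colnames(geno) <- paste0("g", seq_len(n_all))
  reads <- lapply(1:10, function(i) {
    idx <- sort(sample(40, 15))
    ev_read(idx, geno[idx, 1], 2e-3)
  })
  post <- genotype_posterior(evidence_of(reads, 40), geno, params)
  expect_equal(nrow(post$pairs), n_all * (n_all + 1) / 2)
  expect_equal(sum(post$pairs$posterior), 1, tolerance = 1e-9)

  # single allele: homozygous pair with posterior 1
  post1 <- genotype_posterior(evidence_of(reads, 40),
                              geno[, 1, drop = FALSE], params)
  expect_equal(nrow(post1$pairs), 1L)
  expect_equal(post1$pairs$posterior, 1)
})

fake_posterior <- function(df, alleles) {
  structure(list(pairs = cbind(df, loglik = log(df$posterior)),
                 alleles = alleles, n = 10L, locus = "X"),
            class = "prg_pair_posterior")
}

test_that("best-guess calling follows the two-step marginal/pair rule", {
  # {(x,x): 0.6, (x,y): 0.4}: allele1 = x with Q1 = 1, allele2 = x with Q2 = 0.6
  p1 <- fake_posterior(data.frame(a1 = c("x", "x"), a2 = c("x", "y"),
                                  posterior = c(0.6, 0.4)), c("x", "y"))
  c1 <- call_best_guess(p1)
  expect_equal(c1$allele1, "x"); expect_equal(c1$Q1, 1.0)
  expect_equal(c1$allele2, "x"); expect_equal(c1$Q2, 0.6)

  # posterior concentrated on one heterozygous pair
  p2 <- fake_posterior(data.frame(a1 = "x", a2 = "y", posterior = 1.0),
                       c("x", "y"))
  c2 <- call_best_guess(p2)
  expect_setequal(c(c2$allele1, c2$allele2), c("x", "y"))
  expect_equal(c2$Q1, 1.0); expect_equal(c2$Q2, 1.0)

  # uniform over {(x,x),(x,y),(y,y)}: marginals tie at 2/3, lexicographic pick
  p3 <- fake_posterior(data.frame(a1 = c("x", "x", "y"), a2 = c("x", "y", "y"),
                                  posterior = rep(1 / 3, 3)), c("x", "y"))
  c3 <- call_best_guess(p3)
  expect_equal(c3$allele1, "x")
  expect_equal(c3$Q1, 2 / 3, tolerance = 1e-12)
})

test_that("true diploid pair is recovered from simulated PBS evidence", {
  # 10-allele locus, ~3% pairwise PBS divergence, ~30x coverage, 0.2% error
  params <- scoring_params()
  set.seed(43)
  n_pbs <- 270L
  anc <- sample(c("A", "C", "G", "T"), n_pbs, TRUE)
  geno <- vapply(1:10, function(i) {
    v <- anc
    hit <- runif(n_pbs) < 0.015
    v[hit] <- vapply(which(hit), function(p)
      sample(setdiff(c("A", "C", "G", "T"), v[p]), 1), character(1))
    v
  }, character(n_pbs))
  colnames(geno) <- sprintf("g%02d", 1:10)
  hits <- 0L
  n_rep <- 100L
  for (rep in seq_len(n_rep)) {
    truth <- sort(sample(colnames(geno), 2, replace = TRUE))
    reads <- lapply(seq_len(81), function(i) {
      hap <- geno[, sample(truth, 1)]
      a <- sample(n_pbs - 99L, 1)
      idx <- a:(a + 99L)
      obs <- hap[idx]
      err <- runif(100) < 0.002
      obs[err] <- vapply(which(err), function(j)
        sample(setdiff(c("A", "C", "G", "T"), obs[j]), 1), character(1))
      ev_read(idx, obs, 2e-3)
    })
    post <- genotype_posterior(evidence_of(reads, n_pbs), geno, params)
    best <- post$pairs[which.max(post$pairs$posterior), ]
    if (identical(sort(c(best$a1, best$a2)), truth)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.99)
})

test_that("adding reads consistent with the true pair never lowers its posterior", {
  params <- scoring_params()
  set.seed(47)
  geno <- vapply(1:4, function(i) sample(c("A", "C", "G", "T"), 50, TRUE),
                 character(50))
  colnames(geno) <- paste0("g", 1:4)
  truth <- c("g1", "g2")
  make_read <- function() {
    hap <- geno[, sample(truth, 1)]
    idx <- sort(sample(50, 20))
    ev_read(idx, hap[idx], 2e-3)
  }
  reads <- lapply(1:3, function(i) make_read())
  prev <- -Inf
  for (extra in 1:6) {
    reads[[length(reads) + 1L]] <- make_read()
    post <- genotype_posterior(evidence_of(reads, 50), geno, params)
    p_true <- post$pairs$posterior[post$pairs$a1 == "g1" & post$pairs$a2 == "g2"]
    expect_gte(p_true, prev - 1e-12)
    prev <- p_true
  }
})

test_that("quality metrics: planted discrepancies and k-mer coverage", {
  set.seed(53)
  base <- sample(c("A", "C", "G", "T"), 60, TRUE)
  x <- base
  y <- base; y[10] <- setdiff(c("A", "C", "G", "T"), y[10])[1]
  z <- base
  for (p in c(20L, 30L, 40L)) z[p] <- setdiff(c("A", "C", "G", "T"), c(x[p], y[p]))[1]
  prg <- prg_from_rows(c(x = paste(x, collapse = ""),
                         y = paste(y, collapse = ""),
                         z = paste(z, collapse = "")))
  ginfo <- allele_pbs_genotypes(prg, "X")

  # deep error-free evidence from z, but the call is (xG, yG): exactly the 3
  # planted columns are unaccounted for
  reads <- lapply(1:6, function(i) ev_read(1:60, z, 1e-3))
  ev <- evidence_of(reads, 60)
  call <- structure(list(locus = "X", allele1 = "xG", allele2 = "yG",
                         Q1 = 1, Q2 = 1, n_reads = 6L),
                    class = "prg_genotype_call")
  xseq <- paste(x, collapse = "")
  rk <- read_kmer_set(substring(xseq, 1:30, 31:60), k = 31L)
  out <- quality_metrics(call, ev, prg, ginfo, rk, k = 31L)
  expect_equal(out$unaccounted_columns, 3L)
  # reads tiling every 31-mer of the called allele: coverage 1.0
  expect_equal(unname(out$kmer_coverage["xG"]), 1.0)

  # homozygous truth called correctly: no unaccounted columns
  reads_x <- lapply(1:6, function(i) ev_read(1:60, x, 1e-3))
  call_x <- structure(list(locus = "X", allele1 = "xG", allele2 = "xG",
                           Q1 = 1, Q2 = 1, n_reads = 6L),
                      class = "prg_genotype_call")
  out_x <- quality_metrics(call_x, evidence_of(reads_x, 60), prg, ginfo, rk,
                           k = 31L)
  expect_equal(out_x$unaccounted_columns, 0L)

  # below the depth threshold nothing is flagged
  out_shallow <- quality_metrics(call, evidence_of(reads[1:3], 60), prg,
                                 ginfo, rk, k = 31L, min_depth = 5L)
  expect_equal(out_shallow$unaccounted_columns, 0L)
})
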