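test_that("the generator is deterministic under a fixed seed", {
  db1 <- generate_allele_db(tiny_cfg(11))
  db2 <- generate_allele_db(tiny_cfg(11))
  d1 <- tempfile(); d2 <- tempfile()
  write_allele_db(db1, d1); write_allele_db(db2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  r1 <- simulate_diploid_reads(db1, seed = 5)
  r2 <- simulate_diploid_reads(db2, seed = 5)
  expect_identical(r1$seq1, r2$seq1)
  expect_identical(r1$truth, r2$truth)
})

test_that("generated MSAs satisfy the tier invariants and preconditions", {
  for (seed in c(2, 9)) {
    db <- generate_allele_db(tiny_cfg(seed))
    for (lc in db$loci) {
      for (m in c(lc$exonic, list(lc$genomic, lc$regional))) {
        widths <- nchar(m$sequences)
        expect_true(all(widths == m$n_columns))
        expect_false(any(gsub("-", "", m$sequences) == ""))
      }
      # shared-allele substring precondition across adjacent tiers
      for (id in names(lc$genomic$sequences)) {
        gen <- gsub("-", "", lc$genomic$sequences[[id]])
        exo <- paste(vapply(lc$exonic, function(m)
          gsub("-", "", m$sequences[[id]]), character(1)), collapse = "")
        expect_true(all(vapply(lc$exonic, function(m)
          grepl(gsub("-", "", m$sequences[[id]]), gen, fixed = TRUE),
          logical(1))))
        if (id %in% names(lc$regional$sequences))
          expect_true(grepl(gen, gsub("-", "", lc$regional$sequences[[id]]),
                            fixed = TRUE))
      }
      # exon counts: more exonic than genomic than regional alleles
      expect_gte(length(lc$exonic[[1]]$sequences),
                 length(lc$genomic$sequences))
      expect_gte(length(lc$genomic$sequences),
                 length(lc$regional$sequences))
    }
  }
})

test_that("zero divergence collapses the PRG to a linear graph", {
  cfg <- tiny_cfg(3, pbs_divergence = 0, exon_divergence = 0,
                  noncoding_divergence = 0, padding_divergence = 0,
                  indel_rate = 0)
  db <- generate_allele_db(cfg)
  prg <- build_prg_from_db(db, spacer_length = 0L)
  expect_true(all(lengths(prg$edges) == 1L))
})

test_that("the paralogy option plants identical exon 2 between loci", {
  base <- function(...) sim_config(n_loci = 2L, n_exonic = 5L, n_genomic = 2L,
                                   n_regional = 2L, utr5 = 40L, utr3 = 40L,
                                   exons = c(60L, 90L), introns = 60L,
                                   padding = 60L, background_length = 2000L,
                                   pbs_divergence = 0, seed = 3L, ...)
  db <- generate_allele_db(base(paralog_exon2 = TRUE))
  e2 <- lapply(db$loci, function(lc) gsub("-", "", lc$exonic[[2]]$sequences[[1]]))
  expect_identical(e2[[1]], e2[[2]])
  # without the option the exons diverge
  db0 <- generate_allele_db(base())
  e20 <- lapply(db0$loci, function(lc) gsub("-", "", lc$exonic[[2]]$sequences[[1]]))
  expect_false(identical(e20[[1]], e20[[2]]))
})

test_that("read simulation hits the coverage target and plants honest errors", {
  db <- generate_allele_db(tiny_cfg(13))
  reads <- simulate_diploid_reads(db, seed = 3, coverage = 20)
  cfg <- db$cfg
  loc <- names(db$loci)[1]
  expected <- sum(vapply(c(reads$truth$allele1[1], reads$truth$allele2[1]),
                         function(a) {
    hap_len <- nchar(db$loci[[loc]]$haplotypes[[a]])
    max(1, round(20 / 2 * hap_len / (2 * cfg$read_length)))
  }, numeric(1)))
  expect_equal(length(reads$id), expected)
  expect_true(all(nchar(reads$seq1) == cfg$read_length))
  expect_identical(reads$origins$id, reads$id)

  # error rate 0: every read base matches its haplotype
  db0 <- db; db0$cfg$error_rate <- 0
  clean <- simulate_diploid_reads(db0, seed = 3, coverage = 10)
  for (i in seq_along(clean$id)) {
    o <- clean$origins[i, ]
    hap <- db$loci[[o$locus]]$haplotypes[[o$allele]]
    frag <- substr(hap, o$start, o$start + o$fragment_length - 1)
    left <- substr(frag, 1, db$cfg$read_length)
    right <- prgtyper:::revcomp(substr(frag,
                                       o$fragment_length - db$cfg$read_length + 1,
                                       o$fragment_length))
    if (o$swapped) expect_identical(c(clean$seq1[i], clean$seq2[i]),
                                    c(right, left))
    else expect_identical(c(clean$seq1[i], clean$seq2[i]), c(left, right))
  }
  expect_true(all(clean$origins$errors1 == 0L))
})

test_that("the toy fixture files shipped in extdata match the in-code fixture", {
  dir <- system.file("extdata", "toy_fixture", package = "prgtyper")
  expect_true(nzchar(dir))
  fx <- make_toy_fixture()
  on_disk <- read_msa(file.path(dir, "TOY.exonic.2.fasta"), "exonic", "TOY")
  expect_identical(on_disk$sequences, fx$exonic[[1]]$sequences)
  prg_disk <- build_prg_from_dir(dir, spacer_length = 0L)
  prg_code <- toy_fixture_prg()
  expect_identical(prg_disk$edges, prg_code$edges)
  expect_identical(prg_disk$paths, prg_code$paths)
})
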