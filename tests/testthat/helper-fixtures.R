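# Shared fixtures: quick graph construction from explicit allele rows, and a
# small fast simulation configuration.

# build a one-segment gene PRG directly from gapped allele rows
prg_from_rows <- function(rows, locus = "X", feature = "exon_2",
                          pbs_exons = 2L) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  seg <- structure(list(locus = locus, mat = mat,
                        features = rep(feature, ncol(mat)),
                        tiers = rep("genomic", ncol(mat)),
                        segment = rep(1L, ncol(mat)), tier = "genomic"),
                   class = "prg_segmented_gene")
  build_gene_graph(seg, pbs_exons = pbs_exons)
}

# small synthetic world that builds in well under a second
small_cfg <- function(seed, ...) {
  sim_config(n_loci = 2L, n_exonic = 6L, n_genomic = 3L, n_regional = 2L,
             utr5 = 60L, utr3 = 60L, exons = c(90L, 150L, 150L),
             introns = c(120L, 120L), padding = 150L, coverage = 20,
             seed = seed, ...)
}

# tiny world for bulk reconstruction checks
tiny_cfg <- function(seed, ...) {
  sim_config(n_loci = 1L, n_exonic = 5L, n_genomic = 2L, n_regional = 2L,
             utr5 = 40L, utr3 = 40L, exons = c(60L, 90L), introns = 60L,
             padding = 60L, coverage = 20, background_length = 2000L,
             seed = seed, ...)
}

constant_qual <- function(n, q = 30L) strrep(rawToChar(as.raw(33L + q)), n)

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# expected un-gapped input sequence of an allele in a sim db
db_true_sequence <- function(db, locus, id) {
  lc <- db$loci[[locus]]
  if (id %in% names(lc$regional$sequences))
    return(gsub("-", "", lc$regional$sequences[[id]], fixed = TRUE))
  if (id %in% names(lc$genomic$sequences))
    return(gsub("-", "", lc$genomic$sequences[[id]], fixed = TRUE))
  paste(vapply(lc$exonic, function(m)
    gsub("-", "", m$sequences[[id]], fixed = TRUE), character(1)),
    collapse = "")
}

# align all pairs of a simulated read set and genotype every locus
type_sample <- function(db, prg, index, csr, reads, k = 31L,
                        model = insert_size_model(350, 35)) {
  bg <- build_background_kmer_set(character(0), k)
  dec <- filter_read_pairs(reads, index, bg)
  sel <- list()
  for (i in which(dec$keep)) {
    s <- align_read_pair(reads$seq1[i], reads$qual1[i],
                         reads$seq2[i], reads$qual2[i],
                         prg, index, model, csr = csr)
    if (is.null(s)) next
    s$id <- reads$id[i]
    sel[[length(sel) + 1L]] <- s
  }
  rk <- read_kmer_set(c(reads$seq1[dec$keep], reads$seq2[dec$keep]), k)
  calls <- list()
  for (locus in names(prg$pbs))
    calls[[locus]] <- genotype_locus(sel, prg, locus, rk)
  list(calls = calls, selected = sel, decisions = dec)
}
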