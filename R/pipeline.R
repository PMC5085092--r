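# End-to-end orchestration: build-prg -> filter -> align -> type.
# Stages communicate through documented on-disk formats so each one is
# independently re-loadable and testable.

#' Read paired FASTQ mate files
#'
#' Mates are paired by record order; a mismatch in record counts is an error.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return list with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  for (p in c(path1, path2))
    if (!file.exists(p)) stop("FASTQ file does not exist: ", p)
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files have different record counts (", length(r1), " vs ",
         length(r2), ")")
  list(id = sub("\\s.*$", "", names(r1)),
       seq1 = as.character(r1),
       qual1 = as.character(S4Vectors::mcols(r1)$qualities),
       seq2 = as.character(r2),
       qual2 = as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write a read-pair set as two FASTQ files
#' @param pairs list with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param path1,path2 output FASTQ paths.
#' @param which optional logical/integer subset of pairs to write.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, path1, path2, which = NULL) {
  idx <- which %||% seq_along(pairs$id)
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]][idx])
    names(s) <- pairs$id[idx]
    q <- Biostrings::BStringSet(pairs[[paste0("qual", m)]][idx])
    Biostrings::writeXStringSet(s, if (m == 1L) path1 else path2,
                                format = "fastq", qualities = q)
  }
  invisible(c(path1, path2))
}

#' Load a tiered MSA directory into the structure used by the PRG builder
#'
#' Expects the naming convention of [write_allele_db()]:
#' `<locus>.exonic.<k>.fasta`, `<locus>.genomic.fasta`,
#' `<locus>.regional_haplotype.fasta` and a `loci.json` giving each locus its
#' class / PBS exon numbers.
#'
#' @param dir directory path.
#' @return list of per-locus lists (`exonic`, `genomic`, `regional`,
#'   `pbs_exons`).
#' @export
read_allele_dir <- function(dir) {
  meta_path <- file.path(dir, "loci.json")
  if (!file.exists(meta_path)) stop("missing loci.json in ", dir)
  meta <- jsonlite::read_json(meta_path)
  out <- list()
  for (loc in names(meta)) {
    exon_numbers <- if (!is.null(meta[[loc]]$exon_numbers))
      as.integer(unlist(meta[[loc]]$exon_numbers))
    else seq_len(as.integer(meta[[loc]]$n_exons))
    exonic <- lapply(exon_numbers, function(k)
      read_msa(file.path(dir, sprintf("%s.exonic.%d.fasta", loc, k)),
               tier = "exonic", locus = loc))
    genomic <- read_msa(file.path(dir, sprintf("%s.genomic.fasta", loc)),
                        tier = "genomic", locus = loc)
    reg_path <- file.path(dir, sprintf("%s.regional_haplotype.fasta", loc))
    regional <- if (file.exists(reg_path))
      read_msa(reg_path, tier = "regional_haplotype", locus = loc) else NULL
    out[[loc]] <- list(exonic = exonic, genomic = genomic,
                       regional = regional, exon_numbers = exon_numbers,
                       pbs_exons = as.integer(unlist(meta[[loc]]$pbs_exons)))
  }
  out
}

#' Build the joint PRG from an MSA directory
#' @param dir directory as read by [read_allele_dir()].
#' @param spacer_length inter-gene spacer length.
#' @return a `prg`.
#' @export
build_prg_from_dir <- function(dir, spacer_length = 2000L) {
  tiers <- read_allele_dir(dir)
  genes <- lapply(tiers, function(lc) {
    seg <- build_gene_msa(lc$exonic, lc$genomic, lc$regional,
                          exon_numbers = lc$exon_numbers)
    build_gene_graph(seg, pbs_exons = lc$pbs_exons)
  })
  build_joint_prg(unname(genes), spacer_length = spacer_length)
}

# ---- alignment record format -------------------------------------------------
# One row per selected paired alignment and mate. Columns are encoded as a
# token string in walk order: 'M<base><qual>' aligned base, 'I<base><qual>'
# read insertion, 'D' read deletion, 'G' gap-edge traversal. Together with
# start_level, strand, clips and read length this reconstructs the alignment.

encode_alignment_cols <- function(a) {
  tok <- character(length(a$op))
  for (i in seq_along(a$op)) {
    tok[i] <- switch(a$op[i],
      paste0("M", a$base[i], eps_to_phred_char(a$eps[i])),   # 1
      paste0("I", a$base[i], eps_to_phred_char(a$eps[i])),   # 2
      "D",                                                   # 3
      "G")                                                   # 4
  }
  paste(tok, collapse = "")
}

decode_alignment_cols <- function(s, strand, start_level, clip_left, read_len,
                                  eps_floor = 1e-4, eps_ceiling = 0.75) {
  ops <- integer(0); base <- character(0); eps <- numeric(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    c0 <- substr(s, i, i)
    if (c0 %in% c("M", "I")) {
      ops <- c(ops, if (c0 == "M") 1L else 2L)
      base <- c(base, substr(s, i + 1L, i + 1L))
      eps <- c(eps, phred_to_eps(substr(s, i + 2L, i + 2L), eps_floor, eps_ceiling))
      i <- i + 3L
    } else {
      ops <- c(ops, if (c0 == "D") 3L else 4L)
      base <- c(base, NA_character_); eps <- c(eps, NA_real_)
      i <- i + 1L
    }
  }
  lv <- rep(NA_integer_, length(ops))
  adv <- ops %in% c(1L, 3L, 4L)
  lv[adv] <- start_level - 1L + cumsum(adv)[adv]
  rp_local <- rep(NA_integer_, length(ops))
  consume <- ops %in% c(1L, 2L)
  rp_local[consume] <- clip_left + cumsum(consume)[consume]
  rp <- if (strand == "+") rp_local else read_len - rp_local + 1L
  list(level = lv, op = ops, base = base, eps = eps, read_pos = rp)
}

#' Write selected paired alignments to a TSV
#' @param selected list of `prg_paired_alignment` (with `id` and `locus`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(selected, path) {
  rows <- list()
  for (s in selected) {
    for (m in 1:2) {
      a <- s[[paste0("aln", m)]]
      if (is.null(a)) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id %||% NA_character_, mate = m,
        locus = s$locus %||% NA_character_,
        strand = a$strand, start_level = a$start_level,
        clip_left = a$clip_left, clip_right = a$clip_right,
        read_len = a$read_len, score = a$score,
        mapq = s$mapq, pair_loglik = s$loglik,
        insert = s$insert, proper = s$proper,
        cols = encode_alignment_cols(a), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read selected paired alignments back from a TSV
#' @param path TSV written by [write_alignments()].
#' @param params scoring parameters (for the quality decoding bounds).
#' @return list of `prg_paired_alignment`-shaped records (alignment columns,
#'   locus, mapq; candidate posteriors are not retained on disk).
#' @export
read_alignments <- function(path, params = scoring_params()) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$id)) {
    sub <- df[df$id == id, , drop = FALSE]
    rec <- list(id = id, locus = sub$locus[1L], mapq = sub$mapq[1L],
                loglik = sub$pair_loglik[1L], insert = sub$insert[1L],
                proper = sub$proper[1L], aln1 = NULL, aln2 = NULL)
    for (r in seq_len(nrow(sub))) {
      d <- decode_alignment_cols(sub$cols[r], sub$strand[r],
                                 sub$start_level[r], sub$clip_left[r],
                                 sub$read_len[r],
                                 params$eps_floor, params$eps_ceiling)
      lv <- d$level[!is.na(d$level)]
      a <- structure(list(strand = sub$strand[r], score = sub$score[r],
                          start_level = min(lv), end_level = max(lv),
                          clip_left = sub$clip_left[r],
                          clip_right = sub$clip_right[r],
                          level = d$level, op = d$op, label = NULL,
                          base = d$base, eps = d$eps, read_pos = d$read_pos,
                          read_len = sub$read_len[r]),
                     class = "prg_graph_alignment")
      rec[[paste0("aln", sub$mate[r])]] <- a
    }
    out[[length(out) + 1L]] <- structure(rec, class = "prg_paired_alignment")
  }
  out
}

# ---- run configuration -------------------------------------------------------

#' Pipeline configuration
#'
#' Unknown keys are rejected. The resolved configuration is echoed into the
#' output directory for provenance.
#'
#' @param msa_dir tiered MSA directory (see [read_allele_dir()]).
#' @param background_fasta un-gapped FASTA of reference sequence outside the
#'   PRG (background k-mer set); `NULL` for an empty background.
#' @param r1,r2 FASTQ mate files.
#' @param out_dir output directory.
#' @param k k-mer size for index, filter and coverage metric.
#' @param spacer_length inter-gene spacer.
#' @param loci loci to type (`NULL` = all in the PRG).
#' @param insert_mean,insert_sd insert-size model; `NULL` = estimate from the
#'   kept reads by median/MAD.
#' @param thresholds a `prg_filter_thresholds`.
#' @param scoring a `prg_scoring_params`.
#' @param min_depth minimum pileup depth for the unaccounted-columns metric.
#' @param verbose emit progress messages.
#' @param ... rejected (catches unknown keys).
#' @return list of class `prg_run_config`.
#' @export
run_config <- function(msa_dir, r1, r2, out_dir,
                       background_fasta = NULL,
                       k = 31L, spacer_length = 2000L, loci = NULL,
                       insert_mean = NULL, insert_sd = NULL,
                       thresholds = filter_thresholds(),
                       scoring = scoring_params(),
                       min_depth = 5L, verbose = TRUE, ...) {
  extra <- list(...)
  if (length(extra) > 0L)
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  structure(list(msa_dir = msa_dir, background_fasta = background_fasta,
                 r1 = r1, r2 = r2, out_dir = out_dir, k = as.integer(k),
                 spacer_length = as.integer(spacer_length), loci = loci,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 thresholds = thresholds, scoring = scoring,
                 min_depth = as.integer(min_depth), verbose = isTRUE(verbose)),
            class = "prg_run_config")
}

#' Run the full typing pipeline
#'
#' build-prg, filter, align and type in sequence, writing every intermediate
#' artifact (`prg.txt` + sidecar, kept FASTQs, `filter_decisions.tsv`,
#' `alignments.tsv`, `calls.tsv`, `config.json`) to the output directory.
#' Deterministic given the configuration.
#'
#' @param cfg a `prg_run_config`.
#' @return list with `calls` (data.frame), `prg`, `decisions`, `selected`,
#'   and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "prg_run_config"))
  for (p in c(cfg$r1, cfg$r2))
    if (!file.exists(p)) stop("input read file does not exist: ", p)
  if (!dir.exists(cfg$msa_dir)) stop("MSA directory does not exist: ", cfg$msa_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (cfg$verbose) message("[prgtyper] ", ...)

  say("building PRG from ", cfg$msa_dir)
  prg <- build_prg_from_dir(cfg$msa_dir, spacer_length = cfg$spacer_length)
  write_prg(prg, file.path(cfg$out_dir, "prg.txt"))

  say("indexing graph k-mers (k = ", cfg$k, ")")
  index <- build_graph_kmer_index(prg, k = cfg$k)
  background <- if (!is.null(cfg$background_fasta)) {
    build_background_kmer_set(
      Biostrings::readDNAStringSet(cfg$background_fasta), k = cfg$k)
  } else build_background_kmer_set(character(0), k = cfg$k)

  say("filtering read pairs")
  pairs <- read_fastq_pairs(cfg$r1, cfg$r2)
  decisions <- filter_read_pairs(pairs, index, background, cfg$thresholds)
  write.table(decisions, file.path(cfg$out_dir, "filter_decisions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- which(decisions$keep)
  say(length(kept), " of ", length(pairs$id), " pairs kept")
  write_fastq_pairs(pairs, file.path(cfg$out_dir, "kept_1.fastq"),
                    file.path(cfg$out_dir, "kept_2.fastq"), which = kept)

  csr <- prg_csr(prg)
  model <- resolve_insert_model(cfg, pairs, kept, prg, index, csr)
  say("aligning ", length(kept), " pairs (insert model: mean = ",
      round(model$mean, 1), ", sd = ", round(model$sd, 1), ")")
  selected <- list()
  for (i in kept) {
    s <- align_read_pair(pairs$seq1[i], pairs$qual1[i],
                         pairs$seq2[i], pairs$qual2[i],
                         prg, index, model, cfg$scoring, csr)
    if (is.null(s)) next
    s$id <- pairs$id[i]
    selected[[length(selected) + 1L]] <- s
  }
  write_alignments(selected, file.path(cfg$out_dir, "alignments.tsv"))

  say("genotyping")
  read_kmers <- read_kmer_set(c(pairs$seq1[kept], pairs$seq2[kept]), k = cfg$k)
  loci <- cfg$loci %||% names(prg$pbs)
  calls <- list()
  for (locus in loci) {
    call <- genotype_locus(selected, prg, locus, read_kmers,
                           params = cfg$scoring, k = cfg$k)
    if (is.null(call)) next
    for (chrom in 1:2) {
      allele <- if (chrom == 1L) call$allele1 else call$allele2
      calls[[length(calls) + 1L]] <- data.frame(
        Locus = locus, Chromosome = chrom, Allele = allele,
        Q = if (chrom == 1L) call$Q1 else call$Q2,
        KmerCoverage = unname(call$kmer_coverage[allele]),
        UnaccountedColumns = call$unaccounted_columns,
        NReads = call$n_reads, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls) > 0L) do.call(rbind, calls) else
    data.frame(Locus = character(0), Chromosome = integer(0),
               Allele = character(0), Q = numeric(0),
               KmerCoverage = numeric(0), UnaccountedColumns = integer(0),
               NReads = integer(0))
  write.table(calls, file.path(cfg$out_dir, "calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  echo <- cfg
  echo$thresholds <- unclass(cfg$thresholds)
  echo$scoring <- unclass(cfg$scoring)
  jsonlite::write_json(unclass(echo), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  say("done: ", file.path(cfg$out_dir, "calls.tsv"))
  list(calls = calls, prg = prg, decisions = decisions, selected = selected,
       out_dir = cfg$out_dir)
}

# insert-size model: configured, or estimated from up to 200 kept pairs
# aligned under a broad provisional model
resolve_insert_model <- function(cfg, pairs, kept, prg, index, csr) {
  if (!is.null(cfg$insert_mean) && !is.null(cfg$insert_sd))
    return(insert_size_model(cfg$insert_mean, cfg$insert_sd))
  provisional <- insert_size_model(400, 150)
  probe <- head(kept, 200L)
  inserts <- numeric(0)
  for (i in probe) {
    s <- align_read_pair(pairs$seq1[i], pairs$qual1[i],
                         pairs$seq2[i], pairs$qual2[i],
                         prg, index, provisional, cfg$scoring, csr)
    if (!is.null(s) && isTRUE(s$proper)) inserts <- c(inserts, s$insert)
  }
  if (length(inserts) < 10L) return(provisional)
  estimate_insert_model(inserts)
}
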