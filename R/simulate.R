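# Synthetic IMGT-like allele databases and paired-end read simulation.
#
# The generator emulates the layered structure of an HLA-style allele
# database: several paralogous loci derived from one family ancestor; many
# exonic alleles, fewer genomic alleles, and a couple of regional haplotypes
# with non-genic padding; allelic divergence concentrated in the
# peptide-binding-site exons; indels in introns. Homology is tracked during
# simulation, so tier MSAs are exact by construction and no aligner is
# needed to produce them.

#' Simulation configuration
#'
#' Defaults describe a compact HLA-like world: 3 paralogous loci (alternating
#' class I-like, PBS = exons 2+3, and class II-like, PBS = exon 2), 10 exonic
#' alleles of which 4 have genomic sequence and 2 sit on regional haplotypes,
#' ~1.5 kb gene bodies with 3 exons, 500 bp padding, ~10% inter-locus
#' divergence, 2% per-allele substitution rate in the PBS exons, paired-end
#' 2 x 100 bp reads at 30x with 0.2% base error.
#'
#' @param n_loci number of paralogous loci.
#' @param n_exonic,n_genomic,n_regional alleles per tier
#'   (`n_regional <= n_genomic <= n_exonic`).
#' @param utr5,utr3,exons,introns gene layout in bp (`length(introns) ==
#'   length(exons) - 1`).
#' @param pbs_divergence per-base substitution rate per allele (vs the locus
#'   ancestor) in PBS exons; pairwise allele divergence is about twice this.
#' @param exon_divergence same, for non-PBS exons.
#' @param noncoding_divergence same, for introns and UTRs.
#' @param inter_locus_divergence expected pairwise divergence between loci.
#' @param padding_divergence per-base substitution rate between regional
#'   haplotypes in the padding.
#' @param indel_rate expected indels per intron per allele.
#' @param indel_max maximum indel length (lengths uniform on 1..indel_max).
#' @param padding padding length per side (bp).
#' @param read_length,fragment_mean,fragment_sd,error_rate,coverage read
#'   simulation parameters (fragment length = full outer distance).
#' @param background_length length of the unrelated background reference.
#' @param paralog_exon2 if `TRUE`, all locus ancestors share exon 2 verbatim
#'   (a worst-case paralogy fixture for mis-mapping studies; allelic variation
#'   within exon 2 still applies).
#' @param seed integer seed; every generator output is reproducible from it.
#' @return a list of class `prg_sim_config`.
#' @export
sim_config <- function(n_loci = 3L, n_exonic = 10L, n_genomic = 4L,
                       n_regional = 2L,
                       utr5 = 100L, utr3 = 100L,
                       exons = c(150L, 270L, 276L), introns = c(200L, 200L),
                       pbs_divergence = 0.02, exon_divergence = 0.005,
                       noncoding_divergence = 0.01,
                       inter_locus_divergence = 0.10,
                       padding_divergence = 0.002,
                       indel_rate = 0.2, indel_max = 6L,
                       padding = 500L,
                       read_length = 100L, fragment_mean = 350,
                       fragment_sd = 35, error_rate = 0.002, coverage = 30,
                       background_length = 20000L, paralog_exon2 = FALSE,
                       seed = 1L) {
  stopifnot(n_regional <= n_genomic, n_genomic <= n_exonic,
            length(introns) == length(exons) - 1L,
            pbs_divergence >= 0, pbs_divergence <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(as.list(environment()), class = "prg_sim_config")
}

rand_seq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  chars
}

# per-position feature map of the gene body
gene_feature_map <- function(cfg) {
  feats <- c(rep("UTR", cfg$utr5))
  for (i in seq_along(cfg$exons)) {
    feats <- c(feats, rep(paste0("exon_", i), cfg$exons[i]))
    if (i < length(cfg$exons))
      feats <- c(feats, rep(paste0("intron_", i), cfg$introns[i]))
  }
  c(feats, rep("UTR", cfg$utr3))
}

#' Generate a synthetic tiered allele database
#'
#' @param cfg a `prg_sim_config`.
#' @return an object of class `prg_sim_db`: per locus the exonic-tier MSAs
#'   (one per exon), the genomic and regional-haplotype MSAs, full haplotype
#'   sequences (padding + gene + padding) for every allele, and the true
#'   G-group membership; plus the background reference sequence and `cfg`.
#' @export
generate_allele_db <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "prg_sim_config"))
  set.seed(cfg$seed)
  feats <- gene_feature_map(cfg)
  L <- length(feats)
  pbs_feats_of <- function(class)
    paste0("exon_", if (class == "I") c(2L, 3L) else 2L)
  family_gene <- rand_seq(L)
  family_padL <- rand_seq(cfg$padding)
  family_padR <- rand_seq(cfg$padding)
  classes <- rep(c("I", "II"), length.out = cfg$n_loci)

  loci <- list()
  for (li in seq_len(cfg$n_loci)) {
    locus <- sprintf("GENE%d", li)
    class <- classes[li]
    pbs_exons <- if (class == "I") c(2L, 3L) else 2L
    anc <- mutate_chars(family_gene, cfg$inter_locus_divergence / 2)
    if (isTRUE(cfg$paralog_exon2))
      anc[feats == "exon_2"] <- family_gene[feats == "exon_2"]
    padL <- mutate_chars(family_padL, cfg$inter_locus_divergence / 2)
    padR <- mutate_chars(family_padR, cfg$inter_locus_divergence / 2)
    pbs_pos <- feats %in% pbs_feats_of(class)
    exon_pos <- grepl("^exon_", feats) & !pbs_pos
    nc_pos <- !pbs_pos & !exon_pos

    alleles <- list()
    for (ai in seq_len(cfg$n_exonic)) {
      id <- sprintf("%s*%03d", locus, ai)
      sub <- anc
      sub[pbs_pos] <- mutate_chars(anc[pbs_pos], cfg$pbs_divergence)
      sub[exon_pos] <- mutate_chars(anc[exon_pos], cfg$exon_divergence)
      sub[nc_pos] <- mutate_chars(anc[nc_pos], cfg$noncoding_divergence)
      del <- rep(FALSE, L)
      ins <- list()
      for (ii in seq_along(cfg$introns)) {
        span <- which(feats == paste0("intron_", ii))
        # keep indels away from region boundaries so exon blocks stay clean
        safe <- span[(10L + cfg$indel_max):(length(span) - 10L - cfg$indel_max)]
        n_ind <- rpois(1L, cfg$indel_rate)
        for (j in seq_len(n_ind)) {
          len <- sample.int(cfg$indel_max, 1L)
          at <- sample(safe, 1L)
          if (runif(1) < 0.5) {
            del[at:(at + len - 1L)] <- TRUE
          } else {
            ins[[as.character(at)]] <- chars_str(rand_seq(len))
          }
        }
      }
      alleles[[id]] <- list(id = id, sub = sub, del = del, ins = ins)
    }
    ids <- names(alleles)

    gene_seq <- function(a, range = seq_len(L)) {
      base <- a$sub[range]
      base[a$del[range]] <- ""
      ins_here <- a$ins[names(a$ins) %in% as.character(range)]
      if (length(ins_here) > 0L) {
        at <- match(as.integer(names(ins_here)), range)
        base[at] <- paste0(base[at], unlist(ins_here))
      }
      paste(base, collapse = "")
    }

    tier_msa <- function(sel_ids, range, tier) {
      sel <- alleles[sel_ids]
      ins_w <- integer(length(range))
      for (a in sel) {
        at <- match(as.integer(names(a$ins)), range)
        ok <- !is.na(at)
        if (any(ok))
          ins_w[at[ok]] <- pmax(ins_w[at[ok]], nchar(unlist(a$ins))[ok])
      }
      col_feats <- rep(feats[range], times = 1L + ins_w)
      width <- sum(1L + ins_w)
      idx_base <- cumsum(1L + ins_w) - ins_w
      rows <- vapply(sel, function(a) {
        row <- rep("-", width)
        row[idx_base] <- ifelse(a$del[range], "-", a$sub[range])
        at <- match(as.integer(names(a$ins)), range)
        ok <- which(!is.na(at))
        for (j in ok) {
          s <- str_chars(a$ins[[j]])
          row[idx_base[at[j]] + seq_along(s)] <- s
        }
        chars_str(row)
      }, character(1))
      msa(setNames(rows, sel_ids), tier = tier, locus = locus,
          features = col_feats)
    }

    exonic <- lapply(seq_along(cfg$exons), function(k)
      tier_msa(ids, which(feats == paste0("exon_", k)), "exonic"))
    genomic <- tier_msa(ids[seq_len(cfg$n_genomic)], seq_len(L), "genomic")

    reg_ids <- ids[seq_len(cfg$n_regional)]
    reg_gene <- tier_msa(reg_ids, seq_len(L), "regional_haplotype")
    reg_rows <- vapply(reg_ids, function(id) {
      pl <- mutate_chars(padL, cfg$padding_divergence)
      pr <- mutate_chars(padR, cfg$padding_divergence)
      paste0(chars_str(pl), reg_gene$sequences[[id]], chars_str(pr))
    }, character(1))
    regional <- msa(setNames(reg_rows, reg_ids), tier = "regional_haplotype",
                    locus = locus,
                    features = c(rep("padding", cfg$padding),
                                 reg_gene$features,
                                 rep("padding", cfg$padding)))

    haplotypes <- vapply(ids, function(id)
      paste0(chars_str(padL), gene_seq(alleles[[id]]), chars_str(padR)),
      character(1))

    pbs_key <- vapply(ids, function(id) {
      paste(vapply(pbs_exons, function(k)
        gene_seq(alleles[[id]], which(feats == paste0("exon_", k))),
        character(1)), collapse = "|")
    }, character(1))
    members <- split(ids, pbs_key[ids])
    truth_groups <- setNames(rep(vapply(members, function(m)
      paste0(min(m), "G"), character(1)), lengths(members)), unlist(members))

    loci[[locus]] <- list(locus = locus, class = class, pbs_exons = pbs_exons,
                          exonic = exonic, genomic = genomic,
                          regional = regional, alleles = ids,
                          haplotypes = haplotypes,
                          truth_groups = truth_groups[ids])
  }

  background <- chars_str(rand_seq(cfg$background_length))
  structure(list(cfg = cfg, loci = loci,
                 background = c(background_1 = background)),
            class = "prg_sim_db")
}

#' @export
print.prg_sim_db <- function(x, ...) {
  cat(sprintf("<prg_sim_db> %d loci (%s); %d/%d/%d alleles per tier\n",
              length(x$loci), paste(names(x$loci), collapse = ", "),
              x$cfg$n_exonic, x$cfg$n_genomic, x$cfg$n_regional))
  invisible(x)
}

#' Build the joint PRG from a synthetic database
#' @param db a `prg_sim_db`.
#' @param spacer_length spacer length between genes (see [build_joint_prg()]).
#' @return a `prg`.
#' @export
build_prg_from_db <- function(db, spacer_length = 2000L) {
  genes <- lapply(db$loci, function(lc) {
    seg <- build_gene_msa(lc$exonic, lc$genomic, lc$regional,
                          exon_numbers = seq_along(lc$exonic))
    build_gene_graph(seg, pbs_exons = lc$pbs_exons)
  })
  build_joint_prg(unname(genes), spacer_length = spacer_length)
}

#' Simulate paired-end reads for diploid samples with known truth
#'
#' Fragments are drawn uniformly along each haplotype (padding + gene +
#' padding) with normal fragment lengths, FR orientation and random fragment
#' strand; substitution errors are planted at `cfg$error_rate` and quality
#' strings encode the planted error rate.
#'
#' @param db a `prg_sim_db`.
#' @param truth optional data.frame with columns `locus`, `allele1`,
#'   `allele2`; if `NULL`, a diploid genotype is drawn per locus (alleles
#'   sampled with replacement, so homozygous loci occur).
#' @param coverage target total coverage per locus (split over the two
#'   haplotypes); defaults to `db$cfg$coverage`.
#' @param seed RNG seed for this sample.
#' @return a list of class `prg_sim_reads`: `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, plus `truth` (locus/allele/G-group table) and `origins`
#'   (per-read origin and planted error counts).
#' @export
simulate_diploid_reads <- function(db, truth = NULL, coverage = NULL,
                                   seed = 1L) {
  cfg <- db$cfg
  coverage <- coverage %||% cfg$coverage
  set.seed(seed)
  if (is.null(truth)) {
    truth <- do.call(rbind, lapply(names(db$loci), function(loc) {
      picks <- sample(db$loci[[loc]]$alleles, 2L, replace = TRUE)
      data.frame(locus = loc, allele1 = picks[1L], allele2 = picks[2L],
                 stringsAsFactors = FALSE)
    }))
  }
  truth$group1 <- mapply(function(l, a) db$loci[[l]]$truth_groups[[a]],
                         truth$locus, truth$allele1)
  truth$group2 <- mapply(function(l, a) db$loci[[l]]$truth_groups[[a]],
                         truth$locus, truth$allele2)

  rl <- cfg$read_length
  id <- seq1 <- qual1 <- seq2 <- qual2 <- character(0)
  origins <- list()
  qchar <- eps_to_phred_char(max(cfg$error_rate, 1e-4))
  for (t in seq_len(nrow(truth))) {
    loc <- truth$locus[t]
    for (hap in 1:2) {
      allele <- truth[[paste0("allele", hap)]][t]
      hseq <- db$loci[[loc]]$haplotypes[[allele]]
      Lh <- nchar(hseq)
      n_pairs <- max(1L, round(coverage / 2 * Lh / (2 * rl)))
      for (i in seq_len(n_pairs)) {
        repeat {
          flen <- round(rnorm(1L, cfg$fragment_mean, cfg$fragment_sd))
          if (flen >= rl && flen <= Lh) break
        }
        start <- sample.int(Lh - flen + 1L, 1L)
        frag <- substr(hseq, start, start + flen - 1L)
        left <- substr(frag, 1L, rl)
        right <- revcomp(substr(frag, flen - rl + 1L, flen))
        e1 <- plant_errors(left, cfg$error_rate)
        e2 <- plant_errors(right, cfg$error_rate)
        swap <- runif(1) < 0.5
        rid <- sprintf("sim:%s:h%d:%s:%d", loc, hap, allele, i)
        id <- c(id, rid)
        if (swap) {
          seq1 <- c(seq1, e2$seq); seq2 <- c(seq2, e1$seq)
        } else {
          seq1 <- c(seq1, e1$seq); seq2 <- c(seq2, e2$seq)
        }
        qual1 <- c(qual1, strrep(qchar, rl))
        qual2 <- c(qual2, strrep(qchar, rl))
        origins[[length(origins) + 1L]] <- data.frame(
          id = rid, locus = loc, allele = allele, start = start,
          fragment_length = flen, swapped = swap,
          errors1 = if (swap) e2$n else e1$n,
          errors2 = if (swap) e1$n else e2$n, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(id = id, seq1 = seq1, qual1 = qual1,
                 seq2 = seq2, qual2 = qual2,
                 truth = truth, origins = do.call(rbind, origins)),
            class = "prg_sim_reads")
}

plant_errors <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  ch <- str_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = chars_str(ch), n = length(hit))
}

#' The shipped toy fixture: tiered MSAs of the canonical three-tier shape
#'
#' A single-exon class II-like toy locus with 4 exonic alleles, 2 genomic
#' alleles and 2 regional haplotypes (2 shared identifiers per tier
#' boundary). The shared allele `TOY*01` has the exonic row `--ACGTAC`, so
#' its first non-gap character sits in column 3 and the switch-point rule
#' contributes the value 3 to `P_L`.
#'
#' @return list with `exonic` (list of one `prg_msa`), `genomic`, `regional`,
#'   `locus`, `exon_numbers`, `pbs_exons`.
#' @export
make_toy_fixture <- function() {
  exonic <- msa(c("TOY*01" = "--ACGTAC",
                  "TOY*02" = "TTACGTAC",
                  "TOY*03" = "--ACGAAC",
                  "TOY*04" = "--ACGA-C"),
                tier = "exonic", locus = "TOY",
                features = rep("exon_2", 8L))
  genomic <- msa(c("TOY*01" = "CCTGA--ACGTACTGACC",
                   "TOY*02" = "CCTGATTACGTACTGACC"),
                 tier = "genomic", locus = "TOY")
  regional <- msa(c("TOY*01" = "AACCGCCTGA--ACGTACTGACCCGGTT",
                    "TOY*02" = "AACCGCCTGATTACGTACTGACCCGGTT"),
                  tier = "regional_haplotype", locus = "TOY")
  list(exonic = list(exonic), genomic = genomic, regional = regional,
       locus = "TOY", exon_numbers = 2L, pbs_exons = 2L)
}

#' Build the toy fixture's gene PRG
#' @return a `prg` for the toy locus.
#' @export
toy_fixture_prg <- function() {
  fx <- make_toy_fixture()
  seg <- build_gene_msa(fx$exonic, fx$genomic, fx$regional,
                        exon_numbers = fx$exon_numbers)
  build_gene_graph(seg, pbs_exons = fx$pbs_exons)
}

#' Write a synthetic database to a directory of standard files
#'
#' Naming convention: `<locus>.exonic.<k>.fasta` (one aligned FASTA per exon),
#' `<locus>.genomic.fasta`, `<locus>.regional_haplotype.fasta`,
#' `background.fasta`, and `loci.json` (per-locus class, exon count and PBS
#' exon numbers).
#'
#' @param db a `prg_sim_db`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_allele_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (loc in names(db$loci)) {
    lc <- db$loci[[loc]]
    for (k in seq_along(lc$exonic))
      write_msa(lc$exonic[[k]], file.path(dir, sprintf("%s.exonic.%d.fasta", loc, k)))
    write_msa(lc$genomic, file.path(dir, sprintf("%s.genomic.fasta", loc)))
    write_msa(lc$regional, file.path(dir, sprintf("%s.regional_haplotype.fasta", loc)))
    meta[[loc]] <- list(class = lc$class, n_exons = length(lc$exonic),
                        exon_numbers = seq_along(lc$exonic),
                        pbs_exons = lc$pbs_exons)
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(db$background),
    file.path(dir, "background.fasta"))
  jsonlite::write_json(meta, file.path(dir, "loci.json"))
  invisible(dir)
}
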