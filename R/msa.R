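# Tiered multiple sequence alignments: the raw material of PRG construction.

MSA_TIERS <- c("exonic", "genomic", "regional_haplotype")

#' Construct an MSA object
#'
#' A rectangular, gapped alignment of named allele sequences at one input tier
#' (exonic, genomic or regional haplotype). Sequences are uppercase strings
#' over `A,C,G,T,N,-`; every sequence has the same number of columns and at
#' least one non-gap character.
#'
#' @param sequences named character vector of gapped sequences (allele id ->
#'   gapped string). IMGT-style `.` gaps are accepted and normalised to `-`.
#' @param tier one of `"exonic"`, `"genomic"`, `"regional_haplotype"`.
#' @param locus gene name.
#' @param features optional character vector, one feature tag per column
#'   (e.g. `"exon_2"`, `"intron_1"`, `"UTR"`, `"padding"`); used to annotate
#'   PRG levels downstream.
#' @return an object of class `prg_msa` with fields `tier`, `locus`,
#'   `sequences`, `n_columns`, `features`.
#' @export
msa <- function(sequences, tier, locus, features = NULL) {
  tier <- match.arg(tier, MSA_TIERS)
  if (length(sequences) == 0L) stop("MSA for locus ", locus, " is empty")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all MSA sequences must be named with allele ids")
  if (anyDuplicated(ids))
    stop("duplicate allele ids in MSA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- toupper(sequences)
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged alignment: record ", bad, " ('", ids[bad], "') has length ",
         widths[bad], " but record 1 has length ", widths[1L])
  }
  bad_chars <- gsub("[ACGTN-]", "", sequences)
  if (any(nchar(bad_chars) > 0L)) {
    offender <- which(nchar(bad_chars) > 0L)[1L]
    stop("sequence '", ids[offender], "' contains characters outside ",
         "{A,C,G,T,N,-}: '", substr(bad_chars[offender], 1L, 5L), "'")
  }
  if (any(gsub("-", "", sequences, fixed = TRUE) == ""))
    stop("MSA sequence consists only of gaps: ",
         ids[which(gsub("-", "", sequences, fixed = TRUE) == "")[1L]])
  n_columns <- unname(widths[1L])
  if (!is.null(features) && length(features) != n_columns)
    stop("features must have one entry per column")
  structure(
    list(tier = tier, locus = locus, sequences = sequences,
         n_columns = n_columns, features = features),
    class = "prg_msa"
  )
}

#' Read an aligned FASTA file into an MSA
#'
#' Accepts the IMGT alignment dialect: `.` is treated as a gap and normalised
#' to `-`; `*` (unknown sequence) is rejected with an explicit message since a
#' wildcard row cannot be threaded through the graph.
#'
#' @param path aligned FASTA file.
#' @inheritParams msa
#' @return a `prg_msa` object.
#' @export
read_msa <- function(path, tier, locus) {
  if (!file.exists(path)) stop("MSA file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    offender <- names(seqs)[grepl("*", seqs, fixed = TRUE)][1L]
    stop("record '", offender, "' in ", path, " contains '*' (unknown ",
         "sequence in the IMGT dialect); such records cannot be used for ",
         "graph construction and must be removed upstream")
  }
  msa(seqs, tier = tier, locus = locus)
}

#' Write an MSA as aligned FASTA
#' @param x a `prg_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "prg_msa"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x$sequences), path)
  invisible(path)
}

#' @export
print.prg_msa <- function(x, ...) {
  cat(sprintf("<prg_msa> locus=%s tier=%s: %d alleles x %d columns\n",
              x$locus, x$tier, length(x$sequences), x$n_columns))
  invisible(x)
}

# character matrix view (alleles x columns) used by the merge machinery
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$sequences, "", fixed = TRUE))
  rownames(m) <- names(x$sequences)
  m
}
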